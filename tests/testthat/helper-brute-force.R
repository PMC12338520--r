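# Independent brute-force likelihood oracle: enumerates every hidden event
# sequence (dud pattern, per-cycle detachment, Edman outcome, bleach pattern)
# and sums probability x Gaussian emission density. Exponential in dyes and
# cycles; only usable on tiny instances.

bf_log_dnorm <- function(x, mean, sd) {
  if (sd > 0) return(dnorm(x, mean, sd, log = TRUE))
  if (abs(x - mean) < 1e-9) 0 else -Inf
}

bf_emission <- function(read_col, alive, ch, em, n_channels) {
  le <- 0
  for (c in seq_len(n_channels)) {
    cc <- sum(alive & ch == c)
    le <- le + bf_log_dnorm(read_col[c], cc * em$mu,
                            sqrt(cc * em$sigma^2 + em$sigma_bg^2))
  }
  le
}

# recursive enumeration over cycles; returns linear-domain likelihood
bf_loglik <- function(read, f, em, n_channels = f$n_channels) {
  pos <- which(f$labels > 0L)
  ch <- f$labels[pos]
  nd <- length(pos)
  n_t <- em$n_cycles + as.integer(em$initial_image)
  stopifnot(ncol(read) == n_t)

  recurse <- function(cycle, t_img, alive, removed, acc_log) {
    if (cycle > em$n_cycles) return(exp(acc_log))
    total <- 0
    for (detach in c(FALSE, TRUE)) {
      p1 <- if (detach) em$p_detach else 1 - em$p_detach
      if (p1 == 0) next
      a1 <- if (detach) rep(FALSE, nd) else alive
      for (succ in c(TRUE, FALSE)) {
        p2 <- if (succ) 1 - em$p_edman_fail else em$p_edman_fail
        if (p2 == 0) next
        rem2 <- removed + succ
        a2 <- a1 & (pos > rem2)
        live_idx <- which(a2)
        # enumerate bleach outcomes of currently fluorescing dyes
        n_live <- length(live_idx)
        for (mask in 0:(2^n_live - 1)) {
          keep <- live_idx[bitwAnd(mask, bitwShiftL(1L, seq_len(n_live) - 1L)) > 0L]
          n_keep <- length(keep)
          p3 <- em$p_bleach^(n_live - n_keep) * (1 - em$p_bleach)^n_keep
          if (p3 == 0) next
          a3 <- rep(FALSE, nd); a3[keep] <- TRUE
          le <- bf_emission(read[, t_img], a3, ch, em, n_channels)
          total <- total + p1 * p2 * p3 *
            recurse(cycle + 1L, t_img + 1L, a3, rem2, acc_log + le)
        }
      }
    }
    total
  }

  total <- 0
  denom <- 1 - em$p_dud^nd
  for (mask in 1:(2^nd - 1)) {
    a0 <- bitwAnd(mask, bitwShiftL(1L, seq_len(nd) - 1L)) > 0L
    p0 <- (1 - em$p_dud)^sum(a0) * em$p_dud^(nd - sum(a0)) / denom
    acc <- if (em$initial_image)
      bf_emission(read[, 1], a0, ch, em, n_channels) else 0
    total <- total + p0 * recurse(1L, 1L + as.integer(em$initial_image),
                                  a0, 0L, acc)
  }
  log(total)
}
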