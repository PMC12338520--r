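#' Oracle posterior over fluorescence strings
#'
#' An artificial posterior estimator for benchmarking: it knows the true
#' generating string of a read and returns
#' `(1 - e) * [f == f_true] + e / |D_F|`, i.e. a point mass at the truth
#' flattened towards uniform by the error rate `e`. With `e = 0` it is an
#' ideal classifier; with `e = 1` it is uninformative.
#'
#' @param true_string index of the generating string in the universe.
#' @param e oracle error rate in `[0, 1]`.
#' @param n_strings size of the string universe `|D_F|` (null string
#'   included).
#' @return Dense posterior vector of length `n_strings`, summing to 1.
#' @export
oracle_posterior <- function(true_string, e, n_strings) {
  stopifnot(e >= 0, e <= 1, true_string >= 1, true_string <= n_strings)
  p <- rep(e / n_strings, n_strings)
  p[true_string] <- p[true_string] + (1 - e)
  p
}

#' Sparse top-N posteriors
#'
#' Container for truncated per-read posteriors: for each read the `n_b`
#' highest-posterior strings `G_k` with their probabilities, plus a uniform
#' per-string residual `r_k = (1 - sum_{G_k} P) / |D_F|` spread over the
#' whole universe (members of `G_k` included), so each sparsified vector
#' sums to exactly 1.
#'
#' @param top_index integer matrix `n_b x n_reads` of string indices, one
#'   column per read, sorted by decreasing probability (ties by ascending
#'   index).
#' @param top_prob matching matrix of posterior probabilities.
#' @param residual numeric vector of per-string residuals `r_k`.
#' @param n_strings universe size `|D_F|`.
#' @param read_id optional read identifiers.
#' @return Object of class `sparse_posteriors`.
#' @export
sparse_posteriors <- function(top_index, top_prob, residual, n_strings,
                              read_id = NULL) {
  top_index <- as.matrix(top_index); top_prob <- as.matrix(top_prob)
  stopifnot(identical(dim(top_index), dim(top_prob)),
            length(residual) == ncol(top_index),
            nrow(top_index) <= n_strings, all(residual >= -1e-12))
  mass <- colSums(top_prob) + n_strings * residual
  if (any(abs(mass - 1) > 1e-9))
    stop("sparse posterior mass != 1", call. = FALSE)
  structure(list(top_index = top_index, top_prob = top_prob,
                 residual = pmax(residual, 0), n_strings = as.integer(n_strings),
                 read_id = read_id),
            class = "sparse_posteriors")
}

#' @export
print.sparse_posteriors <- function(x, ...) {
  cat("<sparse posteriors:", ncol(x$top_index), "reads, top",
      nrow(x$top_index), "of", x$n_strings, "strings>\n")
  invisible(x)
}

#' Number of reads covered by a posterior set
#' @param posteriors a `sparse_posteriors` or dense posterior matrix.
#' @return Read count.
#' @export
n_reads <- function(posteriors) {
  if (inherits(posteriors, "sparse_posteriors")) ncol(posteriors$top_index)
  else nrow(posteriors)
}

#' Truncate posteriors to their top-N strings
#'
#' Keeps, per read, the `n_b` strings with the highest posterior probability
#' (ties broken by lower string index) and spreads the discarded mass
#' uniformly over the full universe. With `n_b = |D_F|` the sparsified
#' posterior equals the dense one (residual 0).
#'
#' @param posterior dense posterior vector, or a dense matrix with one read
#'   per row.
#' @param n_b number of strings to retain per read.
#' @param read_id optional read identifiers.
#' @return A [sparse_posteriors()] object.
#' @export
sparsify <- function(posterior, n_b, read_id = NULL) {
  if (is.null(dim(posterior)))
    posterior <- matrix(posterior, nrow = 1L)
  d <- ncol(posterior)
  n_b <- min(as.integer(n_b), d)
  stopifnot(n_b >= 1L)
  n <- nrow(posterior)
  top_index <- matrix(0L, n_b, n)
  top_prob <- matrix(0, n_b, n)
  for (k in seq_len(n)) {
    # decreasing value, ties by ascending index (radix is stable)
    ord <- order(posterior[k, ], -seq_len(d), decreasing = TRUE,
                 method = "radix")[seq_len(n_b)]
    top_index[, k] <- ord
    top_prob[, k] <- posterior[k, ord]
  }
  residual <- (1 - colSums(top_prob)) / d
  sparse_posteriors(top_index, top_prob, residual, d, read_id)
}

#' Oracle posteriors for a whole dataset, sparsified
#'
#' Convenience wrapper building [sparse_posteriors()] for every read from
#' its true generating string without materializing dense vectors.
#'
#' @param true_string integer vector of generating-string indices.
#' @param e oracle error rate.
#' @param n_strings universe size `|D_F|`.
#' @param n_b strings retained per read (default: all).
#' @return A [sparse_posteriors()] object.
#' @export
oracle_posteriors <- function(true_string, e, n_strings, n_b = n_strings) {
  n_b <- min(as.integer(n_b), n_strings)
  stopifnot(e >= 0, e <= 1, n_b >= 1L)
  n <- length(true_string)
  base <- e / n_strings
  if (e < 1) {
    # truth is the unique argmax; remaining slots fill with lowest indices
    filler <- matrix(rep(seq_len(n_b), n), n_b, n) # candidate low indices
    top_index <- matrix(0L, n_b, n)
    top_index[1L, ] <- true_string
    if (n_b > 1L) {
      for (k in seq_len(n)) {
        rest <- setdiff(seq_len(n_b), true_string[k])[seq_len(n_b - 1L)]
        top_index[-1L, k] <- rest
      }
    }
    top_prob <- matrix(base, n_b, n)
    top_prob[1L, ] <- base + (1 - e)
  } else {
    top_index <- matrix(rep(seq_len(n_b), n), n_b, n)
    top_prob <- matrix(base, n_b, n)
  }
  residual <- rep((1 - n_b * base - if (e < 1) (1 - e) else 0) / n_strings, n)
  sparse_posteriors(top_index, top_prob, residual, n_strings)
}

# ---------------------------------------------------------------------------
# Exact Bayes HMM likelihood under the simulator's generative model.
#
# Hidden state: (k, m) where k is the number of residues removed so far and
# m the set of dyes still fluorescing; all zero-dye situations (detachment,
# full bleaching, complete removal) collapse into one absorbing dark state.
# Blocking is not modeled (simulations keep it at 0).
# ---------------------------------------------------------------------------

# Enumerate states and transition matrix for string f under error model em.
build_string_hmm <- function(f, em, n_channels = f$n_channels,
                             state_cap = 4096L) {
  nd <- f$dye_count
  if (nd == 0L) stop("f_null has no likelihood model", call. = FALSE)
  if (2^nd > state_cap)
    stop("dye-state space 2^", nd, " exceeds cap ", state_cap,
         "; prune the string universe or raise state_cap", call. = FALSE)
  if (em$p_block_init > 0 || em$p_block_cyclic > 0)
    warning("blocking probabilities are ignored by the HMM likelihood")
  pos <- which(f$labels > 0L)
  ch <- f$labels[pos]
  L <- length(f$labels)

  # state 1 = dark; live states indexed by (k, mask)
  k_of <- integer(0); mask_of <- integer(0)
  id_of <- vector("list", L)            # id_of[[k+1]][mask] -> state id
  n_s <- 1L
  for (k in 0:(L - 1L)) {
    elig <- which(pos > k)
    if (length(elig) == 0L) { id_of[[k + 1L]] <- integer(0); next }
    masks <- integer(2^nd)
    # nonempty subsets of elig, encoded as bitmasks over dyes 1..nd
    subs <- subsets_of(elig, nd)
    ids <- integer(0)
    for (mk in subs) {
      n_s <- n_s + 1L
      k_of <- c(k_of, k); mask_of <- c(mask_of, mk)
      ids[as.character(mk)] <- n_s
    }
    id_of[[k + 1L]] <- ids
  }

  lookup <- function(k, mk) {
    if (mk == 0L || k >= L) return(1L)
    id_of[[k + 1L]][[as.character(mk)]]
  }

  # per-state channel counts (dark first, all zero)
  counts <- matrix(0L, n_s, n_channels)
  for (s in seq_len(n_s - 1L)) {
    dyes <- which(bitwAnd(mask_of[s], bitwShiftL(1L, seq_len(nd) - 1L)) > 0L)
    counts[s + 1L, ] <- tabulate(ch[dyes], nbins = n_channels)
  }

  # transitions
  ti <- tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  add(1L, 1L, 1)
  pb <- em$p_bleach
  for (s in seq_len(n_s - 1L)) {
    from <- s + 1L
    k <- k_of[s]; mk <- mask_of[s]
    if (em$p_detach > 0) add(from, 1L, em$p_detach)
    for (succ in c(TRUE, FALSE)) {
      w <- (1 - em$p_detach) *
        (if (succ) 1 - em$p_edman_fail else em$p_edman_fail)
      if (w == 0) next
      k1 <- if (succ) k + 1L else k
      m1 <- mk
      if (succ) {
        hit <- which(pos == k1)
        if (length(hit) == 1L)
          m1 <- bitwAnd(m1, bitwNot(bitwShiftL(1L, hit - 1L)))
      }
      dyes1 <- which(bitwAnd(m1, bitwShiftL(1L, seq_len(nd) - 1L)) > 0L)
      if (length(dyes1) == 0L) { add(from, 1L, w); next }
      for (sub in c(0L, subsets_of(dyes1, nd))) {
        nkeep <- sum(bitwAnd(sub, bitwShiftL(1L, seq_len(nd) - 1L)) > 0L)
        wb <- w * pb^(length(dyes1) - nkeep) * (1 - pb)^nkeep
        if (wb > 0) add(from, lookup(k1, sub), wb)
      }
    }
  }
  trans <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_s, n_s))

  # initial distribution: dud draws conditioned on >= 1 functional dye
  init <- numeric(n_s)
  denom <- 1 - em$p_dud^nd
  for (mk in subsets_of(seq_len(nd), nd)) {
    nkeep <- sum(bitwAnd(mk, bitwShiftL(1L, seq_len(nd) - 1L)) > 0L)
    init[lookup(0L, mk)] <- init[lookup(0L, mk)] +
      (1 - em$p_dud)^nkeep * em$p_dud^(nd - nkeep) / denom
  }

  list(trans_t = Matrix::t(trans), init = init, counts = counts, n_s = n_s)
}

# all nonempty subsets of dye indices `elig`, as bitmasks over 1..nd
subsets_of <- function(elig, nd) {
  out <- 0L
  for (d in elig) out <- c(out, bitwOr(out, bitwShiftL(1L, d - 1L)))
  out <- unique(out)
  out[out != 0L]
}

log_dnorm_safe <- function(x, mean, sd) {
  if (sd > 0) return(stats::dnorm(x, mean, sd, log = TRUE))
  ifelse(abs(x - mean) < 1e-9, 0, -Inf)
}

#' Exact read log-likelihood given a fluorescence string
#'
#' Marginal likelihood `log P(x | F = f)` of one or more reads under the
#' simulator's generative process (dud conditioning, detachment, Edman
#' failure, bleaching, Gaussian intensities), computed exactly by the
#' forward algorithm over the hidden dye-survival state space. Blocking is
#' not modeled.
#'
#' @param reads intensity matrix (channels x timepoints) or array
#'   (channels x timepoints x reads).
#' @param f a `fluorescence_string` with at least one dye.
#' @param em an [error_model()] matching the read dimensions.
#' @param n_channels instrument channel count.
#' @param state_cap maximum size of the per-string dye-state space.
#' @return Numeric vector of log-likelihoods, one per read.
#' @export
hmm_loglikelihood <- function(reads, f, em = error_model(),
                              n_channels = f$n_channels,
                              state_cap = 4096L) {
  if (length(dim(reads)) == 2L)
    reads <- array(reads, dim = c(dim(reads), 1L))
  n_t <- n_timepoints(em)
  stopifnot(dim(reads)[1] == n_channels, dim(reads)[2] == n_t)
  hmm <- build_string_hmm(f, em, n_channels, state_cap)
  forward_loglik(hmm, reads, em)
}

forward_loglik <- function(hmm, reads, em) {
  n <- dim(reads)[3]
  n_t <- dim(reads)[2]
  n_ch <- dim(reads)[1]
  # distinct channel-count rows to evaluate emissions once per group
  grp_key <- apply(hmm$counts, 1L, paste, collapse = ",")
  grp <- match(grp_key, unique(grp_key))
  ucounts <- hmm$counts[!duplicated(grp_key), , drop = FALSE]
  n_u <- nrow(ucounts)

  A <- matrix(hmm$init, hmm$n_s, n)
  logscale <- numeric(n)
  for (t in seq_len(n_t)) {
    if (t > 1L || !em$initial_image)
      A <- as.matrix(hmm$trans_t %*% A)
    LEu <- matrix(0, n_u, n)
    for (u in seq_len(n_u)) {
      for (c in seq_len(n_ch)) {
        cc <- ucounts[u, c]
        sd <- sqrt(cc * em$sigma^2 + em$sigma_bg^2)
        LEu[u, ] <- LEu[u, ] + log_dnorm_safe(reads[c, t, ], cc * em$mu, sd)
      }
    }
    LE <- LEu[grp, , drop = FALSE]
    mx <- apply(LE, 2L, max)
    ok <- is.finite(mx)
    W <- exp(sweep(LE, 2L, ifelse(ok, mx, 0)))
    W[, !ok] <- 0
    A <- A * W
    s <- colSums(A)
    logscale <- logscale + ifelse(s > 0, log(s) + ifelse(ok, mx, 0), -Inf)
    s[s == 0] <- 1
    A <- sweep(A, 2L, s, "/")
  }
  logscale
}

#' Exact Bayes posterior over fluorescence strings
#'
#' Applies Bayes' rule with a uniform prior over strings: the posterior is
#' the softmax over the non-null universe of [hmm_loglikelihood()] values.
#' The read-wise normalizer is never materialized. The null string gets
#' posterior 0.
#'
#' @param reads intensity matrix or array (see [hmm_loglikelihood()]).
#' @param model a `proteome_model`.
#' @param em an [error_model()].
#' @param state_cap forwarded to [hmm_loglikelihood()].
#' @return Dense posterior matrix, reads x strings; rows sum to 1.
#' @export
exact_posterior <- function(reads, model, em = error_model(),
                            state_cap = 4096L) {
  if (length(dim(reads)) == 2L)
    reads <- array(reads, dim = c(dim(reads), 1L))
  n <- dim(reads)[3]
  d <- n_strings(model)
  n_ch <- model$scheme$n_channels
  LL <- matrix(-Inf, n, d)
  for (s in 2:d)
    LL[, s] <- hmm_loglikelihood(reads, model$strings[[s]], em, n_ch,
                                 state_cap)
  mx <- apply(LL, 1L, max)
  P <- exp(LL - mx)
  P / rowSums(P)
}
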