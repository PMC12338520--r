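#' Fluorosequencing error model
#'
#' Collects the per-cycle and per-dye error probabilities and the intensity
#' model of the simulated instrument. Defaults are the standard small-scale
#' simulation conditions: 11 Edman cycles, 6% Edman failure, 5% detachment,
#' 5% bleaching and 7% dud dyes per cycle/dye, dye intensity 10000 +/- 1600
#' (a.u.) and background noise s.d. 66.7. Blocking, an artifact that halts
#' further Edman degradation, is supported by the simulator but defaults to
#' 0 and is not modeled by the classifiers.
#'
#' @param n_cycles number of Edman degradation cycles.
#' @param p_edman_fail per-cycle probability that the removal chemistry fails.
#' @param p_detach per-cycle probability that the peptide detaches from the
#'   surface (all dyes vanish permanently).
#' @param p_bleach per-cycle per-dye photobleaching probability.
#' @param p_dud per-dye probability that the fluorophore is non-functional
#'   from the start; identical to the dud rate `m` of [build_model()].
#' @param p_block_init probability the peptide is blocked before cycle 1.
#' @param p_block_cyclic per-cycle blocking probability.
#' @param mu mean single-dye light intensity (arbitrary units).
#' @param sigma per-dye intensity standard deviation; with c active dyes the
#'   summed signal is Normal(c*mu, sqrt(c)*sigma) (independent emitters).
#' @param sigma_bg background-noise standard deviation per channel per image.
#' @param initial_image include a pre-Edman image as the first timepoint.
#' @return Object of class `error_model`.
#' @export
error_model <- function(n_cycles = 11L, p_edman_fail = 0.06,
                        p_detach = 0.05, p_bleach = 0.05, p_dud = 0.07,
                        p_block_init = 0, p_block_cyclic = 0,
                        mu = 10000, sigma = 1600, sigma_bg = 66.7,
                        initial_image = TRUE) {
  probs <- c(p_edman_fail = p_edman_fail, p_detach = p_detach,
             p_bleach = p_bleach, p_dud = p_dud,
             p_block_init = p_block_init, p_block_cyclic = p_block_cyclic)
  if (any(probs < 0) || any(probs >= 1))
    stop("all error probabilities must lie in [0, 1)", call. = FALSE)
  stopifnot(n_cycles >= 1L, mu > 0, sigma >= 0, sigma_bg >= 0)
  structure(
    list(n_cycles = as.integer(n_cycles), p_edman_fail = p_edman_fail,
         p_detach = p_detach, p_bleach = p_bleach, p_dud = p_dud,
         p_block_init = p_block_init, p_block_cyclic = p_block_cyclic,
         mu = mu, sigma = sigma, sigma_bg = sigma_bg,
         initial_image = isTRUE(initial_image)),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model:", x$n_cycles, "Edman cycles; edman_fail", x$p_edman_fail,
      "detach", x$p_detach, "bleach", x$p_bleach, "dud", x$p_dud, "\n")
  cat("  intensity", x$mu, "+/-", x$sigma, "; background sd", x$sigma_bg,
      if (x$initial_image) "; initial image on" else "", "\n")
  invisible(x)
}

#' Whole-proteome simulation conditions
#'
#' Preset error models for proteome-scale runs: 39 Edman cycles with either
#' the standard error rates or the "improved chemistry" variant in which all
#' failure probabilities are reduced 100-fold and the per-dye intensity
#' spread 10-fold (background unchanged).
#'
#' @param improved use the reduced-error parameter column.
#' @return An [error_model()].
#' @export
proteome_error_model <- function(improved = FALSE) {
  if (improved)
    error_model(n_cycles = 39L, p_edman_fail = 6e-4, p_detach = 5e-4,
                p_bleach = 5e-4, p_dud = 7e-4, sigma = 160)
  else
    error_model(n_cycles = 39L)
}

n_timepoints <- function(em) em$n_cycles + as.integer(em$initial_image)

#' Sample a relative-abundance vector
#'
#' Draws i.i.d. unit-rate exponential variables and normalizes them to the
#' simplex (equivalently, a flat Dirichlet draw). At proteome scale this
#' yields abundances spanning several orders of magnitude.
#'
#' @param n_proteins number of proteins.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return Protein-space `abundance_vector`.
#' @export
sample_abundances <- function(n_proteins, seed) {
  stopifnot(n_proteins >= 1L)
  set.seed(seed)
  x <- stats::rexp(n_proteins)
  abundance_vector(x / sum(x), "protein")
}

#' Generate random protein sequences
#'
#' Synthetic stand-in proteins for tests and benchmarks: i.i.d. uniform
#' draws over the 20 standard residues. These are not biological sequences.
#'
#' @param n number of proteins.
#' @param length_range integer range of sequence lengths (uniform).
#' @param seed RNG seed.
#' @return Named character vector of sequences (`synthetic_1`, ...).
#' @export
random_proteins <- function(n, length_range = c(80L, 160L), seed = 1L) {
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("synthetic_", seq_len(n))
  seqs
}

# Vectorized simulation of n replicate reads of one fluorescence string.
# Returns list(intensities = array (n_channels, n_t, n), n_rejected).
simulate_string_reads <- function(f, n, em, n_channels = f$n_channels) {
  nd <- f$dye_count
  if (nd == 0L)
    stop("f_null cannot generate a read", call. = FALSE)
  pos <- which(f$labels > 0L)
  ch <- f$labels[pos]
  n_t <- n_timepoints(em)

  # dud draws conditioned on >= 1 functional dye (rejection, counted)
  alive <- matrix(stats::runif(n * nd) >= em$p_dud, n, nd)
  n_rejected <- 0L
  repeat {
    bad <- which(rowSums(alive) == 0L)
    if (length(bad) == 0L) break
    n_rejected <- n_rejected + length(bad)
    alive[bad, ] <- stats::runif(length(bad) * nd) >= em$p_dud
  }

  blocked <- stats::runif(n) < em$p_block_init
  removed <- integer(n)              # Edman count per read
  out <- array(0, dim = c(n_channels, n_t, n))
  t_img <- 0L

  record <- function(alive, out, t_img) {
    for (c in seq_len(n_channels)) {
      idx <- which(ch == c)
      cnt <- if (length(idx)) rowSums(alive[, idx, drop = FALSE]) else
        numeric(n)
      sd <- sqrt(cnt * em$sigma^2 + em$sigma_bg^2)
      out[c, t_img, ] <- stats::rnorm(n, cnt * em$mu, sd)
    }
    out
  }

  if (em$initial_image) {
    t_img <- t_img + 1L
    out <- record(alive, out, t_img)
  }

  for (cycle in seq_len(em$n_cycles)) {
    detach <- stats::runif(n) < em$p_detach
    alive[detach, ] <- FALSE
    succ <- !blocked & (stats::runif(n) >= em$p_edman_fail)
    removed <- removed + succ
    for (d in seq_len(nd)) {
      gone <- succ & removed >= pos[d]
      alive[gone, d] <- FALSE
    }
    blocked <- blocked | (stats::runif(n) < em$p_block_cyclic)
    alive <- alive & matrix(stats::runif(n * nd) >= em$p_bleach, n, nd)
    t_img <- t_img + 1L
    out <- record(alive, out, t_img)
  }
  list(intensities = out, n_rejected = n_rejected)
}

#' Simulate a single fluorosequencing read
#'
#' Runs the generative error process for one molecule of fluorescence string
#' `f`. Event order within a cycle: detachment, Edman removal (unless
#' blocked), cyclic blocking, bleaching, imaging. Dud dyes are drawn first
#' and the read is conditioned on at least one functional dye.
#'
#' @param f a `fluorescence_string` with at least one dye.
#' @param em an [error_model()].
#' @param n_channels channel count of the instrument (defaults to the
#'   string's scheme).
#' @return Intensity matrix, channels x timepoints.
#' @export
simulate_read <- function(f, em = error_model(), n_channels = f$n_channels) {
  simulate_string_reads(f, 1L, em, n_channels)$intensities[, , 1L,
                                                           drop = FALSE][, , 1L]
}

#' Simulate a read dataset from a proteome model
#'
#' Draws, for each read, a generating protein from the indicator
#' distribution q and a fluorescence string from that protein's conditional
#' distribution (jointly equivalent to sampling the marginal string
#' distribution), then simulates the intensity matrix of each read. In pool
#' mode a shared pool of `pool_size` reads per string is pre-simulated and
#' reads are drawn from the pools with replacement; both modes have the same
#' read distribution.
#'
#' @param model a `proteome_model`.
#' @param p true protein-space abundance vector.
#' @param n_reads number of reads.
#' @param em an [error_model()]; its `p_dud` should equal the model's
#'   `dud_rate` for the observability conditioning to be consistent.
#' @param seed RNG seed; the dataset is deterministic given seed and inputs.
#' @param pool_size optional reads-per-string pool size (pool mode).
#' @param intensities simulate intensity matrices (set `FALSE` to generate
#'   only the generating-string truth, e.g. for oracle-classifier studies).
#' @return Object of class `fluor_dataset`: `intensities` (array channels x
#'   timepoints x reads, or NULL), `true_string`, `true_protein`, `true_p`,
#'   `seed`, `error_model`, `n_rejected`.
#' @export
generate_dataset <- function(model, p, n_reads, em = error_model(),
                             seed = 1L, pool_size = NULL,
                             intensities = TRUE) {
  stopifnot(n_reads >= 1L)
  if (!is.null(pool_size) && pool_size < 1L)
    stop("pool_size must be >= 1", call. = FALSE)
  set.seed(seed)
  q <- protein_to_indicator(p, model)
  n_p <- nrow(model$cond_FI)
  true_protein <- sample.int(n_p, n_reads, replace = TRUE,
                             prob = as.numeric(q))
  true_string <- integer(n_reads)
  for (y in unique(true_protein)) {
    idx <- which(true_protein == y)
    cols <- model$support[[y]]
    pr <- model$cond_FI[y, cols]
    true_string[idx] <- if (length(cols) == 1L) cols else
      cols[sample.int(length(cols), length(idx), replace = TRUE, prob = pr)]
  }

  inten <- NULL
  n_rejected <- 0L
  if (intensities) {
    n_ch <- model$scheme$n_channels
    inten <- array(NA_real_, dim = c(n_ch, n_timepoints(em), n_reads))
    for (s in sort(unique(true_string))) {
      idx <- which(true_string == s)
      if (is.null(pool_size)) {
        sim <- simulate_string_reads(model$strings[[s]], length(idx), em,
                                     n_ch)
        inten[, , idx] <- sim$intensities
      } else {
        sim <- simulate_string_reads(model$strings[[s]], pool_size, em, n_ch)
        take <- sample.int(pool_size, length(idx), replace = TRUE)
        inten[, , idx] <- sim$intensities[, , take, drop = FALSE]
      }
      n_rejected <- n_rejected + sim$n_rejected
    }
  }

  structure(
    list(intensities = inten, true_string = true_string,
         true_protein = true_protein,
         true_p = abundance_vector(as.numeric(p), "protein"), seed = seed,
         error_model = em, n_rejected = n_rejected),
    class = "fluor_dataset"
  )
}

#' @export
print.fluor_dataset <- function(x, ...) {
  cat("Fluorosequencing dataset:", length(x$true_string), "reads",
      if (is.null(x$intensities)) "(truth only)" else "", "\n")
  cat("  seed", x$seed, "; all-dud rejections:", x$n_rejected, "\n")
  invisible(x)
}
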