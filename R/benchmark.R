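#' Abundance-recovery experiment over replicate datasets
#'
#' End-to-end driver for the synthetic benchmark: for each of `n_datasets`
#' replicates it samples a true abundance vector, simulates `n_reads`
#' reads, classifies them (oracle with error `e`, or the exact Bayes HMM),
#' optionally truncates the posteriors to `n_b` strings, runs EM for
#' `epochs` epochs, and records the final protein-space MAE next to the MAE
#' of the uniform-abundance guess.
#'
#' Oracle runs aggregate reads by generating string (the oracle posterior
#' depends only on the truth), which makes large read counts cheap.
#'
#' @param model a `proteome_model`.
#' @param em an [error_model()] (used only by the exact classifier and the
#'   simulator).
#' @param n_datasets number of replicate datasets.
#' @param n_reads reads per dataset.
#' @param classifier `"oracle"` or `"exact"`.
#' @param e oracle error rate.
#' @param n_b posterior truncation (default: full universe).
#' @param epochs EM epochs.
#' @param seed base seed; dataset d uses `seed + d`.
#' @return data.frame with one row per dataset: `dataset`, `mae_final`,
#'   `mae_uniform`, `accuracy` (top-1, exact classifier only).
#' @export
abundance_experiment <- function(model, em = error_model(),
                                 n_datasets = 10L, n_reads = 1e5,
                                 classifier = c("oracle", "exact"),
                                 e = 0, n_b = NULL, epochs = 30L,
                                 seed = 1L) {
  classifier <- match.arg(classifier)
  d <- n_strings(model)
  n_p <- nrow(model$cond_FI)
  if (is.null(n_b)) n_b <- d
  out <- data.frame(dataset = seq_len(n_datasets), mae_final = NA_real_,
                    mae_uniform = NA_real_, accuracy = NA_real_)
  for (ds in seq_len(n_datasets)) {
    p <- sample_abundances(n_p, seed = seed * 1000L + ds)
    sim <- generate_dataset(model, p, n_reads, em, seed = seed + ds,
                            intensities = (classifier == "exact"))
    if (classifier == "oracle") {
      tab <- tabulate(sim$true_string, nbins = d)
      used <- which(tab > 0)
      post <- oracle_posteriors(used, e, d, n_b)
      fit <- run_em(post, model, epochs = epochs, truth = p,
                    weights = tab[used])
    } else {
      dense <- exact_posterior(sim$intensities, model, em)
      out$accuracy[ds] <- top1_accuracy(dense, sim$true_string)
      post <- if (n_b < d) sparsify(dense, n_b) else dense
      fit <- run_em(post, model, epochs = epochs, truth = p)
    }
    out$mae_final[ds] <- fit$mae[length(fit$mae)]
    out$mae_uniform[ds] <- mae(rep(1 / n_p, n_p), p)
  }
  out
}
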