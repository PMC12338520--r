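#' Per-read protein evidence weights (eta)
#'
#' For each read k and protein y,
#' `eta_{y,k} = r_k + sum_{f in D_F(y) and G_k} P(f | x_k) P(f | y)`:
#' the posterior mass of the read's retained strings, filtered through the
#' protein's conditional string distribution, plus the uniform residual
#' floor. With dense posteriors (residual 0, full support) this reduces to
#' the untruncated sum over `D_F(y)`.
#'
#' @param posteriors a [sparse_posteriors()] object, or a dense posterior
#'   matrix (reads x strings).
#' @param model a `proteome_model` with the same string universe.
#' @return Dense matrix of eta values, proteins x reads.
#' @export
compute_eta <- function(posteriors, model) {
  d <- n_strings(model)
  if (inherits(posteriors, "sparse_posteriors")) {
    if (posteriors$n_strings != d)
      stop("posterior universe (", posteriors$n_strings,
           ") does not match model (", d, ")", call. = FALSE)
    n <- ncol(posteriors$top_index)
    nb <- nrow(posteriors$top_index)
    S <- Matrix::sparseMatrix(i = as.integer(posteriors$top_index),
                              j = rep(seq_len(n), each = nb),
                              x = as.numeric(posteriors$top_prob),
                              dims = c(d, n))
    eta <- unname(as.matrix(model$cond_FI %*% S))
    sweep(eta, 2L, posteriors$residual, "+")
  } else {
    posteriors <- as.matrix(posteriors)
    if (ncol(posteriors) != d)
      stop("posterior universe does not match model", call. = FALSE)
    unname(as.matrix(Matrix::tcrossprod(model$cond_FI, posteriors)))
  }
}

#' One EM update of the indicator distribution
#'
#' Computes the per-read responsibilities
#' `gamma_{y,k} = eta_{y,k} q_y / sum_l eta_{l,k} q_l` and averages them over
#' reads: `q'_y = (1/N_r) sum_k gamma_{y,k}` (weighted when read
#' multiplicities are supplied). Zero entries of `q` are absorbing.
#'
#' @param q current indicator-space probability vector.
#' @param eta proteins x reads matrix from [compute_eta()].
#' @param weights optional per-read multiplicities.
#' @return Updated indicator-space `abundance_vector`.
#' @export
em_step <- function(q, eta, weights = NULL) {
  q <- as.numeric(q)
  stopifnot(length(q) == nrow(eta), ncol(eta) >= 1L)
  numer <- eta * q
  denom <- colSums(numer)
  if (any(denom == 0))
    stop("degenerate read(s) with zero weighted evidence: ",
         paste(utils::head(which(denom == 0), 5L), collapse = ","),
         call. = FALSE)
  gamma <- sweep(numer, 2L, denom, "/")
  qp <- if (is.null(weights)) rowMeans(gamma)
        else as.numeric(gamma %*% weights) / sum(weights)
  abundance_vector(qp / sum(qp), "indicator")
}

#' Run the EM iteration over a posterior set
#'
#' Batch EM: responsibilities are accumulated over all reads (in batches)
#' and the indicator distribution is updated once per epoch. The trace
#' records the indicator and protein-space estimates after every epoch and,
#' when the true abundances are supplied, the mean absolute error.
#'
#' @param posteriors a [sparse_posteriors()] object or dense posterior
#'   matrix.
#' @param model a `proteome_model`.
#' @param epochs number of full passes (default 30).
#' @param init `"uniform"` or an initial indicator-space vector.
#' @param truth optional true protein-space abundance vector.
#' @param weights optional per-read multiplicities (aggregated reads).
#' @param batch_size reads per accumulation batch.
#' @return Object of class `em_trace`: `q_hat`, `p_hat`, `q_path` (proteins
#'   x epochs+1, initial state first), `mae` (length epochs+1, NA without
#'   truth), `epochs`.
#' @export
run_em <- function(posteriors, model, epochs = 30L, init = "uniform",
                   truth = NULL, weights = NULL, batch_size = 100000L) {
  stopifnot(epochs >= 1L)
  n <- n_reads(posteriors)
  if (n == 0L) stop("empty posterior stream", call. = FALSE)
  n_p <- nrow(model$cond_FI)
  q <- if (identical(init, "uniform")) rep(1 / n_p, n_p)
       else as.numeric(init)
  stopifnot(length(q) == n_p)

  starts <- seq(1L, n, by = batch_size)
  etas <- lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, n)
    list(eta = compute_eta(slice_posteriors(posteriors, idx), model),
         w = if (is.null(weights)) NULL else weights[idx])
  })
  total_w <- if (is.null(weights)) n else sum(weights)

  mae_of <- function(q) {
    if (is.null(truth)) return(NA_real_)
    mae(indicator_to_protein(q, model), truth)
  }

  q_path <- matrix(NA_real_, n_p, epochs + 1L)
  maes <- numeric(epochs + 1L)
  q_path[, 1L] <- q
  maes[1L] <- mae_of(q)

  for (ep in seq_len(epochs)) {
    acc <- numeric(n_p)
    for (b in etas) {
      numer <- b$eta * q
      denom <- colSums(numer)
      if (any(denom == 0))
        stop("degenerate read(s) with zero weighted evidence in epoch ", ep,
             call. = FALSE)
      gamma <- sweep(numer, 2L, denom, "/")
      acc <- acc + if (is.null(b$w)) rowSums(gamma)
                   else as.numeric(gamma %*% b$w)
    }
    q <- acc / total_w
    q <- q / sum(q)
    q_path[, ep + 1L] <- q
    maes[ep + 1L] <- mae_of(q)
  }

  structure(
    list(q_hat = abundance_vector(q, "indicator"),
         p_hat = indicator_to_protein(q, model),
         q_path = q_path, mae = maes, epochs = epochs),
    class = "em_trace"
  )
}

slice_posteriors <- function(posteriors, idx) {
  if (inherits(posteriors, "sparse_posteriors"))
    sparse_posteriors(posteriors$top_index[, idx, drop = FALSE],
                      posteriors$top_prob[, idx, drop = FALSE],
                      posteriors$residual[idx], posteriors$n_strings,
                      posteriors$read_id[idx])
  else posteriors[idx, , drop = FALSE]
}

#' @export
print.em_trace <- function(x, ...) {
  cat("EM trace:", x$epochs, "epochs")
  if (!is.na(x$mae[length(x$mae)]))
    cat("; final MAE", signif(x$mae[length(x$mae)], 4))
  cat("\n")
  invisible(x)
}

#' Relative data log-likelihood of an indicator distribution
#'
#' Brute-force oracle for monotonicity checks on small dense instances:
#' `sum_k log sum_y eta_{y,k} q_y`, equal to the data log-likelihood up to
#' the read-wise classifier normalizers, which cancel between EM iterates.
#' Guarded to small problems; not used in production runs.
#'
#' @param q indicator-space probability vector.
#' @param posteriors dense posterior matrix (reads x strings).
#' @param model a `proteome_model`.
#' @return Scalar relative log-likelihood.
#' @export
data_loglikelihood <- function(q, posteriors, model) {
  stopifnot(is.matrix(posteriors) || is.data.frame(posteriors))
  posteriors <- as.matrix(posteriors)
  n_p <- nrow(model$cond_FI)
  if (nrow(posteriors) * n_p > 1e6)
    stop("data_loglikelihood is a small-instance oracle (N_r * N_P <= 1e6)",
         call. = FALSE)
  eta <- compute_eta(posteriors, model)
  sum(log(colSums(eta * as.numeric(q))))
}

#' Mean absolute error between abundance vectors
#'
#' `MAE = (1/N_P) sum_y |p_hat_y - p_y|`, the evaluation metric for
#' protein-space abundance recovery.
#'
#' @param p_hat,p_true equal-length probability vectors.
#' @return Scalar MAE.
#' @export
mae <- function(p_hat, p_true) {
  p_hat <- as.numeric(p_hat); p_true <- as.numeric(p_true)
  if (length(p_hat) != length(p_true))
    stop("length mismatch", call. = FALSE)
  mean(abs(p_hat - p_true))
}

#' Top-1 string classification accuracy
#'
#' Fraction of reads whose highest-posterior string (ties broken by lowest
#' string index) equals the true generating string.
#'
#' @param posteriors a [sparse_posteriors()] object or dense posterior
#'   matrix.
#' @param truth integer vector of true string indices.
#' @param read_id optional identifiers to check alignment against the
#'   posteriors' `read_id`.
#' @return Fraction in `[0, 1]`.
#' @export
top1_accuracy <- function(posteriors, truth, read_id = NULL) {
  if (inherits(posteriors, "sparse_posteriors")) {
    if (!is.null(read_id) && !is.null(posteriors$read_id) &&
        !identical(as.character(read_id), as.character(posteriors$read_id)))
      stop("read id mismatch", call. = FALSE)
    winner <- posteriors$top_index[1L, ]
    # if the retained mass is all zero every string ties at r_k; lowest wins
    winner[posteriors$top_prob[1L, ] == 0] <- 1L
  } else {
    winner <- max.col(as.matrix(posteriors), ties.method = "first")
  }
  if (length(winner) != length(truth))
    stop("read count mismatch", call. = FALSE)
  mean(winner == truth)
}
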