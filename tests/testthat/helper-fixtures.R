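# Shared fixtures, all built in code at test time.

# Default scheme: channel 1 = {D,E}, channel 2 = {C}, channel 3 = {Y}.

# Two proteins with disjoint single-string supports: "CK" -> string (2),
# "YK" -> string (3). With m = 0 both strings have weight 1.
toy_disjoint_model <- function(m = 0) {
  build_model(c(A = "CK", B = "YK"), label_scheme(), m = m)
}

# Protein 1 sheds strings a = (2) and b = (3) equally, protein 2 only b.
toy_shared_model <- function(m = 0) {
  build_model(c(A = "CKYK", B = "YK"), label_scheme(), m = m)
}

# Five synthetic proteins, compact peptides (max 7 dyes per string) so the
# exact HMM classifier stays cheap.
fixture_model_5 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_model(random_proteins(5, c(60L, 100L), seed = 12L))
    cache
  }
})

# Reconstruct the dense vector a sparse posterior represents (each string
# carries the residual; members of G_k additionally their retained mass).
densify_posteriors <- function(sp) {
  n <- ncol(sp$top_index)
  out <- matrix(rep(sp$residual, each = sp$n_strings), sp$n_strings, n)
  for (k in seq_len(n))
    out[sp$top_index[, k], k] <- out[sp$top_index[, k], k] + sp$top_prob[, k]
  t(out)
}

# Random dense posteriors over the non-null universe (rows on the simplex).
random_dense_posteriors <- function(n_reads, d) {
  P <- matrix(0, n_reads, d)
  raw <- matrix(rexp(n_reads * (d - 1L)), n_reads, d - 1L)
  P[, -1L] <- raw / rowSums(raw)
  P
}

noise_free_em <- function(n_cycles, ...) {
  error_model(n_cycles = n_cycles, p_edman_fail = 0, p_detach = 0,
              p_bleach = 0, p_dud = 0, sigma = 0, sigma_bg = 0, ...)
}
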