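test_that("eta combines retained posterior mass with the residual floor", {
  mod <- toy_shared_model()          # strings: f_null, (2), (3)
  keys <- vapply(mod$strings, function(f) f$key, character(1))
  ia <- which(keys == "2")
  # dense one-hot posterior at string a: eta_y = P(a | y)
  dense <- matrix(0, 1, 3); dense[1, ia] <- 1
  eta <- compute_eta(dense, mod)
  expect_equal(as.numeric(eta), c(0.5, 0))

  # sparse posterior whose retained set misses protein 2's support
  sp <- sparse_posteriors(matrix(ia), matrix(0.7), residual = 0.1,
                          n_strings = 3)
  eta <- compute_eta(sp, mod)
  expect_equal(eta[1, 1], 0.1 + 0.7 * 0.5)
  expect_equal(eta[2, 1], 0.1)       # empty intersection: floor only

  expect_error(compute_eta(sparse_posteriors(matrix(1L), matrix(0.5),
                                             0.1, 5), mod),
               "does not match")
})

test_that("sparse eta equals dense eta at full support", {
  mod <- fixture_model_5()
  d <- n_strings(mod)
  set.seed(19)
  P <- random_dense_posteriors(50, d)
  eta_dense <- compute_eta(P, mod)
  eta_sparse <- compute_eta(sparsify(P, d), mod)
  expect_equal(eta_sparse, eta_dense, tolerance = 1e-12)
})

test_that("one EM step averages exact responsibilities for disjoint supports", {
  mod <- toy_disjoint_model()
  keys <- vapply(mod$strings, function(f) f$key, character(1))
  sA <- which(keys == "2"); sB <- which(keys == "3")
  dense <- matrix(0, 4, 3)
  dense[1:3, sA] <- 1                 # 3 of 4 reads from protein A
  dense[4, sB] <- 1
  eta <- compute_eta(dense, mod)
  q1 <- em_step(c(0.5, 0.5), eta)
  expect_equal(as.numeric(q1), c(0.75, 0.25))

  # uninformative eta leaves q unchanged
  q <- c(0.3, 0.7)
  expect_equal(as.numeric(em_step(q, matrix(1, 2, 6))), q)

  # simplex preservation and absorbing zeros
  set.seed(23)
  eta <- matrix(rexp(3 * 20), 3, 20)
  q0 <- c(0.6, 0.4, 0)
  q1 <- em_step(q0, eta)
  expect_equal(sum(q1), 1, tolerance = 1e-9)
  expect_identical(as.numeric(q1)[3], 0)

  expect_error(em_step(c(1, 0), rbind(0, 1)), "degenerate read")
})

test_that("run_em with one epoch equals a single EM step", {
  mod <- fixture_model_5()
  set.seed(3)
  P <- random_dense_posteriors(40, n_strings(mod))
  fit <- run_em(P, mod, epochs = 1)
  q1 <- em_step(rep(0.2, 5), compute_eta(P, mod))
  expect_equal(as.numeric(fit$q_hat), as.numeric(q1), tolerance = 1e-12)
})

test_that("weighted aggregated reads reproduce the unweighted trajectory", {
  mod <- fixture_model_5()
  d <- n_strings(mod)
  set.seed(29)
  truth <- sample(2:d, 500, replace = TRUE)
  full <- oracle_posteriors(truth, 0.2, d)
  tab <- tabulate(truth, nbins = d); used <- which(tab > 0)
  agg <- oracle_posteriors(used, 0.2, d)
  f1 <- run_em(full, mod, epochs = 5)
  f2 <- run_em(agg, mod, epochs = 5, weights = tab[used])
  expect_equal(f1$q_path, f2$q_path, tolerance = 1e-12)
})

test_that("the relative data log-likelihood behaves as a likelihood oracle", {
  # uninformative evidence: every protein explains every read equally
  mod_same <- build_model(c(A = "CK", B = "CKCK"), label_scheme())
  dense <- matrix(0, 5, n_strings(mod_same))
  dense[, mod_same$support[[1]]] <- 1
  for (q1 in c(0.2, 0.5, 0.9))
    expect_equal(data_loglikelihood(c(q1, 1 - q1), dense, mod_same), 0)

  # one-hot posteriors with disjoint supports: maximized at the
  # empirical string frequencies (multinomial MLE)
  mod <- toy_disjoint_model()
  keys <- vapply(mod$strings, function(f) f$key, character(1))
  dense <- matrix(0, 10, 3)
  dense[1:7, which(keys == "2")] <- 1
  dense[8:10, which(keys == "3")] <- 1
  q_mle <- c(0.7, 0.3)
  ll_mle <- data_loglikelihood(q_mle, dense, mod)
  for (eps in c(-0.2, -0.05, 0.05, 0.2)) {
    q_alt <- q_mle + c(eps, -eps)
    expect_lt(data_loglikelihood(q_alt, dense, mod), ll_mle)
  }

  expect_error(data_loglikelihood(rep(1 / 5, 5),
                                  matrix(0, 2e6, 2), fixture_model_5()),
               "small-instance")
})

test_that("EM never decreases the data likelihood on a dense instance", {
  mod <- build_model(random_proteins(3, c(40L, 80L), seed = 6L))
  set.seed(77)
  P <- random_dense_posteriors(30, n_strings(mod))
  eta <- compute_eta(P, mod)
  q <- rep(1 / 3, 3)
  ll <- data_loglikelihood(q, P, mod)
  for (i in 1:20) {
    q <- em_step(q, eta)
    ll_new <- data_loglikelihood(q, P, mod)
    expect_gte(ll_new, ll - 1e-10)
    ll <- ll_new
  }
})

test_that("estimates concentrate on the truth as reads accumulate", {
  mod <- fixture_model_5()
  d <- n_strings(mod)
  p <- sample_abundances(5, 61)
  maes <- vapply(c(100L, 1000L, 10000L), function(n) {
    ds <- generate_dataset(mod, p, n, error_model(), seed = 71,
                           intensities = FALSE)
    tab <- tabulate(ds$true_string, nbins = d); used <- which(tab > 0)
    fit <- run_em(oracle_posteriors(used, 0, d), mod, epochs = 30,
                  truth = p, weights = tab[used])
    fit$mae[length(fit$mae)]
  }, numeric(1))
  expect_true(all(diff(maes) <= 0))
  expect_lt(maes[3], 0.01)
})

test_that("error metrics follow their closed forms", {
  expect_identical(mae(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_identical(mae(c(1, 0), c(0, 1)), 1)
  for (n in c(4L, 10L))
    expect_equal(mae(rep(1 / n, n), c(1, rep(0, n - 1))),
                 2 * (n - 1) / n^2)
  expect_error(mae(c(1, 0), c(1, 0, 0)), "length mismatch")

  d <- 8L
  truth <- c(3L, 5L, 2L)
  expect_identical(top1_accuracy(oracle_posteriors(truth, 0, d), truth), 1)
  one <- oracle_posteriors(4L, 0.2, d)
  expect_identical(top1_accuracy(one, 4L), 1)
  expect_error(top1_accuracy(one, c(4L, 2L)), "count mismatch")
})
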