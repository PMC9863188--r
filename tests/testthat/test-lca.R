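# Latent class likelihood, E/M steps and the multi-start EM fit.

test_that("log-likelihood matches closed forms and the enumeration oracle", {
  # C = 1, one binary item with rho = (1/2, 1/2): every row has probability 1/2
  p1 <- list(gamma = 1, rho = list(matrix(c(0.5, 0.5), 2, 1)))
  y1 <- data.frame(item1 = c(0L, 1L, 0L, 1L))
  expect_equal(lca_log_likelihood(p1, y1), 4 * log(0.5), tolerance = 1e-12)

  # J = 3 binary items, C = 2: agree with full-pattern enumeration
  set.seed(101)
  for (rep in 1:5) {
    pars <- random_params(J = 3, K = 2, C = 2)
    y <- as.data.frame(matrix(sample(0:1, 8 * 3, replace = TRUE), 8, 3))
    expect_equal(lca_log_likelihood(pars, y),
                 enum_loglik(pars$gamma, pars$rho, as.matrix(y)),
                 tolerance = 1e-10)
  }

  # an all-missing row contributes log(1) = 0
  pars <- random_params(3, 2, 2)
  y <- data.frame(a = c(0L, NA), b = c(1L, NA), c = c(0L, NA))
  expect_equal(lca_log_likelihood(pars, y, n_levels = 2),
               lca_log_likelihood(pars, y[1, , drop = FALSE], n_levels = 2),
               tolerance = 1e-12)

  # level index beyond the rho table errors
  expect_error(lca_log_likelihood(p1, data.frame(item1 = 2L)), "out of range")
})

test_that("E-step reproduces Bayes rule, priors for empty rows, certainty for C = 1", {
  pars <- list(gamma = c(0.5, 0.5),
               rho = list(matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)))
  # y = 0: posterior proportional to (0.5 * 0.8, 0.5 * 0.3) = (8/11, 3/11)
  post <- lca_e_step(pars, data.frame(x = 0L), n_levels = 2)
  expect_equal(as.vector(post), c(8 / 11, 3 / 11), tolerance = 1e-12)

  post2 <- lca_e_step(pars, data.frame(x = NA_integer_), n_levels = 2)
  expect_equal(as.vector(post2), pars$gamma, tolerance = 1e-12)

  p1 <- list(gamma = 1, rho = list(matrix(c(0.5, 0.5), 2, 1)))
  expect_true(all(lca_e_step(p1, data.frame(x = c(0L, 1L)), n_levels = 2) == 1))
})

test_that("M-step recovers shares from hard and uniform posteriors and is an EM fixed point", {
  y <- data.frame(a = c(0L, 0L, 1L, 1L, 1L), b = c(1L, 0L, 0L, 1L, 1L))
  onehot <- cbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1))
  par <- lca_m_step(onehot, y, n_levels = 2)
  expect_equal(par$gamma, c(0.4, 0.6), tolerance = 1e-9)
  expect_equal(par$rho[[1]][, 1], c(1, 0), tolerance = 1e-5)   # a = 0 in class 1
  expect_equal(par$rho[[2]][, 2], c(1 / 3, 2 / 3), tolerance = 1e-9)

  unif <- matrix(0.5, 5, 2)
  par_u <- lca_m_step(unif, y, n_levels = 2)
  marg_a <- c(2, 3) / 5
  expect_equal(par_u$rho[[1]][, 1], marg_a, tolerance = 1e-9)
  expect_equal(par_u$rho[[1]][, 2], marg_a, tolerance = 1e-9)

  # at the MLE, one more E+M round moves parameters by less than tol
  # (J = 5 binary items keeps the 2-class model well identified)
  set.seed(7)
  pars <- random_params(5, 2, 2)
  sim <- simulate_indicators(pars$gamma, pars$rho, 400)
  fit <- lca_fit(sim, 2, n_starts = 5, seed = 3)
  post <- lca_e_step(fit$params, sim, n_levels = 2)
  new_par <- lca_m_step(post, sim, n_levels = 2)
  expect_lt(max(abs(new_par$gamma - fit$params$gamma)), 1e-4)
  expect_lt(max(abs(unlist(new_par$rho) - unlist(fit$params$rho))), 1e-4)

  expect_error(lca_m_step(cbind(rep(1, 5), 0), y, n_levels = 2), "degenerate")
})

test_that("lca_fit: closed-form one-class fit, determinism, monotone chains, label invariance", {
  set.seed(11)
  pars <- random_params(4, 2, 2)
  sim <- simulate_indicators(pars$gamma, pars$rho, 300)

  f1 <- lca_fit(sim, 1)
  expect_equal(unname(f1$params$gamma), 1)
  expect_equal(unname(f1$params$rho[[2]][2, 1]), mean(sim[[2]]), tolerance = 1e-5)
  expect_identical(f1$n_iter, 1L)

  fa <- lca_fit(sim, 2, n_starts = 4, seed = 99)
  fb <- lca_fit(sim, 2, n_starts = 4, seed = 99)
  expect_identical(fa$loglik, fb$loglik)
  expect_identical(fa$params, fb$params)
  expect_identical(fa$posterior, fb$posterior)

  # within-chain monotonicity of the log-likelihood
  expect_true(all(fa$chain_info$min_ll_increase > -1e-8, na.rm = TRUE))
  # best loglik is the max over starts; posterior rows normalised
  expect_equal(fa$loglik, max(fa$chain_info$loglik))
  expect_lt(max(abs(rowSums(fa$posterior) - 1)), 1e-10)
  expect_lt(abs(sum(fa$params$gamma) - 1), 1e-10)
  # canonical ordering: descending prevalence
  expect_true(all(diff(fa$params$gamma) <= 0))

  # permuting class labels leaves the likelihood unchanged
  perm <- list(gamma = fa$params$gamma[2:1],
               rho = lapply(fa$params$rho, function(m) m[, 2:1]))
  expect_equal(lca_log_likelihood(perm, sim, n_levels = 2),
               lca_log_likelihood(fa$params, sim, n_levels = 2), tolerance = 1e-10)
})

test_that("parameter and degrees-of-freedom counts follow the closed forms", {
  expect_identical(lca_n_params(16, 3, 4), 131L)
  expect_identical(lca_n_params(16, 3, 1), 32L)
  expect_identical(lca_n_params(1, 2, 1), 1L)
  expect_equal(lca_df(2, 2, 1), 1)
  expect_equal(lca_df(16, 3, 1), 43046688)
  # mixed level counts
  expect_identical(lca_n_params(3, c(2, 3, 4), 2), 1L + 2L * (1L + 2L + 3L))
})

test_that("tidy and glance return consistent summaries", {
  set.seed(5)
  pars <- random_params(3, 2, 2)
  sim <- simulate_indicators(pars$gamma, pars$rho, 200)
  f <- lca_fit(sim, 2, n_starts = 3, seed = 1)
  td <- tidy(f)
  expect_equal(sum(td$parameter == "gamma"), 2)
  expect_equal(nrow(td), 2 + 3 * 2 * 2)
  expect_equal(sum(td$estimate[td$parameter == "gamma"]), 1, tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$AIC_LL, -2 * f$loglik + 2 * f$n_params)
  expect_equal(gl$n, 200L)
})
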