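# Model-comparison statistics and separation diagnostics.

test_that("G-squared vanishes for a perfectly fitting model and matches hand computation", {
  # J = 2 binary items, counts 10 per pattern: the one-class independence
  # model reproduces the uniform table exactly
  y_unif <- data.frame(
    a = rep(c(0L, 0L, 1L, 1L), each = 10),
    b = rep(c(0L, 1L, 0L, 1L), each = 10))
  f <- lca_fit(y_unif, 1)
  expect_lt(abs(g_squared(f)), 1e-6)

  # association table: hand-computed 2 sum n_p log(n_p / e_p) with
  # independence expectations e_p = n * phat_a * phat_b
  counts <- c(`00` = 30, `01` = 10, `10` = 10, `11` = 10)
  y_dep <- data.frame(
    a = rep(c(0L, 0L, 1L, 1L), counts),
    b = rep(c(0L, 1L, 0L, 1L), counts))
  f2 <- lca_fit(y_dep, 1)
  n <- 60
  pa <- c(40, 20) / n  # P(a = 0), P(a = 1)
  pb <- c(40, 20) / n
  e <- n * c(pa[1] * pb[1], pa[1] * pb[2], pa[2] * pb[1], pa[2] * pb[2])
  g2_hand <- 2 * sum(counts * log(counts / e))
  expect_equal(g_squared(f2), g2_hand, tolerance = 1e-6)
  expect_gte(g_squared(f2), 0)
})

test_that("the two information-criterion bases obey the penalty identities", {
  set.seed(21)
  pars <- random_params(6, 2, 3)
  sim <- simulate_indicators(pars$gamma, pars$rho, 500)
  f2 <- lca_fit(sim, 2, n_starts = 4, seed = 2)
  f3 <- lca_fit(sim, 3, n_starts = 4, seed = 2)
  ic2 <- information_criteria(f2)
  ic3 <- information_criteria(f3)
  for (b in 1:2) {
    expect_equal(ic2$BIC[b] - ic2$AIC[b], f2$n_params * (log(f2$n) - 2),
                 tolerance = 1e-8)
  }
  # AIC differences agree across bases (the saturated term cancels)
  expect_equal(ic3$AIC[1] - ic2$AIC[1], ic3$AIC[2] - ic2$AIC[2], tolerance = 1e-6)
  # recomputation from persisted pieces
  expect_equal(ic2$AIC[2], -2 * f2$loglik + 2 * f2$n_params, tolerance = 1e-10)
})

test_that("relative entropy hits its bounds and the hand-computed two-class value", {
  onehot <- diag(4)[sample.int(4, 50, replace = TRUE), ]
  expect_equal(relative_entropy(onehot), 1, tolerance = 1e-12)
  expect_equal(relative_entropy(matrix(0.25, 50, 4)), 0, tolerance = 1e-12)
  p <- matrix(rep(c(0.8, 0.2), each = 25), 25, 2)
  hand <- 1 - (-(0.8 * log(0.8) + 0.2 * log(0.2))) / log(2)
  expect_equal(relative_entropy(p), hand, tolerance = 1e-10)
  expect_error(relative_entropy(matrix(1, 5, 1)), "undefined")
  # invariant to relabelling
  q <- cbind(runif(30, 0.1, 0.9)); q <- cbind(q, 1 - q)
  expect_equal(relative_entropy(q), relative_entropy(q[, 2:1]), tolerance = 1e-12)
})

test_that("AvePP matrix: identity for one-hot, hand means, tie handling", {
  onehot <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  expect_equal(unname(avepp_matrix(onehot)), diag(3), tolerance = 1e-12)

  p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  m <- avepp_matrix(p)
  expect_equal(unname(m[1, ]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(unname(m[2, ]), c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(rowSums(m), c(class1 = 1, class2 = 1), tolerance = 1e-12)

  expect_identical(modal_assignment(rbind(c(0.5, 0.5))), 1L)  # tie -> lower index
  expect_identical(modal_assignment(rbind(c(0.2, 0.5, 0.3))), 2L)
  expect_error(avepp_matrix(rbind(c(0.9, 0.1), c(0.8, 0.2))), "empty modal class")
})

test_that("replicate stability counts converged starts within tolerance of the best", {
  expect_equal(replicate_stability(rep(-500, 100)), 100)
  ll <- c(rep(-500, 45), rep(-510, 55))
  expect_equal(replicate_stability(ll), 45)
  expect_equal(replicate_stability(c(-500, -500.005, -501), tol = 0.01), 200 / 3)
  expect_equal(replicate_stability(c(-500, -500.005, -501), tol = 0), 100 / 3)
  # failed starts count in the denominator only
  expect_equal(replicate_stability(c(-500, NA, -Inf, -502)), 25)
})

test_that("lca_sweep assembles the comparison table with consistent df and diagnostics", {
  set.seed(31)
  pars <- random_params(5, 2, 2)
  sim <- simulate_indicators(pars$gamma, pars$rho, 400)
  sw <- lca_sweep(sim, n_classes = 1:3, n_starts = 4, seed = 9)
  res <- sw$results
  expect_equal(nrow(res), 3)
  expect_equal(res$df, sapply(1:3, function(C) lca_df(5, 2, C)))
  expect_equal(res$smallest_class_prob[1], 1)
  expect_true(is.na(res$entropy[1]))
  expect_true(all(res$pct_best_replicates > 0 & res$pct_best_replicates <= 100,
                  na.rm = TRUE))
  expect_equal(res$BIC_G2 - res$AIC_G2,
               sapply(1:3, function(C) lca_n_params(5, 2, C)) * (log(400) - 2),
               tolerance = 1e-8)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_identical(tidy(sw), res)
})
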