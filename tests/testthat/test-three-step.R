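# BCH classification-error correction: error matrix, weights, distal
# outcomes, covariate regression and inverse-propensity balancing.

test_that("classification matrix matches hand-computed weighted shares", {
  onehot <- diag(2)[c(1, 1, 2), ]
  expect_equal(unname(classification_matrix(onehot)), diag(2), tolerance = 1e-12)

  # spec-style hand case: posteriors (0.7, 0.3) and (0.4, 0.6)
  p <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  D <- classification_matrix(p)
  expect_equal(unname(D[1, ]), c(0.7 / 1.1, 0.4 / 1.1), tolerance = 1e-12)
  expect_equal(unname(D[2, ]), c(0.3 / 0.9, 0.6 / 0.9), tolerance = 1e-12)
  expect_equal(unname(rowSums(D)), c(1, 1), tolerance = 1e-12)
})

test_that("BCH weights are rows of the inverse error matrix and sum to one", {
  # three individuals, hand-invertible 2x2 D
  p <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.3, 0.7))
  # mass = (1.9, 1.1); D = ((1.6/1.9, 0.3/1.9), (0.4/1.1, 0.7/1.1))
  d11 <- 1.6 / 1.9; d12 <- 0.3 / 1.9; d21 <- 0.4 / 1.1; d22 <- 0.7 / 1.1
  det <- d11 * d22 - d12 * d21
  w <- bch_weights(p)
  expect_equal(unname(w$u[1, ]), c(d22 / det, -d12 / det), tolerance = 1e-10)
  expect_equal(unname(w$u[3, ]), c(-d21 / det, d11 / det), tolerance = 1e-10)
  expect_equal(unname(rowSums(w$u)), rep(1, 3), tolerance = 1e-12)
  # column sums recover total posterior mass (n * gamma-hat)
  expect_equal(unname(colSums(w$u)), unname(colSums(p)), tolerance = 1e-9)

  # one-hot classification: weights are one-hot at the modal class
  u0 <- bch_weights(diag(2)[c(1, 2, 2), ])$u
  expect_equal(unname(u0), diag(2)[c(1, 2, 2), ], tolerance = 1e-12)

  # near-uniform posteriors: D near-singular, BCH refused
  pu <- matrix(0.5, 10, 2) + matrix(rnorm(20, 0, 1e-10), 10, 2)
  pu <- pu / rowSums(pu)
  expect_error(bch_weights(pu), "entropy")
})

test_that("BCH distal reduces to raw proportions under perfect classification", {
  set.seed(12)
  cls <- sample(1:2, 200, replace = TRUE)
  onehot <- diag(2)[cls, ]
  outcome <- factor(ifelse(runif(200) < c(0.2, 0.7)[cls], "yes", "no"))
  d <- bch_distal(bch_weights(onehot), data.frame(out = outcome), boot = 0)
  for (c in 1:2) {
    raw <- 100 * mean(outcome[cls == c] == "yes")
    expect_equal(d$percent[d$class == paste0("class", c) & d$category == "yes"],
                 raw, tolerance = 1e-9)
  }
  # single-category outcome -> 100% everywhere; percents sum to 100 per class
  d1 <- bch_distal(bch_weights(onehot), data.frame(k = factor(rep("only", 200))),
                   boot = 0)
  expect_true(all(d1$percent == 100))
  sums <- tapply(d$percent, d$class, sum)
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("BCH regression matches the closed-form cross-tab odds ratio under perfect classification", {
  set.seed(33)
  n <- 600
  cls <- sample(1:2, n, replace = TRUE)
  x <- rbinom(n, 1, ifelse(cls == 1, 0.3, 0.6)) == 1
  onehot <- diag(2)[cls, ]
  r <- bch_regression(bch_weights(onehot), data.frame(exposed = x),
                      reference = 1, boot = 0)
  or_hat <- exp(r$beta["class2", "exposedTRUE"])
  or_tab <- crosstab_or(sum(cls == 2 & x), sum(cls == 2 & !x),
                        sum(cls == 1 & x), sum(cls == 1 & !x))
  expect_equal(or_hat, or_tab, tolerance = 1e-4)
  # reference class coefficients are exactly zero (OR 1)
  expect_true(all(r$beta["class1", ] == 0))
  td <- tidy(r)
  expect_identical(unique(td$reference_class), "class1")
  expect_false("class1" %in% td$class)
})

test_that("bootstrap CIs bracket the point estimate and reference selection works", {
  set.seed(44)
  n <- 400
  cls <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  x <- rbinom(n, 1, ifelse(cls == 1, 0.3, 0.6)) == 1
  p <- diag(2)[cls, ] * 0.9 + 0.05   # mildly uncertain posteriors
  r <- bch_regression(p, data.frame(exposed = x), boot = 60, seed = 9)
  expect_identical(r$reference, 1L)  # class 1 is the largest
  td <- tidy(r)
  expect_true(all(td$ci_low <= td$or & td$or <= td$ci_high))
  expect_true(all(td$or > 0))
})

test_that("IP weights are near 1 under null covariates and balance a confounded cohort", {
  set.seed(55)
  n <- 1500
  cls <- sample(1:2, n, replace = TRUE)
  p <- diag(2)[cls, ] * 0.92 + 0.04
  # null covariate: independent of class
  xn <- factor(sample(c("a", "b"), n, replace = TRUE))
  ipn <- ip_weights(p, data.frame(x = xn))
  expect_lt(max(abs(ipn$w - 1)), 0.15)
  expect_lt(abs(ipn$mean_weight - 1), 0.05)

  # confounded covariate: strongly class-dependent
  xc <- factor(ifelse(rbinom(n, 1, ifelse(cls == 1, 0.25, 0.7)) == 1, "hi", "lo"))
  ipc <- ip_weights(p, data.frame(x = xc))
  expect_gt(max(abs(ipc$smd$smd_before)), 0.3)
  expect_lt(max(abs(ipc$smd$smd_after)), 0.1)
  # weighted covariate distribution per class approaches the marginal
  uw <- bch_weights(p)$u * ipc$w
  marg <- mean(xc == "hi")
  for (c in 1:2) {
    wprop <- sum(uw[xc == "hi", c]) / sum(uw[, c])
    expect_lt(abs(wprop - marg), 0.05)
  }
  expect_s3_class(autoplot(ipc), "ggplot")
})
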