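# BCH three-step estimation.
#
# Step 1 fits the latent class model; step 2 assigns individuals to their
# modal class and estimates the classification-error matrix
# D_{cj} = P(modal = j | true class = c); step 3 relates classes to external
# variables using weights u_i = row m_i of D^{-1}, which undo the
# classification error in expectation. Row sums of u are exactly 1 (rows of
# D sum to 1), so the weighted multinomial log-likelihood stays convex even
# though individual weights can be negative.

#' Classification-error matrix of a modal assignment
#'
#' `D_{cj} = sum_i p_ic 1(m_i = j) / sum_i p_ic`: the estimated probability
#' of being modally assigned to class `j` for members of true class `c`.
#'
#' @inheritParams relative_entropy
#' @param modal Optional precomputed modal assignment (defaults to
#'   [modal_assignment()] of the posteriors).
#' @return C x C matrix with rows summing to 1.
#' @export
classification_matrix <- function(posteriors, modal = NULL) {
  p <- if (inherits(posteriors, "lca_fit")) posteriors$posterior else posteriors
  C <- ncol(p)
  modal <- modal %||% modal_assignment(p)
  mass <- colSums(p)
  if (any(mass <= 0)) {
    abort(sprintf("class with zero posterior mass: %s",
                  paste(which(mass <= 0), collapse = ", ")))
  }
  D <- matrix(0, C, C)
  for (j in seq_len(C)) {
    D[, j] <- colSums(p[modal == j, , drop = FALSE]) / mass
  }
  cls <- colnames(p) %||% paste0("class", seq_len(C))
  dimnames(D) <- list(true = cls, modal = cls)
  D
}

#' BCH correction weights
#'
#' Computes the modal-assignment BCH weights `u_ic = (D^-1)_{m_i, c}`.
#' Individual weights can be negative; every row sums to exactly 1, and the
#' column sums estimate `n * gamma_c`.
#'
#' @param fit An [lca_fit()] object, or a posterior matrix.
#' @return Object of class `"bch_weights"`: list with `u` (n x C), `D`,
#'   `D_inv`, `modal`, `condition` (condition number of D) and class names.
#' @export
bch_weights <- function(fit) {
  p <- if (inherits(fit, "lca_fit")) fit$posterior else fit
  modal <- modal_assignment(p)
  D <- classification_matrix(p, modal)
  cond <- kappa(D, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    abort(sprintf(paste("classification-error matrix is near-singular",
                        "(condition number %.3g): class separation (entropy)",
                        "is too low for the BCH correction"), cond))
  }
  D_inv <- solve(D)
  u <- D_inv[modal, , drop = FALSE]
  colnames(u) <- colnames(D)
  rownames(u) <- NULL
  structure(list(u = u, D = D, D_inv = D_inv, modal = modal,
                 condition = cond, classes = colnames(D)),
            class = "bch_weights")
}

#' @export
print.bch_weights <- function(x, ...) {
  cat(sprintf("BCH weights: n = %d, %d classes, condition number %.2f\n",
              nrow(x$u), ncol(x$u), x$condition))
  cat("classification-error matrix D (rows = true, cols = modal):\n")
  print(round(x$D, 3))
  invisible(x)
}

resolve_bch <- function(fit) {
  if (inherits(fit, "bch_weights")) fit else bch_weights(fit)
}

bch_distal_point <- function(u, f) {
  # class-conditional category shares; negative cells clipped + renormalised
  C <- ncol(u)
  Q <- nlevels(f)
  tot <- colSums(u)
  if (any(tot <= 0)) {
    abort(sprintf("class with non-positive total BCH weight: %s",
                  paste(which(tot <= 0), collapse = ", ")))
  }
  est <- matrix(0, C, Q, dimnames = list(colnames(u), levels(f)))
  for (q in seq_len(Q)) est[, q] <- colSums(u[f == levels(f)[q], , drop = FALSE]) / tot
  clipped <- FALSE
  if (any(est < 0)) {
    clipped <- TRUE
    est[est < 0] <- 0
    est <- est / rowSums(est)
  }
  structure(est, clipped = clipped)
}

#' BCH-weighted distal outcome distribution by latent class
#'
#' Estimates the class-conditional distribution of one or more categorical
#' outcomes, corrected for classification error: the class-`c` share of
#' category `q` is `sum_i u_ic 1(Y_i = q) / sum_i u_ic`. Negative cell
#' estimates (possible because BCH weights can be negative) are clipped to 0
#' and rows renormalised, with a warning. Confidence intervals come from a
#' nonparametric bootstrap over individuals, recomputing weights per
#' resample from the fixed classification-error matrix `D`.
#'
#' @param fit An [lca_fit()] or [bch_weights()] object.
#' @param outcomes Data frame of categorical outcome columns (factors,
#'   characters or logicals), one row per individual in fit order.
#' @param boot Number of bootstrap resamples for percentile CIs (0 for
#'   point estimates only).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @param ip Optional [ip_weights()] object; if supplied the combined
#'   BCH-and-inverse-propensity weights are used.
#' @return Tibble with columns `outcome`, `class`, `category`, `percent`,
#'   and (if `boot > 0`) `ci_low`, `ci_high`. Percentages within each
#'   class and outcome sum to 100.
#' @export
bch_distal <- function(fit, outcomes, boot = 500, seed = NULL,
                       conf_level = 0.95, ip = NULL) {
  w <- resolve_bch(fit)
  u <- w$u
  if (!is.null(ip)) u <- u * ip$w
  if (!is.data.frame(outcomes)) outcomes <- tibble::as_tibble(outcomes)
  outcomes <- outcomes[setdiff(names(outcomes), "participant_id")]
  if (nrow(outcomes) != nrow(u)) {
    abort("`outcomes` must have one row per fitted individual")
  }
  fs <- lapply(outcomes, function(x) {
    if (is.logical(x)) factor(x, levels = c(FALSE, TRUE), labels = c("no", "yes"))
    else if (is.factor(x)) x else factor(x)
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(u)
  alpha <- (1 - conf_level) / 2
  boot_idx <- if (boot > 0) {
    matrix(sample.int(n, n * boot, replace = TRUE), nrow = n)
  }
  any_clip <- FALSE
  out <- purrr::imap_dfr(fs, function(f, nm) {
    est <- bch_distal_point(u, f)
    any_clip <<- any_clip || attr(est, "clipped")
    res <- tibble::tibble(
      outcome = nm,
      class = rep(rownames(est), ncol(est)),
      category = rep(colnames(est), each = nrow(est)),
      percent = 100 * as.vector(est))
    if (boot > 0) {
      reps <- vapply(seq_len(boot), function(b) {
        idx <- boot_idx[, b]
        as.vector(bch_distal_point(u[idx, , drop = FALSE], f[idx]))
      }, numeric(nrow(est) * ncol(est)))
      res$ci_low <- 100 * apply(reps, 1L, quantile, probs = alpha, names = FALSE)
      res$ci_high <- 100 * apply(reps, 1L, quantile, probs = 1 - alpha, names = FALSE)
    }
    res
  })
  if (any_clip) {
    warn("negative BCH cell estimate(s) clipped to 0 and renormalised")
  }
  out
}

# ---- weighted multinomial logistic regression -------------------------------

softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

# Negative weighted log-likelihood and gradient for multinomial logit with
# per-(individual, class) weights u (rows summing to 1) and reference class
# `ref`. beta is a (C-1) x p matrix in vector form, rows = non-ref classes.
wmlogit_obj <- function(beta_vec, X, u, ref) {
  C <- ncol(u); p <- ncol(X)
  beta <- matrix(0, C, p)
  beta[-ref, ] <- matrix(beta_vec, C - 1L, p)
  eta <- X %*% t(beta)
  m <- apply(eta, 1L, max)
  lse <- m + log(rowSums(exp(eta - m)))
  # row sums of u are 1, so the logsumexp coefficient is 1 per row (convex)
  -(sum(u * eta) - sum(lse))
}

wmlogit_grad <- function(beta_vec, X, u, ref) {
  C <- ncol(u); p <- ncol(X)
  beta <- matrix(0, C, p)
  beta[-ref, ] <- matrix(beta_vec, C - 1L, p)
  pi_hat <- softmax_rows(X %*% t(beta))
  G <- t(pi_hat - u) %*% X   # C x p
  as.vector(G[-ref, , drop = FALSE])
}

fit_wmlogit <- function(X, u, ref, start = NULL, max_iter = 100L,
                        tol = 1e-10) {
  # damped Newton on the convex negative weighted log-likelihood; the
  # Hessian is the standard multinomial-logit Hessian (each individual's
  # weights sum to 1) plus a tiny ridge for numerical safety
  C <- ncol(u); p <- ncol(X)
  free <- setdiff(seq_len(C), ref)
  beta_vec <- start %||% numeric((C - 1L) * p)
  obj <- wmlogit_obj(beta_vec, X, u, ref)
  for (it in seq_len(max_iter)) {
    beta <- matrix(0, C, p)
    beta[free, ] <- matrix(beta_vec, C - 1L, p)
    pi_hat <- softmax_rows(X %*% t(beta))
    grad <- as.vector((t(pi_hat) %*% X - t(u) %*% X)[free, , drop = FALSE])
    H <- matrix(0, (C - 1L) * p, (C - 1L) * p)
    for (a in seq_along(free)) {
      for (b in seq_len(a)) {
        wab <- if (a == b) pi_hat[, free[a]] * (1 - pi_hat[, free[a]])
               else -pi_hat[, free[a]] * pi_hat[, free[b]]
        blk <- crossprod(X * wab, X)
        # parameters are vectorised column-major over the (C-1) x p matrix,
        # so entry (class a, predictor s) sits at (s-1)(C-1) + a
        ra <- a + (C - 1L) * (seq_len(p) - 1L)
        rb <- b + (C - 1L) * (seq_len(p) - 1L)
        H[ra, rb] <- blk
        if (a != b) H[rb, ra] <- t(blk)
      }
    }
    diag(H) <- diag(H) + 1e-8
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    lambda <- 1
    repeat {
      cand <- beta_vec - lambda * step
      obj_new <- wmlogit_obj(cand, X, u, ref)
      if (obj_new <= obj + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    done <- max(abs(beta_vec - cand)) < 1e-8 || abs(obj - obj_new) < tol * (abs(obj) + 1)
    beta_vec <- cand
    obj <- obj_new
    if (done) break
  }
  beta <- matrix(0, C, p, dimnames = list(colnames(u), colnames(X)))
  beta[free, ] <- matrix(beta_vec, C - 1L, p)
  list(beta = beta, value = -obj, convergence = 0L)
}

build_covariate_matrix <- function(covariates) {
  covariates <- covariates[setdiff(names(covariates), "participant_id")]
  if (anyNA(covariates)) {
    abort("covariates contain missing values; BCH regression is complete-case — filter first")
  }
  covariates <- as.data.frame(lapply(covariates, function(x) {
    if (is.character(x) || is.logical(x)) factor(x) else x
  }))
  X <- stats::model.matrix(~ ., data = covariates)
  attr(X, "terms") <- NULL
  X
}

#' BCH-weighted multinomial logistic regression of class on covariates
#'
#' Expands each individual into C pseudo-records carrying the BCH weights
#' and maximises the weighted multinomial log-likelihood
#' `sum_i sum_c u_ic log P(class = c | x_i; beta)`. Because each
#' individual's weights sum to 1 the objective is convex, so BFGS with the
#' analytic gradient finds the global optimum. Odds ratios contrast each
#' class against the reference class (default: the largest class, the
#' minimal-symptoms analogue); confidence intervals are nonparametric
#' bootstrap percentiles over individuals, with BCH weights recomputed per
#' resample from the fixed classification-error matrix.
#'
#' @param fit An [lca_fit()] or [bch_weights()] object.
#' @param covariates Data frame of covariates (factors/characters become
#'   dummy-coded with the first level as reference; numeric kept linear),
#'   one row per fitted individual, complete cases only.
#' @param reference `"largest"` (default) or a class index.
#' @param boot Bootstrap resamples for CIs (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `"bch_regression"` with the coefficient matrix,
#'   weights, model matrix and bootstrap draws; use [tidy.bch_regression()]
#'   for the odds-ratio table.
#' @export
bch_regression <- function(fit, covariates, reference = "largest",
                           boot = 500, seed = NULL, conf_level = 0.95) {
  w <- resolve_bch(fit)
  u <- w$u
  C <- ncol(u)
  X <- build_covariate_matrix(covariates)
  if (nrow(X) != nrow(u)) abort("`covariates` must have one row per fitted individual")
  ref <- if (identical(reference, "largest")) {
    unname(which.max(colSums(u)))
  } else {
    as.integer(reference)
  }

  point <- fit_wmlogit(X, u, ref)
  big <- abs(point$beta) > 15
  if (any(big)) {
    abort(sprintf("possible separation: unbounded coefficient(s) for %s",
                  paste(unique(colnames(X)[which(big, arr.ind = TRUE)[, 2]]),
                        collapse = ", ")))
  }

  boot_beta <- NULL
  if (boot > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- nrow(u)
    start <- as.vector(point$beta[-ref, , drop = FALSE])
    boot_beta <- array(NA_real_, dim = c(C, ncol(X), boot),
                       dimnames = list(rownames(point$beta), colnames(X), NULL))
    for (b in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_wmlogit(X[idx, , drop = FALSE], u[idx, , drop = FALSE],
                                 ref, start = start),
                     error = function(e) NULL)
      if (!is.null(fb)) boot_beta[, , b] <- fb$beta
    }
  }
  structure(list(beta = point$beta, loglik = point$value, reference = ref,
                 classes = w$classes, u = u, X = X, D = w$D,
                 boot_beta = boot_beta, conf_level = conf_level,
                 covariate_data = tibble::as_tibble(covariates)),
            class = "bch_regression")
}

#' Predicted class-membership probabilities from a BCH covariate model
#'
#' @param object A [bch_regression()] object.
#' @param ... Unused.
#' @return n x C matrix of `P(class = c | x_i)`.
#' @export
predict_class_probs <- function(object, ...) {
  pr <- softmax_rows(object$X %*% t(object$beta))
  colnames(pr) <- object$classes
  pr
}

#' Odds-ratio table of a BCH covariate regression
#'
#' @param x A [bch_regression()] object.
#' @param ... Unused.
#' @return Tibble with `class`, `term`, `or`, `ci_low`, `ci_high` (bootstrap
#'   percentile, when available). Reference-class rows and intercepts are
#'   omitted; reference covariate levels are implicit (OR 1).
#' @export
tidy.bch_regression <- function(x, ...) {
  C <- nrow(x$beta)
  keep_cls <- setdiff(seq_len(C), x$reference)
  terms <- setdiff(colnames(x$beta), "(Intercept)")
  out <- tidyr::expand_grid(class = x$classes[keep_cls], term = terms)
  out$or <- exp(x$beta[cbind(match(out$class, x$classes), match(out$term, colnames(x$beta)))])
  if (!is.null(x$boot_beta)) {
    alpha <- (1 - x$conf_level) / 2
    idx <- cbind(match(out$class, x$classes), match(out$term, colnames(x$beta)))
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    for (r in seq_len(nrow(out))) {
      draws <- x$boot_beta[idx[r, 1], idx[r, 2], ]
      draws <- draws[!is.na(draws)]
      out$ci_low[r] <- exp(quantile(draws, alpha, names = FALSE))
      out$ci_high[r] <- exp(quantile(draws, 1 - alpha, names = FALSE))
    }
  }
  out$reference_class <- x$classes[x$reference]
  out
}

#' @export
print.bch_regression <- function(x, ...) {
  cat(sprintf("BCH multinomial regression: %d classes (reference: %s), %d terms\n",
              length(x$classes), x$classes[x$reference], ncol(x$beta)))
  print(as.data.frame(dplyr::mutate(tidy(x), dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 3)))), row.names = FALSE)
  invisible(x)
}
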