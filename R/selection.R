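# Model comparison across class counts and class-separation diagnostics:
# G-squared against the saturated pattern multinomial, AIC/BIC on both the
# G-squared and -2LL scales, relative entropy, average posterior
# probabilities by modal class, and multi-start replicate stability.

#' Likelihood-ratio statistic against the saturated pattern model
#'
#' `G^2 = 2 (LL_sat - LL_model)` where `LL_sat = sum_p n_p log(n_p / n)`
#' over the distinct observed response patterns. The missingness pattern is
#' part of the pattern key, so partially missing rows stay well-defined
#' without imputation.
#'
#' @param fit An [lca_fit()] object.
#' @param data Optional indicator data; defaults to the data the model was
#'   fitted to. If supplied it must have the same number of rows.
#' @return Non-negative scalar (up to numerical tolerance).
#' @export
g_squared <- function(fit, data = NULL) {
  y <- if (is.null(data)) fit$y else as_indicator_matrix(data, fit$n_levels)
  if (nrow(y) != fit$n) abort("`data` does not match the fitted model (row count)")
  key <- apply(y, 1L, paste, collapse = ".")
  n_p <- table(key)
  ll_sat <- sum(n_p * log(n_p / nrow(y)))
  2 * (ll_sat - fit$loglik)
}

#' Information criteria on the G-squared and -2LL bases
#'
#' Reports AIC and BIC both as `G^2 + penalty` (the convention of the LCA
#' software lineage whose fit tables the G-squared column structure mirrors)
#' and as `-2 LL + penalty`. On either basis `BIC - AIC = P (ln n - 2)`, and
#' differences between models fitted to the same data are identical across
#' bases (the saturated term cancels).
#'
#' @inheritParams g_squared
#' @return Tibble with columns `basis` (`"G2"`, `"minus2LL"`), `AIC`, `BIC`.
#' @export
information_criteria <- function(fit, data = NULL) {
  g2 <- g_squared(fit, data)
  P <- fit$n_params
  n <- fit$n
  tibble::tibble(
    basis = c("G2", "minus2LL"),
    AIC = c(g2 + 2 * P, -2 * fit$loglik + 2 * P),
    BIC = c(g2 + P * log(n), -2 * fit$loglik + P * log(n))
  )
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - sum_i sum_c (-p_ic log p_ic) / (n log C)`, with `0 log 0 = 0`.
#' 1 means perfectly separated classes (one-hot posteriors), 0 means no
#' separation (uniform posteriors).
#'
#' @param posteriors n x C matrix of normalised posterior probabilities, or
#'   an [lca_fit()] object.
#' @return Scalar in `[0, 1]`.
#' @export
relative_entropy <- function(posteriors) {
  p <- if (inherits(posteriors, "lca_fit")) posteriors$posterior else posteriors
  C <- ncol(p)
  if (C < 2L) abort("relative entropy is undefined for a 1-class model")
  h <- -p * log(p)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(p) * log(C))
}

#' Modal class assignment
#'
#' Argmax of each posterior row; ties go to the lowest class index
#' (deterministic).
#'
#' @inheritParams relative_entropy
#' @return Integer vector of class indices in `1..C`.
#' @export
modal_assignment <- function(posteriors) {
  p <- if (inherits(posteriors, "lca_fit")) posteriors$posterior else posteriors
  max.col(p, ties.method = "first")
}

#' Average posterior probabilities by modal class
#'
#' Entry `(k, j)` is the mean posterior probability of class `j` among
#' individuals modally assigned to class `k`. Diagonal values above 0.7 are
#' conventionally read as indicating well-separated classes.
#'
#' @inheritParams relative_entropy
#' @return C x C matrix (rows sum to 1) with class dimnames.
#' @export
avepp_matrix <- function(posteriors) {
  p <- if (inherits(posteriors, "lca_fit")) posteriors$posterior else posteriors
  C <- ncol(p)
  modal <- modal_assignment(p)
  counts <- tabulate(modal, nbins = C)
  if (any(counts == 0L)) {
    abort(sprintf("empty modal class: %s", paste(which(counts == 0L), collapse = ", ")))
  }
  m <- rowsum(p, group = modal) / counts
  cls <- colnames(p) %||% paste0("class", seq_len(C))
  dimnames(m) <- list(cls, cls)
  m
}

#' Share of random starts reaching the best log-likelihood
#'
#' `100 * #(converged starts with loglik >= best - tol) / #(starts)`; the
#' model-stability column of the fit-comparison table.
#'
#' @param start_logliks Final log-likelihoods of every start (NA or -Inf for
#'   failed starts), or an [lca_fit()] object.
#' @param tol Log-likelihood tie tolerance (default 0.01).
#' @return Percentage in `(0, 100]`.
#' @export
replicate_stability <- function(start_logliks, tol = 0.01) {
  if (inherits(start_logliks, "lca_fit")) {
    fit <- start_logliks
    ll <- fit$chain_info$loglik[fit$chain_info$converged]
    n_starts <- nrow(fit$chain_info)
  } else {
    ll <- start_logliks[is.finite(start_logliks)]
    n_starts <- length(start_logliks)
  }
  if (length(ll) == 0L) abort("no converged starts")
  100 * sum(ll >= max(ll) - tol) / n_starts
}

#' Fit latent class models across a range of class counts
#'
#' Fits each candidate number of classes with [lca_fit()] and assembles the
#' goodness-of-fit comparison table: degrees of freedom, AIC and BIC on both
#' the G-squared and -2LL bases, log-likelihood, smallest class prevalence,
#' relative entropy and replicate stability. No class count is selected
#' automatically: the print method restates the selection criteria (lower
#' AIC/BIC, higher entropy, class sizes, stability, AvePP diagonals > 0.7,
#' substantive meaning) and flags when the BIC is still decreasing at the
#' edge of the range; choosing C is the analyst's act.
#'
#' @inheritParams lca_fit
#' @param n_classes Integer vector of class counts to fit (default `1:6`).
#' @param ... Further arguments passed to [lca_fit()].
#' @return Object of class `"lca_sweep"`: list with `results` (one tibble
#'   row per class count), `fits` (named list of `lca_fit` objects; `NULL`
#'   where a fit failed) and `errors`.
#' @export
lca_sweep <- function(data, n_classes = 1:6, n_starts = 100, seed = NULL, ...) {
  y <- as_indicator_matrix(data)
  fits <- vector("list", length(n_classes))
  errors <- setNames(vector("list", length(n_classes)), as.character(n_classes))
  for (i in seq_along(n_classes)) {
    C <- n_classes[i]
    seed_c <- if (is.null(seed)) NULL else as.integer(seed) + C
    fits[[i]] <- tryCatch(
      lca_fit(y, C, n_starts = n_starts, seed = seed_c, ...),
      error = function(e) {
        errors[[as.character(C)]] <<- conditionMessage(e)
        warn(sprintf("fit with %d classes failed: %s", C, conditionMessage(e)))
        NULL
      })
  }
  names(fits) <- paste0("C", n_classes)
  results <- purrr::map2_dfr(fits, n_classes, function(f, C) {
    if (is.null(f)) {
      return(tibble::tibble(n_classes = C, df = lca_df(ncol(y), attr(y, "K"), C),
                            loglik = NA_real_, g_squared = NA_real_,
                            AIC_G2 = NA_real_, BIC_G2 = NA_real_,
                            AIC_LL = NA_real_, BIC_LL = NA_real_,
                            smallest_class_prob = NA_real_, entropy = NA_real_,
                            pct_best_replicates = NA_real_))
    }
    ic <- information_criteria(f)
    tibble::tibble(
      n_classes = C,
      df = f$df,
      loglik = f$loglik,
      g_squared = g_squared(f),
      AIC_G2 = ic$AIC[1], BIC_G2 = ic$BIC[1],
      AIC_LL = ic$AIC[2], BIC_LL = ic$BIC[2],
      smallest_class_prob = min(f$params$gamma),
      entropy = if (C > 1L) relative_entropy(f) else NA_real_,
      pct_best_replicates = replicate_stability(f)
    )
  })
  structure(list(results = results, fits = fits, errors = errors,
                 n_starts = n_starts, seed = seed),
            class = "lca_sweep")
}

#' @export
print.lca_sweep <- function(x, ...) {
  cat("Latent class model comparison\n")
  print(as.data.frame(dplyr::mutate(x$results, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 3)))), row.names = FALSE)
  cat("\nSelection criteria (judged together, no automatic choice):\n",
      " - lower AIC/BIC (G2 basis shown first) balances fit and parsimony\n",
      " - higher relative entropy = better class separation\n",
      " - relative class sizes (avoid vanishing classes)\n",
      " - higher % of replicates at the best log-likelihood = stability\n",
      " - AvePP diagonals > 0.7 (see avepp_matrix()) and substantive meaning\n",
      sep = "")
  ok <- !is.na(x$results$BIC_G2)
  if (sum(ok) >= 2L) {
    bic <- x$results$BIC_G2[ok]
    if (which.min(bic) == sum(ok)) {
      cat("note: BIC is still decreasing at the upper edge of the class range\n")
    }
  }
  invisible(x)
}

#' @export
tidy.lca_sweep <- function(x, ...) x$results

#' Plot the class-count comparison
#'
#' Line plot of AIC/BIC (G-squared basis) and relative entropy against the
#' number of classes.
#'
#' @param object An [lca_sweep()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lca_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$results[c("n_classes", "AIC_G2", "BIC_G2", "entropy")],
    cols = -"n_classes", names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_classes, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of classes", y = NULL,
                  title = "Latent class model comparison")
}
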