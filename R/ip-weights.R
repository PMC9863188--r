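# Inverse-propensity balancing across latent classes.
#
# The BCH-weighted covariate model doubles as the propensity model: the
# stabilised weight for pseudo-record (i, c) is
# w_ic = P(class = c) / P(class = c | x_i), and the combined analysis weight
# is u_ic * w_ic. Balance is checked with weighted standardised mean
# differences per covariate level, each class against the reference.

#' Inverse-propensity weights for balancing covariates across classes
#'
#' Builds stabilised inverse-propensity weights from a BCH-weighted
#' multinomial covariate model (fitted internally if not supplied) and
#' reports standardised-mean-difference balance diagnostics before (BCH
#' weights only) and after (combined BCH-and-IP weights) weighting.
#'
#' @param fit An [lca_fit()] or [bch_weights()] object.
#' @param covariates Data frame of covariates, one row per individual
#'   (complete cases).
#' @param class_model Optional fitted [bch_regression()] on the same
#'   individuals; computed internally (without bootstrap) when `NULL`.
#' @param reference `"largest"` or a class index (passed to
#'   [bch_regression()] when the model is fitted internally).
#' @param min_prob Predicted class probabilities below this trigger an
#'   error listing extreme individuals.
#' @return Object of class `"ip_weights"`: list with `w` (n x C stabilised
#'   weights), `smd` (tibble of balance diagnostics), `mean_weight`,
#'   `class_model` and `reference`.
#' @export
ip_weights <- function(fit, covariates, class_model = NULL,
                       reference = "largest", min_prob = 1e-6) {
  w_bch <- resolve_bch(fit)
  u <- w_bch$u
  if (is.null(class_model)) {
    class_model <- bch_regression(w_bch, covariates, reference = reference, boot = 0)
  }
  pr <- predict_class_probs(class_model)
  if (nrow(pr) != nrow(u)) abort("class model and weights cover different individuals")
  if (any(pr < min_prob)) {
    bad <- unique(which(pr < min_prob, arr.ind = TRUE)[, 1])
    abort(sprintf("predicted class probability below %g for individual(s): %s",
                  min_prob, paste(head(bad, 10), collapse = ", ")))
  }
  marg <- colSums(u) / nrow(u)          # BCH-estimated class prevalences
  w <- sweep(1 / pr, 2L, marg, "*")     # stabilised: gamma_c / P(c | x)
  colnames(w) <- w_bch$classes
  mean_weight <- mean(rowSums(u * w))
  smd <- balance_smd(u, u * w, class_model$covariate_data, class_model$reference)
  structure(list(w = w, smd = smd, mean_weight = mean_weight,
                 class_model = class_model, reference = class_model$reference,
                 classes = w_bch$classes),
            class = "ip_weights")
}

weighted_level_props <- function(x, wt) {
  # wt: n x C; returns levels x C matrix of weighted proportions
  f <- if (is.factor(x)) x else factor(x)
  tot <- colSums(wt)
  m <- vapply(levels(f), function(l) colSums(wt[f == l, , drop = FALSE]) / tot,
              numeric(ncol(wt)))
  t(m)
}

balance_smd <- function(u, uw, covariates, ref) {
  covariates <- covariates[setdiff(names(covariates), "participant_id")]
  C <- ncol(u)
  purrr::imap_dfr(covariates, function(x, nm) {
    if (is.numeric(x) && !is.factor(x)) {
      # continuous: weighted mean difference over pooled SD
      stat <- function(wt) {
        mu <- colSums(wt * x) / colSums(wt)
        v <- colSums(wt * (x - rep(mu, each = length(x)))^2) / colSums(wt)
        list(mu = mu, v = v)
      }
      smd_of <- function(wt) {
        s <- stat(wt)
        (s$mu - s$mu[ref]) / sqrt((s$v + s$v[ref]) / 2)
      }
      before <- smd_of(u); after <- smd_of(uw)
      keep <- setdiff(seq_len(C), ref)
      tibble::tibble(covariate = nm, level = "(mean)",
                     class = colnames(u)[keep],
                     smd_before = before[keep], smd_after = after[keep])
    } else {
      pb <- weighted_level_props(x, u)
      pa <- weighted_level_props(x, uw)
      smd_cat <- function(p) {
        sw <- sweep(p, 1L, p[, ref], "-") /
          sqrt((p * (1 - p) + p[, ref] * (1 - p[, ref])) / 2)
        sw[!is.finite(sw)] <- 0
        sw
      }
      sb <- smd_cat(pb); sa <- smd_cat(pa)
      keep <- setdiff(seq_len(C), ref)
      tibble::tibble(
        covariate = nm,
        level = rep(rownames(pb), length(keep)),
        class = rep(colnames(u)[keep], each = nrow(pb)),
        smd_before = as.vector(sb[, keep]),
        smd_after = as.vector(sa[, keep]))
    }
  })
}

#' @export
print.ip_weights <- function(x, ...) {
  cat(sprintf("IP weights: mean combined stabilised weight %.3f (target 1)\n",
              x$mean_weight))
  cat(sprintf("max |SMD| before weighting %.3f, after %.3f (balance if < 0.1)\n",
              max(abs(x$smd$smd_before)), max(abs(x$smd$smd_after))))
  invisible(x)
}

#' @export
tidy.ip_weights <- function(x, ...) x$smd

#' Covariate balance (love) plot for IP weighting
#'
#' Absolute standardised mean differences per covariate level and class
#' contrast, before (BCH only) and after (BCH + IP) weighting, with the
#' conventional 0.1 balance threshold.
#'
#' @param object An [ip_weights()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ip_weights <- function(object, ...) {
  long <- tidyr::pivot_longer(object$smd, cols = c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd")
  long$stage <- factor(long$stage, levels = c("smd_before", "smd_after"),
                       labels = c("BCH weighted", "BCH + IP weighted"))
  long$label <- paste(long$covariate, long$level, sep = ": ")
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd), y = .data$label,
                                     colour = .data$stage, shape = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardised mean difference|", y = NULL,
                  colour = NULL, shape = "class vs reference",
                  title = "Covariate balance across latent classes")
}
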