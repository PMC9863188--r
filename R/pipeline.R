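# Pipeline orchestration and presentation artifacts: the class-profile
# table used to name classes, deterministic naming suggestions, and a
# reproducible end-to-end run writing tidy CSV artifacts plus a manifest.

#' Class profile table: response-level percents by class vs the margin
#'
#' For every indicator and response level, the model-based class-specific
#' percent (from the fitted item-response probabilities), the marginal
#' percent in the study population (prevalence-weighted mixture of the
#' class profiles), the posterior-weighted empirical percent, and a flag
#' marking class percents higher/lower than the marginal. Classes are named
#' by comparing the `sometimes` and `often` percents of each class against
#' the whole-population percents.
#'
#' @param fit An [lca_fit()] object.
#' @param data Optional indicator data (defaults to the fitted data) for
#'   the empirical percents.
#' @param tol Flag percents within `tol` of the marginal as `"neutral"`.
#' @return Tibble with columns `item`, `level`, `class`, `percent_model`,
#'   `percent_empirical`, `percent_marginal`, `flag`.
#' @export
class_profile_table <- function(fit, data = NULL, tol = 1e-8) {
  y <- if (is.null(data)) fit$y else as_indicator_matrix(data, fit$n_levels)
  post <- fit$posterior
  gamma <- fit$params$gamma
  purrr::imap_dfr(fit$params$rho, function(m, item) {
    j <- match(item, fit$item_names)
    obs <- y[, j] > 0L
    wsum <- colSums(post[obs, , drop = FALSE])
    emp <- vapply(seq_len(nrow(m)), function(k) {
      colSums(post[obs & y[, j] == k, , drop = FALSE]) / wsum
    }, numeric(ncol(post)))
    marg <- as.vector(m %*% gamma)
    tibble::tibble(
      item = item,
      level = rep(c("never_rarely", "sometimes", "often")[seq_len(nrow(m))],
                  each = ncol(m)),
      class = rep(colnames(m), nrow(m)),
      percent_model = 100 * as.vector(t(m)),
      percent_empirical = 100 * as.vector(emp),
      percent_marginal = 100 * rep(marg, each = ncol(m)),
      flag = dplyr::case_when(
        .data$percent_model > .data$percent_marginal + 100 * tol ~ "higher",
        .data$percent_model < .data$percent_marginal - 100 * tol ~ "lower",
        TRUE ~ "neutral"))
  })
}

#' Deterministic class-naming suggestions from a profile table
#'
#' Summarises, for each class, which indicators sit above and below the
#' marginal percents at the `sometimes` and `often` levels. No labels are
#' invented beyond the flag lists: naming the classes is the analyst's act.
#'
#' @param profile Output of [class_profile_table()].
#' @return Tibble with one row per class and level: `class`, `level`,
#'   `higher` and `lower` (comma-separated indicator lists), `n_higher`,
#'   `n_lower`, and a `summary` sentence.
#' @export
name_suggestions <- function(profile) {
  keep <- profile[profile$level %in% c("sometimes", "often"), ]
  out <- keep |>
    dplyr::group_by(.data$class, .data$level) |>
    dplyr::summarise(
      higher = paste(.data$item[.data$flag == "higher"], collapse = ", "),
      lower = paste(.data$item[.data$flag == "lower"], collapse = ", "),
      n_higher = sum(.data$flag == "higher"),
      n_lower = sum(.data$flag == "lower"),
      .groups = "drop")
  n_items <- length(unique(profile$item))
  out$summary <- dplyr::case_when(
    out$n_higher == 0L & out$n_lower == n_items ~
      sprintf("below-marginal on all indicators at '%s'", out$level),
    out$n_higher == n_items ~
      sprintf("above-marginal on all indicators at '%s'", out$level),
    out$n_higher == 0L & out$n_lower == 0L ~
      sprintf("at the margin on all indicators at '%s'", out$level),
    TRUE ~ sprintf("above-marginal at '%s': %s", out$level,
                   ifelse(out$higher == "", "(none)", out$higher)))
  out
}

#' Plot class-specific distal outcome distributions
#'
#' Bar chart of the BCH-weighted outcome category percents by latent class.
#'
#' @param distal Output tibble of [bch_distal()].
#' @return A ggplot object.
#' @export
plot_distal <- function(distal) {
  p <- ggplot2::ggplot(distal, ggplot2::aes(x = .data$category,
                                            y = .data$percent,
                                            fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "percent of class",
                  title = "Health service use by latent class (BCH weighted)")
  if ("ci_low" %in% names(distal)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3)
  }
  p
}

#' Plot class symptom profiles
#'
#' Line plot of the model-based percents for the `sometimes` and `often`
#' levels of every indicator per class, against the marginal percents.
#'
#' @param profile Output of [class_profile_table()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  keep <- profile[profile$level %in% c("sometimes", "often"), ]
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$item, y = .data$percent_model,
                                     group = .data$class, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$percent_marginal),
                        colour = "grey40", shape = 4) +
    ggplot2::facet_wrap(~level, ncol = 1) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "percent of class (model)",
                  title = "Symptom frequency by latent class (x = marginal)")
}

#' Run the full symptom-pattern analysis pipeline
#'
#' Recode -> class-count sweep -> diagnostics for the chosen class count ->
#' class profile -> BCH covariate regression -> BCH (and optionally
#' BCH+IP) distal outcome tables, writing tidy CSV artifacts and a
#' manifest (seeds, file hashes, versions) sufficient to re-run
#' bit-identically.
#'
#' @param survey Raw survey data frame (see [recode_symptoms()]), including
#'   `return_date` when service tables are supplied.
#' @param covariates Covariate data frame keyed by `participant_id`
#'   (complete cases retained; others dropped with a message).
#' @param visits,dispensings,admissions Service record tables (see
#'   [recode_service_use()]); any may be `NULL`.
#' @param out_dir Output directory for artifacts.
#' @param n_classes_range Class counts for the comparison sweep.
#' @param chosen_classes Class count used for the three-step stages.
#' @param n_starts Random starts per fit.
#' @param seed Master seed; every random stage derives its seed from it.
#' @param boot Bootstrap resamples for three-step CIs.
#' @param ip_weighting Also compute BCH+IP weighted distal tables.
#' @param reference Reference class rule for the regression.
#' @param dialect Survey response dialect (see [recode_symptoms()]).
#' @return Invisibly, a list with every in-memory artifact (`indicators`,
#'   `outcomes`, `sweep`, `fit`, `avepp`, `profile`, `naming`,
#'   `regression`, `distal`, `distal_ip`, `manifest`).
#' @export
run_lca_pipeline <- function(survey, covariates, visits = NULL,
                             dispensings = NULL, admissions = NULL,
                             out_dir = NULL, n_classes_range = 1:6,
                             chosen_classes = 4, n_starts = 100, seed = 1,
                             boot = 500, ip_weighting = TRUE,
                             reference = "largest",
                             dialect = c("labels", "codes")) {
  dialect <- match.arg(dialect)
  stage <- function(what, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)))
    })
    message(sprintf("[%s] %.1fs", what, as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  indicators <- stage("recode symptoms", recode_symptoms(survey, dialect = dialect))

  # complete-case on covariates, keeping indicator and covariate rows aligned
  covariates <- covariates[match(indicators$participant_id,
                                 covariates$participant_id), , drop = FALSE]
  cc <- stats::complete.cases(covariates)
  if (any(!cc)) {
    inform(sprintf("dropped %d participant(s) with missing covariate data", sum(!cc)))
    indicators <- indicators[cc, , drop = FALSE]
    covariates <- covariates[cc, , drop = FALSE]
  }

  outcomes <- NULL
  if (!is.null(visits) || !is.null(dispensings) || !is.null(admissions)) {
    sd <- survey[c("participant_id", "return_date")]
    sd <- sd[sd$participant_id %in% indicators$participant_id, ]
    outcomes <- stage("recode service use",
                      recode_service_use(sd, visits = visits,
                                         dispensings = dispensings,
                                         admissions = admissions))
    outcomes <- outcomes[match(indicators$participant_id,
                               outcomes$participant_id), , drop = FALSE]
  }

  sweep_res <- stage("class-count sweep",
                     lca_sweep(indicators, n_classes = n_classes_range,
                               n_starts = n_starts, seed = seed))
  fit <- sweep_res$fits[[paste0("C", chosen_classes)]]
  if (is.null(fit)) abort(sprintf("no fit available for %d classes", chosen_classes))

  avepp <- stage("diagnostics", avepp_matrix(fit))
  profile <- stage("class profiles", class_profile_table(fit))
  naming <- name_suggestions(profile)

  regression <- stage("BCH covariate regression",
                      bch_regression(fit, covariates, reference = reference,
                                     boot = boot, seed = seed + 101L))
  distal <- distal_ip <- NULL
  if (!is.null(outcomes)) {
    distal <- stage("BCH distal outcomes",
                    bch_distal(fit, outcomes, boot = boot, seed = seed + 202L))
    if (ip_weighting) {
      ipw <- stage("IP weights", ip_weights(fit, covariates,
                                            class_model = regression))
      distal_ip <- stage("BCH+IP distal outcomes",
                         bch_distal(fit, outcomes, boot = boot,
                                    seed = seed + 303L, ip = ipw))
    }
  }

  artifacts <- list(indicators = indicators, outcomes = outcomes,
                    sweep = sweep_res, fit = fit, avepp = avepp,
                    profile = profile, naming = naming,
                    regression = regression, distal = distal,
                    distal_ip = distal_ip)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      path <- file.path(out_dir, name)
      readr::write_csv(x, path)
      path
    }
    files <- c(
      wr(indicators, "indicators.csv"),
      if (!is.null(outcomes)) wr(outcomes, "outcomes.csv"),
      wr(sweep_res$results, "sweep.csv"),
      wr(tibble::as_tibble(avepp, rownames = "modal_class"), "avepp.csv"),
      wr(profile, "profile.csv"),
      wr(tidy(regression), "associations.csv"),
      if (!is.null(distal)) wr(distal, "distal.csv"),
      if (!is.null(distal_ip)) wr(distal_ip, "distal_ip.csv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("sympat")),
      r_version = R.version.string,
      seed = seed,
      n_starts = n_starts,
      n_classes_range = n_classes_range,
      chosen_classes = chosen_classes,
      boot = boot,
      ip_weighting = ip_weighting,
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    artifacts$manifest <- manifest
  }
  invisible(artifacts)
}
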