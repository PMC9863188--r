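# Synthetic cohort generator.
#
# Real cohort data of this kind (survey plus linked administrative records)
# are access-restricted, so every downstream stage is exercised against
# synthetic cohorts drawn from a fully known latent-class truth: a class is
# drawn per participant, the 19 raw four-level symptom responses are drawn
# class-conditionally (independent within class), MCAR missingness is
# applied, covariates and service-use outcomes are drawn from
# class-conditional distributions, and service use is rendered as dated
# records — including decoy records outside the counting windows and
# pregnancy-coded admissions, so the recoding filters are genuinely
# exercised. Truth labels are returned separately and never appear in the
# pipeline input tables.

simplex_check <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("%s is not a probability distribution", what))
  }
  invisible(p)
}

# class-conditional 4-level response profiles (never, rarely, sometimes, often)
profile_levels <- function() {
  list(
    low    = c(0.65, 0.20, 0.12, 0.03),
    mid    = c(0.35, 0.25, 0.28, 0.12),
    high   = c(0.15, 0.15, 0.40, 0.30),
    vhigh  = c(0.08, 0.10, 0.37, 0.45),
    rare   = c(0.85, 0.09, 0.05, 0.01),
    rare_mid = c(0.60, 0.20, 0.15, 0.05),
    rare_high = c(0.45, 0.20, 0.20, 0.15)
  )
}

#' Construct a synthetic cohort specification
#'
#' A full generative description of a cohort: class prevalences, per-class
#' four-level response distributions for the 19 raw items, class-conditional
#' covariate distributions, class-conditional service-use outcome
#' distributions, and an MCAR per-item missingness rate. The three-level
#' item-response truth implied by the recoding rules is available in closed
#' form via [implied_rho()].
#'
#' @param n Number of participants.
#' @param gamma Class prevalences (simplex).
#' @param raw_response_model List of 19 matrices (one per [symptom_items()]
#'   item), each 4 x C with columns summing to 1: `P(response | class)`.
#' @param covariate_model Named list; each element a levels x C matrix of
#'   class-conditional covariate distributions (columns sum to 1), plus a
#'   `"age"` entry handled as continuous is not supported — covariates are
#'   categorical.
#' @param outcome_model List with elements `gp` (6 x C), `specialist`
#'   (3 x C), `medication` (4 x C) — class-conditional bin distributions —
#'   and `admission` (2 x C, rows same-day and overnight admission
#'   probabilities, not a simplex).
#' @param missing_rate Per-item MCAR missingness probability.
#' @param label Scenario label.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n, gamma, raw_response_model, covariate_model,
                           outcome_model, missing_rate = 0.02,
                           label = "custom") {
  C <- length(gamma)
  simplex_check(gamma, "gamma")
  stopifnot(length(raw_response_model) == 19L)
  for (m in raw_response_model) {
    stopifnot(nrow(m) == 4L, ncol(m) == C)
    for (c in seq_len(C)) simplex_check(m[, c], "raw response column")
  }
  for (nm in names(covariate_model)) {
    for (c in seq_len(C)) simplex_check(covariate_model[[nm]][, c],
                                        paste("covariate", nm))
  }
  names(raw_response_model) <- symptom_items()
  structure(list(n = as.integer(n), n_classes = C, gamma = gamma,
                 raw_response_model = raw_response_model,
                 covariate_model = covariate_model,
                 outcome_model = outcome_model,
                 missing_rate = missing_rate, label = label),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic cohort spec '%s': n = %d, %d classes, gamma = (%s), %d%% MCAR\n",
              x$label, x$n, x$n_classes,
              paste(format(x$gamma, digits = 3), collapse = ", "),
              round(100 * x$missing_rate)))
  invisible(x)
}

# build a 19-item raw response model from a per-class intensity map
build_raw_model <- function(intensity_by_class) {
  lv <- profile_levels()
  items <- symptom_items()
  C <- length(intensity_by_class)
  lapply(items, function(it) {
    m <- vapply(intensity_by_class, function(map) lv[[map[[it]]]], numeric(4))
    rownames(m) <- RESPONSE_LEVELS
    m
  })
}

intensity_map <- function(default, ...) {
  over <- list(...)
  map <- setNames(rep(default, 19L), symptom_items())
  for (nm in names(over)) map[nm] <- over[[nm]]
  as.list(map)
}

paper_like_raw_model <- function() {
  menstrual <- c("premenstrual_tension", "heavy_periods", "severe_period_pain")
  mood <- c("depression", "intense_anxiety", "palpitations")
  build_raw_model(list(
    # minimal: everything infrequent
    minimal = intensity_map("low",
      urine_burns = "rare", urine_leak = "rare",
      constipation = "rare", haemorrhoids = "rare", other_bowel = "rare"),
    # menstrual-elevated, mood-suppressed
    menstrual = intensity_map("low",
      premenstrual_tension = "high", heavy_periods = "high",
      severe_period_pain = "high", irregular_periods = "mid",
      severe_tiredness = "mid", difficulty_sleeping = "mid",
      back_pain = "mid",
      urine_burns = "rare", urine_leak = "rare",
      constipation = "rare_mid", haemorrhoids = "rare", other_bowel = "rare_mid"),
    # mood-elevated, menstrual-suppressed
    mood = intensity_map("low",
      depression = "high", intense_anxiety = "high", palpitations = "high",
      severe_tiredness = "high", difficulty_sleeping = "high",
      headaches_migraines = "mid", back_pain = "mid",
      urine_burns = "rare_mid", urine_leak = "rare_mid",
      constipation = "rare_mid", haemorrhoids = "rare", other_bowel = "rare_mid"),
    # many: everything frequent
    many = intensity_map("vhigh",
      allergies = "high", vaginal_discharge = "high", skin_problems = "high",
      urine_burns = "rare_high", urine_leak = "rare_high",
      constipation = "rare_high", haemorrhoids = "rare_mid",
      other_bowel = "rare_high")
  ))
}

# class-conditional covariate distributions loosely shaped like the
# published whole-cohort profile tables (designed fixtures, not estimates)
paper_like_covariates <- function() {
  list(
    income_difficulty = matrix(c(
      .70, .24, .06,
      .53, .36, .11,
      .43, .37, .20,
      .26, .37, .37), nrow = 3,
      dimnames = list(c("not_too_bad", "sometimes", "always"), NULL)),
    education = matrix(c(
      .73, .16, .11,
      .61, .26, .13,
      .53, .29, .18,
      .33, .41, .26), nrow = 3,
      dimnames = list(c("degree", "certificate", "high_school"), NULL)),
    smoking = matrix(c(
      .925, .075,
      .862, .138,
      .835, .165,
      .707, .293), nrow = 2,
      dimnames = list(c("no", "yes"), NULL)),
    bmi = matrix(c(
      .668, .218, .114,
      .534, .255, .211,
      .543, .243, .214,
      .409, .219, .372), nrow = 3,
      dimnames = list(c("under_25", "25_to_29.9", "30_plus"), NULL))
  )
}

null_covariates_model <- function(C) {
  lapply(paper_like_covariates(), function(m) {
    marg <- rowMeans(m)
    matrix(rep(marg / sum(marg), C), nrow = nrow(m),
           dimnames = list(rownames(m), NULL))
  })
}

paper_like_outcomes <- function() {
  list(
    gp = matrix(c(
      .30, .28, .25, .10, .05, .02,
      .20, .26, .28, .14, .07, .05,
      .16, .24, .28, .16, .09, .07,
      .08, .16, .26, .20, .14, .16), nrow = 6,
      dimnames = list(GP_BINS, NULL)),
    specialist = matrix(c(
      .62, .30, .08,
      .52, .36, .12,
      .47, .38, .15,
      .35, .42, .23), nrow = 3,
      dimnames = list(SPECIALIST_BINS, NULL)),
    medication = matrix(c(
      .45, .27, .15, .13,
      .33, .28, .18, .21,
      .28, .27, .19, .26,
      .17, .22, .18, .43), nrow = 4,
      dimnames = list(MEDICATION_BINS, NULL)),
    admission = matrix(c(
      .045, .030,
      .070, .050,
      .090, .060,
      .140, .100), nrow = 2,
      dimnames = list(c("same_day", "overnight"), NULL))
  )
}

scale_outcomes <- function(model, C) {
  lapply(model, function(m) m[, seq_len(C), drop = FALSE])
}

#' Library of named synthetic-cohort scenarios
#'
#' * `paper_like`: four classes with the published prevalences
#'   (0.366, 0.219, 0.262, 0.153), profile shapes matching the four named
#'   patterns (minimal / menstrual-elevated / mood-elevated / elevated
#'   everywhere), class-dependent (confounded) covariates and a monotone
#'   service-use gradient many > mood > menstrual > minimal; n = 7797.
#' * `high_separation`: four well-separated block-structured classes
#'   (entropy above 0.9); n = 5000.
#' * `low_separation`: the same block structure with milder contrasts
#'   (entropy around 0.6-0.75), the regime where the BCH correction
#'   matters; n = 5000.
#' * `null_covariates`: well-separated classes with covariates drawn
#'   independently of class (all true covariate odds ratios 1); n = 2000.
#'
#' @return Named list of [synthetic_spec()] objects.
#' @export
scenario_library <- function() {
  lv <- profile_levels()
  sep_model <- function(lo, hi) {
    # block structure: class1 low everywhere, class2 high on items 1-8,
    # class3 high on items 9-16, class4 high everywhere (items 17-19, the
    # bowel sources, follow class4 only mildly)
    items <- symptom_items()
    lapply(seq_along(items), function(j) {
      cols <- cbind(
        lo,
        if (j <= 8) hi else lo,
        if (j > 8 && j <= 16) hi else lo,
        hi)
      rownames(cols) <- RESPONSE_LEVELS
      cols
    })
  }
  hi_sep <- sep_model(lo = c(0.90, 0.05, 0.04, 0.01), hi = c(0.02, 0.03, 0.15, 0.80))
  lo_sep <- sep_model(lo = c(0.55, 0.20, 0.17, 0.08), hi = c(0.22, 0.16, 0.33, 0.29))
  even_gamma <- c(0.30, 0.25, 0.25, 0.20)

  list(
    paper_like = synthetic_spec(
      n = 7797, gamma = c(0.366, 0.219, 0.262, 0.153),
      raw_response_model = paper_like_raw_model(),
      covariate_model = paper_like_covariates(),
      outcome_model = paper_like_outcomes(),
      missing_rate = 0.02, label = "paper_like"),
    high_separation = synthetic_spec(
      n = 5000, gamma = even_gamma,
      raw_response_model = hi_sep,
      covariate_model = paper_like_covariates(),
      outcome_model = paper_like_outcomes(),
      missing_rate = 0.02, label = "high_separation"),
    low_separation = synthetic_spec(
      n = 5000, gamma = even_gamma,
      raw_response_model = lo_sep,
      covariate_model = paper_like_covariates(),
      outcome_model = paper_like_outcomes(),
      missing_rate = 0.02, label = "low_separation"),
    null_covariates = synthetic_spec(
      n = 2000, gamma = even_gamma,
      raw_response_model = hi_sep,
      covariate_model = null_covariates_model(4L),
      outcome_model = paper_like_outcomes(),
      missing_rate = 0.02, label = "null_covariates")
  )
}

sample_categorical <- function(prob_matrix, class, levels) {
  # prob_matrix: levels x C; class: integer vector
  n <- length(class)
  u <- runif(n)
  cum <- apply(prob_matrix, 2L, cumsum)
  idx <- rowSums(outer(u, rep(1, nrow(prob_matrix))) > t(cum[, class, drop = FALSE])) + 1L
  levels[idx]
}

atc_pool <- function(n_codes = 40L) {
  set <- expand.grid(l1 = c("A", "C", "J", "N", "R"),
                     d1 = sprintf("%02d", 1:4),
                     l2 = c("AA", "BE"),
                     d2 = sprintf("%02d", 1:2), stringsAsFactors = FALSE)
  codes <- with(set, paste0(l1, d1, l2, d2))
  head(codes, n_codes)
}

icd10_pool <- function() c("K35", "J06", "S52", "N39", "M54", "F32", "R10", "I10", "E11", "G43")

count_in_bin <- function(bin, kind) {
  # draw an actual count consistent with a drawn category
  switch(kind,
    gp = switch(bin, "<2" = sample(0:1, 1), "2-3" = sample(2:3, 1),
                "4-6" = sample(4:6, 1), "7-9" = sample(7:9, 1),
                "10-12" = sample(10:12, 1), ">12" = sample(13:20, 1)),
    specialist = switch(bin, "0" = 0L, "1-2" = sample(1:2, 1), "3+" = sample(3:8, 1)),
    medication = switch(bin, "0" = 0L, "1" = 1L, "2" = 2L, "3+" = sample(3:6, 1)))
}

#' Generate a complete synthetic cohort
#'
#' Draws classes, raw survey responses, covariates and service-use records
#' per the specification; renders service use as dated record tables
#' including decoy out-of-window and pregnancy-coded records that the
#' recoding filters must remove; returns the truth labels (and the intended
#' outcome categories) in a separate table used only for evaluation.
#'
#' @param spec A [synthetic_spec()] object (see [scenario_library()]).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param n Optional override of `spec$n`.
#' @return List of tibbles: `survey` (id, return_date, 19 raw items),
#'   `covariates`, `visits`, `dispensings`, `admissions`, and `truth`
#'   (id, true class, intended outcome categories — evaluation only).
#' @export
generate_cohort <- function(spec, seed = NULL, n = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n %||% spec$n)
  C <- spec$n_classes
  cls <- sample.int(C, n, replace = TRUE, prob = spec$gamma)
  id <- sprintf("P%06d", seq_len(n))

  return_date <- as.Date("2017-04-01") + sample(0:152, n, replace = TRUE)  # Apr-Aug

  survey <- tibble::tibble(participant_id = id, return_date = return_date)
  for (it in symptom_items()) {
    resp <- sample_categorical(spec$raw_response_model[[it]], cls, RESPONSE_LEVELS)
    resp[runif(n) < spec$missing_rate] <- NA_character_
    survey[[it]] <- resp
  }

  covariates <- tibble::tibble(participant_id = id)
  for (nm in names(spec$covariate_model)) {
    m <- spec$covariate_model[[nm]][, seq_len(C), drop = FALSE]
    covariates[[nm]] <- sample_categorical(m, cls, rownames(m))
  }

  om <- scale_outcomes(spec$outcome_model, C)
  gp_bin <- sample_categorical(om$gp, cls, GP_BINS)
  sp_bin <- sample_categorical(om$specialist, cls, SPECIALIST_BINS)
  med_bin <- sample_categorical(om$medication, cls, MEDICATION_BINS)
  same_day <- runif(n) < om$admission["same_day", cls]
  overnight <- runif(n) < om$admission["overnight", cls]

  gp_n <- vapply(gp_bin, count_in_bin, integer(1) + 0L, kind = "gp")
  sp_n <- vapply(sp_bin, count_in_bin, integer(1) + 0L, kind = "specialist")
  med_n <- vapply(med_bin, count_in_bin, integer(1) + 0L, kind = "medication")

  # visits inside the 12-month window, plus out-of-window decoys for ~10%
  mk_visits <- function(counts, type) {
    idx <- rep.int(seq_len(n), counts)
    tibble::tibble(participant_id = id[idx], provider_type = type,
                   date = return_date[idx] + sample(0:364, length(idx), replace = TRUE))
  }
  visits <- dplyr::bind_rows(mk_visits(gp_n, "gp"), mk_visits(sp_n, "specialist"))
  decoy <- runif(n) < 0.10
  if (any(decoy)) {
    visits <- dplyr::bind_rows(visits, tibble::tibble(
      participant_id = id[decoy], provider_type = "gp",
      date = return_date[decoy] + sample(365:500, sum(decoy), replace = TRUE)))
  }

  # dispensings: med_n distinct ATC codes in Apr-Sep, some codes dispensed
  # twice (duplicates must not inflate the distinct count), plus decoy
  # out-of-window dispensings with otherwise-new codes
  pool <- atc_pool()
  idx <- rep.int(seq_len(n), med_n)
  code_slot <- unlist(lapply(med_n[med_n > 0], seq_len), use.names = FALSE)
  codes <- pool[code_slot]
  disp_date <- as.Date("2017-04-01") + sample(0:182, length(idx), replace = TRUE)
  dispensings <- tibble::tibble(participant_id = id[idx], atc_code = codes,
                                date = disp_date)
  refill <- runif(nrow(dispensings)) < 0.3
  if (any(refill)) {
    dispensings <- dplyr::bind_rows(dispensings, dplyr::mutate(
      dispensings[refill, ], date = pmin(.data$date + 30, as.Date("2017-09-30"))))
  }
  decoy_d <- runif(n) < 0.10
  if (any(decoy_d)) {
    dispensings <- dplyr::bind_rows(dispensings, tibble::tibble(
      participant_id = id[decoy_d],
      atc_code = pool[length(pool)],  # code otherwise unused in-window? use last pool code
      date = as.Date("2017-02-01") + sample(0:27, sum(decoy_d), replace = TRUE)))
  }

  # admissions: real ones in-window with non-pregnancy codes; decoy
  # pregnancy-coded and out-of-window admissions
  mk_adm <- function(flag, sd) {
    k <- sum(flag)
    tibble::tibble(participant_id = id[flag],
                   admission_date = return_date[flag] +
                     sample(0:364, k, replace = TRUE),
                   same_day = sd,
                   primary_icd10 = sample(icd10_pool(), k, replace = TRUE))
  }
  admissions <- dplyr::bind_rows(mk_adm(same_day, TRUE), mk_adm(overnight, FALSE))
  decoy_a <- runif(n) < 0.05
  if (any(decoy_a)) {
    admissions <- dplyr::bind_rows(admissions, tibble::tibble(
      participant_id = id[decoy_a],
      admission_date = return_date[decoy_a] + sample(0:364, sum(decoy_a), replace = TRUE),
      same_day = runif(sum(decoy_a)) < 0.5,
      primary_icd10 = sample(c("O80", "O26", "O9A", "O03"), sum(decoy_a), replace = TRUE)))
  }
  decoy_a2 <- runif(n) < 0.05
  if (any(decoy_a2)) {
    admissions <- dplyr::bind_rows(admissions, tibble::tibble(
      participant_id = id[decoy_a2],
      admission_date = return_date[decoy_a2] + sample(370:500, sum(decoy_a2), replace = TRUE),
      same_day = runif(sum(decoy_a2)) < 0.5,
      primary_icd10 = sample(icd10_pool(), sum(decoy_a2), replace = TRUE)))
  }

  truth <- tibble::tibble(participant_id = id, class = cls,
                          gp_category = factor(gp_bin, levels = GP_BINS),
                          specialist_category = factor(sp_bin, levels = SPECIALIST_BINS),
                          medication_category = factor(med_bin, levels = MEDICATION_BINS),
                          any_admission = same_day | overnight,
                          same_day_admission = same_day,
                          overnight_admission = overnight)

  list(survey = survey, covariates = covariates, visits = visits,
       dispensings = dispensings, admissions = admissions, truth = truth)
}

#' Exact three-level item-response truth implied by a synthetic spec
#'
#' Applies the never/rarely collapse — and, for the combined urinary and
#' bowel indicators, the priority combination rule — to the four-level
#' generative model, by exact enumeration over the source items' joint
#' distribution (class-conditional independence) including the MCAR
#' missingness state of each source item. The result is the exact
#' `P(indicator = k | class)` truth that a correctly recoded and fitted
#' model should recover, conditional on the indicator being observed.
#'
#' @param spec A [synthetic_spec()] object.
#' @return Named list of 16 matrices (3 x C, rows never/rarely, sometimes,
#'   often) in [indicator_names()] order.
#' @export
implied_rho <- function(spec) {
  C <- spec$n_classes
  m <- spec$missing_rate
  collapse4 <- function(p4) c(p4[1] + p4[2], p4[3], p4[4])

  singles <- setdiff(indicator_names(), c("any_urinary", "any_bowel"))
  out <- lapply(singles, function(it) {
    mat <- apply(spec$raw_response_model[[it]], 2L, collapse4)
    rownames(mat) <- c("never_rarely", "sometimes", "often")
    mat
  })
  names(out) <- singles

  combined <- function(source_items) {
    S <- length(source_items)
    # 5 states per source: 4 observed levels (prob * (1-m)) + missing (m)
    states <- c(RESPONSE_LEVELS, NA_character_)
    grid <- expand.grid(rep(list(seq_len(5L)), S))
    mat <- matrix(0, 3L, C,
                  dimnames = list(c("never_rarely", "sometimes", "often"), NULL))
    for (c in seq_len(C)) {
      probs <- vapply(source_items, function(it) {
        c(spec$raw_response_model[[it]][, c] * (1 - m), m)
      }, numeric(5L))
      acc <- c(never_rarely = 0, sometimes = 0, often = 0, miss = 0)
      for (r in seq_len(nrow(grid))) {
        st <- as.integer(grid[r, ])
        pr <- prod(probs[cbind(st, seq_len(S))])
        resp <- states[st]
        comb <- combine_any_symptom(as.list(matrix(resp, nrow = 1))[seq_len(S)])
        if (is.na(comb)) {
          acc["miss"] <- acc["miss"] + pr
        } else {
          k <- collapse_to_three(comb) + 1L
          acc[k] <- acc[k] + pr
        }
      }
      mat[, c] <- acc[1:3] / sum(acc[1:3])  # conditional on observed
    }
    mat
  }
  out$any_urinary <- combined(urinary_items())
  out$any_bowel <- combined(bowel_items())
  out[indicator_names()]
}

#' Align fitted classes to a reference truth
#'
#' Finds the class permutation minimising the mean absolute difference
#' between fitted and reference item-response probabilities (all
#' permutations enumerated; intended for C <= 6).
#'
#' @param fit An [lca_fit()] object.
#' @param rho_ref Reference item-response probabilities: list of K x C
#'   matrices in fitted item order (e.g. [implied_rho()] output).
#' @return Integer permutation `perm` such that fitted class `perm[c]`
#'   corresponds to reference class `c`.
#' @export
align_classes <- function(fit, rho_ref) {
  C <- fit$n_classes
  perms <- all_permutations(C)
  rho_fit <- fit$params$rho
  cost <- vapply(seq_len(nrow(perms)), function(p) {
    pm <- perms[p, ]
    sum(vapply(seq_along(rho_fit), function(j) {
      sum(abs(rho_fit[[j]][, pm, drop = FALSE] - rho_ref[[j]]))
    }, numeric(1)))
  }, numeric(1))
  perms[which.min(cost), ]
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
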