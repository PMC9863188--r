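# Latent class model fitting.
#
# Model: each participant belongs to one of C latent classes with prevalence
# gamma_c; conditional on class, the J categorical indicators are independent
# with item-response probabilities rho_{j, k | c}. The observed-data
# log-likelihood sums over classes; missing indicators drop out of the
# within-class product (MAR). Maximisation is by EM with multiple random
# starts (the surface is multimodal); the best converged start is returned
# with classes relabelled into a canonical order (descending gamma).

#' Coerce an indicator data frame to the internal coded matrix
#'
#' @param data Data frame or matrix of categorical indicators: integer codes
#'   starting at 0, or factors. Non-indicator identifier columns named
#'   `participant_id` are dropped automatically.
#' @param n_levels Number of levels per item (scalar or vector); default
#'   `NULL` derives `max(code) + 1` per item.
#' @return Integer matrix with codes 1..K_j and 0 for missing; attribute
#'   `"K"` holds the per-item level counts.
#' @keywords internal
as_indicator_matrix <- function(data, n_levels = NULL) {
  if (is.matrix(data) && !is.null(attr(data, "K"))) {
    return(data)  # already coded (e.g. the `y` slot of an lca_fit)
  }
  if (is.data.frame(data)) {
    data <- data[setdiff(names(data), "participant_id")]
    data <- as.data.frame(lapply(data, function(x) {
      if (is.factor(x)) as.integer(x) - 1L else as.integer(x)
    }))
    data <- as.matrix(data)
  }
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) abort("indicator codes must be >= 0")
  maxcode <- apply(data, 2L, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  if (is.null(n_levels) && any(!is.finite(maxcode))) {
    abort("an indicator column is entirely missing; supply `n_levels`")
  }
  maxcode[!is.finite(maxcode)] <- 0
  K <- if (is.null(n_levels)) maxcode + 1L else rep_len(as.integer(n_levels), ncol(data))
  if (any(maxcode + 1L > K)) abort("indicator level index out of range for `n_levels`")
  if (any(K < 2L)) K[K < 2L] <- 2L
  y <- data + 1L
  y[is.na(y)] <- 0L
  attr(y, "K") <- as.integer(K)
  y
}

rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

random_start <- function(J, K, C) {
  list(gamma = rdirichlet1(C),
       rho = lapply(seq_len(J), function(j) {
         m <- matrix(0, K[j], C)
         for (c in seq_len(C)) m[, c] <- rdirichlet1(K[j])
         m
       }))
}

#' Number of free parameters of a latent class model
#'
#' `P = (C - 1) + sum_j C * (K_j - 1)`: class prevalences plus item-response
#' probabilities.
#'
#' @param n_items Number of indicators J.
#' @param n_levels Levels per item (scalar or length-J vector).
#' @param n_classes Number of classes C.
#' @return Integer count of free parameters.
#' @export
#' @examples
#' lca_n_params(16, 3, 4)  # 131
lca_n_params <- function(n_items, n_levels, n_classes) {
  K <- rep_len(n_levels, n_items)
  as.integer((n_classes - 1) + n_classes * sum(K - 1))
}

#' Residual degrees of freedom of a latent class model
#'
#' `df = prod_j K_j - P - 1`: cells of the full cross-classification minus
#' free parameters minus one. Computed in double precision (exact for the
#' 3^16-scale tables arising with 16 three-level indicators).
#'
#' @inheritParams lca_n_params
#' @return Numeric (integer-valued) degrees of freedom.
#' @export
#' @examples
#' lca_df(16, 3, 4)  # 43046589
lca_df <- function(n_items, n_levels, n_classes) {
  K <- rep_len(as.numeric(n_levels), n_items)
  prod(K) - lca_n_params(n_items, n_levels, n_classes) - 1
}

#' Observed-data log-likelihood of a latent class model
#'
#' `sum_i log sum_c gamma_c prod_{j in obs(i)} rho_{j, y_ij | c}`, with the
#' product over observed items only (missing at random). Rows with every
#' indicator missing contribute `log 1 = 0`.
#'
#' @param params List with elements `gamma` (length C) and `rho` (list of J
#'   matrices, K_j x C), e.g. the `params` element of an [lca_fit()] object.
#' @param data Indicator data frame or matrix (codes 0..K-1, `NA` missing).
#' @param n_levels Optional per-item level counts (see [lca_fit()]).
#' @return The log-likelihood (scalar).
#' @export
lca_log_likelihood <- function(params, data, n_levels = NULL) {
  y <- as_indicator_matrix(data, n_levels)
  attr(e_step_impl(params, y), "loglik")
}

# n x C matrix of log(gamma_c) + sum_j log rho_{j, y_ij | c}
ll_matrix <- function(params, y) {
  n <- nrow(y); J <- ncol(y); C <- length(params$gamma)
  K <- attr(y, "K")
  lp <- matrix(log(params$gamma), n, C, byrow = TRUE)
  for (j in seq_len(J)) {
    rj <- params$rho[[j]]
    if (nrow(rj) < K[j]) abort(sprintf("item %d: level index out of range", j))
    obs <- y[, j] > 0L
    lp[obs, ] <- lp[obs, , drop = FALSE] + log(rj)[y[obs, j], , drop = FALSE]
  }
  lp
}

e_step_impl <- function(params, y) {
  lp <- ll_matrix(params, y)
  m <- apply(lp, 1L, max)
  p <- exp(lp - m)
  s <- rowSums(p)
  post <- p / s
  structure(post, loglik = sum(m + log(s)))
}

#' E-step: posterior class-membership probabilities
#'
#' `p_ic` proportional to `gamma_c prod_{j in obs(i)} rho_{j, y_ij | c}`,
#' normalised per row and computed in log space. A row with all indicators
#' missing gets posterior equal to the prevalences `gamma`.
#'
#' @inheritParams lca_log_likelihood
#' @return n x C matrix of posterior probabilities (rows sum to 1), with the
#'   log-likelihood in attribute `"loglik"`.
#' @export
lca_e_step <- function(params, data, n_levels = NULL) {
  e_step_impl(params, as_indicator_matrix(data, n_levels))
}

#' M-step: closed-form parameter update from posteriors
#'
#' `gamma_c = mean_i p_ic`; `rho_{j,k|c}` is the posterior-weighted share of
#' level `k` among rows with item `j` observed. Estimates are clipped to
#' `[eps, 1 - eps]` and renormalised.
#'
#' @param posteriors n x C matrix of normalised posterior probabilities.
#' @inheritParams lca_log_likelihood
#' @param eps Boundary clip for probabilities.
#' @return List with `gamma` and `rho` in the format of [lca_log_likelihood()].
#' @export
lca_m_step <- function(posteriors, data, n_levels = NULL, eps = 1e-6) {
  m_step_impl(posteriors, as_indicator_matrix(data, n_levels), eps = eps)
}

m_step_impl <- function(posteriors, y, eps = 1e-6) {
  K <- attr(y, "K")
  C <- ncol(posteriors)
  mass <- colSums(posteriors)
  if (any(mass < 1e-8)) {
    abort(sprintf("degenerate class (no posterior mass): class %s",
                  paste(which(mass < 1e-8), collapse = ", ")))
  }
  clip_norm <- function(v) {
    v <- pmin(pmax(v, eps), 1 - eps)
    v / sum(v)
  }
  gamma <- clip_norm(mass / nrow(y))
  rho <- lapply(seq_len(ncol(y)), function(j) {
    obs <- y[, j] > 0L
    rs <- rowsum(posteriors[obs, , drop = FALSE], group = y[obs, j])
    num <- matrix(0, K[j], C)
    num[as.integer(rownames(rs)), ] <- rs
    den <- colSums(posteriors[obs, , drop = FALSE])
    m <- sweep(num, 2L, den, "/")
    matrix(apply(m, 2L, clip_norm), K[j], C)
  })
  list(gamma = gamma, rho = rho)
}

canonical_order <- function(gamma, rho) {
  # descending gamma; ties broken by the first item's last-level rho
  tie <- rho[[1]][nrow(rho[[1]]), ]
  order(-gamma, -tie)
}

#' Fit a latent class model by EM with multiple random starts
#'
#' Runs `n_starts` EM chains from independent Dirichlet(1) random starting
#' values, keeps the converged chain with the highest log-likelihood, and
#' relabels classes in descending order of prevalence. Missing indicator
#' values are handled under the missing-at-random assumption (they drop out
#' of the likelihood; nothing is imputed). The log-likelihood is
#' non-decreasing within each chain (monitored and reported).
#'
#' @param data Indicator data frame or matrix: integer codes starting at 0
#'   (0 = never/rarely, 1 = sometimes, 2 = often for the symptom pipeline)
#'   or factors; `NA` for missing. A `participant_id` column is ignored.
#' @param n_classes Number of latent classes C (>= 1).
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer master seed; per-start initial values are drawn from
#'   it so the whole fit is reproducible. `NULL` uses the current RNG state.
#' @param tol_param,tol_ll Convergence: maximum absolute parameter change
#'   below `tol_param` and relative log-likelihood change below `tol_ll`.
#' @param max_iter Maximum EM iterations per chain.
#' @param eps Probability boundary clip.
#' @param n_levels Optional per-item level count (scalar or vector); default
#'   derives it from the data.
#' @return Object of class `"lca_fit"`: a list with `params` (`gamma`,
#'   `rho`), `posterior`, `loglik`, `n_params`, `df`, `converged`, `n_iter`,
#'   `start_logliks`, `chain_info` (per-start tibble), `n`, `item_names`,
#'   `n_levels`, `seed`, and the coded data matrix `y`.
#' @seealso [lca_sweep()] to compare class counts; [tidy.lca_fit()],
#'   [glance.lca_fit()].
#' @export
lca_fit <- function(data, n_classes, n_starts = 100, seed = NULL,
                    tol_param = 1e-6, tol_ll = 1e-9, max_iter = 5000,
                    eps = 1e-6, n_levels = NULL) {
  stopifnot(n_classes >= 1, n_starts >= 1)
  y <- as_indicator_matrix(data, n_levels)
  K <- attr(y, "K")
  n <- nrow(y); J <- ncol(y)
  if (n < n_classes) abort("need at least as many rows as classes")
  item_names <- colnames(y) %||% paste0("item", seq_len(J))

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }

  if (n_classes == 1L) {
    post <- matrix(1, n, 1L)
    params <- m_step_impl(post, y, eps = eps)
    ll <- attr(e_step_impl(params, y), "loglik")
    fit <- new_lca_fit(params, post, ll, y, K, item_names,
                       converged = TRUE, n_iter = 1L,
                       chain_info = tibble::tibble(
                         start = 1L, loglik = ll, converged = TRUE,
                         n_iter = 1L, min_ll_increase = NA_real_),
                       seed = seed)
    return(fit)
  }

  starts <- lapply(seq_len(n_starts), function(s) random_start(J, K, n_classes))
  chains <- lapply(starts, function(st) {
    res <- lca_em_cpp(y, K, st$gamma, st$rho,
                      tol_param, tol_ll, as.integer(max_iter), eps)
    res
  })
  chain_info <- tibble::tibble(
    start = seq_len(n_starts),
    loglik = vapply(chains, function(ch) ch$loglik, numeric(1)),
    converged = vapply(chains, function(ch) isTRUE(ch$converged) &&
                         !isTRUE(ch$degenerate), logical(1)),
    n_iter = vapply(chains, function(ch) as.integer(ch$n_iter), integer(1)),
    min_ll_increase = vapply(chains, function(ch) ch$min_ll_increase, numeric(1))
  )
  if (!any(chain_info$converged)) {
    abort(c("no EM chain converged",
            sprintf("chains run: %d; max iterations: %d; best log-likelihood: %.4f",
                    n_starts, max_iter, max(chain_info$loglik))))
  }
  best_idx <- which(chain_info$converged)[
    which.max(chain_info$loglik[chain_info$converged])]
  best <- chains[[best_idx]]

  ord <- canonical_order(best$gamma, best$rho)
  params <- list(gamma = best$gamma[ord],
                 rho = lapply(best$rho, function(m) m[, ord, drop = FALSE]))
  post <- best$posterior[, ord, drop = FALSE]

  fit <- new_lca_fit(params, post, best$loglik, y, K, item_names,
                     converged = TRUE, n_iter = best$n_iter,
                     chain_info = chain_info, seed = seed)
  fit
}

new_lca_fit <- function(params, post, ll, y, K, item_names, converged, n_iter,
                        chain_info, seed) {
  C <- length(params$gamma)
  class_names <- paste0("class", seq_len(C))
  names(params$gamma) <- class_names
  params$rho <- lapply(params$rho, function(m) {
    dimnames(m) <- list(paste0("level", seq_len(nrow(m)) - 1L), class_names)
    m
  })
  names(params$rho) <- item_names
  colnames(post) <- class_names
  structure(list(
    params = params,
    posterior = post,
    loglik = ll,
    n_params = lca_n_params(ncol(y), K, C),
    df = lca_df(ncol(y), K, C),
    converged = converged,
    n_iter = n_iter,
    start_logliks = chain_info$loglik,
    chain_info = chain_info,
    n = nrow(y),
    n_classes = C,
    item_names = item_names,
    n_levels = K,
    seed = seed,
    y = y
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent class model: %d classes, %d items, n = %d\n",
              x$n_classes, length(x$item_names), x$n))
  cat(sprintf("log-likelihood %.2f on %d parameters (df %s); %s in %d iterations\n",
              x$loglik, x$n_params, format(x$df, big.mark = ","),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("class prevalences:\n")
  print(round(x$params$gamma, 3))
  invisible(x)
}

#' Tidy a latent class fit into a long parameter tibble
#'
#' @param x An [lca_fit()] object.
#' @param ... Unused.
#' @return Tibble with columns `parameter` (`"gamma"` or `"rho"`), `item`,
#'   `level`, `class`, `estimate`.
#' @export
tidy.lca_fit <- function(x, ...) {
  g <- tibble::tibble(parameter = "gamma", item = NA_character_,
                      level = NA_integer_, class = names(x$params$gamma),
                      estimate = unname(x$params$gamma))
  r <- purrr::imap_dfr(x$params$rho, function(m, item) {
    tibble::tibble(parameter = "rho", item = item,
                   level = rep(seq_len(nrow(m)) - 1L, ncol(m)),
                   class = rep(colnames(m), each = nrow(m)),
                   estimate = as.vector(m))
  })
  dplyr::bind_rows(g, r)
}

#' One-row summary of a latent class fit
#'
#' @param x An [lca_fit()] object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_classes`, `loglik`, `n_params`, `df`,
#'   `AIC_LL`, `BIC_LL`, `entropy`, `smallest_class_prob`,
#'   `pct_best_replicates`, `converged`, `n_iter`.
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = x$n_classes,
    loglik = x$loglik,
    n_params = x$n_params,
    df = x$df,
    AIC_LL = -2 * x$loglik + 2 * x$n_params,
    BIC_LL = -2 * x$loglik + x$n_params * log(x$n),
    entropy = if (x$n_classes > 1L) relative_entropy(x$posterior) else NA_real_,
    smallest_class_prob = min(x$params$gamma),
    pct_best_replicates = replicate_stability(x$start_logliks),
    converged = x$converged,
    n_iter = x$n_iter
  )
}
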