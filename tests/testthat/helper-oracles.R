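# Independent oracles used across tests. These deliberately avoid the
# package's own computation paths.

# Full-pattern enumeration of the latent-class likelihood: builds the joint
# probability of every complete response pattern per class and sums the
# mixture, then looks up each observed row. Only for tiny J/K/C.
enum_loglik <- function(gamma, rho, y) {
  J <- length(rho)
  K <- vapply(rho, nrow, integer(1))
  grid <- expand.grid(lapply(K, seq_len))
  mix <- numeric(nrow(grid))
  for (c in seq_along(gamma)) {
    pr <- rep(gamma[c], nrow(grid))
    for (j in seq_len(J)) pr <- pr * rho[[j]][grid[, j], c]
    mix <- mix + pr
  }
  ll <- 0
  for (i in seq_len(nrow(y))) {
    row <- y[i, ] + 1L
    obs <- !is.na(row)
    if (!any(obs)) next
    if (all(obs)) {
      hit <- rep(TRUE, nrow(grid))
      for (j in seq_len(J)) hit <- hit & grid[, j] == row[j]
      ll <- ll + log(mix[hit])
    } else {
      # marginalise the enumeration over unobserved items
      hit <- rep(TRUE, nrow(grid))
      for (j in which(obs)) hit <- hit & grid[, j] == row[j]
      ll <- ll + log(sum(mix[hit]))
    }
  }
  ll
}

# random parameter set for a small latent class instance
random_params <- function(J, K, C) {
  list(gamma = {
    g <- stats::rgamma(C, 1); g / sum(g)
  },
  rho = lapply(seq_len(J), function(j) {
    m <- matrix(stats::rgamma(K * C, 1), K, C)
    sweep(m, 2L, colSums(m), "/")
  }))
}

# odds ratio from a 2 x 2 count table: (a/b) / (c/d)
crosstab_or <- function(n11, n10, n01, n00) (n11 / n10) / (n01 / n00)

# small indicator data frame simulated from params (complete data)
simulate_indicators <- function(gamma, rho, n) {
  C <- length(gamma)
  cls <- sample.int(C, n, replace = TRUE, prob = gamma)
  as.data.frame(lapply(seq_along(rho), function(j) {
    K <- nrow(rho[[j]])
    vapply(cls, function(c) sample.int(K, 1, prob = rho[[j]][, c]) - 1L, integer(1))
  })) |> stats::setNames(paste0("item", seq_along(rho)))
}

# a tiny raw survey data frame with every item set to a default response
flat_survey <- function(n = 1, fill = "never") {
  df <- tibble::tibble(participant_id = sprintf("P%03d", seq_len(n)))
  for (it in symptom_items()) df[[it]] <- rep(fill, n)
  df
}
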