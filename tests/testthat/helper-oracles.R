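# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each quantity from its definition with naive
# loops, sharing no code with the implementation under test.

# empirical survival function (no censoring): fraction of subjects with
# time > t
naive_survival <- function(time, t) mean(time > t)

# Kaplan-Meier product-limit by explicit loop over distinct event times
naive_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ts, survival = out)
}

# row-by-row censored-data negative log-likelihood
naive_nll <- function(eps, event) {
  total <- 0
  for (i in seq_along(eps)) {
    h <- 1 / (1 + exp(-eps[i]))
    h <- min(max(h, 1e-12), 1 - 1e-12)
    total <- total - if (event[i] == 1) log(h) else log(1 - h)
  }
  total
}

# O(n^2) double-loop Harrell C with truncation; tie rules per the package's
# documented convention (tied times unusable, tied scores 0.5)
naive_harrell_c <- function(time, event, scores, truncate_at = NULL) {
  if (!is.null(truncate_at)) {
    event <- as.integer(event == 1 & time <= truncate_at)
    time <- pmin(time, truncate_at)
  }
  usable <- 0
  num <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      if (time[i] < time[k] && event[i] == 1) {
        usable <- usable + 1
        if (scores[i] > scores[k]) num <- num + 1
        else if (scores[i] == scores[k]) num <- num + 0.5
      }
    }
  }
  if (usable == 0) return(NA_real_)
  num / usable
}

# a small cohort tibble from vectors, with covariates
make_cohort <- function(time, event, ...) {
  covs <- list(...)
  out <- tibble::tibble(id = paste0("s", seq_along(time)),
                        time = time, event = as.integer(event))
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  attr(out, "covariates") <- names(covs)
  out
}

# random person-period-like table for likelihood tests
random_pp_table <- function(n_rows, n_cov = 2) {
  out <- tibble::tibble(
    id = paste0("s", seq_len(n_rows)),
    j = sample(1:3, n_rows, replace = TRUE),
    event = rbinom(n_rows, 1, 0.3)
  )
  out$tj <- as.numeric(out$j)
  for (k in seq_len(n_cov)) out[[paste0("x", k)]] <- rnorm(n_rows)
  attr(out, "covariates") <- paste0("x", seq_len(n_cov))
  out
}

# simple two-covariate simulated cohort with a linear true log-odds
linear_test_spec <- function(n, intercept = -2.5, b1 = 0.8, b2 = -0.5,
                             intervals = 3, cutoff = intervals) {
  cohort_spec(
    n = n,
    covariates = list(x1 = list(dist = "normal", mean = 0, sd = 1),
                      x2 = list(dist = "normal", mean = 0, sd = 1)),
    log_odds = sprintf("%f + %f * x1 + %f * x2", intercept, b1, b2),
    width = 1, max_intervals = intervals,
    cutoff = list(dist = "fixed", value = cutoff)
  )
}
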