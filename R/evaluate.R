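#' Predicted cumulative incidence at a horizon
#'
#' For each subject, the model's log-odds is evaluated at every interval
#' `1..t/width`, mapped to hazards through the logistic link, and composed
#' into the survival probability \eqn{S(t) = \prod_k (1 - h_k)}. The
#' returned risk is the cumulative incidence \eqn{1 - S(t)}.
#'
#' Predictions are only defined at interval boundaries within the model's
#' trained range: a horizon beyond the intervals observed in training is an
#' extrapolation error, not a number.
#'
#' @param model a hazard model ([log_odds()] contract).
#' @param data cohort tibble (one row per subject, baseline covariates).
#' @param horizons numeric vector of horizons (years), each a multiple of
#'   `width`.
#' @param width interval width; defaults to the model's training width.
#' @return Tibble `(id, horizon, risk)`, `nrow(data) * length(horizons)`
#'   rows.
#' @export
predict_risk <- function(model, data, horizons, width = NULL) {
  width <- width %||% model$delta %||% 1
  J <- horizons / width
  if (any(abs(J - round(J)) > 1e-8)) {
    stop("each horizon must be a multiple of the interval width",
         call. = FALSE)
  }
  J <- as.integer(round(J))
  trained <- model$trained_intervals
  if (!is.null(trained) && any(J > trained)) {
    stop("horizon beyond the model's trained intervals (1..", trained,
         "); predictions are only valid at observed time points",
         call. = FALSE)
  }
  n <- nrow(data)
  S <- rep(1, n)
  out <- vector("list", length(horizons))
  ord <- order(J)
  jj_done <- 0L
  for (o in ord) {
    while (jj_done < J[o]) {
      jj_done <- jj_done + 1L
      nd <- data
      nd$j <- jj_done
      nd$tj <- as.numeric(jj_done)
      S <- S * (1 - logistic_hazard(log_odds(model, nd)))
    }
    out[[o]] <- tibble::tibble(id = data$id, horizon = horizons[o],
                               risk = 1 - S)
  }
  dplyr::bind_rows(out)
}

#' Truncated Harrell's C-statistic for censored data
#'
#' Follow-up is truncated at `truncate_at` (events after the horizon are
#' recoded as censored at it). A pair of subjects is *usable* when it can be
#' ordered under censoring: the member with the strictly shorter observed
#' time experienced an event. The statistic is
#' `(concordant + 0.5 * score-tied) / usable`, where a pair is concordant
#' when the shorter-lived member received the higher risk score. Pairs with
#' tied observed times are never usable.
#'
#' @param data cohort tibble with `time` and `event`.
#' @param scores numeric risk scores, one per subject (higher = higher
#'   predicted risk).
#' @param truncate_at optional truncation horizon in years.
#' @return Scalar in `[0, 1]`; `NA` (with a warning) when no pair is usable.
#' @export
harrell_c <- function(data, scores, truncate_at = NULL) {
  stopifnot(length(scores) == nrow(data))
  time <- data$time
  event <- data$event
  if (!is.null(truncate_at)) {
    event <- as.integer(event == 1 & time <= truncate_at)
    time <- pmin(time, truncate_at)
  }
  n <- length(time)
  # usable[i, j]: i had the event strictly before j's observed time
  shorter <- outer(time, time, `<`)
  usable <- shorter & (event == 1)
  n_usable <- sum(usable)
  if (n_usable == 0) {
    warning("no usable pairs; C-statistic undefined", call. = FALSE)
    return(NA_real_)
  }
  conc <- sum(usable & outer(scores, scores, `>`))
  tied <- sum(usable & outer(scores, scores, `==`))
  (conc + 0.5 * tied) / n_usable
}

#' Calibration groups at a horizon
#'
#' Subjects are ranked by predicted survival `S(t) = 1 - risk` and cut into
#' `g` groups of near-equal size (the remainder is spread over the
#' lowest-rank groups, i.e. the highest-risk end). Per group, the predicted
#' number of events is `size * mean(risk)`; the observed number is
#' `size * (1 - KM_g(t))` with the Kaplan-Meier estimate computed within the
#' group, which accounts for censoring before the horizon. A group with no
#' subject still at risk at `t` has an undefined observed value and is
#' flagged.
#'
#' @param data cohort tibble with `time` and `event`.
#' @param risks predicted cumulative incidence `1 - S(t)` per subject.
#' @param t horizon (years).
#' @param g number of groups (>= 2; default deciles).
#' @return Tibble `(group, size, mean_risk, predicted_events,
#'   observed_events, km_survival, at_risk_at_t)`.
#' @export
calibration_table <- function(data, risks, t, g = 10) {
  stopifnot(length(risks) == nrow(data))
  if (g < 2) stop("g must be >= 2", call. = FALSE)
  n <- nrow(data)
  if (n < g) stop("cohort smaller than the number of groups", call. = FALSE)
  sizes <- n %/% g + (seq_len(g) <= n %% g)
  # rank by predicted S(t) ascending: group 1 = highest predicted risk
  ord <- order(1 - risks, seq_len(n))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(g), times = sizes)
  purrr::map_dfr(seq_len(g), function(k) {
    sel <- grp == k
    sub <- data[sel, , drop = FALSE]
    at_risk <- any(sub$time >= t)
    km_s <- if (at_risk) survival_at(kaplan_meier(sub), t) else NA_real_
    tibble::tibble(
      group = k,
      size = sum(sel),
      mean_risk = mean(risks[sel]),
      predicted_events = sum(sel) * mean(risks[sel]),
      observed_events = if (at_risk) sum(sel) * (1 - km_s) else NA_real_,
      km_survival = km_s,
      at_risk_at_t = at_risk
    )
  })
}

#' Generalized Hosmer-Lemeshow chi-square for survival calibration
#'
#' \deqn{\chi^2 = \sum_g \frac{(O_g - P_g)^2}{P_g (1 - P_g / n_g)}}
#' over the calibration groups, compared against a chi-square distribution
#' with `df` degrees of freedom (default `g - 1`, the convention consistent
#' with decile grouping). The simpler Pearson-style variance
#' `(O - P)^2 / P` is available with `variance = "simple"`.
#'
#' @param calibration tibble from [calibration_table()]; observed values
#'   must all be defined.
#' @param df degrees of freedom (default: number of groups minus 1).
#' @param variance `"binomial"` (default) or `"simple"`.
#' @return Tibble `(chi_squared, df, p_value, g)`.
#' @export
hosmer_lemeshow <- function(calibration, df = NULL,
                            variance = c("binomial", "simple")) {
  variance <- match.arg(variance)
  if (anyNA(calibration$observed_events)) {
    stop("calibration groups with undefined observed values; ",
         "cannot compute the statistic", call. = FALSE)
  }
  g <- nrow(calibration)
  df <- df %||% (g - 1)
  p <- calibration$predicted_events
  o <- calibration$observed_events
  size <- calibration$size
  degenerate <- p <= 0 | p >= size
  if (any(degenerate)) {
    warning("predicted events of 0 or the full group size; ",
            "continuity correction applied", call. = FALSE)
    p <- pmin(pmax(p, 0.5), size - 0.5)
  }
  denom <- if (variance == "binomial") p * (1 - p / size) else p
  chi2 <- sum((o - p)^2 / denom)
  tibble::tibble(chi_squared = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 g = g)
}

#' Model-vs-Kaplan-Meier survival curves
#'
#' The model curve at each horizon is the cohort mean of the per-subject
#' model survival probabilities; the reference curve is the Kaplan-Meier
#' estimate with a +/- 2 standard-error band.
#'
#' @param model a hazard model.
#' @param data cohort tibble.
#' @param horizons horizons (years).
#' @param width interval width (defaults to the model's).
#' @return Tibble `(time, source, estimate, se, lower, upper)` with
#'   `source` in `"model"`, `"km"`.
#' @export
survival_curve_comparison <- function(model, data, horizons = c(1, 3, 5),
                                      width = NULL) {
  risks <- predict_risk(model, data, horizons, width = width)
  model_s <- risks |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(estimate = mean(1 - .data$risk), .groups = "drop") |>
    dplyr::transmute(time = .data$horizon, source = "model",
                     estimate = .data$estimate,
                     se = NA_real_, lower = NA_real_, upper = NA_real_)
  km <- kaplan_meier(data)
  s <- survival_at(km, horizons, "survival")
  se <- survival_at(km, horizons, "std_err")
  km_s <- tibble::tibble(time = horizons, source = "km", estimate = s,
                         se = se, lower = pmax(s - 2 * se, 0),
                         upper = pmin(s + 2 * se, 1))
  out <- dplyr::bind_rows(model_s, km_s)
  class(out) <- c("survgp_curves", class(out))
  out
}

#' Evaluate a hazard model on a validation cohort
#'
#' One-stop censoring-aware assessment: truncated C-statistic, calibration
#' groups and generalized Hosmer-Lemeshow chi-square at each horizon, plus
#' the model-vs-KM survival curves.
#'
#' @param model a hazard model.
#' @param data validation cohort tibble.
#' @param horizons evaluation horizons (years).
#' @param g calibration groups.
#' @param width interval width (defaults to the model's).
#' @return An object of class `survgp_evaluation` with elements
#'   `c_statistics`, `calibration`, `hl`, `curves` (all tibbles).
#' @export
evaluate_model <- function(model, data, horizons = c(1, 3, 5), g = 10,
                           width = NULL) {
  risks <- predict_risk(model, data, horizons, width = width)
  per_h <- lapply(horizons, function(t) {
    r <- risks$risk[risks$horizon == t]
    cal <- calibration_table(data, r, t, g = g)
    hl <- if (anyNA(cal$observed_events)) {
      tibble::tibble(chi_squared = NA_real_, df = g - 1,
                     p_value = NA_real_, g = g)
    } else {
      hosmer_lemeshow(cal)
    }
    list(
      c = tibble::tibble(horizon = t,
                         c_statistic = harrell_c(data, r, truncate_at = t)),
      cal = dplyr::mutate(cal, horizon = t, .before = 1),
      hl = dplyr::mutate(hl, horizon = t, .before = 1)
    )
  })
  structure(
    list(c_statistics = dplyr::bind_rows(lapply(per_h, `[[`, "c")),
         calibration = dplyr::bind_rows(lapply(per_h, `[[`, "cal")),
         hl = dplyr::bind_rows(lapply(per_h, `[[`, "hl")),
         curves = survival_curve_comparison(model, data, horizons,
                                            width = width),
         horizons = horizons, g = g, n = nrow(data)),
    class = "survgp_evaluation")
}

#' @export
print.survgp_evaluation <- function(x, ...) {
  cat("<survgp_evaluation> n =", x$n, "\n\nC-statistic:\n")
  print(x$c_statistics)
  cat("\nCalibration (generalized Hosmer-Lemeshow):\n")
  print(x$hl)
  invisible(x)
}

#' Write an evaluation report to plain-text files
#'
#' Emits `c_statistics.csv`, `calibration.csv`, `hosmer_lemeshow.csv`,
#' `curves.csv` and a machine-readable `report.json` into `dir`.
#'
#' @param report a `survgp_evaluation`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$c_statistics, file.path(dir, "c_statistics.csv"))
  readr::write_csv(report$calibration, file.path(dir, "calibration.csv"))
  readr::write_csv(report$hl, file.path(dir, "hosmer_lemeshow.csv"))
  readr::write_csv(report$curves, file.path(dir, "curves.csv"))
  jsonlite::write_json(
    list(n = report$n, horizons = report$horizons, g = report$g,
         c_statistics = report$c_statistics, hl = report$hl),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
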