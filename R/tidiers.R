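#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a linear discrete-time hazard model
#'
#' @param x a `linear_discrete_model`.
#' @param ... unused.
#' @return Tibble `(term, type, estimate)` with `type` distinguishing
#'   per-interval intercepts (`"alpha"`) from covariate coefficients
#'   (`"beta"`).
#' @export
tidy.linear_discrete_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = paste0("interval_", names(x$alpha)),
                   type = "alpha", estimate = unname(x$alpha)),
    tibble::tibble(term = names(x$beta), type = "beta",
                   estimate = unname(x$beta))
  )
}

#' @export
glance.linear_discrete_model <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_intervals = length(x$intervals),
                 n_covariates = length(x$beta),
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy an evolved tree model
#'
#' @param x a `gp_tree`.
#' @param ... unused.
#' @return Tibble with one row per predictor the tree references.
#' @export
tidy.gp_tree <- function(x, ...) {
  tibble::tibble(term = predictors_used(x))
}

#' @export
glance.gp_tree <- function(x, ...) {
  used <- predictors_used(x)
  tibble::tibble(depth = tree_depth(x), size = tree_size(x),
                 n_predictors = length(setdiff(used, "tj")),
                 uses_time = "tj" %in% used)
}

#' @export
tidy.gp_run <- function(x, ...) x$history

#' @export
glance.gp_run <- function(x, ...) {
  tibble::tibble(population_size = length(x$population),
                 evaluations = x$evaluations,
                 best_train_nll = min(x$fitness),
                 best_holdout_nll = x$best_holdout_nll,
                 elapsed = x$elapsed)
}

#' @export
tidy.survgp_evaluation <- function(x, ...) {
  dplyr::left_join(x$c_statistics,
                   x$hl[c("horizon", "chi_squared", "df", "p_value")],
                   by = "horizon")
}

#' Fitness trajectory of a GP run
#'
#' Best and median training negative log-likelihood against offspring
#' evaluations.
#'
#' @param object a `gp_run`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gp_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("best_train_nll", "median_train_nll"),
                              names_to = "statistic", values_to = "nll")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$evaluations, y = .data$nll,
                                     colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offspring evaluations",
                  y = "training negative log-likelihood", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Model-vs-Kaplan-Meier survival curves
#'
#' @param object a `survgp_curves` tibble from
#'   [survival_curve_comparison()].
#' @param ... unused.
#' @return A ggplot with the KM +/- 2 SE error bars.
#' @export
autoplot.survgp_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$source)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      data = object[object$source == "km", ],
      width = 0.15, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "years", y = "S(t)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot at each horizon
#'
#' Observed (within-group Kaplan-Meier) versus predicted incidence per risk
#' group, with the identity line.
#'
#' @param object a `survgp_evaluation`.
#' @param ... unused.
#' @return A ggplot faceted by horizon.
#' @export
autoplot.survgp_evaluation <- function(object, ...) {
  cal <- dplyr::mutate(object$calibration,
                       observed_risk = .data$observed_events / .data$size)
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_risk,
                                    y = .data$observed_risk)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mean predicted incidence 1 - S(t)",
                  y = "observed incidence (KM)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
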