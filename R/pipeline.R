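#' Simulate a synthetic cardiovascular-like cohort to disk
#'
#' Generates a cohort from [smart_like_spec()] (or a supplied spec), writes
#' `cohort.csv` and the truth side-channel `truth.csv`, and prints a short
#' summary (n, events, median follow-up).
#'
#' @param n cohort size (ignored when `spec` is given).
#' @param seed generation seed.
#' @param dir output directory; `NULL` to skip writing.
#' @param spec optional [cohort_spec()] overriding the default.
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(n = 3873, seed = 1, dir = NULL, spec = NULL) {
  spec <- spec %||% smart_like_spec(n)
  cohort <- generate_cohort(spec, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cohort, file.path(dir, "cohort.csv"))
    readr::write_csv(attr(cohort, "truth"), file.path(dir, "truth.csv"))
  }
  message(sprintf(
    "simulated %d subjects | %d events (%.1f%%) | median follow-up %.2f years",
    nrow(cohort), sum(cohort$event), 100 * mean(cohort$event),
    stats::median(cohort$time)))
  invisible(cohort)
}

#' Fit GP models (and the linear baseline) on a derivation cohort
#'
#' Runs `n_runs` seeded GP repetitions. Each repetition draws its own
#' stratified 2/3:1/3 train/holdout split of the derivation cohort,
#' winsorises (1st/99th centile) and standardises the continuous covariates
#' on its training part, expands both parts to the person-period format and
#' evolves a population; the best-of-run model (lowest holdout negative
#' log-likelihood in the final population) is retained with its
#' preprocessing parameters embedded. Optionally fits the linear
#' discrete-time baseline on the full derivation set.
#'
#' @param data derivation cohort tibble.
#' @param config a [gp_config()]; its `seed` is ignored in favour of
#'   per-run seeds derived from `seed`.
#' @param n_runs number of repeated GP runs (each on its own split).
#' @param seed master seed; run `r` uses `seed + r`.
#' @param width interval width in years.
#' @param continuous columns to winsorise/standardise (default: covariates
#'   taking more than two distinct values).
#' @param baseline fit the linear discrete-time model as well?
#' @param holdout_fraction inner holdout share.
#' @param dir optional output directory for model documents and fitness
#'   logs.
#' @return A list of class `survgp_fit`: `models` (list of [gp_tree()]),
#'   `baseline` (or `NULL`), `runs` (per-run tibble: seed, holdout NLL,
#'   predictors used), `predictor_summary` (median and IQR of the number of
#'   predictors used across runs).
#' @export
run_fit <- function(data, config = gp_config(), n_runs = 1, seed = 1,
                    width = 1, continuous = NULL, baseline = TRUE,
                    holdout_fraction = 1 / 3, dir = NULL) {
  covs <- cohort_covariates(data)
  if (is.null(continuous)) {
    continuous <- covs[vapply(covs, function(cl)
      length(unique(data[[cl]])) > 2, logical(1))]
  }
  runs <- vector("list", n_runs)
  models <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    parts <- stratified_split(data, fraction = 1 - holdout_fraction,
                              seed = run_seed)
    train <- parts$a
    if (length(continuous) > 0) {
      train <- winsorize(train, continuous)
      winsor <- attr(train, "winsor_limits")
      train <- standardize(train, continuous)
      scaling <- attr(train, "scaling")
      pp <- list(winsor = winsor, scaling = scaling)
      holdout <- apply_preprocess(parts$b, pp)
    } else {
      pp <- NULL
      holdout <- parts$b
    }
    cfg <- config
    cfg$seed <- run_seed
    res <- steady_state_evolve(to_person_period(train, width),
                               to_person_period(holdout, width), cfg)
    model <- res$best_tree
    model$preprocess <- pp
    models[[r]] <- model
    used <- setdiff(predictors_used(model), "tj")
    runs[[r]] <- tibble::tibble(
      run = r, seed = run_seed, evaluations = res$evaluations,
      best_train_nll = res$best_train_nll,
      best_holdout_nll = res$best_holdout_nll,
      n_predictors = length(used),
      predictors = paste(sort(used), collapse = ";"))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_hazard_model(model, file.path(dir, sprintf("gp_model_%02d.json", r)))
      readr::write_csv(res$history,
                       file.path(dir, sprintf("gp_history_%02d.csv", r)))
    }
  }
  runs <- dplyr::bind_rows(runs)
  base_model <- NULL
  if (baseline) {
    dtrain <- data
    pp <- NULL
    if (length(continuous) > 0) {
      dtrain <- winsorize(dtrain, continuous)
      winsor <- attr(dtrain, "winsor_limits")
      dtrain <- standardize(dtrain, continuous)
      pp <- list(winsor = winsor, scaling = attr(dtrain, "scaling"))
    }
    base_model <- tryCatch(
      fit_linear_discrete(to_person_period(dtrain, width)),
      error = function(e) {
        warning("linear baseline failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(base_model)) {
      base_model$preprocess <- pp
      if (!is.null(dir)) {
        write_hazard_model(base_model, file.path(dir, "linear_baseline.json"))
      }
    }
  }
  nq <- stats::quantile(runs$n_predictors, c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(models = models, baseline = base_model, runs = runs,
              predictor_summary = tibble::tibble(
                median_predictors = nq[2], q1 = nq[1], q3 = nq[3]))
  class(out) <- "survgp_fit"
  if (!is.null(dir)) readr::write_csv(runs, file.path(dir, "runs.csv"))
  out
}

#' @export
print.survgp_fit <- function(x, ...) {
  cat("<survgp_fit>", length(x$models), "GP run(s)",
      if (!is.null(x$baseline)) "+ linear baseline" else "", "\n")
  cat("  predictors used per run: median",
      x$predictor_summary$median_predictors,
      sprintf("(IQR %s-%s)", x$predictor_summary$q1, x$predictor_summary$q3),
      "\n")
  invisible(x)
}

#' Evaluate fitted models on a validation cohort
#'
#' @param fit a `survgp_fit` (or a list of hazard models).
#' @param data validation cohort.
#' @param horizons evaluation horizons (years).
#' @param g calibration groups.
#' @param dir optional output directory (one subdirectory per model).
#' @return Named list of `survgp_evaluation` objects (`gp_1`, ...,
#'   `baseline`), plus a `comparison` tibble of C-statistics and HL
#'   chi-squares across models.
#' @export
run_evaluate <- function(fit, data, horizons = c(1, 3, 5), g = 10,
                         dir = NULL) {
  models <- if (inherits(fit, "survgp_fit")) {
    out <- stats::setNames(fit$models,
                           sprintf("gp_%d", seq_along(fit$models)))
    if (!is.null(fit$baseline)) out$baseline <- fit$baseline
    out
  } else fit
  reports <- lapply(models, evaluate_model, data = data,
                    horizons = horizons, g = g)
  comparison <- purrr::imap_dfr(reports, function(rep, nm) {
    dplyr::left_join(rep$c_statistics,
                     rep$hl[c("horizon", "chi_squared", "p_value")],
                     by = "horizon") |>
      dplyr::mutate(model = nm, .before = 1)
  })
  if (!is.null(dir)) {
    for (nm in names(reports)) {
      write_evaluation(reports[[nm]], file.path(dir, nm))
    }
    readr::write_csv(comparison, file.path(dir, "comparison.csv"))
  }
  c(reports, list(comparison = comparison))
}
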