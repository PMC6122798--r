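#' Load a subject-level survival cohort from a delimited file
#'
#' Reads a comma-separated table with reserved columns `id`, `time`
#' (follow-up in years) and `event` (1 = event observed at `time`,
#' 0 = censored), plus one column per covariate named in `schema`.
#' Categorical covariates are expanded to `n - 1` indicator columns
#' (`NAME_level`, first declared level as reference). The loader is strict:
#' missing cells, non-numeric values, negative times or event codes outside
#' \{0, 1\} are rejected with the offending row/column named, because
#' imputation is deliberately out of scope for this package.
#'
#' @param path path to a CSV file with a header row.
#' @param schema covariate schema: either a named list/vector mapping
#'   covariate name to `"continuous"`, `"binary"`, or
#'   `"categorical:lev1,lev2,..."`, or the path to a YAML file holding such
#'   a mapping.
#' @return A tibble with columns `id`, `time`, `event` and the (expanded)
#'   covariates, carrying the covariate names in `attr(, "covariates")` and
#'   the parsed schema in `attr(, "schema")`.
#' @export
load_cohort <- function(path, schema) {
  schema <- parse_schema(schema)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("id", "time", "event", names(schema))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[required]

  check_cell <- function(col, parsed, extra_ok = rep(TRUE, length(parsed))) {
    bad <- which(is.na(raw[[col]]) | is.na(parsed) | !extra_ok)
    if (length(bad) > 0) {
      stop("invalid or missing value in column '", col, "', row ", bad[1],
           call. = FALSE)
    }
  }

  out <- tibble::tibble(id = raw$id)
  time <- suppressWarnings(as.numeric(raw$time))
  check_cell("time", time, extra_ok = !is.na(time) & time >= 0)
  event <- suppressWarnings(as.numeric(raw$event))
  check_cell("event", event, extra_ok = event %in% c(0, 1))
  out$time <- time
  out$event <- as.integer(event)

  cov_names <- character(0)
  for (nm in names(schema)) {
    sp <- schema[[nm]]
    if (sp$type == "categorical") {
      vals <- raw[[nm]]
      bad <- which(is.na(vals) | !vals %in% sp$levels)
      if (length(bad) > 0) {
        stop("invalid or missing value in column '", nm, "', row ", bad[1],
             call. = FALSE)
      }
      for (lev in sp$levels[-1]) {
        col <- paste0(nm, "_", lev)
        out[[col]] <- as.numeric(vals == lev)
        cov_names <- c(cov_names, col)
      }
    } else {
      x <- suppressWarnings(as.numeric(raw[[nm]]))
      check_cell(nm, x)
      if (sp$type == "binary" && !all(x %in% c(0, 1))) {
        bad <- which(!x %in% c(0, 1))
        stop("non-binary value in column '", nm, "', row ", bad[1],
             call. = FALSE)
      }
      out[[nm]] <- x
      cov_names <- c(cov_names, nm)
    }
  }
  attr(out, "covariates") <- cov_names
  attr(out, "schema") <- schema
  out
}

parse_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
  }
  schema <- as.list(schema)
  lapply(schema, function(s) {
    s <- as.character(s)
    if (s %in% c("continuous", "binary")) return(list(type = s))
    if (startsWith(s, "categorical:")) {
      levels <- strsplit(sub("^categorical:", "", s), ",", fixed = TRUE)[[1]]
      levels <- trimws(levels)
      if (length(levels) < 2) stop("categorical covariate needs >= 2 levels",
                                   call. = FALSE)
      return(list(type = "categorical", levels = levels))
    }
    stop("unknown covariate type: ", s, call. = FALSE)
  })
}

#' Covariate columns of a cohort or person-period table
#'
#' @param data a cohort or person-period tibble.
#' @return character vector of covariate column names (everything except the
#'   reserved columns when no attribute is present).
#' @export
cohort_covariates <- function(data) {
  cv <- attr(data, "covariates")
  if (!is.null(cv)) return(cv)
  setdiff(names(data), c("id", "time", "event", "j", "tj"))
}

#' Winsorise extreme covariate values at empirical centiles
#'
#' Values below the lower / above the upper empirical centile (linear
#' interpolation quantiles, R type 7) are replaced by those centiles. When
#' `limits` is supplied (as returned in `attr(, "winsor_limits")` from a
#' previous call on training data), those stored limits are applied instead
#' of recomputing them, so validation data is truncated with training
#' centiles.
#'
#' @param data cohort tibble.
#' @param columns continuous covariate columns to truncate.
#' @param probs length-2 vector of centile probabilities (default 1st/99th).
#' @param limits optional tibble `(column, lower, upper)` of stored limits.
#' @return The data with truncated columns; the limits used are attached as
#'   `attr(, "winsor_limits")`.
#' @export
winsorize <- function(data, columns, probs = c(0.01, 0.99), limits = NULL) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    stop("column not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(limits)) {
    limits <- purrr::map_dfr(columns, function(col) {
      q <- stats::quantile(data[[col]], probs = probs, type = 7, names = FALSE)
      tibble::tibble(column = col, lower = q[1], upper = q[2])
    })
  }
  for (i in seq_len(nrow(limits))) {
    col <- limits$column[i]
    lo <- limits$lower[i]; hi <- limits$upper[i]
    if (lo == hi) {
      warning("column '", col, "' is constant at the chosen centiles; ",
              "left unchanged", call. = FALSE)
      next
    }
    data[[col]] <- pmin(pmax(data[[col]], lo), hi)
  }
  attr(data, "winsor_limits") <- limits
  data
}

#' Centre and scale continuous covariates
#'
#' Columns are centred to mean 0 and scaled to standard deviation 1 using
#' training-set statistics. Pass the stored `scaling` (from
#' `attr(, "scaling")`) to apply training statistics to new data.
#'
#' @param data cohort tibble.
#' @param columns continuous covariate columns.
#' @param scaling optional tibble `(column, mean, sd)` of stored parameters.
#' @return The data with scaled columns and `attr(, "scaling")` set.
#' @export
standardize <- function(data, columns, scaling = NULL) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    stop("column not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(scaling)) {
    scaling <- purrr::map_dfr(columns, function(col) {
      s <- stats::sd(data[[col]])
      if (!is.finite(s) || s == 0) {
        stop("zero-variance column: ", col, call. = FALSE)
      }
      tibble::tibble(column = col, mean = mean(data[[col]]), sd = s)
    })
  }
  for (i in seq_len(nrow(scaling))) {
    col <- scaling$column[i]
    data[[col]] <- (data[[col]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(data, "scaling") <- scaling
  data
}

#' Expand a cohort to the person-period (counting-process) format
#'
#' Each subject contributes one row per observed discrete interval:
#' `J = max(1, ceiling(time / width))` rows with interval index
#' `j = 1, ..., J`. Intervals are half-open `((j-1)w, jw]`, so a follow-up
#' time falling exactly on a boundary belongs to the lower interval. The
#' event flag is placed on the last row only; censored subjects contribute
#' their final partial interval as an at-risk, non-event row. The time
#' indicator column `tj` carries the interval index and is available as a
#' model terminal.
#'
#' @param data cohort tibble (`id`, `time`, `event`, covariates).
#' @param width interval width \eqn{\Delta} in years (default 1).
#' @return Person-period tibble with columns `id`, `j`, `tj`, `event` and
#'   the covariates, with `attr(, "width")` and `attr(, "covariates")`.
#' @export
to_person_period <- function(data, width = 1) {
  stopifnot(width > 0)
  covs <- cohort_covariates(data)
  J <- pmax(1L, as.integer(ceiling(data$time / width - 1e-12)))
  idx <- rep(seq_len(nrow(data)), J)
  j <- sequence(J)
  out <- tibble::tibble(
    id = data$id[idx],
    j = j,
    tj = as.numeric(j),
    event = as.integer(j == rep(J, J) & data$event[idx] == 1)
  )
  for (col in covs) out[[col]] <- data[[col]][idx]
  attr(out, "width") <- width
  attr(out, "covariates") <- covs
  out
}

#' Kaplan-Meier survival curve with Greenwood standard errors
#'
#' Product-limit estimate of the survival function, reported at each
#' distinct event time, with Greenwood standard errors (via
#' [survival::survfit()]). Use [survival_at()] to evaluate the step function
#' at arbitrary times.
#'
#' @param data cohort tibble with `time` and `event`.
#' @return Tibble `(time, survival, std_err, n_risk, n_event)`; zero rows
#'   when no events occur (the estimate is then identically 1).
#' @export
kaplan_meier <- function(data) {
  if (nrow(data) < 1) stop("empty cohort", call. = FALSE)
  fit <- survival::survfit(survival::Surv(data$time, data$event) ~ 1,
                           conf.type = "plain")
  keep <- fit$n.event > 0
  tibble::tibble(
    time = fit$time[keep],
    survival = fit$surv[keep],
    std_err = fit$std.err[keep] * fit$surv[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep]
  )
}

#' Evaluate a survival curve at arbitrary times
#'
#' Step interpolation of a curve produced by [kaplan_meier()]: the estimate
#' is 1 (SE 0) before the first event time and constant between event times.
#'
#' @param curve tibble from [kaplan_meier()].
#' @param t numeric vector of times.
#' @param what `"survival"` or `"std_err"`.
#' @return numeric vector, same length as `t`.
#' @export
survival_at <- function(curve, t, what = c("survival", "std_err")) {
  what <- match.arg(what)
  default <- if (what == "survival") 1 else 0
  if (nrow(curve) == 0) return(rep(default, length(t)))
  idx <- findInterval(t + 1e-12, curve$time)
  out <- rep(default, length(t))
  out[idx > 0] <- curve[[what]][idx[idx > 0]]
  out
}

#' Stratified random split of a cohort
#'
#' Splits subjects into two parts, stratified on the event indicator so that
#' each part's event count is within one subject of exact proportionality.
#' With zero events a plain random split is used, with a warning.
#'
#' @param data cohort tibble.
#' @param fraction proportion of subjects assigned to the first part.
#' @param seed optional integer; when given, the split is reproducible and
#'   the caller's RNG state is untouched.
#' @return `list(a = , b = )` of two tibbles preserving attributes.
#' @export
stratified_split <- function(data, fraction = 2 / 3, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  pick <- local_seed(seed, {
    ev <- which(data$event == 1)
    ce <- which(data$event == 0)
    if (length(ev) == 0) {
      warning("cohort has no events; using a plain random split",
              call. = FALSE)
      sample(seq_len(nrow(data)), round(fraction * nrow(data)))
    } else {
      c(sample(ev, round(fraction * length(ev))),
        sample(ce, round(fraction * length(ce))))
    }
  })
  a <- data[sort(pick), , drop = FALSE]
  b <- data[setdiff(seq_len(nrow(data)), pick), , drop = FALSE]
  for (at in c("covariates", "schema", "width")) {
    attr(a, at) <- attr(data, at)
    attr(b, at) <- attr(data, at)
  }
  list(a = a, b = b)
}

# evaluate `code` under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
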