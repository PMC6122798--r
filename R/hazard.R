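#' Logistic link from log-odds to discrete-time hazard
#'
#' Maps an unbounded log-odds \eqn{\varepsilon} to the conditional event
#' probability \eqn{h = 1 / (1 + e^{-\varepsilon})}, clipped to
#' `[1e-12, 1 - 1e-12]` so that the censored-data log-likelihood stays
#' finite for arbitrarily extreme model output.
#'
#' @param eps numeric vector of log-odds.
#' @return numeric vector of hazards in `[1e-12, 1 - 1e-12]`.
#' @export
logistic_hazard <- function(eps) {
  pmin(pmax(stats::plogis(eps), 1e-12), 1 - 1e-12)
}

#' Discrete-time survival function from per-interval hazards
#'
#' \eqn{S(t_j) = \prod_{k \le j} (1 - h_k)}: the probability of remaining
#' event-free through interval `j` is the product of the per-interval
#' complements.
#'
#' @param h numeric vector of per-interval hazards, each in `[0, 1]`.
#' @return numeric vector of the same length; non-increasing, starts at
#'   `1 - h[1]`. (S at time 0 is 1 by convention and not returned.)
#' @export
survival_from_hazards <- function(h) {
  if (any(h < 0 | h > 1)) stop("hazards must lie in [0, 1]", call. = FALSE)
  cumprod(1 - h)
}

#' Log-odds of a hazard model on a person-period table
#'
#' The common contract of every hazard model in the package: given rows of
#' covariates plus the interval index `tj`, return the log-odds
#' \eqn{\varepsilon} of the discrete-time hazard for each row. Methods exist
#' for evolved expression trees ([gp_tree()]), the linear discrete-time
#' baseline ([fit_linear_discrete()]), and plain functions wrapped with
#' [hazard_function()].
#'
#' @param object a hazard model.
#' @param data person-period rows (`tj` plus covariates).
#' @param ... method-specific arguments.
#' @return numeric vector of finite log-odds, one per row.
#' @export
log_odds <- function(object, data, ...) UseMethod("log_odds")

#' @export
log_odds.gp_tree <- function(object, data, ...) {
  data <- apply_preprocess(data, object$preprocess)
  evaluate_tree(object, data)
}

#' @export
log_odds.linear_discrete_model <- function(object, data, ...) {
  data <- apply_preprocess(data, object$preprocess)
  j <- if ("j" %in% names(data)) data$j else data$tj
  key <- match(as.integer(j), object$intervals)
  if (anyNA(key)) {
    stop("interval index outside the model's trained range (1..",
         max(object$intervals), "); refusing to extrapolate", call. = FALSE)
  }
  missing_cols <- setdiff(names(object$beta), names(data))
  if (length(missing_cols) > 0) {
    stop("covariate mismatch: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  eps <- object$alpha[key]
  if (length(object$beta) > 0) {
    X <- as.matrix(data[names(object$beta)])
    eps <- eps + drop(X %*% object$beta)
  }
  unname(eps)
}

#' Wrap a plain function as a hazard model
#'
#' @param fn function taking a person-period data frame and returning a
#'   log-odds vector.
#' @param delta interval width in years.
#' @return A `hazard_fn` model implementing [log_odds()].
#' @export
hazard_function <- function(fn, delta = 1) {
  structure(list(fn = fn, delta = delta),
            class = c("hazard_fn", "hazard_model"))
}

#' @export
log_odds.hazard_fn <- function(object, data, ...) {
  out <- object$fn(data)
  rep_len(out, nrow(data))
}

apply_preprocess <- function(data, preprocess) {
  if (is.null(preprocess)) return(data)
  if (!is.null(preprocess$winsor)) {
    data <- winsorize(data, preprocess$winsor$column,
                      limits = preprocess$winsor)
  }
  if (!is.null(preprocess$scaling)) {
    data <- standardize(data, preprocess$scaling$column,
                        scaling = preprocess$scaling)
  }
  data
}

#' Censored-data negative log-likelihood (the GP fitness function)
#'
#' The joint probability of the observed event/censoring pattern under a
#' discrete-time hazard model, on a person-period table:
#' \deqn{-\sum_{i}\sum_{j} [E_{ij} \log h(t_{ij}) +
#'       (1 - E_{ij}) \log(1 - h(t_{ij}))]}
#' with \eqn{h} from [logistic_hazard()]. Lower is fitter; the value is
#' always finite (hazard clipping) and non-negative.
#'
#' @param object a hazard model.
#' @param data person-period tibble with an `event` column.
#' @return non-negative scalar.
#' @export
negative_log_likelihood <- function(object, data) {
  h <- logistic_hazard(log_odds(object, data))
  ev <- data$event
  -sum(ev * log(h) + (1 - ev) * log1p(-h))
}

#' Fit the linear discrete-time hazard baseline
#'
#' Maximum-likelihood fit of the linear predictor
#' \deqn{\varepsilon = \alpha_1 D_1 + \dots + \alpha_J D_J +
#'       \beta_1 x_1 + \dots + \beta_P x_P}
#' where the \eqn{D_j} are dummy indicators of the time interval: a logistic
#' regression of the person-period event flag on interval dummies plus
#' covariates, fitted by iteratively reweighted least squares
#' (Newton-Raphson; [stats::glm()]). Intervals with no events in training
#' have no interior MLE; their intercepts are capped at the hazard clipping
#' bound with a warning. Separation in covariates aborts the fit.
#'
#' @param data person-period tibble (from [to_person_period()]).
#' @param covariates covariate columns (default: all non-reserved columns).
#' @param max_iter,tol IRLS iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `linear_discrete_model` with elements
#'   `alpha` (per-interval intercepts), `beta`, `intervals`, `loglik`,
#'   `iterations`, `converged`, `delta`.
#' @export
fit_linear_discrete <- function(data, covariates = NULL,
                                max_iter = 100, tol = 1e-8) {
  if (sum(data$event) == 0) {
    stop("no events in the table: the likelihood has no interior maximum",
         call. = FALSE)
  }
  if (is.null(covariates)) covariates <- cohort_covariates(data)
  intervals <- sort(unique(as.integer(data$j)))
  df <- data.frame(.event = data$event)
  # explicit dummy time indicators (robust to a single observed interval)
  dummy_cols <- paste0(".D", intervals)
  for (k in seq_along(intervals)) {
    df[[dummy_cols[k]]] <- as.numeric(data$j == intervals[k])
  }
  for (col in covariates) df[[col]] <- data[[col]]
  rhs <- c("0", dummy_cols, covariates)
  fml <- stats::as.formula(paste(".event ~", paste(rhs, collapse = " + ")))

  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop("IRLS did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  cf <- stats::coef(fit)
  alpha <- cf[dummy_cols]
  beta <- cf[covariates]
  if (anyNA(cf)) {
    stop("design matrix is rank deficient (aliased coefficients)",
         call. = FALSE)
  }
  if (length(covariates) > 0 && any(abs(beta) > 50) && sep_warning) {
    stop("separation detected: divergent covariate coefficients; fit aborted",
         call. = FALSE)
  }
  # intervals with no events have no interior MLE: their intercepts drift
  # towards -Inf; report them at the hazard clipping bound instead
  ev_by_j <- tapply(data$event, factor(data$j, levels = intervals), sum)
  empty <- which(ev_by_j == 0)
  if (length(empty) > 0) {
    warning("interval(s) without events: ",
            paste(intervals[empty], collapse = ", "),
            "; intercept capped at the hazard clipping bound", call. = FALSE)
    alpha[empty] <- stats::qlogis(1e-12)
  }
  structure(
    list(alpha = stats::setNames(unname(alpha), intervals),
         beta = stats::setNames(unname(beta), covariates),
         intervals = intervals,
         covariates = covariates,
         loglik = as.numeric(stats::logLik(fit)),
         iterations = fit$iter,
         converged = fit$converged,
         delta = attr(data, "width") %||% 1,
         preprocess = NULL,
         trained_intervals = max(intervals)),
    class = c("linear_discrete_model", "hazard_model")
  )
}

#' @export
print.linear_discrete_model <- function(x, ...) {
  cat("<linear_discrete_model> ", length(x$intervals), " interval(s), ",
      length(x$beta), " covariate(s)\n", sep = "")
  cat("  logLik ", format(x$loglik), " (", x$iterations, " IRLS iterations)\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- model documents -----------------------------------------------------

#' Read and write hazard-model documents
#'
#' Models serialise to a structured-text (JSON) document carrying covariate
#' names, the interval width, preprocessing parameters and either the full-
#' precision coefficients (linear model) or the expression string (tree).
#' Round-trips are exact for coefficients.
#'
#' @param model a `gp_tree` or `linear_discrete_model`.
#' @param path file path.
#' @return `read_hazard_model()` returns the model; `write_hazard_model()`
#'   its path, invisibly.
#' @export
write_hazard_model <- function(model, path) {
  doc <- if (inherits(model, "gp_tree")) {
    list(type = "gp_tree",
         expression = serialize_tree(model),
         terminals = model$terminals,
         delta = model$delta,
         trained_intervals = model$trained_intervals,
         preprocess = model$preprocess)
  } else if (inherits(model, "linear_discrete_model")) {
    list(type = "linear_discrete",
         alpha = as.list(model$alpha),
         beta = as.list(model$beta),
         intervals = model$intervals,
         covariates = model$covariates,
         loglik = model$loglik,
         delta = model$delta,
         preprocess = model$preprocess)
  } else {
    stop("cannot serialise objects of class ", class(model)[1], call. = FALSE)
  }
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_hazard_model
#' @export
read_hazard_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- NULL
  if (!is.null(doc$preprocess)) {
    pp <- list()
    if (!is.null(doc$preprocess$winsor))
      pp$winsor <- tibble::as_tibble(doc$preprocess$winsor)
    if (!is.null(doc$preprocess$scaling))
      pp$scaling <- tibble::as_tibble(doc$preprocess$scaling)
  }
  if (doc$type == "gp_tree") {
    out <- parse_tree(doc$expression, terminals = doc$terminals,
                      delta = doc$delta,
                      trained_intervals = doc$trained_intervals)
    out$preprocess <- pp
    return(out)
  }
  if (doc$type == "linear_discrete") {
    return(structure(
      list(alpha = stats::setNames(unlist(doc$alpha), doc$intervals),
           beta = stats::setNames(
             if (length(doc$beta)) unlist(doc$beta) else numeric(0),
             names(doc$beta)),
           intervals = as.integer(doc$intervals),
           covariates = as.character(unlist(doc$covariates)),
           loglik = doc$loglik,
           iterations = NA_integer_,
           converged = TRUE,
           delta = doc$delta,
           preprocess = pp,
           trained_intervals = max(as.integer(doc$intervals))),
      class = c("linear_discrete_model", "hazard_model")))
  }
  stop("unknown model document type: ", doc$type, call. = FALSE)
}
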