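test_that("predicted risk composes hazards through the horizon", {
  co <- make_cohort(time = rep(5, 4), event = rep(0, 4), x = 1:4)
  m0 <- hazard_function(function(d) 0)
  m0$trained_intervals <- 5L
  r <- predict_risk(m0, co, 2)
  expect_equal(r$risk, rep(0.75, 4)) # h = 0.5 twice -> S = 0.25
  rneg <- predict_risk(hazard_function(function(d) -1e9), co, 3)
  expect_equal(rneg$risk, rep(0, 4), tolerance = 1e-9)
  expect_error(predict_risk(m0, co, 6), "trained")
  expect_error(predict_risk(m0, co, 1.5), "multiple")

  # linear model: agreement with a naive per-subject interval loop
  spec <- linear_test_spec(300)
  sim <- generate_cohort(spec, seed = 12)
  fit <- fit_linear_discrete(to_person_period(sim, 1))
  ten <- sim[1:10, ]
  got <- predict_risk(fit, ten, 3)$risk
  want <- vapply(seq_len(10), function(i) {
    S <- 1
    for (j in 1:3) {
      eps <- fit$alpha[[as.character(j)]] +
        fit$beta[["x1"]] * ten$x1[i] + fit$beta[["x2"]] * ten$x2[i]
      S <- S * (1 - logistic_hazard(eps))
    }
    1 - S
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("Harrell's C matches the pairwise definition", {
  # perfect ordering, no censoring
  co <- make_cohort(time = c(1, 2, 3, 4), event = rep(1, 4))
  expect_equal(harrell_c(co, c(4, 3, 2, 1)), 1)
  expect_equal(harrell_c(co, rep(1, 4)), 0.5)
  expect_equal(harrell_c(co, c(1, 2, 3, 4)), 0)

  set.seed(19)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    co <- make_cohort(time = round(runif(n, 0, 6), 2),
                      event = rbinom(n, 1, 0.5))
    s <- rnorm(n)
    tr <- sample(c(1, 3, 5), 1)
    expect_equal(harrell_c(co, s, truncate_at = tr),
                 naive_harrell_c(co$time, co$event, s, tr))
    # antisymmetry for tie-free scores
    expect_equal(harrell_c(co, s) + harrell_c(co, -s), 1)
    # invariance under strictly monotone transforms
    expect_equal(harrell_c(co, s), harrell_c(co, exp(s)))
  }

  # agreement with the survival package on tie-free uncensored data
  set.seed(20)
  co <- make_cohort(time = runif(60), event = rep(1, 60))
  s <- rnorm(60)
  cf <- survival::concordance(survival::Surv(time, event) ~ s,
                              data = cbind(co, s = s), reverse = TRUE)
  expect_equal(harrell_c(co, s), unname(cf$concordance))

  allc <- make_cohort(time = 1:4, event = rep(0, 4))
  expect_warning(cc <- harrell_c(allc, 1:4), "no usable pairs")
  expect_true(is.na(cc))
})

test_that("calibration groups are equal-sized with remainder spread low", {
  set.seed(25)
  co <- make_cohort(time = runif(25, 0.1, 4), event = rbinom(25, 1, 0.5))
  risks <- runif(25)
  cal <- calibration_table(co, risks, t = 2, g = 10)
  expect_equal(cal$size, c(3, 3, 3, 3, 3, 2, 2, 2, 2, 2))
  expect_equal(sum(cal$size), 25)
  expect_equal(sum(cal$predicted_events), sum(risks))
  # group 1 holds the highest predicted risks
  expect_gt(cal$mean_risk[1], cal$mean_risk[10])
  expect_error(calibration_table(co, risks, 2, g = 1), "g must be")
})

test_that("a well-calibrated model shows predicted close to observed", {
  # two deterministic risk strata, no censoring
  set.seed(33)
  n <- 2000
  p <- rep(c(0.1, 0.4), each = n / 2)
  event <- rbinom(n, 1, p)
  co <- make_cohort(time = ifelse(event == 1, 0.5, 3), event = event)
  cal <- calibration_table(co, p, t = 1, g = 4)
  expect_true(all(abs(cal$observed_events - cal$predicted_events) <
                    3 * sqrt(cal$predicted_events)))
})

test_that("the generalized Hosmer-Lemeshow statistic follows its formula", {
  cal <- tibble::tibble(group = 1:2, size = c(50, 50),
                        mean_risk = c(0.2, 0.4),
                        predicted_events = c(10, 20),
                        observed_events = c(14, 17),
                        km_survival = c(0.72, 0.66),
                        at_risk_at_t = TRUE)
  hl <- hosmer_lemeshow(cal, df = 1)
  want <- (14 - 10)^2 / (10 * (1 - 10 / 50)) + (17 - 20)^2 / (20 * (1 - 20 / 50))
  expect_equal(hl$chi_squared, want, tolerance = 1e-12)
  expect_equal(hl$p_value, pchisq(want, 1, lower.tail = FALSE))
  # simple variance variant
  hl2 <- hosmer_lemeshow(cal, df = 1, variance = "simple")
  expect_equal(hl2$chi_squared, 16 / 10 + 9 / 20, tolerance = 1e-12)
  # exact agreement -> zero statistic, p = 1
  cal$observed_events <- cal$predicted_events
  expect_equal(hosmer_lemeshow(cal)$chi_squared, 0)
  expect_equal(hosmer_lemeshow(cal)$p_value, 1)
  # degenerate prediction triggers the continuity guard
  cal$predicted_events <- c(0, 20)
  expect_warning(hosmer_lemeshow(cal), "continuity")
})

test_that("survival curve comparison pairs model and KM estimates", {
  set.seed(41)
  co <- make_cohort(time = runif(100, 0.2, 6), event = rbinom(100, 1, 0.4))
  m0 <- hazard_function(function(d) -1e9)
  m0$trained_intervals <- 5L
  curves <- survival_curve_comparison(m0, co, horizons = c(1, 3, 5))
  expect_equal(curves$estimate[curves$source == "model"], rep(1, 3))
  km <- kaplan_meier(co)
  expect_equal(curves$estimate[curves$source == "km"],
               survival_at(km, c(1, 3, 5)))
  curves2 <- survival_curve_comparison(m0, co, horizons = c(1, 3, 5))
  expect_identical(curves, curves2)
})

test_that("evaluate_model bundles discrimination and calibration", {
  spec <- linear_test_spec(600, intercept = -2, b1 = 1, b2 = -0.6)
  co <- generate_cohort(spec, seed = 3)
  rep <- evaluate_model(true_hazard_model(spec), co, horizons = c(1, 2, 3),
                        g = 5)
  expect_equal(rep$c_statistics$horizon, c(1, 2, 3))
  expect_true(all(rep$c_statistics$c_statistic > 0.5))
  expect_true(all(rep$hl$df == 4))
  expect_equal(nrow(rep$calibration), 15)
  td <- tidy(rep)
  expect_named(td, c("horizon", "c_statistic", "chi_squared", "df",
                     "p_value"))
  # report round-trips losslessly through its CSV form
  dir <- withr::local_tempdir()
  write_evaluation(rep, dir)
  back <- readr::read_csv(file.path(dir, "c_statistics.csv"),
                          show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep$c_statistics))
})
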