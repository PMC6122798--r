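test_that("load_cohort reads, validates and dummy-codes a delimited file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,event,age,smoking",
               "a,1.5,0,60,never",
               "b,2.0,1,55,former",
               "c,0.4,1,70,current"), path)
  schema <- list(age = "continuous",
                 smoking = "categorical:never,former,current")
  co <- load_cohort(path, schema)
  expect_equal(nrow(co), 3)
  # 3-level categorical -> 2 indicators, reference = first declared level
  expect_equal(cohort_covariates(co),
               c("age", "smoking_former", "smoking_current"))
  expect_equal(co$smoking_former, c(0, 1, 0))
  expect_equal(co$smoking_current, c(0, 0, 1))
  expect_equal(co$time, c(1.5, 2.0, 0.4))

  writeLines(c("id,time,event,age", "a,1,2,60"), path)
  expect_error(load_cohort(path, list(age = "continuous")), "row 1")
  writeLines(c("id,time,event,age", "a,-1,0,60"), path)
  expect_error(load_cohort(path, list(age = "continuous")), "'time'")
  writeLines(c("id,time,event,age", "a,1,0,"), path)
  expect_error(load_cohort(path, list(age = "continuous")), "'age'")
  writeLines(c("id,time,event", "a,1,0"), path)
  expect_error(load_cohort(path, list(age = "continuous")), "missing column")
})

test_that("winsorize truncates at interpolated centiles and is idempotent", {
  co <- make_cohort(rep(1, 100), rep(0, 100), x = as.numeric(1:100))
  w <- winsorize(co, "x")
  q <- quantile(1:100, c(0.01, 0.99), type = 7, names = FALSE)
  expect_equal(min(w$x), q[1])
  expect_equal(max(w$x), q[2])
  expect_equal(sort(unique(w$x))[2], 2) # interior untouched
  # re-applying the stored limits changes nothing
  w2 <- winsorize(w, "x", limits = attr(w, "winsor_limits"))
  expect_equal(w2$x, w$x)
  # degenerate inputs
  const <- make_cohort(rep(1, 5), rep(0, 5), x = rep(3, 5))
  expect_warning(wc <- winsorize(const, "x"), "constant")
  expect_equal(wc$x, rep(3, 5))
  expect_equal(winsorize(co, "x", probs = c(0, 1))$x, co$x)
  expect_error(winsorize(co, "nope"), "not found")
})

test_that("standardize centres/scales with reusable training statistics", {
  co <- make_cohort(c(1, 1), c(0, 0), x = c(0, 2))
  s <- standardize(co, "x")
  expect_equal(s$x, c(-1, 1) / sqrt(2)) # sample sd convention
  expect_equal(attr(s, "scaling")$mean, 1)
  # idempotent on its own output
  s2 <- standardize(s, "x")
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  # training statistics applied to shifted validation data keep the shift
  val <- make_cohort(c(1, 1), c(0, 0), x = c(10, 12))
  sv <- standardize(val, "x", scaling = attr(s, "scaling"))
  expect_equal(mean(sv$x), (11 - 1) / sd(c(0, 2)))
  expect_error(standardize(make_cohort(1, 0, x = 1), "x"), "variance")
})

test_that("person-period expansion reproduces the counting-process layout", {
  co <- make_cohort(time = c(2.0, 3.0, 0.4), event = c(0, 1, 1),
                    x1 = c(1, 0, 2))
  pp <- to_person_period(co, width = 1)
  # censored at 2 -> rows (j=1,e=0),(j=2,e=0); event at 3 -> (0,0,1)
  expect_equal(pp$j[pp$id == "s1"], 1:2)
  expect_equal(pp$event[pp$id == "s1"], c(0L, 0L))
  expect_equal(pp$j[pp$id == "s2"], 1:3)
  expect_equal(pp$event[pp$id == "s2"], c(0L, 0L, 1L))
  expect_equal(pp$event[pp$id == "s3"], 1L)
  expect_equal(pp$x1, c(1, 1, 0, 0, 0, 2))
  expect_equal(pp$tj, as.numeric(pp$j))
})

test_that("person-period row and event counts are conserved", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50
    co <- make_cohort(time = runif(n, 0, 8), event = rbinom(n, 1, 0.4),
                      x = rnorm(n))
    pp <- to_person_period(co, width = 1)
    expect_equal(nrow(pp), sum(pmax(1, ceiling(co$time))))
    expect_equal(sum(pp$event), sum(co$event))
    # halving the width at most doubles each subject's row count
    J1 <- table(pp$id)
    J2 <- table(to_person_period(co, width = 0.5)$id)
    expect_true(all(J2[names(J1)] %in% c(2 * J1 - 1, 2 * J1)))
  }
})

test_that("Kaplan-Meier matches hand product-limit and empirical survival", {
  co <- make_cohort(time = 1:4, event = rep(1, 4))
  km <- kaplan_meier(co)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # Greenwood SE at the first event time: S * sqrt(d / (n (n - d)))
  expect_equal(km$std_err[1], 0.75 * sqrt(1 / (4 * 3)))

  one <- make_cohort(1, 1)
  expect_equal(kaplan_meier(one)$survival, 0)

  cens <- make_cohort(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_equal(nrow(kaplan_meier(cens)), 0)
  expect_equal(survival_at(kaplan_meier(cens), c(0.5, 2, 10)), c(1, 1, 1))

  # no censoring: KM equals the empirical survival function exactly
  set.seed(7)
  for (rep in 1:5) {
    co <- make_cohort(time = sample(1:6, 30, replace = TRUE),
                      event = rep(1, 30))
    km <- kaplan_meier(co)
    for (t in c(0.5, 1, 2.5, 4, 6)) {
      expect_equal(survival_at(km, t), naive_survival(co$time, t))
    }
  }
  expect_error(kaplan_meier(make_cohort(numeric(0), integer(0))), "empty")
})

test_that("stratified split is proportionate, seeded and reproducible", {
  co <- make_cohort(time = 1:9, event = c(1, 1, 1, rep(0, 6)))
  sp <- stratified_split(co, 2 / 3, seed = 11)
  expect_equal(nrow(sp$a), 6)
  expect_equal(sum(sp$a$event), 2)
  expect_equal(sum(sp$b$event), 1)
  sp2 <- stratified_split(co, 2 / 3, seed = 11)
  expect_identical(sp$a$id, sp2$a$id)
  # different seeds give a different partition (w.h.p. on 9 choose 6)
  sp3 <- stratified_split(co, 2 / 3, seed = 12)
  sp4 <- stratified_split(co, 2 / 3, seed = 13)
  expect_true(!identical(sp$a$id, sp3$a$id) || !identical(sp$a$id, sp4$a$id))
  noev <- make_cohort(time = 1:10, event = rep(0, 10))
  expect_warning(spn <- stratified_split(noev, 0.5, seed = 1), "no events")
  expect_equal(nrow(spn$a), 5)
})
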