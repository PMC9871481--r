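test_that("concordance index handles the perfect, constant and random cases", {
  tm <- c(10, 20, 30, 40)
  expect_equal(concordance_index(-tm, tm, rep(1, 4)), 1)   # anti-ranks time
  expect_equal(concordance_index(rep(2, 4), tm, rep(1, 4)), 0.5)
  expect_error(concordance_index(1, 5, 0), "comparable")

  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    b <- random_batch(n)
    expect_identical(concordance_index(b$risk, b$time, b$event),
                     brute_cindex(b$risk, b$time, b$event))
  }
})

test_that("concordance is invariant under strictly increasing transforms", {
  set.seed(8)
  b <- random_batch(25)
  c0 <- concordance_index(b$risk, b$time, b$event)
  expect_equal(concordance_index(exp(b$risk), b$time, b$event), c0)
  expect_equal(concordance_index(3 * b$risk - 10, b$time, b$event), c0)
})

test_that("concordance agrees with the survival package on censored data", {
  set.seed(9)
  b <- random_batch(60, tie_prob = 0)
  cc <- survival::concordance(survival::Surv(b$time, b$event) ~ b$risk,
                              reverse = TRUE)
  expect_equal(concordance_index(b$risk, b$time, b$event),
               unname(cc$concordance))
})

test_that("risk-class accuracy matches a hand count on a toy cohort", {
  pi_train <- c(-2, -1, 0, 1, 2, 3)   # terciles at 1/3 and 2/3 quantiles
  sch <- risk_class_scheme(pi_train)
  # six cases: survival class high(<300)/mid(300-450 incl)/low(>450)
  pi <- c(3, 2.5, 0.2, 0.1, -1.8, -1.9)
  tm <- c(100, 200, 300, 450, 500, 900)
  # hand: pi classes = H,H,M,M,L,L; day classes = H,H,M,M,L,L
  expect_equal(risk_class_accuracy(pi, tm, sch), 1)
  tm2 <- c(100, 500, 300, 450, 500, 100)   # two mismatches
  expect_equal(risk_class_accuracy(pi, tm2, sch), 4 / 6)
  # a PI strictly decreasing in time with aligned cuts scores 1
  tm3 <- sort(tm)
  expect_equal(risk_class_accuracy(rev(sort(pi)), tm3, sch), 1)
})

test_that("Kaplan-Meier matches the hand product-limit and the no-censoring ECDF", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  km0 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  set.seed(10)
  tm <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(tm, rep(1, 30))
  ec <- 1 - ecdf(tm)(km2$time)
  expect_equal(km2$surv, ec)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("log-rank test is symmetric and null on identical groups", {
  set.seed(11)
  tA <- rexp(20, 0.01); eA <- rbinom(20, 1, 0.8)
  tB <- rexp(25, 0.02); eB <- rbinom(25, 1, 0.8)
  r1 <- log_rank_test(c(tA, tB), c(eA, eB), rep(c("a", "b"), c(20, 25)))
  r2 <- log_rank_test(c(tB, tA), c(eB, eA), rep(c("b", "a"), c(25, 20)))
  expect_equal(r1$chi2, r2$chi2)
  rid <- log_rank_test(c(tA, tA), c(eA, eA), rep(c("x", "y"), each = 20))
  expect_lt(rid$chi2, 1e-10)
  expect_gt(rid$p, 0.999)
})

test_that("median-PI stratification separates a strongly prognostic score", {
  set.seed(12)
  eta <- rnorm(120, sd = 1.5)
  st <- draw_survival_times(eta, 1 / 400, 1 / 1200)
  res <- km_by_median_pi(eta, st$time, st$event)
  expect_lt(res$log_rank$p, 0.01)
  expect_named(res$km, c("low", "high"))
})

test_that("Cox fit recovers a null effect and a unit log-hazard ratio", {
  # duplicated cohort with identical survival in both groups: beta ~ 0
  tm <- rep(c(5, 10, 20, 40, 80, 160), 2)
  ev <- rep(1, 12)
  grp <- rep(c(0, 1), each = 6)
  cf0 <- fit_cox(data.frame(g = grp), tm, ev)
  expect_lt(abs(unname(cf0$beta[1])), 1e-6)
  expect_gte(cf0$loglik[2], cf0$loglik[1])   # optimum at least the null

  set.seed(13)
  x <- rnorm(1000)
  st <- draw_survival_times(1.0 * x, 1 / 400, 1 / 1200)
  cf <- fit_cox(data.frame(x = x), st$time, st$event)
  expect_lt(abs(unname(cf$beta[1]) - 1), 3 * cf$se[1])
})

test_that("Cox fit validates its preconditions", {
  tm <- c(5, 10, 20, 40); ev <- c(1, 1, 0, 0)
  expect_error(fit_cox(data.frame(a = rep(1, 4)), tm, ev), "constant")
  x <- rnorm(4)
  expect_error(fit_cox(data.frame(a = x, b = 2 * x, c = x + 1), tm,
                       c(1, 1, 1, 1)), "collinear")
})

test_that("Schoenfeld residuals sum to zero at the optimum and match survival", {
  set.seed(14)
  x <- rnorm(80)
  st <- draw_survival_times(0.8 * x, 1 / 300, 1 / 900)
  sc <- schoenfeld_test(x, st$time, st$event)
  expect_lt(abs(sum(sc$residuals$residual)), 1e-6)
  fit <- survival::coxph(survival::Surv(st$time, st$event) ~ x,
                         ties = "breslow")
  ref <- residuals(fit, type = "schoenfeld")
  expect_equal(unname(sc$residuals$residual), unname(ref), tolerance = 1e-6)
  expect_true(sc$p_value >= 0 && sc$p_value <= 1)
  expect_identical(nrow(sc$residuals), as.integer(sum(st$event)))
})

test_that("Schoenfeld diagnostic detects a sign-flipping covariate effect", {
  set.seed(15)
  hits <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    x <- rnorm(300)
    st <- draw_tv_survival_times(1.2 * x, 1 / 300, t_flip = 200)
    sc <- schoenfeld_test(x, st$time, st$event)
    if (sc$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("Schoenfeld diagnostic requires enough events", {
  expect_error(schoenfeld_test(rnorm(6), c(1, 2, 3, 4, 5, 6),
                               c(1, 0, 0, 0, 0, 0)), "5 events")
})

test_that("time-dependent ROC: perfect and null markers behave as expected", {
  set.seed(16)
  tm <- sort(runif(300, 1, 1000))
  ev <- rep(1, 300)
  td <- time_dependent_roc(-tm, tm, ev)
  expect_equal(td$auc, rep(1, 4))

  pi0 <- rnorm(2000)
  tm0 <- rexp(2000, 1 / 400)
  td0 <- time_dependent_roc(pi0, tm0, rep(1, 2000))
  expect_true(all(abs(td0$auc - 0.5) <= 0.03))
})

test_that("without censoring the IPCW AUC equals the plain empirical AUC", {
  set.seed(17)
  n <- 150
  pi <- rnorm(n)
  st <- draw_survival_times(0.7 * pi, 1 / 400, censor_rate = 0)
  for (tau in c(200, 400)) {
    td <- time_dependent_roc(pi, st$time, st$event, horizons = tau)
    expect_equal(td$auc, brute_auc(pi, st$time <= tau))
  }
})

test_that("a horizon with no cases or controls is flagged, others returned", {
  tm <- c(100, 150, 900, 950)
  ev <- c(1, 1, 0, 0)
  td <- time_dependent_roc(c(4, 3, 2, 1), tm, ev, horizons = c(50, 200))
  expect_identical(td$flag, c("undefined", "ok"))
  expect_true(is.na(td$auc[1]))
  expect_false(is.na(td$auc[2]))
})
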