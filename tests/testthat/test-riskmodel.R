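test_that("endpoint derivation follows the event definitions", {
  fu <- data.frame(patient_id = c("a", "b", "c"),
                   relapse_time = c(730, NA, NA),
                   death_time = c(1095, NA, 365),
                   followup_time = c(1095, 1825, 365))
  e <- derive_endpoints(fu)
  expect_equal(e$rfs_time, c(730, 1825, 365))
  expect_equal(e$rfs_event, c(1, 0, 1))
  expect_equal(e$os_time, c(1095, 1825, 365))
  expect_equal(e$os_event, c(1, 0, 1))
  expect_equal(e$efs_time, e$rfs_time)

  bad <- data.frame(patient_id = "x", relapse_time = 100, death_time = 50,
                    followup_time = 100)
  expect_error(derive_endpoints(bad), "death before relapse")
})

test_that("log-rank matches a hand-computed toy example", {
  # 6 subjects, all events, two groups; O-E and V enumerated by hand below
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- c(0, 1, 0, 1, 0, 1)
  # walk the risk sets
  O <- 0; E <- 0; V <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == t)
    O <- O + sum(time == t & group == 1)
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_hand <- (O - E)^2 / V
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, chisq_hand, tolerance = 1e-12)

  # identical groups -> statistic 0, p = 1
  t2 <- rep(time, 2); e2 <- rep(event, 2); g2 <- rep(0:1, each = 6)
  lr2 <- logrank_test(t2, e2, g2)
  expect_lt(lr2$chisq, 1e-12)
  expect_equal(lr2$p, 1)
})

test_that("permuted labels give a uniform log-rank null", {
  set.seed(15)
  n <- 40
  time <- rexp(n, 0.1); event <- rep(1, n)
  g <- rep(0:1, each = n / 2)
  ps <- replicate(1000, logrank_test(time, event, sample(g))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("univariate screening retains at the 0.20 default", {
  expect_equal(formals(univariate_screen)$threshold, 0.20)
  set.seed(16)
  n <- 500
  x_sig <- rnorm(n); x_null <- rnorm(n)
  time <- rexp(n, 0.1 * exp(1 * x_sig))
  scr <- univariate_screen(time, rep(1, n),
                           cbind(sig = x_sig, null = x_null))
  expect_true(scr$retained[scr$covariate == "sig"])
  expect_error(univariate_screen(time, rep(1, n), cbind(a = x_sig),
                                 threshold = 0), "\\(0, 1\\]")
  expect_warning(univariate_screen(time, rep(1, n),
                                   cbind(a = x_sig, const = rep(1, n))),
                 "constant")
})

test_that("null covariates are screened in at about the nominal rate", {
  set.seed(17)
  kept <- replicate(100, {
    n <- 200
    x <- rnorm(n)
    time <- rexp(n, 0.1)
    univariate_screen(time, rep(1, n), cbind(x = x))$retained
  })
  rate <- mean(kept)
  expect_lt(abs(rate - 0.20), 3 * sqrt(0.2 * 0.8 / 100) + 0.02)
})

test_that("penalized Cox shrinks fully at large lambda and matches Newton at 0", {
  set.seed(18)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  time <- rexp(n, 0.1 * exp(X %*% c(0.8, -0.5, 0)))
  event <- rep(1, n)

  m_inf <- fit_penalized_cox(time, event, X, fixed_lambda = 10)
  expect_true(all(m_inf$coef == 0))

  m0 <- fit_penalized_cox(time, event, X, fixed_lambda = 0)
  oracle <- newton_cox(time, event, X)
  expect_lt(max(abs(m0$coef - oracle)), 1e-3)
})

test_that("lasso path is monotone in the active-set size", {
  set.seed(19)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  time <- rexp(n, 0.1 * exp(X[, 1] * 0.9 - X[, 2] * 0.6))
  fit <- glmnet::glmnet(X, survival::Surv(time, rep(1, n)), family = "cox",
                        alpha = 1)
  nz <- fit$df
  lam <- fit$lambda   # decreasing
  # active set never shrinks as lambda decreases along the default path
  expect_true(all(diff(nz) >= 0 | diff(lam) > 0))
  expect_equal(nz[1], 0)
})

test_that("risk stratification splits at the median with ties to low", {
  model <- structure(list(coef = c(x = 1), covariates = "x",
                          cutpoint = 0.5, lambda = 0.1, alpha = 1,
                          nfolds = 10),
                     class = "risk_model")
  X <- cbind(x = c(0.1, 0.2, 0.8, 0.9))
  g <- risk_stratify(model, X)
  expect_equal(as.character(g), c("low", "low", "high", "high"))

  # even n, distinct in-sample scores -> exactly n/2 per group
  set.seed(20)
  n <- 100
  X2 <- cbind(a = rnorm(n), b = rnorm(n))
  time <- rexp(n, 0.1 * exp(X2[, 1]))
  m <- fit_penalized_cox(time, rep(1, n), X2, fixed_lambda = 0.01)
  g2 <- risk_stratify(m, X2)
  expect_equal(unname(table(g2)["high"]), n / 2)

  # monotone transform of the score leaves the grouping unchanged
  m3 <- m; m3$coef <- 3 * m$coef; m3$cutpoint <- 3 * m$cutpoint
  expect_equal(as.character(risk_stratify(m3, X2)), as.character(g2))

  # degenerate equal scores -> all low with warning
  m4 <- m; m4$coef[] <- 0; m4$cutpoint <- 0
  expect_warning(g4 <- risk_stratify(m4, X2), "all risk scores equal")
  expect_true(all(g4 == "low"))

  # missing covariates excluded with warning
  X5 <- X2; X5[1, 1] <- NA
  expect_warning(g5 <- risk_stratify(m, X5), "excluded")
  expect_true(is.na(g5[1]))
})

test_that("Cox HR estimation is calibrated on toy and planted data", {
  # self-comparison gives HR 1
  d <- planted_hr_data(60, hr = 2, seed = 21)
  hr1 <- cox_hr(rep(d$time, 2), rep(d$event, 2), rep(0:1, each = 60))
  expect_equal(hr1$hr, 1, tolerance = 1e-8)

  # 4-subject toy fit matches grid-search partial-likelihood maximization
  time <- c(2, 5, 7, 11); event <- rep(1, 4); grp <- c(1, 0, 1, 0)
  fit <- cox_hr(time, event, grp)
  grid <- seq(-4, 4, by = 1e-4)
  pl <- vapply(grid, function(b) {
    s <- 0
    for (i in 1:4) {
      rs <- which(time >= time[i])
      s <- s + b * grp[i] - log(sum(exp(b * grp[rs])))
    }
    s
  }, 0)
  expect_lt(abs(fit$coef - grid[which.max(pl)]), 1e-4)

  # planted HR = 4, n = 2000, 20% censoring
  d4 <- planted_hr_data(2000, hr = 4, censor_rate = 0.2, seed = 22)
  fit4 <- cox_hr(d4$time, d4$event, d4$group)
  expect_gt(fit4$hr, 3.4); expect_lt(fit4$hr, 4.7)

  # KM curves: non-increasing and, with no censoring, the empirical survivor
  d0 <- planted_hr_data(100, hr = 1, seed = 23)
  km <- cox_hr(d0$time, d0$event, d0$group)$km
  expect_true(all(diff(km$surv[1:km$strata[1]]) <= 1e-12))
  g0 <- d0$time[d0$group == 0]
  t5 <- sort(g0)[5]
  s_emp <- mean(g0 > t5)
  s_km <- summary(km[1], times = t5)$surv
  expect_equal(s_km, s_emp, tolerance = 1e-12)
})

test_that("Schoenfeld PH check is calibrated and counts residuals", {
  set.seed(24)
  # residual count equals event count on a toy fit
  n <- 40
  x <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.5 * x))
  event <- rbinom(n, 1, 0.8)
  fit <- survival::coxph(survival::Surv(time, event) ~ x)
  expect_equal(length(residuals(fit, type = "schoenfeld")), sum(event))
  zph <- check_ph(fit)
  expect_true("x" %in% rownames(zph$table))

  # under exact PH the rejection rate is near nominal
  rej <- replicate(100, {
    x <- rnorm(100)
    t0 <- rexp(100, 0.1 * exp(0.7 * x))
    f <- survival::coxph(survival::Surv(t0, rep(1, 100)) ~ x)
    check_ph(f)$table["x", "p"] < 0.05
  })
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 100) + 0.02)

  # planted time-varying effect is detected
  hits <- replicate(20, {
    n <- 500
    x <- rnorm(n)
    # effect reverses sign mid-follow-up
    t1 <- rexp(n, 0.3 * exp(1.2 * x))
    flip <- t1 > stats::median(t1)
    t1[flip] <- stats::median(t1) + rexp(sum(flip), 0.3 * exp(-1.2 * x[flip]))
    f <- survival::coxph(survival::Surv(t1, rep(1, n)) ~ x)
    check_ph(f)$table["x", "p"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Gray's test reduces to 1 - KM without competing events", {
  set.seed(25)
  n <- 120
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.7)
  group <- rep(0:1, each = n / 2)
  gt <- grays_test(time, ifelse(event == 1, 1, 0), group, cause = 1)
  km <- survival::survfit(survival::Surv(time, event) ~ group)
  # compare CIF of group "0", cause 1 against 1 - KM at the event times
  km0 <- km[1]
  sf <- stats::stepfun(km0$time, c(1, km0$surv))
  tq <- sort(time[group == 0 & event == 1])
  cif_at <- cmprsk::timepoints(gt$cuminc, tq)$est["0 1", ]
  expect_lt(max(abs(cif_at - (1 - sf(tq)))), 1e-12)
})

test_that("Gray's test handles identical groups and rejects empty causes", {
  time <- rep(c(1, 3, 5, 7), 2)
  status <- rep(c(1L, 2L, 1L, 0L), 2)
  group <- rep(0:1, each = 4)
  gt <- grays_test(time, status, group, cause = 1)
  expect_lt(gt$statistic, 1e-12)
  expect_gt(gt$p, 0.999)
  expect_error(grays_test(time, rep(0L, 8), group), "no events")
  # factor status coding works
  st <- factor(c("relapse", "death", "relapse", "censored"),
               levels = c("censored", "relapse", "death"))
  gt2 <- grays_test(c(1, 3, 5, 7, 1, 3, 5, 7),
                    rep(as.character(st), 2), group, cause = "relapse")
  expect_equal(gt2$p, gt$p)
})

test_that("MRD stratification uses the strict 1e-4 negativity rule", {
  expect_equal(as.character(mrd_stratify(c(5e-5, 1e-4, 0, 2e-3))),
               c("negative", "positive", "negative", "positive"))
  expect_error(mrd_stratify(-1e-5), ">= 0")
})

test_that("marker dichotomization applies cutoff and median rules", {
  expect_equal(as.character(dichotomize_marker(c(0.2, 0.1, 0.05),
                                               "cutoff", cutoff = 0.1)),
               c("high", "low", "low"))
  expect_equal(as.character(dichotomize_marker(1:4, "median")),
               c("low", "low", "high", "high"))
  expect_error(dichotomize_marker(c(NA_real_, NA_real_), "median"),
               "missing")
})

test_that("bootstrap AUROC comparison behaves at the extremes", {
  set.seed(26)
  y <- rep(c(TRUE, FALSE), each = 20)
  s <- rnorm(40, ifelse(y, 2, 0))
  same <- compare_auroc_bootstrap(s, s, y, iterations = 200, seed = 1)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_equal(same$iterations, 200)
  expect_equal(formals(compare_auroc_bootstrap)$iterations, 4000L)

  good <- s
  noise <- rnorm(40)
  cmp <- compare_auroc_bootstrap(good, noise, y, iterations = 500, seed = 2)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$auc_a, cmp$auc_b)
})

test_that("IPCW AUC is 1 for a perfect score and ~0.5 for noise", {
  expect_equal(eval(formals(time_dependent_roc)$grid_years), c(2, 4, 6, 8))
  set.seed(27)
  n <- 400
  time <- rexp(n, 1 / (4 * 365.25))
  event <- rep(1, n)
  # perfect score: reverse order of event times
  roc <- time_dependent_roc(-time, time, event)
  expect_true(all(roc$auc[!is.na(roc$auc)] == 1))
  expect_equal(roc$c_statistic, 1)

  # independent score: AUC(t) within the null band, averaged over draws to
  # tame the Monte Carlo error of the sparse late grid points
  null_auc <- replicate(10, {
    n <- 1000
    time <- rexp(n, 1 / (4 * 365.25))
    time_dependent_roc(rnorm(n), time, rep(1, n))$auc
  })
  avg <- rowMeans(null_auc, na.rm = TRUE)
  expect_true(all(avg > 0.45 & avg < 0.55))
  n <- 1000
  time <- rexp(n, 1 / (4 * 365.25))
  noise <- rnorm(n)

  # C-statistic is rank-invariant
  sc <- rexp(n)
  c1 <- time_dependent_roc(sc, time, rep(1, n))$c_statistic
  c2 <- time_dependent_roc(log(sc), time, rep(1, n))$c_statistic
  expect_equal(c1, c2)

  # grid points beyond follow-up are missing, one warning each
  w <- capture_warnings(
    rocw <- time_dependent_roc(noise, pmin(time, 3 * 365.25), rep(1, n)))
  expect_length(w, 3)
  expect_match(w, "beyond the last follow-up", all = TRUE)
  expect_true(all(is.na(rocw$auc[2:4])))
})

test_that("combined risk + MRD model keeps independent effects", {
  set.seed(28)
  n <- 400
  rg <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  ms <- factor(sample(c("negative", "positive"), n, TRUE),
               levels = c("negative", "positive"))
  lp <- 0.9 * (rg == "high") + 0.9 * (ms == "positive")
  time <- rexp(n, 0.05 * exp(lp))
  cm <- combine_models(rg, ms, time, rep(1, n), grid_years = 2,
                       days_per_year = 1)
  expect_lt(cm$wald_p["risk_group"], 0.05)
  expect_lt(cm$wald_p["mrd_status"], 0.05)
  expect_warning(combine_models(rg, factor(ifelse(rg == "high", "positive",
                                                  "negative")),
                                time, rep(1, n), grid_years = 2,
                                days_per_year = 1),
                 "collinear")
})

test_that("planted-signal covariates are selected by the penalized model", {
  set.seed(29)
  ok_runs <- 0
  for (r in 1:10) {
    co <- generate_cohort(cohort_spec(n = 500, censor_rate = 0.2,
                                      seed = 100 + r))
    e <- derive_endpoints(co$survival)
    X <- as.matrix(co$covariates[, -1])
    m <- fit_penalized_cox(e$rfs_time, e$rfs_event, X, seed = r)
    sel <- m$coef
    good <- sel["age"] > 0 && sel["platelet"] < 0 && sel["cd4_pd1_tim3"] > 0
    ok_runs <- ok_runs + good
  }
  expect_gte(ok_runs / 10, 0.8)
})
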