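# Survival layer: endpoint derivation, univariate screening, L1-penalized
# Cox risk model with median stratification, KM/log-rank/HR, proportional-
# hazards diagnostics, Gray's competing-risks test, MRD stratification, and
# model comparison by bootstrap AUROC and IPCW time-dependent ROC.

#' Derive OS / RFS / EFS endpoints from raw follow-up records
#'
#' OS events are deaths; RFS and EFS events are the first of relapse or
#' death; patients without the event are censored at the last day of
#' follow-up.
#'
#' @param followup data.frame with `patient_id`, `relapse_time`,
#'   `death_time` (NA when the event did not occur) and `followup_time`
#'   (last follow-up), all in days from diagnosis.
#' @return data.frame with `patient_id` and, per endpoint (`os`, `rfs`,
#'   `efs`), `<endpoint>_time` and `<endpoint>_event` (1 = event,
#'   0 = censored).
#' @export
derive_endpoints <- function(followup) {
  need <- c("patient_id", "relapse_time", "death_time", "followup_time")
  miss <- setdiff(need, names(followup))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rel <- followup$relapse_time; dea <- followup$death_time
  fup <- followup$followup_time
  if (any(c(rel, dea, fup) < 0, na.rm = TRUE)) stop("negative times")
  bad <- !is.na(rel) & !is.na(dea) & dea < rel
  if (any(bad))
    stop("death before relapse for patient(s): ",
         paste(followup$patient_id[bad], collapse = ", "))

  os_event <- as.integer(!is.na(dea))
  os_time <- ifelse(os_event == 1, dea, fup)
  first <- pmin(rel, dea, na.rm = TRUE)
  rfs_event <- as.integer(!is.na(rel) | !is.na(dea))
  rfs_time <- ifelse(rfs_event == 1, first, fup)
  data.frame(patient_id = followup$patient_id,
             os_time = os_time, os_event = os_event,
             rfs_time = rfs_time, rfs_event = rfs_event,
             efs_time = rfs_time, efs_event = rfs_event,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' @param time,event follow-up times and event indicators (1 = event).
#' @param group two-level grouping.
#' @return list with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) != 2)
    stop("two non-empty groups are required")
  if (sum(event) < 1) stop("at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = p)
}

#' Univariate Cox screen of candidate covariates
#'
#' Each covariate is tested in a univariate Cox proportional-hazards model
#' (score/log-rank test); covariates with p below the threshold (default
#' 0.20) are retained. Constant covariates are skipped with a warning.
#'
#' @param time,event endpoint vectors.
#' @param X covariate matrix/data.frame (columns = candidates).
#' @param threshold retention p-value threshold in (0, 1]; default 0.20.
#' @return data.frame (`covariate`, `p`, `retained`) with attribute
#'   `retained` holding the retained names.
#' @export
univariate_screen <- function(time, event, X, threshold = 0.20) {
  if (!is_num1(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  X <- as.matrix(X)
  res <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning("covariate '", nm, "' is constant; skipped")
      return(NULL)
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ v)
    p <- summary(fit)$sctest["pvalue"]
    data.frame(covariate = nm, p = unname(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$retained <- res$p < threshold
  attr(res, "retained") <- res$covariate[res$retained]
  res
}

#' Fit an L1-penalized Cox risk model with cross-validated lambda
#'
#' Elastic-net Cox regression with the mixing parameter fixed at pure L1
#' (`alpha = 1`, configurable for sensitivity runs); the penalty weight
#' lambda is chosen to minimize the mean K-fold cross-validated partial-
#' likelihood deviance. Covariates are standardized internally (coefficients
#' are returned on the input scale). Fold assignment is seed-controlled and
#' refolded (with a warning) if any training split lacks events. The
#' in-sample median of the linear predictor is stored as the stratification
#' cutpoint.
#'
#' @param time,event endpoint vectors (>= 2 events).
#' @param X covariate matrix (screened covariates).
#' @param nfolds CV fold count (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param alpha elastic-net mixing parameter; 1 = lasso (default).
#' @param fixed_lambda optional: skip cross-validation and return the fit at
#'   this penalty (0 gives the unpenalized partial-likelihood fit).
#' @return object of class `risk_model`: `coef` (named, incl. zeros),
#'   `lambda`, `nfolds`, `alpha`, `cutpoint`, `lp` (in-sample linear
#'   predictor), `covariates`, `seed`.
#' @export
fit_penalized_cox <- function(time, event, X, nfolds = 10L, seed = 1L,
                              alpha = 1, fixed_lambda = NULL) {
  X <- as.matrix(X)
  if (sum(event) < 2) stop("at least 2 events are required")
  y <- survival::Surv(time, event)

  if (!is.null(fixed_lambda)) {
    pre <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                          standardize = TRUE)
    path <- sort(unique(c(pre$lambda, fixed_lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                          lambda = path, standardize = TRUE, thresh = 1e-14,
                          maxit = 1e6)
    beta <- as.numeric(stats::coef(fit, s = fixed_lambda))
    lambda <- fixed_lambda
  } else {
    n <- length(time)
    set.seed(substream_seed(seed, "cvfolds"))
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    for (try in seq_len(100)) {
      ok <- all(vapply(seq_len(nfolds), function(k)
        sum(event[foldid != k]) >= 2 && sum(event[foldid == k]) >= 1, TRUE))
      if (ok) break
      warning("a CV fold lacked events; refolding")
      foldid <- sample(rep(seq_len(nfolds), length.out = n))
    }
    cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                            foldid = foldid, standardize = TRUE)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
    lambda <- cv$lambda.min
  }
  names(beta) <- colnames(X)
  lp <- drop(X %*% beta)
  structure(list(coef = beta, lambda = lambda, nfolds = nfolds,
                 alpha = alpha, cutpoint = stats::median(lp), lp = lp,
                 covariates = colnames(X), seed = seed),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("L1-penalized Cox risk model (alpha =", x$alpha, ")\n")
  cat("  lambda =", signif(x$lambda, 4), " (", x$nfolds, "-fold CV)\n", sep = "")
  nz <- x$coef[x$coef != 0]
  cat("  nonzero coefficients:", if (length(nz)) "" else " none", "\n")
  for (nm in names(nz)) cat(sprintf("    %-20s % .4f\n", nm, nz[[nm]]))
  cat("  median risk-score cutpoint:", signif(x$cutpoint, 4), "\n")
  invisible(x)
}

#' Stratify patients into high- and low-risk groups at the median risk score
#'
#' The model's linear predictor is computed per patient and split at the
#' model's stored (in-sample median) cutpoint; scores above the cutpoint are
#' high-risk, ties go to low-risk, so for an even in-sample cohort with
#' distinct scores the groups are equally sized. Patients with missing
#' covariates are excluded (NA) with a warning.
#'
#' @param model a [fit_penalized_cox()] `risk_model`.
#' @param X covariate matrix containing the model covariates.
#' @return factor with levels `low`, `high` (NA for excluded patients);
#'   attribute `lp` carries the linear predictor.
#' @export
risk_stratify <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$covariates, colnames(X))
  if (length(miss)) stop("covariate(s) missing from data: ",
                         paste(miss, collapse = ", "))
  Xm <- X[, model$covariates, drop = FALSE]
  bad <- rowSums(is.na(Xm)) > 0
  if (any(bad))
    warning(sum(bad), " patient(s) excluded for missing covariates")
  lp <- rep(NA_real_, nrow(Xm))
  lp[!bad] <- drop(Xm[!bad, , drop = FALSE] %*% model$coef)
  if (all(lp[!bad] == model$cutpoint, na.rm = TRUE) ||
      stats::sd(lp[!bad]) == 0) {
    warning("all risk scores equal; every patient assigned low-risk")
    g <- factor(ifelse(bad, NA, "low"), levels = c("low", "high"))
    attr(g, "lp") <- lp
    return(g)
  }
  g <- factor(ifelse(is.na(lp), NA,
                     ifelse(lp > model$cutpoint, "high", "low")),
              levels = c("low", "high"))
  attr(g, "lp") <- lp
  g
}

#' Cox hazard ratio, log-rank test and KM curves for a binary stratification
#'
#' @param time,event endpoint vectors.
#' @param group binary grouping (second level is the "high" group whose HR
#'   is reported against the first).
#' @return object of class `stratified_survival`: `hr`, `ci` (Wald 95%),
#'   `logrank_p`, `coef`, `fit` (coxph), `km` (survfit by group).
#' @export
cox_hr <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("binary grouping required")
  if (sum(event) < 1) stop("no events in either group")
  fit <- survival::coxph(survival::Surv(time, event) ~ group)
  s <- summary(fit)
  hr <- unname(s$conf.int[1, "exp(coef)"])
  ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
  lr <- logrank_test(time, event, group)
  structure(list(hr = hr, ci = ci, logrank_p = lr$p,
                 coef = unname(stats::coef(fit)), fit = fit,
                 km = survival::survfit(survival::Surv(time, event) ~ group)),
            class = "stratified_survival")
}

#' @export
print.stratified_survival <- function(x, ...) {
  cat(sprintf("HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.4g\n",
              x$hr, x$ci[1], x$ci[2], x$logrank_p))
  invisible(x)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals are regressed on Kaplan-Meier-scaled time;
#' a small p-value signals a time-varying effect.
#'
#' @param fit a fitted `coxph` model with >= 3 events.
#' @param transform time transform passed to [survival::cox.zph()]
#'   (default "km").
#' @return the `cox.zph` table (per-covariate chisq and p plus GLOBAL).
#' @export
check_ph <- function(fit, transform = "km") {
  if (fit$nevent < 3) stop("at least 3 events are required")
  survival::cox.zph(fit, transform = transform)
}

#' Gray's test and cumulative incidence functions under competing risks
#'
#' Aalen-Johansen cumulative incidence per group and cause, and Gray's
#' K-sample test of the subdistribution hazard for each cause.
#'
#' @param time follow-up times.
#' @param status event type: factor/character in
#'   {"censored", "relapse", "death"} or integer (0 = censored, 1, 2).
#' @param group grouping variable.
#' @param cause the tested cause (1 = relapse, 2 = death, or the label).
#' @return list: `cuminc` (the [cmprsk::cuminc()] object with per-group CIF
#'   curves), `statistic` and `p` for the tested cause, `tests` (all causes).
#' @export
grays_test <- function(time, status, group, cause = 1) {
  if (is.character(status) || is.factor(status)) {
    map <- c(censored = 0L, relapse = 1L, death = 2L)
    status <- map[as.character(status)]
    if (any(is.na(status))) stop("unknown event type in status")
  }
  if (is.character(cause)) cause <- c(relapse = 1L, death = 2L)[cause]
  if (sum(status == cause) < 1)
    stop("no events of the tested cause")
  ci <- cmprsk::cuminc(ftime = time, fstatus = status, group = group,
                       cencode = 0)
  tests <- ci$Tests
  row <- match(as.character(cause), rownames(tests))
  list(cuminc = ci,
       statistic = unname(tests[row, "stat"]),
       p = unname(tests[row, "pv"]),
       tests = tests)
}

#' Classify MRD status from the leukemic blast fraction
#'
#' MRD negativity is a blast fraction strictly below 1e-4 per healthy cells.
#'
#' @param blast_fraction numeric fraction(s) >= 0.
#' @param cutoff MRD negativity cutoff (default 1e-4).
#' @return factor with levels `negative`, `positive`.
#' @export
mrd_stratify <- function(blast_fraction, cutoff = 1e-4) {
  if (any(blast_fraction < 0, na.rm = TRUE))
    stop("blast fraction must be >= 0")
  factor(ifelse(blast_fraction < cutoff, "negative", "positive"),
         levels = c("negative", "positive"))
}

#' Dichotomize a continuous marker into low/high groups
#'
#' Fixed-cutoff rule: high iff value > cutoff (e.g. > 0.1% CD4+PD1+TIM3+
#' T cells). Cohort-median rule: high iff value > median. Ties go to low.
#'
#' @param values numeric marker values.
#' @param rule "cutoff" or "median".
#' @param cutoff the fixed cutoff (required for rule = "cutoff").
#' @return factor with levels `low`, `high` (NA preserved).
#' @export
dichotomize_marker <- function(values, rule = c("cutoff", "median"),
                               cutoff = NULL) {
  rule <- match.arg(rule)
  if (all(is.na(values))) stop("all marker values are missing")
  cut <- if (rule == "cutoff") {
    if (!is_num1(cutoff)) stop("a numeric cutoff is required")
    cutoff
  } else stats::median(values, na.rm = TRUE)
  factor(ifelse(is.na(values), NA, ifelse(values > cut, "high", "low")),
         levels = c("low", "high"))
}

#' Area under the ROC curve (rank estimator)
#'
#' Mann-Whitney estimator with ties counted as 1/2.
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param outcome logical or 0/1 outcome.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare two risk scores by paired bootstrap of the AUROC difference
#'
#' Patients are resampled with replacement (paired, preserving each
#' patient's scores and outcome); the two-sided p-value is derived from the
#' bootstrap distribution of the AUROC difference.
#'
#' @param score_a,score_b risk scores for the same patients.
#' @param outcome binary outcome.
#' @param iterations bootstrap iterations (default 4000).
#' @param seed integer seed.
#' @return list: `auc_a`, `auc_b`, `diff`, percentile `ci_diff`, `p`,
#'   `iterations`.
#' @export
compare_auroc_bootstrap <- function(score_a, score_b, outcome,
                                    iterations = 4000L, seed = 1L) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("both outcome classes must be present")
  n <- length(outcome)
  auc_a <- auroc(score_a, outcome)
  auc_b <- auroc(score_b, outcome)
  set.seed(substream_seed(seed, "auroc_boot"))
  diffs <- numeric(iterations)
  for (i in seq_len(iterations)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[idx])) == 2) break
    }
    diffs[i] <- auroc(score_a[idx], outcome[idx]) -
      auroc(score_b[idx], outcome[idx])
  }
  p <- if (all(diffs == 0)) 1 else
    min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b,
       ci_diff = unname(stats::quantile(diffs, c(0.025, 0.975))),
       p = p, iterations = iterations)
}

# Kaplan-Meier estimator of the censoring distribution G(t); returns a
# function of (t, left) where left = TRUE gives the left limit G(t-).
km_censoring <- function(time, event) {
  g <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- g$time[g$n.event > 0]
  ss <- g$surv[g$n.event > 0]
  function(t, left = FALSE) {
    if (!length(tt)) return(rep(1, length(t)))
    idx <- if (left) findInterval(t, tt, left.open = TRUE)
           else findInterval(t, tt)
    c(1, ss)[idx + 1L]
  }
}

#' IPCW time-dependent ROC and Harrell C-statistic
#'
#' Cumulative/dynamic AUC(t): cases are subjects with an event by t, weighted
#' by the inverse Kaplan-Meier censoring survival at their event time
#' (left limit); controls are subjects still at risk beyond t, weighted by
#' the inverse censoring survival at t. Grid points beyond the last follow-up
#' are missing with a warning. The C-statistic is Harrell's concordance over
#' usable pairs (rank-invariant in the score).
#'
#' @param score risk score (higher = higher risk).
#' @param time,event endpoint vectors.
#' @param grid_years evaluation times in years (default 2, 4, 6, 8).
#' @param days_per_year conversion for the grid (default 365.25; set 1 if
#'   `time` is already in years).
#' @return list: `grid_years`, `times`, `auc` (per grid point),
#'   `c_statistic`.
#' @export
time_dependent_roc <- function(score, time, event,
                               grid_years = c(2, 4, 6, 8),
                               days_per_year = 365.25) {
  ok <- !is.na(score) & !is.na(time) & !is.na(event)
  score <- score[ok]; time <- time[ok]; event <- event[ok]
  G <- km_censoring(time, event)
  times <- grid_years * days_per_year
  auc <- rep(NA_real_, length(times))
  for (k in seq_along(times)) {
    t0 <- times[k]
    if (t0 > max(time)) {
      warning("grid point ", grid_years[k],
              " y is beyond the last follow-up; missing")
      next
    }
    case <- time <= t0 & event == 1
    ctrl <- time > t0
    if (!any(case) || !any(ctrl)) next
    wc <- 1 / pmax(G(time[case], left = TRUE), 1e-12)
    wk <- rep(1 / pmax(G(t0), 1e-12), sum(ctrl))
    sc <- score[case]; sk <- score[ctrl]
    cmp <- outer(sc, sk, function(a, b) (a > b) + 0.5 * (a == b))
    auc[k] <- sum(wc * (cmp %*% wk)) / (sum(wc) * sum(wk))
  }
  cs <- survival::concordance(
    survival::Surv(time, event) ~ score, reverse = TRUE)$concordance
  list(grid_years = grid_years, times = times, auc = auc,
       c_statistic = unname(cs))
}

#' Joint Cox model of the immunoprofiling risk group and MRD status
#'
#' Two-covariate Cox fit with per-covariate Wald p-values; the combined
#' linear predictor is scored with the IPCW time-dependent ROC. Collinear
#' inputs (identical groupings) trigger a warning but the fit is still
#' returned.
#'
#' @param risk_group factor from [risk_stratify()].
#' @param mrd_status factor from [mrd_stratify()].
#' @param time,event endpoint vectors.
#' @param grid_years ROC evaluation grid (years).
#' @param days_per_year conversion for the grid.
#' @return list: `fit`, `wald_p` (named), `lp`, `roc`
#'   ([time_dependent_roc()] of the combined predictor).
#' @export
combine_models <- function(risk_group, mrd_status, time, event,
                           grid_years = c(2, 4, 6, 8),
                           days_per_year = 365.25) {
  ok <- !is.na(risk_group) & !is.na(mrd_status)
  if (mean(ok) < 0.8)
    stop("both inputs must be present for at least 80% of patients")
  rg <- droplevels(as.factor(risk_group[ok]))
  ms <- droplevels(as.factor(mrd_status[ok]))
  if (nlevels(rg) == 2 && nlevels(ms) == 2 &&
      (all((rg == levels(rg)[2]) == (ms == levels(ms)[2])) ||
       all((rg == levels(rg)[2]) == (ms == levels(ms)[1]))))
    warning("risk group and MRD status are collinear (identical groupings)")
  fit <- survival::coxph(survival::Surv(time[ok], event[ok]) ~ rg + ms)
  s <- summary(fit)$coefficients
  wald_p <- stats::setNames(s[, "Pr(>|z|)"], c("risk_group", "mrd_status"))
  lp <- stats::predict(fit, type = "lp")
  roc <- time_dependent_roc(lp, time[ok], event[ok],
                            grid_years = grid_years,
                            days_per_year = days_per_year)
  list(fit = fit, wald_p = wald_p, lp = lp, roc = roc)
}
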