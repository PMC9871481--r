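#' Harrell's concordance index
#'
#' Probability that a comparable pair is ranked concordantly by the risk
#' score: pairs `(i, j)` with `t_i < t_j` and `delta_i = 1` are comparable;
#' the pair is concordant when `pi_i > pi_j` (higher risk, shorter life) and
#' ties in the score count 1/2.
#'
#' @param pi Risk scores (higher = worse prognosis).
#' @param time Survival times.
#' @param event Event indicators.
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(pi, time, event) {
  n <- length(pi)
  stopifnot(length(time) == n, length(event) == n)
  comparable <- 0
  score <- 0
  for (i in which(event == 1)) {
    ok <- time > time[i]
    m <- sum(ok)
    if (!m) next
    comparable <- comparable + m
    score <- score + sum(pi[i] > pi[ok]) + 0.5 * sum(pi[i] == pi[ok])
  }
  if (comparable == 0)
    stop("no comparable pairs (need at least one event preceding another ",
         "case's follow-up)", call. = FALSE)
  score / comparable
}

#' Three-class risk scheme
#'
#' Survival-day classes use the 300/450-day cuts (high risk < 300 days,
#' mid risk 300-450 inclusive, low risk > 450); prognostic-index classes cut
#' the PI at its training-set terciles, the top third being high risk.
#'
#' @param pi_train Training-set prognostic indices (the only data the cuts
#'   may see).
#' @param day_cuts Increasing day thresholds.
#' @return A `coxdae_risk_scheme` with `day_cuts` and `pi_cuts`.
#' @export
risk_class_scheme <- function(pi_train, day_cuts = c(300, 450)) {
  stopifnot(length(day_cuts) == 2L, diff(day_cuts) > 0)
  pc <- quantile(pi_train, c(1 / 3, 2 / 3), names = FALSE)
  structure(list(day_cuts = day_cuts, pi_cuts = pc),
            class = "coxdae_risk_scheme")
}

day_class <- function(time, day_cuts) {
  ifelse(time < day_cuts[1L], 3L, ifelse(time <= day_cuts[2L], 2L, 1L))
}

pi_class <- function(pi, pi_cuts) {
  ifelse(pi > pi_cuts[2L], 3L, ifelse(pi > pi_cuts[1L], 2L, 1L))
}

#' Three-class risk accuracy
#'
#' Fraction of cases whose PI tercile class (high PI = high risk) matches
#' their survival-day class under the scheme's 300/450-day cuts.
#'
#' @param pi Prognostic indices of the evaluated set.
#' @param time Survival times (days).
#' @param scheme A [risk_class_scheme()] fitted on the training set.
#' @return Accuracy in \[0, 1\].
#' @export
risk_class_accuracy <- function(pi, time, scheme) {
  stopifnot(inherits(scheme, "coxdae_risk_scheme"),
            length(pi) == length(time))
  mean(pi_class(pi, scheme$pi_cuts) == day_class(time, scheme$day_cuts))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Survival times.
#' @param event Event indicators.
#' @return A `coxdae_km`: data frame with `time`, `n_risk`, `n_event`,
#'   `surv` (non-increasing, within \[0, 1\]).
#' @export
km_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv),
            class = c("coxdae_km", "data.frame"))
}

#' Two-sample log-rank test
#'
#' @param time,event Pooled survival data.
#' @param group Two-level group label (e.g. high/low PI at the median split).
#' @return List with `chi2`, `df` and `p`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test needs exactly two nonempty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- sd$chisq
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Median-PI risk-group stratification with Kaplan-Meier and log-rank
#'
#' Splits the set at its median PI into high- and low-risk groups and
#' compares their survival.
#'
#' @param pi Prognostic indices.
#' @param time,event Survival data.
#' @return List with `group` (factor), the two `coxdae_km` curves and the
#'   log-rank result.
#' @export
km_by_median_pi <- function(pi, time, event) {
  grp <- factor(ifelse(pi > median(pi), "high", "low"),
                levels = c("low", "high"))
  if (nlevels(droplevels(grp)) != 2L)
    stop("median split produced a single group (constant PI?)",
         call. = FALSE)
  list(group = grp,
       km = lapply(split(seq_along(pi), grp), function(i)
         km_estimate(time[i], event[i])),
       log_rank = log_rank_test(time, event, grp))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood (Newton-type iteration via the
#' survival package, convergence tolerance 1e-12, at most 100 iterations)
#' and returns the Breslow baseline cumulative hazard.
#'
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @param time,event Survival data.
#' @return A `coxdae_cox`: list with `beta`, `se`, `baseline` (data frame
#'   `time`, `cumhaz`), `loglik`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(covariates, time, event) {
  x <- as.data.frame(covariates)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("x", seq_along(x))
  mm <- model.matrix(~ ., data = as.data.frame(lapply(x, function(col) {
    if (is.character(col)) factor(col) else col
  })))[, -1, drop = FALSE]
  consts <- apply(mm, 2L, function(col) length(unique(col)) == 1L)
  if (any(consts))
    stop("constant covariate(s): ", paste(colnames(mm)[consts],
                                          collapse = ", "), call. = FALSE)
  if (sum(event) < ncol(mm))
    stop("fewer events (", sum(event), ") than covariates (", ncol(mm), ")",
         call. = FALSE)
  qr_mm <- qr(cbind(1, scale(mm, scale = FALSE)))
  if (qr_mm$rank < ncol(mm) + 1L)
    stop("collinear covariates: ",
         paste(colnames(mm)[qr_mm$pivot[seq(qr_mm$rank + 1L,
                                            ncol(mm) + 1L)] - 1L],
               collapse = ", "), call. = FALSE)
  df <- data.frame(mm, check.names = TRUE)
  covnames <- setdiff(names(df), c(".time", ".event"))
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covnames), collapse = " + ")))
  fit <- survival::coxph(
    fml, data = df, ties = "breslow",
    control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-13,
                                      iter.max = 100))
  if (any(is.na(coef(fit))))
    stop("Cox fit failed (non-estimable coefficient); check for separation",
         call. = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(beta = coef(fit),
                 se = sqrt(diag(fit$var)),
                 baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 loglik = fit$loglik, fit = fit, x = mm),
            class = "coxdae_cox")
}

#' Schoenfeld residual diagnostic of proportional hazards
#'
#' Fits a univariate Cox model on the prognostic index, computes the
#' Schoenfeld residual at each event time
#' `r_i = pi_i - sum_{j in R(t_i)} pi_j w_j / sum_{j in R(t_i)} w_j` with
#' `w_j = exp(beta * pi_j)`, smooths the residuals against time with Lowess,
#' and tests the Pearson correlation between the residuals and the rank of
#' the event time. A flat smooth and a non-significant correlation indicate
#' that the PI's effect does not drift with time (proportional hazards).
#'
#' @param pi Prognostic indices.
#' @param time,event Survival data (at least 5 events).
#' @param span Lowess span (default 2/3, 3 robustifying iterations).
#' @return A `coxdae_schoenfeld`: list with `beta`, `residuals` (data frame
#'   `time`, `residual`), `lowess` (smoothed curve), `cor`, `p_value`.
#' @export
schoenfeld_test <- function(pi, time, event, span = 2 / 3) {
  stopifnot(length(pi) == length(time), length(time) == length(event))
  if (sum(event) < 5)
    stop("need at least 5 events for the Schoenfeld diagnostic",
         call. = FALSE)
  cf <- fit_cox(data.frame(pi = pi), time, event)
  beta <- unname(cf$beta[1L])
  w <- exp(beta * pi)
  ev <- which(event == 1)
  ev <- ev[order(time[ev])]
  res <- vapply(ev, function(i) {
    rs <- time >= time[i]
    pi[i] - sum(pi[rs] * w[rs]) / sum(w[rs])
  }, 0)
  tev <- time[ev]
  lo <- lowess(tev, res, f = span, iter = 3L)
  ct <- suppressWarnings(cor.test(res, rank(tev), method = "pearson"))
  structure(list(beta = beta,
                 residuals = data.frame(time = tev, residual = res),
                 lowess = data.frame(time = lo$x, smooth = lo$y),
                 cor = unname(ct$estimate), p_value = ct$p.value),
            class = "coxdae_schoenfeld")
}

#' @export
print.coxdae_schoenfeld <- function(x, ...) {
  cat("<coxdae_schoenfeld> beta =", signif(x$beta, 4),
      "| cor(residual, time rank) =", signif(x$cor, 3),
      "| p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

# Kaplan-Meier estimate of the censoring distribution G(t), returned as a
# step function; eps shifts evaluate G at t- (left limit)
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- c(1, sf$surv)
    idx <- findInterval(t, sf$time + 1e-12) + 1L
    s[idx]
  }
}

#' Time-dependent ROC (cumulative/dynamic, IPCW)
#'
#' For each horizon `tau`, cases are subjects with an observed event by
#' `tau` and controls are subjects still under observation beyond `tau`;
#' censoring is handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution (cases weighted
#' `1/G(t_i-)`, controls `1/G(tau)`). With no censoring the weights are all
#' 1 and the AUC reduces to the empirical AUC of the dichotomized outcome.
#'
#' @param pi Prognostic indices (higher = earlier death expected).
#' @param time,event Survival data.
#' @param horizons Evaluation days (default 200-day stages up to 800).
#' @return A `coxdae_tdroc`: data frame `horizon`, `auc`, `n_cases`,
#'   `n_controls`, `flag`, plus a `curves` attribute with
#'   sensitivity/specificity grids per horizon.
#' @export
time_dependent_roc <- function(pi, time, event,
                               horizons = c(200, 400, 600, 800)) {
  stopifnot(length(pi) == length(time), length(time) == length(event))
  G <- censoring_km(time, event)
  curves <- list()
  rows <- lapply(horizons, function(tau) {
    case <- which(time <= tau & event == 1)
    ctrl <- which(time > tau)
    if (!length(case) || !length(ctrl)) {
      return(data.frame(horizon = tau, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl),
                        flag = "undefined"))
    }
    wc <- 1 / pmax(G(time[case] - 1e-9), 1e-12)
    wk <- rep(1 / pmax(G(tau), 1e-12), length(ctrl))
    cmp <- outer(pi[case], pi[ctrl], `>`) + 0.5 * outer(pi[case], pi[ctrl],
                                                        `==`)
    wgt <- outer(wc, wk)
    auc <- sum(cmp * wgt) / sum(wgt)
    thr <- sort(unique(pi), decreasing = TRUE)
    sens <- vapply(thr, function(cu) sum(wc[pi[case] >= cu]) / sum(wc), 0)
    spec <- vapply(thr, function(cu) sum(wk[pi[ctrl] < cu]) / sum(wk), 0)
    curves[[as.character(tau)]] <<- data.frame(threshold = thr,
                                               sensitivity = sens,
                                               specificity = spec)
    data.frame(horizon = tau, auc = auc, n_cases = length(case),
               n_controls = length(ctrl), flag = "ok")
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  class(out) <- c("coxdae_tdroc", "data.frame")
  out
}
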