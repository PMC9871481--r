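#' Fit a Cox regression nomogram
#'
#' Multivariate Cox model combining the prognostic index with clinical risk
#' factors (default: age, sex, race, KPS, radiotherapy, chemotherapy), turned
#' into a point system: each covariate's contribution `beta_j * x_j` is
#' shifted to start at 0 and scaled so that the largest single-covariate
#' range spans exactly 100 points. Total points map back to the linear
#' predictor through a stored affine map (no information loss), and to
#' survival probabilities at the requested horizons through the Breslow
#' baseline.
#'
#' Rows with missing covariates are dropped (complete-case) with a message
#' reporting the count.
#'
#' @param pi Prognostic indices.
#' @param clinical Data frame of clinical covariates (character columns are
#'   dummy-coded).
#' @param time,event Survival data.
#' @param horizons Days at which survival probabilities are tabulated.
#' @return A `coxdae_nomogram`: list with the Cox fit, `points` (per-covariate
#'   point scales), `affine` (`lp = a + b * total_points`), and
#'   `survival_lookup` (per horizon, total points -> predicted survival).
#' @export
fit_nomogram <- function(pi, clinical = NULL, time, event,
                         horizons = c(300, 450)) {
  df <- if (is.null(clinical) || (is.data.frame(clinical) && !ncol(clinical)))
    data.frame(pi = pi)
  else data.frame(pi = pi, clinical, stringsAsFactors = FALSE)
  cc <- complete.cases(df)
  if (any(!cc))
    message("dropping ", sum(!cc), " case(s) with missing covariates ",
            "(complete-case analysis)")
  df <- df[cc, , drop = FALSE]
  time <- time[cc]
  event <- event[cc]
  xlevels <- lapply(df, function(col)
    if (is.character(col) || is.factor(col)) levels(factor(col)) else NULL)
  cf <- fit_cox(df, time, event)
  mm <- cf$x
  beta <- cf$beta
  contrib <- sweep(mm, 2L, beta, `*`)            # beta_j * x_j per case
  lo <- apply(contrib, 2L, min)
  hi <- apply(contrib, 2L, max)
  maxrange <- max(hi - lo)
  if (maxrange <= 0) stop("degenerate nomogram (no covariate variation)",
                          call. = FALSE)
  scale <- 100 / maxrange
  points <- sweep(contrib, 2L, lo, `-`) * scale
  total <- rowSums(points)
  lp <- as.numeric(mm %*% beta)
  # lp = sum(lo) + total / scale
  affine <- c(a = sum(lo), b = 1 / scale)
  lookup <- lapply(horizons, function(tau) {
    H0 <- baseline_cumhaz_at(cf$baseline, tau)
    grid <- seq(0, sum(100 * (hi - lo) / maxrange), length.out = 101L)
    data.frame(total_points = grid,
               survival = exp(-H0 * exp(affine["a"] + affine["b"] * grid)))
  })
  names(lookup) <- as.character(horizons)
  structure(list(cox = cf, beta = beta, xlevels = xlevels,
                 points_range = rbind(lo = lo, hi = hi),
                 scale = scale, affine = affine, horizons = horizons,
                 survival_lookup = lookup,
                 data = list(mm = mm, time = time, event = event,
                             total_points = total, lp = lp)),
            class = "coxdae_nomogram")
}

baseline_cumhaz_at <- function(baseline, tau) {
  idx <- findInterval(tau, baseline$time)
  if (idx == 0L) 0 else baseline$cumhaz[idx]
}

#' Points and linear predictor for new covariate values
#'
#' @param model A `coxdae_nomogram`.
#' @param newdata Data frame with the model's covariates (including `pi`);
#'   defaults to the training data.
#' @return Data frame with per-covariate points, `total_points` and the
#'   reconstructed linear predictor `lp`.
#' @export
nomogram_points <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "coxdae_nomogram"))
  mm <- if (is.null(newdata)) model$data$mm else {
    nd <- as.data.frame(newdata)
    miss <- setdiff(names(model$xlevels), names(nd))
    if (length(miss))
      stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    nd <- nd[names(model$xlevels)]
    for (nm in names(nd))
      if (!is.null(model$xlevels[[nm]]))   # restore training factor coding
        nd[[nm]] <- factor(nd[[nm]], levels = model$xlevels[[nm]])
    mm2 <- model.matrix(~ ., data = nd)[, -1, drop = FALSE]
    mm2[, colnames(model$data$mm), drop = FALSE]
  }
  contrib <- sweep(mm, 2L, model$beta, `*`)
  pts <- sweep(contrib, 2L, model$points_range["lo", ], `-`) * model$scale
  total <- rowSums(pts)
  lp <- model$affine[["a"]] + model$affine[["b"]] * total
  data.frame(pts, total_points = total, lp = lp, check.names = TRUE)
}

#' Concordance of the nomogram's linear predictor
#'
#' @param model A `coxdae_nomogram`.
#' @param newdata Optional list with `mm`-compatible covariates, `time`,
#'   `event`; defaults to the training data.
#' @return C-index.
#' @export
nomogram_cindex <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "coxdae_nomogram"))
  if (is.null(newdata)) {
    with(model$data, concordance_index(lp, time, event))
  } else {
    lp <- nomogram_points(model, newdata$covariates)$lp
    concordance_index(lp, newdata$time, newdata$event)
  }
}

#' Predicted survival probability at a horizon
#'
#' @param model A `coxdae_nomogram`.
#' @param lp Linear predictors.
#' @param tau Horizon (days).
#' @return Predicted survival probabilities `S0(tau)^exp(lp)`.
#' @export
nomogram_survival <- function(model, lp, tau) {
  H0 <- baseline_cumhaz_at(model$cox$baseline, tau)
  exp(-H0 * exp(lp))
}

#' Calibration curve of the nomogram
#'
#' Cases are ranked by their predicted survival at the horizon and split
#' into equal-count groups; each group contributes one point comparing the
#' mean predicted survival with the observed Kaplan-Meier estimate at the
#' horizon (Greenwood standard error). Points from groups with no subject at
#' risk at the horizon are flagged.
#'
#' @param model A `coxdae_nomogram`.
#' @param horizon Evaluation day.
#' @param n_groups Number of risk groups (default 3).
#' @param newdata Optional list with `covariates`, `time`, `event`.
#' @return A `coxdae_calibration` data frame with `group`, `n`, `predicted`,
#'   `observed`, `se`, `flag`.
#' @export
calibration_curve <- function(model, horizon, n_groups = 3L,
                              newdata = NULL) {
  stopifnot(inherits(model, "coxdae_nomogram"), n_groups >= 1L)
  if (is.null(newdata)) {
    lp <- model$data$lp
    time <- model$data$time
    event <- model$data$event
  } else {
    lp <- nomogram_points(model, newdata$covariates)$lp
    time <- newdata$time
    event <- newdata$event
  }
  pred <- nomogram_survival(model, lp, horizon)
  grp <- cut(rank(pred, ties.method = "first"),
             breaks = seq(0, length(pred), length.out = n_groups + 1L),
             labels = FALSE)
  rows <- lapply(seq_len(n_groups), function(g) {
    i <- which(grp == g)
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    sm <- summary(sf, times = horizon, extend = TRUE)
    at_risk <- sum(time[i] >= horizon)
    data.frame(group = g, n = length(i), predicted = mean(pred[i]),
               observed = sm$surv, se = sm$std.err,
               flag = if (at_risk == 0L) "no subjects at risk" else "ok")
  })
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  class(out) <- c("coxdae_calibration", "data.frame")
  out
}
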