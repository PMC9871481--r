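#' Configuration of the synthetic tumour cohort generator
#'
#' The generator emulates the prognostic drivers reported for glioblastoma —
#' tumour size, necrosis, contrast enhancement and peritumoural edema — with
#' an ellipsoidal phantom: a tumour core whose outer shell is "enhancing"
#' (label 4) around a necrotic / non-enhancing interior (label 1), wrapped in
#' an edema shell (label 2), placed in a spherical "brain" of background
#' tissue. Per-modality contrasts follow clinical convention (enhancing rim
#' bright in T1ce, edema bright in FLAIR/T2, necrosis dark in T1ce).
#'
#' Four scale-free phenotype features are computed from the segmentation:
#' log relative tumour volume, necrotic fraction of the core, enhancing
#' fraction of the whole tumour, and edema extent. Standardized with fixed
#' reference moments of the geometry distribution, they define the true
#' log hazard `eta = sum(w_k * z_k)` (plus an optional age term). Event times
#' are drawn from a Weibull hazard `h(t) = lambda0 * shape * t^(shape-1) *
#' exp(eta)` (exponential at `shape = 1`, so proportional hazards holds by
#' construction) and censoring times from an independent exponential.
#'
#' @param n_patients Number of cases (>= 2).
#' @param vol_shape Shape of the generated full volume (before VOI
#'   extraction).
#' @param baseline_hazard Baseline event rate per day (`lambda0 > 0`).
#' @param effect_weights Named log-hazard coefficients of the standardized
#'   phenotype features `log_volume`, `necrotic_fraction`,
#'   `enhancing_fraction`, `edema_extent`.
#' @param censor_rate Independent censoring rate per day (0 = no censoring).
#' @param noise_sd Gaussian intensity noise, in raw intensity units
#'   (tissue contrasts span roughly 250-900).
#' @param age_effect Additional log hazard per year of age above 60.
#' @param weibull_shape Weibull shape of the event hazard; 1 = exponential.
#'   Values != 1 keep proportional hazards but change the time profile.
#' @param seed Master seed; per-case seeds are derived by fixed hashing of
#'   (seed, patient index).
#' @return A `coxdae_sim_config` list.
#' @export
sim_config <- function(n_patients = 100L,
                       vol_shape = c(48L, 48L, 48L),
                       baseline_hazard = 1 / 400,
                       effect_weights = c(log_volume = 1.0,
                                          necrotic_fraction = 0.4,
                                          enhancing_fraction = -0.4,
                                          edema_extent = 0.3),
                       censor_rate = 1 / 1200,
                       noise_sd = 30,
                       age_effect = 0.02,
                       weibull_shape = 1,
                       seed = 1L) {
  stopifnot(n_patients >= 2L, baseline_hazard > 0, censor_rate >= 0,
            noise_sd >= 0, weibull_shape > 0, length(vol_shape) == 3L)
  w <- c(log_volume = 0, necrotic_fraction = 0, enhancing_fraction = 0,
         edema_extent = 0)
  if (length(effect_weights)) {
    bad <- setdiff(names(effect_weights), names(w))
    if (length(bad)) stop("unknown effect weight(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    w[names(effect_weights)] <- effect_weights
  }
  structure(list(n_patients = as.integer(n_patients),
                 vol_shape = as.integer(vol_shape),
                 baseline_hazard = baseline_hazard,
                 effect_weights = w, censor_rate = censor_rate,
                 noise_sd = noise_sd, age_effect = age_effect,
                 weibull_shape = weibull_shape, seed = as.integer(seed)),
            class = "coxdae_sim_config")
}

# fixed reference moments of the phenotype features under the generator's
# geometry distribution (continuum formulas, 2e5 Monte-Carlo draws); they fix
# the standardization so that per-case generation stays independent
.feature_ref <- list(
  mean = c(log_volume = -3.6226, necrotic_fraction = 0.5886,
           enhancing_fraction = 0.1670, edema_extent = 0.5940),
  sd = c(log_volume = 0.5312, necrotic_fraction = 0.1032,
         enhancing_fraction = 0.0650, edema_extent = 0.1169))

# raw per-region intensity means for (T1, T2, T1ce, FLAIR)
.tissue_intensity <- rbind(
  brain     = c(500, 400, 500, 450),
  edema     = c(380, 750, 400, 800),
  necrotic  = c(300, 820, 250, 500),
  enhancing = c(550, 550, 900, 600))

derive_case_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

#' Phenotype features of a segmented tumour
#'
#' Recomputes the generator's four scale-free features from a segmentation
#' label array alone, so they are exactly reproducible from any generated (or
#' real) mask.
#'
#' @param seg 3-D integer label array (codes 0/1/2/4).
#' @return Named numeric vector of raw (unstandardized) features.
#' @export
phenotype_features <- function(seg) {
  d <- min(dim(seg))
  n1 <- sum(seg == 1L); n2 <- sum(seg == 2L); n4 <- sum(seg == 4L)
  whole <- n1 + n2 + n4
  core <- n1 + n4
  if (whole == 0L) stop("empty tumour segmentation", call. = FALSE)
  c(log_volume = log(whole) - 3 * log(d),
    necrotic_fraction = if (core > 0L) n1 / core else 0,
    enhancing_fraction = n4 / whole,
    edema_extent = n2 / whole)
}

standardize_features <- function(f) {
  (f - .feature_ref$mean[names(f)]) / .feature_ref$sd[names(f)]
}

#' Draw survival and censoring times for given log hazards
#'
#' Event times follow a Weibull hazard `lambda0 * shape * t^(shape-1) *
#' exp(eta)`; censoring is exponential with rate `censor_rate` (none if 0).
#'
#' @param eta Vector of log relative hazards.
#' @param lambda0 Baseline rate per day.
#' @param censor_rate Censoring rate per day.
#' @param shape Weibull shape (1 = exponential).
#' @return Data frame with `time` (days) and `event` (0/1).
#' @export
draw_survival_times <- function(eta, lambda0, censor_rate = 0, shape = 1) {
  n <- length(eta)
  u <- rexp(n)                              # cumulative hazard at event
  t_event <- (u / (lambda0 * exp(eta)))^(1 / shape)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(time = pmax(pmin(t_event, t_cens), 1e-8),
             event = as.numeric(t_event <= t_cens))
}

#' Survival times under a hazard whose effect reverses over time
#'
#' Piecewise-exponential sampler used to exercise proportional-hazards
#' diagnostics under a known violation: before `t_flip` the log hazard is
#' `+eta`, afterwards `-eta`.
#'
#' @inheritParams draw_survival_times
#' @param t_flip Time (days) at which the covariate effect flips sign.
#' @return Data frame with `time` and `event`.
#' @export
draw_tv_survival_times <- function(eta, lambda0, t_flip, censor_rate = 0) {
  n <- length(eta)
  r1 <- lambda0 * exp(eta)
  r2 <- lambda0 * exp(-eta)
  t1 <- rexp(n, r1)
  t_event <- ifelse(t1 <= t_flip, t1, t_flip + rexp(n, r2))
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(time = pmax(pmin(t_event, t_cens), 1e-8),
             event = as.numeric(t_event <= t_cens))
}

#' Simulate one synthetic multimodal case
#'
#' @param cfg A [sim_config()].
#' @param index Patient index (used for the id and the derived per-case
#'   seed).
#' @param case_seed Explicit seed overriding the derived one.
#' @return A `coxdae_sim_case`: list with `volume` (a `coxdae_volume`),
#'   `record` (a `coxdae_record` with clinical covariates),
#'   `true_log_hazard` and the raw `features`.
#' @export
simulate_case <- function(cfg, index = 1L, case_seed = NULL) {
  stopifnot(inherits(cfg, "coxdae_sim_config"))
  if (is.null(case_seed)) case_seed <- derive_case_seed(cfg$seed, index)
  rng <- local_rng(case_seed)
  on.exit(rng(), add = TRUE)

  d <- cfg$vol_shape
  dmin <- min(d)
  geom <- NULL
  for (try in 1:25) {
    r <- runif(3, 0.08, 0.20) * dmin          # core semi-axes, voxels
    s_r <- runif(1, 0.75, 0.92)               # necrotic interior scale
    s_e <- runif(1, 1.15, 1.60)               # edema outer scale
    ctr <- d / 2 + runif(3, -2, 2)
    if (all(ctr - r * s_e > 1.5) && all(ctr + r * s_e < d - 0.5)) {
      geom <- list(r = r, s_r = s_r, s_e = s_e, ctr = ctr)
      break
    }
  }
  if (is.null(geom))
    stop("tumour geometry does not fit the volume after 25 attempts",
         call. = FALSE)

  ax <- (seq_len(d[1]) - geom$ctr[1]) / geom$r[1]
  ay <- (seq_len(d[2]) - geom$ctr[2]) / geom$r[2]
  az <- (seq_len(d[3]) - geom$ctr[3]) / geom$r[3]
  rho2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  rho <- sqrt(rho2)

  seg <- array(0L, dim = d)
  seg[rho <= geom$s_e] <- 2L                  # edema shell
  seg[rho <= 1] <- 4L                         # enhancing rim
  seg[rho <= geom$s_r] <- 1L                  # necrotic / non-enhancing core

  # spherical brain envelope; background outside stays exactly zero
  bx <- (seq_len(d[1]) - d[1] / 2 - 0.5)
  by <- (seq_len(d[2]) - d[2] / 2 - 0.5)
  bz <- (seq_len(d[3]) - d[3] / 2 - 0.5)
  brad2 <- outer(outer(bx^2, by^2, `+`), bz^2, `+`)
  brain <- brad2 <= (0.48 * dmin)^2

  channels <- array(0, dim = c(d, 4L))
  region <- array(1L, dim = d)                # 1 = brain tissue
  region[seg == 2L] <- 2L
  region[seg == 1L] <- 3L
  region[seg == 4L] <- 4L
  for (k in 1:4) {
    a <- .tissue_intensity[region, k]
    dim(a) <- d
    if (cfg$noise_sd > 0)
      a <- a + rnorm(length(a), 0, cfg$noise_sd)
    a[a < 1] <- 1
    a[!brain & seg == 0L] <- 0
    channels[, , , k] <- a
  }

  feats <- phenotype_features(seg)
  z <- standardize_features(feats)
  eta <- sum(cfg$effect_weights[names(z)] * z)

  age <- round(min(85, max(30, rnorm(1, 60, 10))))
  eta <- eta + cfg$age_effect * (age - 60)
  st <- draw_survival_times(eta, cfg$baseline_hazard, cfg$censor_rate,
                            cfg$weibull_shape)

  rec <- survival_record(
    patient_id = sprintf("sim%04d", index),
    time = st$time, event = st$event, age = age,
    kps = sample(c(60, 70, 80, 90, 100), 1,
                 prob = c(0.10, 0.20, 0.30, 0.25, 0.15)),
    sex = sample(c("male", "female"), 1, prob = c(0.6, 0.4)),
    race = sample(c("white", "black", "asian", "other"), 1,
                  prob = c(0.75, 0.12, 0.08, 0.05)),
    radiotherapy = sample(c("yes", "no"), 1, prob = c(0.8, 0.2)),
    chemotherapy = sample(c("yes", "no"), 1, prob = c(0.7, 0.3)))

  structure(list(volume = new_volume(rec$patient_id, channels, c(1, 1, 1), seg),
                 record = rec, true_log_hazard = eta, features = feats),
            class = "coxdae_sim_case")
}

#' Simulate a synthetic cohort
#'
#' Generates `cfg$n_patients` cases and optionally writes the preprocessed
#' VOIs plus survival records to an HDF5 container ([pack_h5()]) and the
#' clinical covariates to CSV.
#'
#' @param cfg A [sim_config()].
#' @param voi_shape If non-`NULL`, normalize each case and extract a VOI of
#'   this shape (required when writing HDF5).
#' @param h5_path,clinical_path Optional output paths.
#' @return List with `cases` (the `coxdae_sim_case` list), `vois` (if
#'   extracted), `clinical` (data frame) and `true_log_hazard` (vector).
#' @export
simulate_cohort <- function(cfg, voi_shape = NULL, h5_path = NULL,
                            clinical_path = NULL) {
  stopifnot(inherits(cfg, "coxdae_sim_config"))
  cases <- lapply(seq_len(cfg$n_patients), function(i) simulate_case(cfg, i))
  out <- list(cases = cases,
              true_log_hazard = vapply(cases, `[[`, 0, "true_log_hazard"))
  clin <- do.call(rbind, lapply(cases, function(cs) {
    r <- cs$record
    data.frame(patient_id = r$patient_id, time_days = r$time,
               event = r$event, age = r$age, sex = r$sex, race = r$race,
               kps = r$kps, radiotherapy = r$radiotherapy,
               chemotherapy = r$chemotherapy, stringsAsFactors = FALSE)
  }))
  out$clinical <- clin
  if (!is.null(voi_shape)) {
    out$vois <- lapply(cases, function(cs) {
      list(voi = extract_voi(normalize_modalities(cs$volume), voi_shape),
           record = cs$record)
    })
  }
  if (!is.null(h5_path)) {
    if (is.null(out$vois))
      stop("voi_shape is required when writing an HDF5 cohort", call. = FALSE)
    pack_h5(out$vois, h5_path)
  }
  if (!is.null(clinical_path))
    write.csv(clin, clinical_path, row.names = FALSE)
  out
}
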