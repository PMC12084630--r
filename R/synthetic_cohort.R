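#' Configuration for the synthetic-cohort simulator
#'
#' The simulator emulates the longitudinal structure of a large-MCA-stroke
#' ICU cohort: admission within 24 h of last-seen-well, CT scans at
#' irregular intervals (mean near 11.3 h for a derivation-style cohort and
#' 18.8 h for a validation-style cohort), MLS trajectories that rise and
#' peak roughly 2-5 days post-ictus before receding, lab/vital drift
#' preceding class worsening, treatments correlated with severity,
#' censoring at decompressive hemicraniectomy, and
#' missing-completely-at-random gaps per variable family.
#'
#' @param n_patients number of hospitalizations to simulate.
#' @param seed integer master seed; every stream of randomness derives
#'   from it.
#' @param profile `"derivation"` or `"validation"`; selects the default
#'   mean inter-scan interval (11.3 h vs 18.8 h).
#' @param scan_interval_mean_h mean hours between scans (overrides the
#'   profile default when supplied).
#' @param scan_interval_shape gamma shape for inter-scan gaps; the
#'   default gives a standard deviation close to the mean, matching the
#'   wide observed spread of scan intervals.
#' @param peak_window_h length-2 vector: the window (hours post
#'   last-seen-well) in which each patient's MLS trajectory peaks.
#'   Default 48-120 h (2-5 days).
#' @param class_mix probability 4-vector over the eventual maximum MLS
#'   class (codes 0:3); must sum to 1.
#' @param signal_strength non-negative scale on the WBC / temperature /
#'   sodium drift that precedes an MLS class transition; 0 removes all
#'   covariate signal beyond the scans themselves.
#' @param text_informativeness non-negative concentration of the
#'   simulated report class probabilities around the true future class;
#'   0 makes them uninformative (uniform in expectation).
#' @param missing_static,missing_dynamic,missing_radiographic
#'   missing-completely-at-random rates per variable family, in [0, 1].
#' @param dhc_prob_severe probability that a patient whose trajectory
#'   reaches the severe (>8 mm) class undergoes decompressive
#'   hemicraniectomy, which censors all later data.
#' @param traj_noise_sd standard deviation (mm) of the Gaussian
#'   measurement noise on the MLS trajectory.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       profile = c("derivation", "validation"),
                       scan_interval_mean_h = NULL,
                       scan_interval_shape = 1.6,
                       peak_window_h = c(48, 120),
                       class_mix = c(0.10, 0.25, 0.40, 0.25),
                       signal_strength = 1,
                       text_informativeness = 4,
                       missing_static = 0.10,
                       missing_dynamic = 0.25,
                       missing_radiographic = 0.10,
                       dhc_prob_severe = 0.30,
                       traj_noise_sd = 0.25) {
  profile <- match.arg(profile)
  if (is.null(scan_interval_mean_h)) {
    scan_interval_mean_h <- if (profile == "derivation") 11.3 else 18.8
  }
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  if (scan_interval_mean_h <= 0) stop("scan_interval_mean_h must be > 0")
  if (scan_interval_shape <= 0) stop("scan_interval_shape must be > 0")
  if (length(class_mix) != 4 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be a probability 4-vector summing to 1")
  }
  rates <- c(missing_static, missing_dynamic, missing_radiographic)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  if (signal_strength < 0) stop("signal_strength must be >= 0")
  if (text_informativeness < 0) stop("text_informativeness must be >= 0")
  if (length(peak_window_h) != 2 || peak_window_h[1] >= peak_window_h[2]) {
    stop("peak_window_h must be an increasing pair of hours")
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              profile = profile,
              scan_interval_mean_h = scan_interval_mean_h,
              scan_interval_shape = scan_interval_shape,
              peak_window_h = peak_window_h, class_mix = class_mix,
              signal_strength = signal_strength,
              text_informativeness = text_informativeness,
              missing_static = missing_static,
              missing_dynamic = missing_dynamic,
              missing_radiographic = missing_radiographic,
              dhc_prob_severe = dhc_prob_severe,
              traj_noise_sd = traj_noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an MLS trajectory
#'
#' Piecewise log-linear rise/decay with additive Gaussian measurement
#' noise: the noiseless curve rises exponentially from near zero to
#' `peak_mm` at `peak_hour` and then decays with a fixed half-life.
#' Noise is frozen at integer hours from the seed and linearly
#' interpolated, so the returned function is deterministic given the
#' seed and can be evaluated at arbitrary (real) hours.
#'
#' @param peak_mm peak MLS magnitude in mm (>= 0); 0 yields the
#'   identically-zero trajectory.
#' @param peak_hour hour (from last-seen-well) of the noiseless peak.
#' @param seed integer seed for the noise stream.
#' @param noise_sd Gaussian noise standard deviation in mm.
#' @param decay_half_h half-life of the post-peak decay in hours.
#' @param floor_mm near-zero value of the noiseless curve at hour 0.
#' @return a function `hour -> mls_mm` (vectorized, clamped at 0), with
#'   attributes `base` (the noiseless curve) and `peak_mm`, `peak_hour`.
#' @export
simulate_mls_trajectory <- function(peak_mm, peak_hour, seed,
                                    noise_sd = 0.25, decay_half_h = 96,
                                    floor_mm = 0.05) {
  if (peak_mm < 0) stop("peak_mm must be >= 0")
  base <- if (peak_mm == 0) {
    function(hour) rep(0, length(hour))
  } else {
    k_rise <- log(peak_mm / floor_mm) / max(peak_hour, 1)
    k_decay <- log(2) / decay_half_h
    function(hour) {
      ifelse(hour <= peak_hour,
             peak_mm * exp(-k_rise * (peak_hour - hour)),
             peak_mm * exp(-k_decay * (hour - peak_hour)))
    }
  }
  noise_hours <- 0:500
  old <- .Random.seed_save()
  set.seed(seed)
  noise <- stats::rnorm(length(noise_hours), 0, noise_sd)
  .Random.seed_restore(old)
  f <- function(hour) {
    if (peak_mm == 0) return(rep(0, length(hour)))
    n <- stats::approx(noise_hours, noise, xout = pmin(pmax(hour, 0), 500),
                       rule = 2)$y
    pmax(base(hour) + n, 0)
  }
  attr(f, "base") <- base
  attr(f, "peak_mm") <- peak_mm
  attr(f, "peak_hour") <- peak_hour
  f
}

# Save/restore the global RNG state so seeded sub-streams do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Simulate report class probabilities
#'
#' Stands in for transformer-derived radiology-report features: for each
#' prediction horizon (8, 24, 36 h) a probability 4-vector is drawn from
#' a Dirichlet distribution whose concentration is raised on the true
#' future class, so the vector's mode is the true class and sharpens as
#' `informativeness` grows. `informativeness = 0` gives a symmetric
#' Dirichlet(1,1,1,1), i.e. expectation (1/4, 1/4, 1/4, 1/4).
#'
#' @param true_future_classes integer 3-vector of class codes (0:3), one
#'   per horizon in order 8 h, 24 h, 36 h.
#' @param informativeness non-negative concentration boost.
#' @return named numeric vector of length 12
#'   (`p8_class0` ... `p36_class3`), each horizon block summing to 1.
#' @export
simulate_report_probs <- function(true_future_classes, informativeness) {
  stopifnot(length(true_future_classes) == 3,
            all(true_future_classes %in% 0:3), informativeness >= 0)
  out <- numeric(0)
  for (k in true_future_classes) {
    alpha <- rep(1, 4)
    alpha[k + 1] <- 1 + informativeness
    g <- stats::rgamma(4, shape = alpha)
    out <- c(out, g / sum(g))
  }
  names(out) <- report_prob_names()
  out
}

#' Simulate a synthetic cohort
#'
#' Generates `n_patients` hospitalizations, each passing
#' [validate_patient()], deterministically for a given seed. See
#' [sim_config()] for the structure being emulated.
#'
#' @param config a [sim_config()].
#' @return named list of [patient_record()]s.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 5, seed = 1))
#' length(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  patient_seeds <- sample.int(2^31 - 2, config$n_patients)
  records <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, patient_seeds[i],
                     sprintf("SIM%05d", i))
  })
  names(records) <- vapply(records, `[[`, character(1), "patient_id")
  records
}

simulate_patient <- function(config, pseed, id) {
  set.seed(pseed)
  admission_hour <- stats::runif(1, 0.5, 20)
  max_class <- sample(0:3, 1, prob = config$class_mix)
  peak_mm <- switch(as.character(max_class),
                    "0" = 0,
                    "1" = stats::runif(1, 0.8, 2.8),
                    "2" = stats::runif(1, 3.4, 7.6),
                    "3" = stats::runif(1, 8.6, 14))
  peak_hour <- stats::runif(1, config$peak_window_h[1],
                            config$peak_window_h[2])
  traj <- simulate_mls_trajectory(peak_mm, peak_hour, seed = pseed + 1,
                                  noise_sd = config$traj_noise_sd)
  base_fn <- attr(traj, "base")
  end_hour <- admission_hour +
    min(max(stats::rlnorm(1, log(220), 0.45), 48), 400)

  # scan times: first scan shortly after admission, then gamma gaps
  sh <- config$scan_interval_shape
  t <- admission_hour + stats::runif(1, 0.5, 2)
  scan_hours <- t
  repeat {
    gap <- stats::rgamma(1, shape = sh,
                         rate = sh / config$scan_interval_mean_h)
    t <- t + max(gap, 0.25)
    if (t > end_hour) break
    scan_hours <- c(scan_hours, t)
  }
  if (length(scan_hours) < 2) {       # imaging after the first day is an
    scan_hours <- c(scan_hours,       # inclusion requirement
                    min(scan_hours[1] + 25, end_hour))
    end_hour <- max(end_hour, scan_hours[2])
  }
  scan_hours <- round(sort(scan_hours), 2)
  scan_hours <- scan_hours[!duplicated(scan_hours)]
  mls <- round(pmax(traj(scan_hours), 0), 1)
  scans <- build_scan_table(scan_hours, mls, config)

  # report probabilities per scan: Dirichlet around the true future
  # window-max class of the noiseless curve
  probs <- t(vapply(scan_hours, function(h) {
    futs <- vapply(c(8, 24, 36), function(W) {
      grid <- seq(h + 0.5, h + W, by = 0.5)
      mls_to_class(max(base_fn(grid)))
    }, integer(1))
    simulate_report_probs(futs, config$text_informativeness)
  }, numeric(12)))
  scans <- cbind(scans, as.data.frame(probs))

  series <- simulate_dynamic_series(config, admission_hour, end_hour,
                                    base_fn, max_class)
  treatments <- simulate_treatments(config, admission_hour, end_hour,
                                    peak_hour, max_class, mls, scan_hours)
  statics <- simulate_statics(config, admission_hour, max_class)

  # hemicraniectomy censors everything after it
  dhc <- treatments$hour[treatments$kind == "hemicraniectomy"]
  if (length(dhc)) {
    dhc <- min(dhc)
    keep_scan <- scans$hour <= dhc
    if (sum(keep_scan) >= 2) {   # keep the record usable for modelling
      scans <- scans[keep_scan, , drop = FALSE]
      series <- series[series$hour <= dhc, , drop = FALSE]
      treatments <- treatments[treatments$hour <= dhc, , drop = FALSE]
      end_hour <- dhc
    } else {
      treatments <- treatments[treatments$kind != "hemicraniectomy", ,
                               drop = FALSE]
    }
  }
  rownames(scans) <- rownames(series) <- rownames(treatments) <- NULL
  patient_record(id, admission_hour, statics, series, scans, treatments,
                 round(end_hour, 2))
}

# Expand per-scan MLS measurements into the full 36-column radiographic
# table (direct reads plus threshold/timing features a labelling team
# would extract).
build_scan_table <- function(scan_hours, mls, config) {
  n <- length(scan_hours)
  pineal <- round(pmax(0.5 * mls + stats::rnorm(n, 0, 0.3), 0), 1)
  cistern <- stats::rbinom(n, 1, stats::plogis(1.2 * (mls - 5)))
  first_over <- function(thr) {
    i <- which(mls > thr)
    if (length(i)) scan_hours[min(i)] else NA_real_
  }
  running_first_over <- function(thr) {
    out <- rep(NA_real_, n)
    i <- which(mls > thr)
    if (length(i)) out[seq(min(i), n)] <- scan_hours[min(i)]
    out
  }
  df <- data.frame(
    hour = scan_hours,
    mls_mm = mls,
    pineal_shift_mm = pineal,
    basal_cistern_effacement = cistern,
    sulcal_effacement = stats::rbinom(n, 1, stats::plogis(0.8 * (mls - 3))),
    ventricle_compression = stats::rbinom(n, 1, stats::plogis(mls - 4)),
    uncal_herniation = stats::rbinom(n, 1, stats::plogis(1.5 * (mls - 9))),
    hydrocephalus = stats::rbinom(n, 1, 0.05),
    petechial_hemorrhage = rep(stats::rbinom(1, 1, 0.5), n),
    parenchymal_hemorrhage = rep(stats::rbinom(1, 1, 0.1), n),
    hemorrhagic_transformation = rep(stats::rbinom(1, 1, 0.15), n),
    infarct_fraction_mca = round(pmin(pmax(
      stats::runif(1, 0.5, 1) + cumsum(stats::rnorm(n, 0.005, 0.02)),
      0.5), 1), 2),
    aca_involvement = rep(stats::rbinom(1, 1, 0.07), n),
    pca_involvement = rep(stats::rbinom(1, 1, 0.05), n),
    insular_involvement = rep(stats::rbinom(1, 1, 0.6), n),
    basal_ganglia_involvement = rep(stats::rbinom(1, 1, 0.4), n),
    aspects_followup = pmin(pmax(round(
      5 - 0.2 * mls + stats::rnorm(n, 0, 1)), 0), 10),
    collateral_score = rep(sample(0:3, 1), n),
    cerebral_atrophy_grade = rep(stats::rbinom(1, 1, 0.44), n),
    edema_extent_score = pmin(pmax(round(mls / 3 +
      stats::rnorm(n, 0, 0.5)), 0), 5),
    gray_white_differentiation_loss = stats::rbinom(n, 1,
      stats::plogis(0.5 * mls - 1)),
    mass_effect_grade = pmin(floor(mls / 4), 3),
    midline_shift_present = as.integer(mls > 0),
    mls_over_3mm = as.integer(mls > 3),
    mls_over_5mm = as.integer(mls > 5),
    mls_over_8mm = as.integer(mls > 8),
    hours_since_prior_scan = c(NA, diff(scan_hours)),
    mls_change_from_prior = c(NA, diff(mls)),
    first_mls_value = rep(mls[1], n),
    first_mls_hour = rep(scan_hours[1], n),
    first_mls_over_3mm_hour = running_first_over(3),
    first_mls_over_5mm_hour = running_first_over(5),
    max_mls_to_date = cummax(mls),
    pineal_shift_change_from_prior = c(NA, diff(pineal)),
    contralateral_ventricle_dilation = stats::rbinom(n, 1,
      stats::plogis(mls - 7)),
    cistern_effacement_grade = pmin(cistern + as.integer(mls > 8), 2),
    scan_hour_lsw = scan_hours
  )
  for (cl in names(df)) df[[cl]] <- as.numeric(df[[cl]])
  # MCAR missingness on non-core columns (MLS itself is always read)
  soft_cols <- setdiff(names(df), c("hour", "mls_mm", "scan_hour_lsw",
                                    "first_mls_hour"))
  for (cl in soft_cols) {
    drop <- stats::runif(n) < config$missing_radiographic
    df[[cl]][drop] <- NA
  }
  df
}

# Typical-value baselines for the 16 dynamic EHR variables.
dynamic_baselines <- function() {
  list(glucose = c(140, 25), wbc = c(10, 2.5), sodium = c(138, 2.5),
       potassium = c(4.1, 0.4), creatinine = c(1.1, 0.3),
       bun = c(20, 7), osmolality = c(298, 8), temperature = c(98.1, 0.7),
       heart_rate = c(82, 12), sbp = c(148, 18), dbp = c(80, 10),
       map = c(102, 12), spo2 = c(97, 1.5), respiratory_rate = c(18, 3),
       gcs = c(11, 2.5))
}

simulate_dynamic_series <- function(config, admission_hour, end_hour,
                                    base_fn, max_class) {
  bl <- dynamic_baselines()
  # class up-transition hours of the noiseless curve, for the pre-event
  # drift in WBC / temperature / sodium
  grid <- seq(floor(admission_hour), ceiling(end_hour), by = 1)
  cls <- mls_to_class(pmax(base_fn(grid), 0))
  trans_hours <- grid[c(FALSE, diff(cls) > 0)]
  drift_amp <- c(wbc = 3.0, temperature = 1.2, sodium = 2.5)
  drift_at <- function(t) {
    if (!length(trans_hours) || config$signal_strength == 0) {
      return(rep(0, length(t)))
    }
    d <- rep(0, length(t))
    for (tt in trans_hours) {      # ramp over the 12 h before transition,
      u <- (t - (tt - 12)) / 12    # then fades over the following 24 h
      d <- d + pmax(pmin(u, 1, 1 - (t - tt) / 24), 0)
    }
    pmin(d, 1.5)
  }
  rows <- list()
  for (v in names(bl)) {
    times <- seq(admission_hour + stats::runif(1, 0, 2), end_hour, by = 4)
    times <- times + stats::runif(length(times), -0.5, 0.5)
    times <- round(times[times >= admission_hour & times <= end_hour], 2)
    if (!length(times)) next
    base_v <- stats::rnorm(1, bl[[v]][1], bl[[v]][2])
    ar <- stats::filter(stats::rnorm(length(times), 0, bl[[v]][2] / 3),
                        0.7, method = "recursive")
    vals <- base_v + as.numeric(ar)
    if (v %in% names(drift_amp)) {
      vals <- vals + config$signal_strength * drift_amp[[v]] * drift_at(times)
    }
    if (v == "gcs") vals <- pmin(pmax(round(vals), 3), 15)
    keep <- stats::runif(length(times)) >= config$missing_dynamic
    if (!any(keep)) keep[1] <- TRUE
    rows[[v]] <- data.frame(variable = v, hour = times[keep],
                            value = round(vals[keep], 2))
  }
  # osmotic therapy as a dynamic binary marker while edema is significant
  if (max_class >= 2 && stats::runif(1) < 0.6) {
    on_hours <- grid[pmax(base_fn(grid), 0) > 3]
    on_hours <- on_hours[on_hours >= admission_hour & on_hours <= end_hour]
    if (length(on_hours)) {
      oh <- on_hours[seq(1, length(on_hours), by = 6)]
      rows[["osmotic_therapy"]] <- data.frame(
        variable = "osmotic_therapy", hour = oh,
        value = 1)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variable = character(), hour = numeric(),
                      value = numeric())
  }
  out <- out[order(out$variable, out$hour), ]
  rownames(out) <- NULL
  out
}

simulate_treatments <- function(config, admission_hour, end_hour,
                                peak_hour, max_class, mls, scan_hours) {
  rows <- list()
  if (stats::runif(1) < 0.45) {
    rows$tpa <- data.frame(hour = admission_hour + stats::runif(1, 0, 3),
                           kind = "thrombolysis_tpa")
  }
  if (stats::runif(1) < 0.2 + 0.1 * (max_class >= 2)) {
    rows$mt <- data.frame(hour = admission_hour + stats::runif(1, 1, 8),
                          kind = "thrombectomy")
  }
  if (max_class >= 2 && stats::runif(1) < 0.55) {
    kind <- sample(c("osmotic_mannitol", "osmotic_hypertonic_3",
                     "osmotic_hypertonic_23.4"), 1,
                   prob = c(0.5, 0.3, 0.2))
    rows$osm <- data.frame(
      hour = min(peak_hour - stats::runif(1, 6, 24), end_hour),
      kind = kind)
  }
  if (max_class == 3 && stats::runif(1) < config$dhc_prob_severe) {
    dhc_hour <- min(max(peak_hour + stats::runif(1, -12, 12),
                        admission_hour + 30), end_hour)
    rows$dhc <- data.frame(hour = dhc_hour, kind = "hemicraniectomy")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(hour = numeric(), kind = character())
  }
  out <- out[out$hour >= 0 & out$hour <= end_hour, , drop = FALSE]
  out <- out[order(out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out$hour <- round(out$hour, 2)
  out
}

simulate_statics <- function(config, admission_hour, max_class) {
  rn <- function(m, s) stats::rnorm(1, m, s)
  rb <- function(p) stats::rbinom(1, 1, p)
  sev <- max_class / 3
  x <- c(
    age = round(min(max(rn(68, 15), 20), 100)),
    sex_female = rb(0.5),
    nihss_admission = round(min(max(rn(17 + 2 * sev, 5.8), 2), 42)),
    aspects_admission = round(min(max(rn(5 - sev, 2.9), 0), 10)),
    prior_stroke = rb(0.11),
    history_hypertension = rb(0.72),
    history_atrial_fibrillation = rb(0.48),
    history_diabetes = rb(0.3),
    anticoagulant_use = rb(0.25),
    antiplatelet_use = rb(0.35),
    sbp_admission = round(rn(150, 29)),
    dbp_admission = round(rn(80, 15)),
    map_admission = round(rn(103, 18)),
    heart_rate_admission = round(rn(82, 19)),
    temperature_admission = round(rn(97.7, 1), 1),
    respiratory_rate_admission = round(min(max(rn(18, 4), 8), 40)),
    spo2_admission = round(min(max(rn(97, 2), 80), 100)),
    wbc_admission = round(max(rn(11.7, 4), 2), 1),
    glucose_admission = round(max(rn(150, 59), 50)),
    hba1c_admission = round(max(rn(6.2, 1.3), 4), 1),
    sodium_admission = round(rn(137.8, 3.5), 1),
    potassium_admission = round(rn(4.1, 0.5), 1),
    creatinine_admission = round(max(rn(1.1, 0.6), 0.3), 2),
    bun_admission = round(max(rn(21, 12), 4)),
    osmolality_admission = round(rn(299, 12)),
    hemoglobin_admission = round(rn(13.5, 2), 1),
    platelets_admission = round(max(rn(250, 80), 30)),
    inr_admission = round(max(rn(1.1, 0.3), 0.8), 2),
    admission_hour_lsw = round(admission_hour, 2),
    left_hemisphere_stroke = rb(0.48),
    vessel_occlusion_grade = sample(0:3, 1, prob = c(0.73, 0.19, 0.07, 0.01)),
    history_dyslipidemia = rb(0.4),
    history_smoking = rb(0.3)
  )
  miss <- stats::runif(length(x)) < config$missing_static
  miss[names(x) == "admission_hour_lsw"] <- FALSE
  x[miss] <- NA
  x
}
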