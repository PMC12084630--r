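test_that("simulation is deterministic and validates", {
  cfg <- sim_config(n_patients = 10, seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(lengths(lapply(a, validate_patient)) == 0))
  expect_length(a, 10)
})

test_that("a degenerate class mix of all-zero severity yields zero MLS everywhere", {
  cfg <- sim_config(n_patients = 8, seed = 5, class_mix = c(1, 0, 0, 0))
  co <- simulate_cohort(cfg)
  for (r in co) expect_true(all(r$scans$mls_mm == 0))
})

test_that("empirical mean scan interval tracks the configured mean", {
  co <- cached_cohort(200, 7)
  gaps <- unlist(lapply(co, function(r) diff(r$scans$hour)))
  expect_gt(length(gaps), 500)
  expect_lt(abs(mean(gaps) - 11.3) / 11.3, 0.2)
})

test_that("validation profile widens the scan interval", {
  cfg <- sim_config(n_patients = 60, seed = 8, profile = "validation")
  co <- simulate_cohort(cfg)
  gaps <- unlist(lapply(co, function(r) diff(r$scans$hour)))
  expect_lt(abs(mean(gaps) - 18.8) / 18.8, 0.25)
})

test_that("MLS trajectories rise to a peak in the configured window then recede", {
  tr <- simulate_mls_trajectory(peak_mm = 9, peak_hour = 72, seed = 3,
                                noise_sd = 0)
  grid <- seq(0, 168, by = 1)
  v <- tr(grid)
  expect_true(all(v >= 0))
  expect_equal(grid[which.max(v)], 72)
  expect_lt(tr(0), 0.2)
  expect_true(all(diff(v[grid <= 72]) >= 0))
  expect_true(all(diff(v[grid >= 72]) <= 0))
  # class sequence along scans is non-decreasing then non-increasing
  cls <- mls_to_class(v)
  expect_true(all(diff(cls[grid <= 72]) >= 0))
  expect_true(all(diff(cls[grid >= 72]) <= 0))

  expect_identical(simulate_mls_trajectory(0, 72, seed = 3)(grid),
                   rep(0, length(grid)))
  # same params, different seeds: same noiseless peak, different noise
  t1 <- simulate_mls_trajectory(9, 72, seed = 1, noise_sd = 0.5)
  t2 <- simulate_mls_trajectory(9, 72, seed = 2, noise_sd = 0.5)
  expect_false(identical(t1(grid), t2(grid)))
  expect_identical(attr(t1, "base")(grid), attr(t2, "base")(grid))
})

test_that("report probabilities live on the simplex and sharpen with informativeness", {
  set.seed(21)
  p <- simulate_report_probs(c(2L, 3L, 1L), informativeness = 5)
  expect_length(p, 12)
  for (b in seq(1, 12, by = 4)) {
    expect_equal(sum(p[b:(b + 3)]), 1, tolerance = 1e-12)
  }
  # informativeness 0: expectation uniform
  set.seed(22)
  draws <- t(replicate(4000, simulate_report_probs(c(1L, 1L, 1L), 0)[1:4]))
  expect_equal(unname(colMeans(draws)), rep(0.25, 4), tolerance = 0.02)
  # informativeness 5: argmax recovers the true class in a clear majority
  set.seed(23)
  am <- replicate(4000, which.max(simulate_report_probs(c(2L, 0L, 0L), 5)[1:4]) - 1)
  expect_gt(mean(am == 2), 0.5)
  # large informativeness: mass concentrates on the true class
  set.seed(24)
  big <- replicate(200, simulate_report_probs(c(3L, 3L, 3L), 1000)[4])
  expect_gt(mean(big), 0.99)
})

test_that("hemicraniectomy censors all later data", {
  co <- cached_cohort(200, 7)
  dhc <- vapply(co, function(r) {
    h <- r$treatments$hour[r$treatments$kind == "hemicraniectomy"]
    if (length(h)) min(h) else NA_real_
  }, numeric(1))
  expect_gt(sum(!is.na(dhc)), 0)
  for (i in which(!is.na(dhc))) {
    r <- co[[i]]
    expect_lte(max(r$scans$hour), dhc[i])
    if (nrow(r$series)) expect_lte(max(r$series$hour), dhc[i])
    expect_equal(r$end_hour, unname(dhc[i]), tolerance = 0.01)
  }
})

test_that("pre-transition lab drift appears only with positive signal strength", {
  # With signal_strength 0 the WBC series is pure AR(1) noise around the
  # baseline; with a strong signal the hours just before a class
  # transition carry systematically higher WBC.
  drift_gap <- function(strength, seed) {
    co <- simulate_cohort(sim_config(n_patients = 60, seed = seed,
                                     signal_strength = strength,
                                     missing_dynamic = 0,
                                     class_mix = c(0, 0.2, 0.4, 0.4)))
    pre <- base <- numeric(0)
    for (r in co) {
      cls <- mls_to_class(pmax(r$scans$mls_mm, 0))
      up <- which(diff(cls) > 0)
      if (!length(up)) next
      tt <- r$scans$hour[up[1] + 1]
      w <- r$series[r$series$variable == "wbc", ]
      pre <- c(pre, w$value[w$hour > tt - 12 & w$hour <= tt])
      base <- c(base, w$value[w$hour <= tt - 24])
    }
    mean(pre) - mean(base)
  }
  expect_gt(drift_gap(3, 31), drift_gap(0, 31) + 0.5)
})
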