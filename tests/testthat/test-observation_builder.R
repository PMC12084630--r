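test_that("hourly grid spans admission to discharge, censors at surgery, truncates at 7 days", {
  rec <- two_scan_record()
  rec$admission_hour <- 2
  rec$end_hour <- 10
  rec$scans <- data.frame(hour = 3, mls_mm = 1)
  expect_identical(build_hourly_grid(rec), 2:10)

  dhc <- rec
  dhc$end_hour <- 80
  dhc$treatments <- data.frame(hour = 50, kind = "hemicraniectomy")
  g <- build_hourly_grid(dhc)
  expect_identical(g, 2:49)

  long <- rec
  long$end_hour <- 400
  expect_identical(max(build_hourly_grid(long)), 170L)  # 2 + 168

  late <- rec
  late$end_hour <- 1
  expect_identical(build_hourly_grid(late), integer(0))
})

test_that("forward-fill takes the most recent measurement at or before each hour", {
  s <- data.frame(hour = c(3, 9), value = c(5, 7))
  expect_equal(forward_fill(s, 10), 7)
  expect_equal(forward_fill(s, 2), NA_real_)
  expect_equal(forward_fill(s, 9), 7)
  expect_equal(forward_fill(s[1, ], c(3, 5, 10)), c(5, 5, 5))
  # latest raw value within the same hour wins
  tie <- data.frame(hour = c(3.2, 3.7), value = c(1, 2))
  expect_equal(forward_fill(tie, 4), 2)
  # idempotence: forward-filling already-filled hourly values changes nothing
  grid <- 3:20
  filled <- forward_fill(s, grid)
  again <- forward_fill(data.frame(hour = grid, value = filled), grid)
  expect_identical(again, filled)
})

test_that("rolling max uses the half-open 24-hour window", {
  s <- data.frame(hour = c(1, 10), value = c(4, 9))
  expect_equal(rolling_max_24h(s, 12), 9)
  expect_equal(rolling_max_24h(s[1, ], 30), NA_real_)   # 1 <= 30 - 24
  expect_equal(rolling_max_24h(s[1, ], 25), NA_real_)   # 1 not in (1, 25]
  expect_equal(rolling_max_24h(s[1, ], 24.5), 4)        # 1 in (0.5, 24.5]
  expect_equal(rolling_max_24h(data.frame(hour = 7, value = 3), 7), 3)
  # boundary: measurement exactly 24 h old is excluded
  expect_equal(rolling_max_24h(data.frame(hour = 6, value = 3), 30),
               NA_real_)
  expect_equal(rolling_max_24h(data.frame(hour = 6.5, value = 3), 30), 3)
})

test_that("rolling max dominates forward-fill while the filled value is in window", {
  set.seed(9)
  s <- data.frame(hour = sort(runif(30, 0, 100)),
                  value = rnorm(30))
  grid <- 0:100
  ff <- forward_fill(s, grid)
  rm24 <- rolling_max_24h(s, grid)
  both <- !is.na(ff) & !is.na(rm24)
  expect_true(all(rm24[both] >= ff[both]))
})

test_that("imputer means are computed on training patients and applied to others", {
  sch <- feature_schema(text_features = FALSE)
  mk <- function(id, age, wbc) {
    sf <- rep(NA_real_, 33)
    names(sf) <- default_static_names()
    sf[] <- 1   # keep every feature observed so the imputer can fit
    sf["age"] <- age
    sf["wbc_admission"] <- wbc
    patient_record(id, 2, sf,
                   scans = data.frame(hour = 3, mls_mm = 1), end_hour = 30)
  }
  train <- list(A = mk("A", 1, 10), B = mk("B", 3, NA), C = mk("C", NA, 14))
  imp <- fit_imputer(train, sch)
  expect_equal(unname(imp["age"]), 2)            # mean(1, 3)
  expect_equal(unname(imp["wbc_admission"]), 12) # mean(10, 14)

  test_rec <- mk("D", NA, NA)
  obs <- build_observations(test_rec, sch, imp)
  expect_true(all(obs$age == 2))
  expect_true(all(obs$wbc_admission == 12))

  broken <- lapply(train, function(r) {
    r$static_features["age"] <- NA; r
  })
  expect_error(fit_imputer(broken, sch), "age")
})

test_that("derived feature counts follow the schema arithmetic", {
  sch <- feature_schema()
  cats <- sch$categories
  expect_identical(sum(cats == "dynamic_ehr"), 32L)         # 2 x 16
  expect_identical(sum(cats == "human_radiographic"), 73L)  # 2 x 36 + 1
  expect_identical(sum(cats == "llm_text"), 12L)
  expect_identical(sum(cats == "static"), 33L)
  expect_identical(length(sch$feature_names), 33L + 32L + 73L + 12L)

  co <- cached_cohort(6, 42)
  imp <- fit_imputer(co, sch)
  obs <- build_observations(co[[1]], sch, imp)
  expect_true(all(sch$feature_names %in% names(obs)))
  expect_identical(ncol(obs) - 4L, length(sch$feature_names))

  no_text <- feature_schema(text_features = FALSE)
  expect_identical(length(no_text$feature_names), 33L + 32L + 73L)
})

test_that("observations start at the first scan and stay within the grid", {
  co <- cached_cohort(6, 42)
  sch <- feature_schema()
  imp <- fit_imputer(co, sch)
  for (r in co) {
    obs <- build_observations(r, sch, imp)
    grid <- build_hourly_grid(r)
    expect_lte(nrow(obs), length(grid))
    if (nrow(obs)) {
      expect_gte(min(obs$hour), min(r$scans$hour))
      expect_true(all(!is.na(obs$current_class)))
      # current class comes from the most recent scan at or before the hour
      i <- nrow(obs)
      last_scan <- max(r$scans$hour[r$scans$hour <= obs$hour[i]])
      expect_identical(obs$current_class[i],
                       mls_to_class(r$scans$mls_mm[r$scans$hour == last_scan]))
    }
  }
})

test_that("a single-scan patient has a missing prior-MLS feature", {
  rec <- two_scan_record()
  rec$scans <- rec$scans[1, ]
  sch <- feature_schema(text_features = FALSE)
  sf <- rec$static_features; sf[] <- 1
  rec$static_features <- sf
  imp <- fit_imputer(list(rec), sch)
  obs <- build_observations(rec, sch, imp)
  expect_true(all(is.na(obs$mls_prior_ff)))

  rec2 <- two_scan_record(t0 = 10, gap = 5, mls = c(2, 9))
  rec2$static_features <- sf
  obs2 <- build_observations(rec2, sch, imp)
  # after the second scan the prior-MLS feature is the first scan's value
  expect_equal(obs2$mls_prior_ff[obs2$hour >= 15], rep(2, sum(obs2$hour >= 15)))
  expect_true(all(is.na(obs2$mls_prior_ff[obs2$hour < 15])))
})
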