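# Shared fixtures: tiny hand-built records and cached simulated cohorts.

# A minimal record with two scans a configurable gap apart, used for the
# target-window worked examples.
two_scan_record <- function(t0 = 10, gap = 40, mls = c(2, 9),
                            end_hour = 120) {
  sf <- c(rep(NA_real_, 33))
  names(sf) <- default_static_names()
  sf["age"] <- 70
  patient_record("P1", admission_hour = 5, static_features = sf,
                 scans = data.frame(hour = c(t0, t0 + gap), mls_mm = mls),
                 end_hour = end_hour)
}

# Simulated cohorts are cached per (n, seed) so several test files can
# share one generation run.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed, ...) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(
      sim_config(n_patients = n, seed = seed, ...))
  }
  .cohort_cache[[key]]
}

# Observation table with targets for a cached cohort.
cached_obs <- function(n, seed, horizon) {
  key <- paste0("obs_n", n, "_s", seed, "_h", horizon)
  if (is.null(.cohort_cache[[key]])) {
    co <- cached_cohort(n, seed)
    sch <- feature_schema()
    imp <- fit_imputer(co, sch)
    obs <- build_cohort_observations(co, sch, imp)
    .cohort_cache[[key]] <- attach_targets(obs, co, horizon)
  }
  .cohort_cache[[key]]
}

# Uniform draws on the probability 4-simplex (Dirichlet(1,1,1,1)).
runif_simplex <- function(n, k = 4) {
  g <- matrix(-log(runif(n * k)), n, k)
  g / rowSums(g)
}

# Independent brute-force implementation of the threshold-averaged
# weighted one-vs-rest curve areas: enumerates unique score cutoffs and
# accumulates confusion counts with plain loops. Kept deliberately
# naive and separate from the package implementation.
brute_force_ovr_areas <- function(p, targets) {
  th <- sort(unique(c(0, 1, as.vector(p))), decreasing = TRUE)
  counts <- tabulate(targets + 1L, nbins = 4)
  wsum <- sum(counts)
  tpr <- fpr <- prec <- numeric(length(th))
  for (ti in seq_along(th)) {
    t <- th[ti]
    for (c in 0:3) {
      if (counts[c + 1] == 0) next
      predpos <- p[, c + 1] >= t
      ispos <- targets == c
      tp <- sum(predpos & ispos); fp <- sum(predpos & !ispos)
      w <- counts[c + 1] / wsum
      tpr[ti] <- tpr[ti] + w * tp / sum(ispos)
      fpr[ti] <- fpr[ti] + w * fp / sum(!ispos)
      prec[ti] <- prec[ti] + w * (if (tp + fp > 0) tp / (tp + fp) else 1)
    }
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(auroc = trap(c(0, fpr, 1), c(0, tpr, 1)),
       auprc = trap(c(0, tpr), c(prec[1], prec)))
}
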