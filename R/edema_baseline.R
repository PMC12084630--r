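#' EDEMA-score feature vector for hourly observations
#'
#' The comparator model uses the eight inputs of the EDEMA risk score:
#' the static features blood glucose at admission, HbA1c at admission,
#' history of previous stroke, mechanical thrombectomy at any point
#' during the stay, and thrombolysis with tPA at any point, plus the
#' dynamic features most recent blood glucose, basal cistern effacement
#' on the most recent scan, and MLS on the most recent scan. The
#' "at any point" treatment flags are deliberately static: they are 1
#' even at hours before the treatment occurred.
#'
#' @param record a [patient_record()].
#' @param hours integer observation hours (each with >= 1 prior scan).
#' @param imputer an [fit_imputer()] result used for missing statics.
#' @return numeric matrix with 8 named columns, one row per hour.
#' @export
build_edema_features <- function(record, hours, imputer) {
  g <- record$static_features[["glucose_admission"]]
  h <- record$static_features[["hba1c_admission"]]
  ps <- record$static_features[["prior_stroke"]]
  if (is.na(g)) g <- imputer[["glucose_admission"]]
  if (is.na(h)) h <- imputer[["hba1c_admission"]]
  if (is.na(ps)) ps <- imputer[["prior_stroke"]]
  mt <- as.numeric(any(record$treatments$kind == "thrombectomy"))
  tpa <- as.numeric(any(record$treatments$kind == "thrombolysis_tpa"))
  n <- length(hours)
  glu_ff <- forward_fill(series_for(record, "glucose"), hours)
  cist_ff <- forward_fill(scan_series_for(record, "basal_cistern_effacement"),
                          hours)
  mls_ff <- forward_fill(
    data.frame(hour = record$scans$hour, value = record$scans$mls_mm), hours)
  cbind(glucose_admission = rep(g, n), hba1c_admission = rep(h, n),
        prior_stroke = rep(ps, n), thrombectomy_any = rep(mt, n),
        thrombolysis_tpa_any = rep(tpa, n),
        glucose_recent = glu_ff,
        basal_cistern_effacement_recent = cist_ff,
        mls_recent = mls_ff)
}

#' Build the EDEMA feature table for a cohort observation table
#'
#' @param obs targeted cohort observation table.
#' @param records list of [patient_record()]s.
#' @inheritParams build_edema_features
#' @return numeric matrix aligned row-by-row with `obs`.
#' @export
build_cohort_edema_features <- function(obs, records, imputer) {
  out <- matrix(NA_real_, nrow(obs), 8)
  for (id in unique(obs$patient_id)) {
    ix <- which(obs$patient_id == id)
    out[ix, ] <- build_edema_features(records[[as.character(id)]],
                                      obs$hour[ix], imputer)
  }
  colnames(out) <- c("glucose_admission", "hba1c_admission", "prior_stroke",
                     "thrombectomy_any", "thrombolysis_tpa_any",
                     "glucose_recent", "basal_cistern_effacement_recent",
                     "mls_recent")
  out
}

#' Train the EDEMA-style multinomial baseline
#'
#' A 4-class multinomial logistic regression on the eight EDEMA-score
#' inputs, retrained per cohort and task (the published score's original
#' coefficients are not reused). A small ridge penalty is applied for
#' numerical stability. Missing feature values are imputed with
#' training-split column means stored in the bundle. Fitting is
#' deterministic given the data.
#'
#' @param obs targeted cohort observation table.
#' @param records list of [patient_record()]s the observations came
#'   from.
#' @param imputer an [fit_imputer()] result.
#' @param train_ids training-side patient identifiers; default all.
#' @param lambda ridge penalty.
#' @return object of class `model_bundle` (`model_type = "edema"`).
#' @export
train_edema <- function(obs, records, imputer, train_ids = NULL,
                        lambda = 1e-3) {
  if (is.null(train_ids)) train_ids <- unique(obs$patient_id)
  E <- build_cohort_edema_features(obs, records, imputer)
  keep <- obs$valid & !is.na(obs$target_class) &
    obs$patient_id %in% train_ids
  X <- E[keep, , drop = FALSE]
  y <- as.integer(obs$target_class[keep])
  if (length(unique(y)) < 2) {
    stop("training data contain a single target class")
  }
  col_means <- colMeans(X, na.rm = TRUE)
  col_means[!is.finite(col_means)] <- 0
  X <- impute_columns(X, col_means)
  fit <- glmnet::glmnet(X, factor(y, levels = 0:3),
                        family = "multinomial", alpha = 0, lambda = lambda)
  structure(list(model_type = "edema", fit = fit,
                 feature_names = colnames(X),
                 categories = NULL, col_means = col_means,
                 lambda = lambda),
            class = "model_bundle")
}

#' Predict baseline probabilities for an observation table
#'
#' Convenience wrapper building the EDEMA features for `obs` and
#' applying the fitted baseline; the companion of [predict_proba()] for
#' the `"edema"` bundle type, which needs the raw records to build its
#' forward-filled inputs.
#'
#' @inheritParams train_edema
#' @param bundle an `"edema"` `model_bundle`.
#' @export
predict_edema <- function(bundle, obs, records, imputer) {
  stopifnot(bundle$model_type == "edema")
  E <- build_cohort_edema_features(obs, records, imputer)
  E <- impute_columns(E, bundle$col_means)
  p <- predict(bundle$fit, E, type = "response", s = bundle$lambda)[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  colnames(p) <- mls_class_labels()
  unname(p)
}
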