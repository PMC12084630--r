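#' Feature schema
#'
#' Declares the variable name lists for the three families (static,
#' dynamic EHR, human-extracted radiographic) together with the derived
#' feature naming rule: each dynamic and radiographic variable yields two
#' derived columns, `<name>_ff` (forward-fill, most recent measurement)
#' and `<name>_max24` (maximum over the previous 24 h), plus one extra
#' radiographic column `mls_prior_ff` carrying the last known MLS value
#' prior to the most recent measurement. When text features are enabled,
#' twelve forward-filled report-probability columns are appended. Every
#' derived feature carries one category tag in
#' `{static, dynamic_ehr, human_radiographic, llm_text}`.
#'
#' @param static_names,dynamic_names,radiographic_names character
#'   vectors of variable names (defaults have 33 / 16 / 36 entries, the
#'   reference cardinalities).
#' @param text_features logical; include the 12 report-probability
#'   columns.
#' @return an object of class `feature_schema` with elements
#'   `feature_names` (all model columns, in order) and `categories`
#'   (named character vector, one tag per feature).
#' @export
feature_schema <- function(static_names = default_static_names(),
                           dynamic_names = default_dynamic_names(),
                           radiographic_names = default_radiographic_names(),
                           text_features = TRUE) {
  stopifnot(!anyDuplicated(static_names), !anyDuplicated(dynamic_names),
            !anyDuplicated(radiographic_names))
  if (!"mls_mm" %in% radiographic_names) {
    stop("radiographic_names must include mls_mm")
  }
  dyn_derived <- as.vector(rbind(paste0(dynamic_names, "_ff"),
                                 paste0(dynamic_names, "_max24")))
  rad_derived <- c(as.vector(rbind(paste0(radiographic_names, "_ff"),
                                   paste0(radiographic_names, "_max24"))),
                   "mls_prior_ff")
  text_cols <- if (text_features) report_prob_names() else character()
  feats <- c(static_names, dyn_derived, rad_derived, text_cols)
  cats <- c(rep("static", length(static_names)),
            rep("dynamic_ehr", length(dyn_derived)),
            rep("human_radiographic", length(rad_derived)),
            rep("llm_text", length(text_cols)))
  names(cats) <- feats
  sch <- list(static_names = static_names, dynamic_names = dynamic_names,
              radiographic_names = radiographic_names,
              text_features = text_features,
              feature_names = feats, categories = cats)
  class(sch) <- "feature_schema"
  sch
}

#' @method print feature_schema
#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf(
    "<feature_schema: %d static, %d dynamic (%d derived), %d radiographic (%d derived), %d text; %d features total>\n",
    length(x$static_names), length(x$dynamic_names),
    2 * length(x$dynamic_names), length(x$radiographic_names),
    2 * length(x$radiographic_names) + 1,
    if (x$text_features) 12L else 0L, length(x$feature_names)))
  invisible(x)
}

#' Hourly observation grid for one patient
#'
#' Consecutive integer hours (on the last-seen-well axis) from the first
#' whole hour at or after admission until discharge, censoring at
#' decompressive hemicraniectomy (hours strictly before the surgery) and
#' truncating seven days (168 h) after admission.
#'
#' @param record a validated [patient_record()].
#' @return integer vector of hours (possibly empty).
#' @export
build_hourly_grid <- function(record) {
  start <- ceiling(record$admission_hour)
  stop_h <- min(record$end_hour, record$admission_hour + 168)
  dhc <- dhc_hour(record)
  if (is.finite(dhc)) {
    stop_h <- min(stop_h, dhc - 1e-9)
  }
  stop_h <- floor(stop_h)
  if (is.finite(dhc) && stop_h >= dhc) stop_h <- ceiling(dhc) - 1
  if (stop_h < start) return(integer(0))
  seq.int(start, stop_h)
}

#' Forward-fill a timed series onto a grid
#'
#' At each grid hour `h`, the most recent raw value with event hour
#' `<= h`; `NA` when no measurement exists yet. When several raw values
#' share an hour the latest one wins.
#'
#' @param series data.frame with columns `hour`, `value`, sorted by
#'   hour (ties kept in recording order).
#' @param grid numeric vector of query hours.
#' @return numeric vector, one value per grid hour.
#' @export
forward_fill <- function(series, grid) {
  if (!nrow(series)) return(rep(NA_real_, length(grid)))
  o <- order(series$hour)
  h <- series$hour[o]
  v <- series$value[o]
  idx <- findInterval(grid, h)
  out <- rep(NA_real_, length(grid))
  out[idx > 0] <- v[idx[idx > 0]]
  out
}

#' 24-hour rolling maximum of a timed series on a grid
#'
#' At each grid hour `h`, the maximum raw value with event hour in the
#' half-open window `(h - 24, h]`; `NA` when the window holds no
#' measurement.
#'
#' @inheritParams forward_fill
#' @export
rolling_max_24h <- function(series, grid) {
  if (!nrow(series)) return(rep(NA_real_, length(grid)))
  o <- order(series$hour)
  h <- series$hour[o]
  v <- series$value[o]
  hi <- findInterval(grid, h)                      # count of hours <= h
  lo <- findInterval(grid - 24, h)                 # count of hours <= h - 24
  out <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    if (hi[i] > lo[i]) {
      out[i] <- max(v[(lo[i] + 1):hi[i]], na.rm = TRUE)
      if (!is.finite(out[i])) out[i] <- NA_real_
    }
  }
  out
}

#' Fit the static-feature mean imputer
#'
#' Arithmetic per-feature means over the supplied (training-split)
#' patients. Fitting on the training split only avoids leaking test-set
#' statistics into the design matrix.
#'
#' @param records list of [patient_record()]s (training patients).
#' @param schema a [feature_schema()].
#' @return object of class `imputer_stats`: named numeric vector of
#'   means, one per static feature.
#' @export
fit_imputer <- function(records, schema) {
  m <- do.call(rbind, lapply(records, function(r) {
    r$static_features[schema$static_names]
  }))
  colnames(m) <- schema$static_names
  means <- colMeans(m, na.rm = TRUE)
  empty <- !is.finite(means)
  if (any(empty)) {
    stop("static feature(s) entirely missing in training data: ",
         paste(schema$static_names[empty], collapse = ", "))
  }
  structure(means, class = "imputer_stats")
}

# Long series for one variable from a record's timed-event table.
series_for <- function(record, variable) {
  s <- record$series[record$series$variable == variable, c("hour", "value")]
  s[!is.na(s$value), , drop = FALSE]
}

# Long series for one radiographic column of the scan table.
scan_series_for <- function(record, column) {
  if (!column %in% names(record$scans)) {
    return(data.frame(hour = numeric(), value = numeric()))
  }
  s <- data.frame(hour = record$scans$hour, value = record$scans[[column]])
  s[!is.na(s$value), , drop = FALSE]
}

#' Build hourly observations for one patient
#'
#' One observation per grid hour with at least one prior scan. Features
#' are the mean-imputed statics, forward-fill and 24-h rolling-max
#' transforms of every dynamic and radiographic variable, the prior-MLS
#' feature (last known MLS before the most recent measurement), and,
#' when enabled, the twelve forward-filled report-probability columns.
#' Derived dynamic/radiographic values with no measurement yet are left
#' `NA` here; model training mean-imputes them with training-split
#' column means (see [train_helmet()]).
#'
#' @param record a validated [patient_record()].
#' @param schema a [feature_schema()].
#' @param imputer an [fit_imputer()] result.
#' @param report_probs optional data.frame overriding the per-scan
#'   report probabilities (columns `hour` + the 12 probability names);
#'   by default they are read from the scan table.
#' @return data.frame with columns `patient_id`, `hour`,
#'   `current_class`, `current_mls`, then one column per schema feature;
#'   attribute `categories` carries the per-feature category tags.
#' @export
build_observations <- function(record, schema, imputer,
                               report_probs = NULL) {
  stopifnot(inherits(schema, "feature_schema"),
            inherits(imputer, "imputer_stats"))
  grid <- build_hourly_grid(record)
  if (!length(grid) || !nrow(record$scans)) {
    return(empty_observations(schema))
  }
  grid <- grid[grid >= min(record$scans$hour)]   # need a prior scan
  if (!length(grid)) return(empty_observations(schema))

  n <- length(grid)
  out <- vector("list", length(schema$feature_names))
  names(out) <- schema$feature_names

  sv <- record$static_features[schema$static_names]
  missing_feats <- setdiff(schema$static_names, names(record$static_features))
  if (length(missing_feats)) {
    stop("record lacks static feature(s): ",
         paste(missing_feats, collapse = ", "))
  }
  sv[is.na(sv)] <- imputer[is.na(sv)]
  for (f in schema$static_names) out[[f]] <- rep(unname(sv[f]), n)

  for (v in schema$dynamic_names) {
    s <- series_for(record, v)
    out[[paste0(v, "_ff")]] <- forward_fill(s, grid)
    out[[paste0(v, "_max24")]] <- rolling_max_24h(s, grid)
  }
  for (v in schema$radiographic_names) {
    s <- scan_series_for(record, v)
    out[[paste0(v, "_ff")]] <- forward_fill(s, grid)
    out[[paste0(v, "_max24")]] <- rolling_max_24h(s, grid)
  }
  # last known MLS prior to the most recent measurement
  ns <- nrow(record$scans)
  if (ns >= 2) {
    prior <- data.frame(hour = record$scans$hour[-1],
                        value = record$scans$mls_mm[-ns])
  } else {
    prior <- data.frame(hour = numeric(), value = numeric())
  }
  out[["mls_prior_ff"]] <- forward_fill(prior, grid)

  if (schema$text_features) {
    if (is.null(report_probs)) {
      pcols <- report_prob_names()
      if (!all(pcols %in% names(record$scans))) {
        stop("scan table lacks report-probability columns and no ",
             "report_probs table was supplied")
      }
      report_probs <- record$scans[, c("hour", pcols)]
    }
    for (p in report_prob_names()) {
      s <- data.frame(hour = report_probs$hour, value = report_probs[[p]])
      s <- s[!is.na(s$value), , drop = FALSE]
      out[[p]] <- forward_fill(s, grid)
    }
  }
  cur_mls <- forward_fill(
    data.frame(hour = record$scans$hour, value = record$scans$mls_mm), grid)
  obs <- data.frame(patient_id = record$patient_id, hour = grid,
                    current_class = mls_to_class(cur_mls),
                    current_mls = cur_mls)
  obs <- cbind(obs, as.data.frame(out, check.names = FALSE))
  attr(obs, "categories") <- schema$categories
  obs
}

empty_observations <- function(schema) {
  obs <- data.frame(patient_id = character(), hour = integer(),
                    current_class = integer(), current_mls = numeric())
  for (f in schema$feature_names) obs[[f]] <- numeric(0)
  attr(obs, "categories") <- schema$categories
  obs
}

#' Build the observation table for a whole cohort
#'
#' Applies [build_observations()] to every record and row-binds the
#' results, preserving the category attribute.
#'
#' @param records list of [patient_record()]s.
#' @inheritParams build_observations
#' @export
build_cohort_observations <- function(records, schema, imputer) {
  parts <- lapply(records, build_observations, schema = schema,
                  imputer = imputer)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  obs <- do.call(rbind, parts)
  rownames(obs) <- NULL
  attr(obs, "categories") <- schema$categories
  obs
}
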