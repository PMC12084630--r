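#' Midline-shift severity classes
#'
#' Midline shift (MLS) of the septum pellucidum, in millimetres, is binned
#' into four ordinal severity classes: no shift (0 mm), mild (0-3 mm),
#' moderate (3-8 mm), and severe (>8 mm). Boundary values belong to the
#' lower class, so 3 mm is "0-3mm" and 8 mm is "3-8mm"; only values
#' strictly exceeding 8 mm are ">8mm".
#'
#' @param mls_mm numeric vector of non-negative, finite MLS measurements
#'   in millimetres.
#' @return `mls_to_class` returns an integer vector of class codes in
#'   0:3; `mls_class_labels` returns the four class labels in code order.
#' @examples
#' mls_to_class(c(0, 2.5, 5, 10))
#' mls_class_labels()
#' @export
mls_to_class <- function(mls_mm) {
  if (!is.numeric(mls_mm)) {
    stop("mls_mm must be numeric")
  }
  bad <- !is.na(mls_mm) & (!is.finite(mls_mm) | mls_mm < 0)
  if (any(bad)) {
    stop("mls_mm must be finite and >= 0 (got ",
         paste(utils::head(mls_mm[bad], 3), collapse = ", "), ")")
  }
  out <- integer(length(mls_mm))
  out[mls_mm > 0] <- 1L
  out[mls_mm > 3] <- 2L
  out[mls_mm > 8] <- 3L
  out[is.na(mls_mm)] <- NA_integer_
  out
}

#' @rdname mls_to_class
#' @export
mls_class_labels <- function() {
  c("0mm", "0-3mm", "3-8mm", ">8mm")
}

#' Reference variable name lists
#'
#' Default name lists for the three variable families used throughout the
#' package: 33 static admission features, 16 dynamic EHR variables, and 36
#' human-extracted radiographic variables. The cardinalities match the
#' reference feature set; the exact membership is configurable wherever a
#' schema is accepted. Race and ethnicity are deliberately excluded from
#' the static feature list.
#'
#' @return character vector of variable names.
#' @export
default_static_names <- function() {
  c("age", "sex_female", "nihss_admission", "aspects_admission",
    "prior_stroke", "history_hypertension", "history_atrial_fibrillation",
    "history_diabetes", "anticoagulant_use", "antiplatelet_use",
    "sbp_admission", "dbp_admission", "map_admission",
    "heart_rate_admission", "temperature_admission",
    "respiratory_rate_admission", "spo2_admission", "wbc_admission",
    "glucose_admission", "hba1c_admission", "sodium_admission",
    "potassium_admission", "creatinine_admission", "bun_admission",
    "osmolality_admission", "hemoglobin_admission", "platelets_admission",
    "inr_admission", "admission_hour_lsw", "left_hemisphere_stroke",
    "vessel_occlusion_grade", "history_dyslipidemia", "history_smoking")
}

#' @rdname default_static_names
#' @export
default_dynamic_names <- function() {
  c("glucose", "wbc", "sodium", "potassium", "creatinine", "bun",
    "osmolality", "temperature", "heart_rate", "sbp", "dbp", "map",
    "spo2", "respiratory_rate", "gcs", "osmotic_therapy")
}

#' @rdname default_static_names
#' @export
default_radiographic_names <- function() {
  c("mls_mm", "pineal_shift_mm", "basal_cistern_effacement",
    "sulcal_effacement", "ventricle_compression", "uncal_herniation",
    "hydrocephalus", "petechial_hemorrhage", "parenchymal_hemorrhage",
    "hemorrhagic_transformation", "infarct_fraction_mca",
    "aca_involvement", "pca_involvement", "insular_involvement",
    "basal_ganglia_involvement", "aspects_followup", "collateral_score",
    "cerebral_atrophy_grade", "edema_extent_score",
    "gray_white_differentiation_loss", "mass_effect_grade",
    "midline_shift_present", "mls_over_3mm", "mls_over_5mm",
    "mls_over_8mm", "hours_since_prior_scan", "mls_change_from_prior",
    "first_mls_value", "first_mls_hour", "first_mls_over_3mm_hour",
    "first_mls_over_5mm_hour", "max_mls_to_date",
    "pineal_shift_change_from_prior", "contralateral_ventricle_dilation",
    "cistern_effacement_grade", "scan_hour_lsw")
}

#' Treatment vocabulary
#'
#' Treatment kinds recognised in the timed treatment table. Decompressive
#' hemicraniectomy (`"hemicraniectomy"`) censors all later data.
#' @return character vector of treatment kinds.
#' @export
treatment_kinds <- function() {
  c("osmotic_mannitol", "osmotic_hypertonic_3", "osmotic_hypertonic_23.4",
    "thrombolysis_tpa", "thrombectomy", "hemicraniectomy")
}

report_prob_names <- function() {
  as.vector(t(outer(c(8, 24, 36), 0:3,
                    function(w, k) sprintf("p%d_class%d", w, k))))
}

#' Construct a patient record
#'
#' Bundles one hospitalization: a static profile, a long table of timed
#' dynamic measurements, a time-sorted scan table of human-extracted
#' radiographic variables (plus optional per-scan report text or report
#' class probabilities), timed treatments, and a discharge/censoring hour.
#' All hours are measured from the time the patient was last seen well
#' (LSW).
#'
#' @param patient_id opaque identifier (character or coercible).
#' @param admission_hour hours from last-seen-well to presentation; must
#'   lie in [0, 24].
#' @param static_features named numeric vector of static features (NA =
#'   missing).
#' @param series data.frame with columns `variable`, `hour`, `value`
#'   (long format timed measurements).
#' @param scans data.frame with column `hour` plus radiographic variable
#'   columns (at minimum `mls_mm`); optional `report_text` and the twelve
#'   `p{8,24,36}_class{0..3}` report-probability columns.
#' @param treatments data.frame with columns `hour`, `kind`.
#' @param end_hour discharge or censoring hour (from LSW).
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, admission_hour, static_features,
                           series = NULL, scans = NULL, treatments = NULL,
                           end_hour) {
  if (is.null(series)) {
    series <- data.frame(variable = character(), hour = numeric(),
                         value = numeric())
  }
  if (is.null(scans)) {
    scans <- data.frame(hour = numeric(), mls_mm = numeric())
  }
  if (is.null(treatments)) {
    treatments <- data.frame(hour = numeric(), kind = character())
  }
  rec <- list(
    patient_id = as.character(patient_id),
    admission_hour = as.numeric(admission_hour),
    static_features = static_features,
    series = series,
    scans = scans,
    treatments = treatments,
    end_hour = as.numeric(end_hour)
  )
  class(rec) <- "patient_record"
  rec
}

#' @method print patient_record
#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record %s: admission %.1f h, %d scans, %d timed values, %d treatments, end %.1f h>\n",
    x$patient_id, x$admission_hour, nrow(x$scans), nrow(x$series),
    nrow(x$treatments), x$end_hour))
  invisible(x)
}

#' Validate a patient record
#'
#' Checks the structural invariants of a [patient_record()] and returns a
#' character vector of violations (empty when the record conforms).
#' Violations are returned rather than thrown so that a whole cohort can
#' be screened in one pass.
#'
#' Checked rules: admission within 24 h of last-seen-well; non-negative
#' event hours; scans sorted strictly increasing in hour; finite,
#' non-negative MLS; end hour at or after the last retained event; unique
#' static feature names; treatments drawn from the declared vocabulary.
#'
#' @param record a [patient_record()].
#' @return character vector of human-readable violations.
#' @export
validate_patient <- function(record) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(record, "patient_record")) {
    return("not a patient_record object")
  }
  if (is.na(record$admission_hour) || record$admission_hour < 0 ||
      record$admission_hour > 24) {
    add(sprintf("admission_hour: admission within 24 h of last-seen-well violated (got %s)",
                format(record$admission_hour)))
  }
  nm <- names(record$static_features)
  if (length(nm) && anyDuplicated(nm)) {
    add("static_features: duplicated feature names")
  }
  if (length(nm) && any(grepl("^race|^ethnic", nm, ignore.case = TRUE))) {
    add("static_features: race/ethnicity must not be model features")
  }
  if (nrow(record$series)) {
    if (any(record$series$hour < 0, na.rm = TRUE)) {
      add("series: event hour < 0")
    }
  }
  if (nrow(record$scans)) {
    h <- record$scans$hour
    if (any(is.na(h)) || any(h < 0)) add("scans: scan hour missing or < 0")
    if (is.unsorted(h, strictly = TRUE)) {
      add("scans: scan ordering not strictly increasing in hour")
    }
    m <- record$scans$mls_mm
    if (any(is.na(m)) || any(!is.finite(m)) || any(m < 0)) {
      add("scans: mls_mm must be finite and >= 0")
    }
  }
  if (nrow(record$treatments)) {
    if (any(record$treatments$hour < 0, na.rm = TRUE)) {
      add("treatments: event hour < 0")
    }
    unknown <- setdiff(unique(record$treatments$kind), treatment_kinds())
    if (length(unknown)) {
      add(sprintf("treatments: unknown kind(s) %s",
                  paste(unknown, collapse = ", ")))
    }
  }
  max_event <- suppressWarnings(max(c(record$scans$hour, record$series$hour,
                                      record$treatments$hour, -Inf),
                                    na.rm = TRUE))
  if (is.finite(max_event) && record$end_hour < max_event) {
    add(sprintf("end_hour: end_hour (%.1f) precedes last event (%.1f)",
                record$end_hour, max_event))
  }
  v
}

dhc_hour <- function(record) {
  h <- record$treatments$hour[record$treatments$kind == "hemicraniectomy"]
  if (length(h)) min(h) else Inf
}

#' Read and write a cohort as delimited text
#'
#' A cohort is stored as four UTF-8 CSV files with header rows and empty
#' fields for missing values: `statics.csv` (one row per patient with
#' `patient_id`, `admission_hour`, `end_hour` and the static features),
#' `events.csv` (long format: `patient_id`, `variable`, `hour`, `value`),
#' `scans.csv` (`patient_id`, `hour`, radiographic columns, optional
#' report-probability columns), and `treatments.csv` (`patient_id`,
#' `hour`, `kind`).
#'
#' @param records list of [patient_record()] objects.
#' @param dir directory to write to / read from (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   a named list of `patient_record`s.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stat_rows <- lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, admission_hour = r$admission_hour,
               end_hour = r$end_hour, t(r$static_features),
               check.names = FALSE)
  })
  statics <- do.call(rbind, stat_rows)
  bind_with_id <- function(field) {
    parts <- lapply(records, function(r) {
      df <- r[[field]]
      if (!nrow(df)) return(NULL)
      cbind(data.frame(patient_id = r$patient_id), df)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(NULL)
    do.call(rbind, parts)
  }
  events <- bind_with_id("series")
  scans <- bind_with_id("scans")
  treatments <- bind_with_id("treatments")
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), variable = character(),
                         hour = numeric(), value = numeric())
  }
  if (is.null(scans)) {
    scans <- data.frame(patient_id = character(), hour = numeric(),
                        mls_mm = numeric())
  }
  if (is.null(treatments)) {
    treatments <- data.frame(patient_id = character(), hour = numeric(),
                             kind = character())
  }
  utils::write.csv(statics, file.path(dir, "statics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(events, file.path(dir, "events.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(scans, file.path(dir, "scans.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(treatments, file.path(dir, "treatments.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE,
                                    na.strings = "",
                                    stringsAsFactors = FALSE)
  statics <- rd("statics.csv")
  events <- rd("events.csv")
  scans <- rd("scans.csv")
  treatments <- rd("treatments.csv")
  ids <- as.character(statics$patient_id)
  feat_cols <- setdiff(names(statics),
                       c("patient_id", "admission_hour", "end_hour"))
  records <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    sf <- as.numeric(statics[i, feat_cols])
    names(sf) <- feat_cols
    ev <- events[as.character(events$patient_id) == id,
                 setdiff(names(events), "patient_id"), drop = FALSE]
    ev$hour <- as.numeric(ev$hour)
    ev$value <- as.numeric(ev$value)
    sc <- scans[as.character(scans$patient_id) == id,
                setdiff(names(scans), "patient_id"), drop = FALSE]
    sc <- sc[order(sc$hour), , drop = FALSE]
    for (cl in names(sc)) sc[[cl]] <- as.numeric(sc[[cl]])
    tr <- treatments[as.character(treatments$patient_id) == id,
                     setdiff(names(treatments), "patient_id"), drop = FALSE]
    tr$hour <- as.numeric(tr$hour)
    rownames(ev) <- rownames(sc) <- rownames(tr) <- NULL
    patient_record(id, statics$admission_hour[i], sf, ev, sc, tr,
                   statics$end_hour[i])
  })
  names(records) <- ids
  records
}
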