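#' Crop a radiology report to its Findings and Impression sections
#'
#' Reports from different hospitals share the "Findings" and
#' "Impression" sections, so only those are retained (matched
#' case-insensitively, in either order). If neither header is present
#' the whole text is returned with a warning.
#'
#' @param report_text a single non-empty report string.
#' @return the cropped text.
#' @export
extract_sections <- function(report_text) {
  if (!is.character(report_text) || length(report_text) != 1 ||
      is.na(report_text) || !nzchar(trimws(report_text))) {
    stop("report_text must be a non-empty string")
  }
  headers <- c("findings", "impression", "technique", "comparison",
               "indication", "history", "clinical information",
               "examination", "procedure")
  pat <- paste0("(?i)\\b(", paste(headers, collapse = "|"), ")\\s*:")
  mm <- gregexpr(pat, report_text, perl = TRUE)
  m <- mm[[1]]
  if (m[1] == -1) {
    warning("no Findings/Impression headers found; returning full text")
    return(report_text)
  }
  starts <- as.integer(m)
  labs <- tolower(gsub("\\s*:$", "",
                       regmatches(report_text, mm)[[1]]))
  ends <- c(starts[-1] - 1, nchar(report_text))
  keep <- labs %in% c("findings", "impression")
  if (!any(keep)) {
    warning("no Findings/Impression headers found; returning full text")
    return(report_text)
  }
  sections <- substring(report_text, starts[keep], ends[keep])
  paste(trimws(sections), collapse = "\n")
}

tokenize_report <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Sparse document-term count matrix over a fixed vocabulary.
dtm <- function(texts, vocab = NULL) {
  tok_list <- lapply(texts, tokenize_report)
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(tok_list)))
  }
  ii <- jj <- xx <- integer(0)
  for (d in seq_along(tok_list)) {
    tt <- table(factor(tok_list[[d]], levels = vocab))
    nz <- which(tt > 0)
    ii <- c(ii, rep(d, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, as.integer(tt[nz]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(texts), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Fit desk-scale stand-in report classifiers
#'
#' Fits one 4-class probabilistic classifier per prediction horizon (8,
#' 24 and 36 h) mapping cropped report text to the future window-maximum
#' MLS class. The classifier is a ridge-regularized multinomial logistic
#' regression on token counts: deterministic, probabilistic, and
#' swappable for any adapter honouring the same interface (e.g. a
#' fine-tuned clinical transformer; a typical adapter configuration is
#' six epochs at an initial learning rate of 2e-5).
#'
#' Texts are split 80/20 at the patient level; the held-out argmax
#' accuracy per horizon is stored on the returned object.
#'
#' @param texts character vector of cropped report texts (one per scan).
#' @param targets data.frame / list with integer class columns `h8`,
#'   `h24`, `h36` (codes 0:3, NA allowed; NA rows are dropped per
#'   horizon).
#' @param patient_ids identifier per text, used for the patient-level
#'   split.
#' @param seed integer seed (controls the split only; fitting is
#'   deterministic).
#' @param lambda ridge penalty passed to [glmnet::glmnet()].
#' @return object of class `standin_text_model` with one fitted model
#'   per horizon and `holdout_accuracy`.
#' @export
fit_standin_classifier <- function(texts, targets, patient_ids, seed,
                                   lambda = 0.05) {
  stopifnot(length(texts) == length(patient_ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pats <- unique(patient_ids)
  test_pats <- sample(pats, max(1, floor(0.2 * length(pats))))
  is_test <- patient_ids %in% test_pats
  X <- dtm(texts)
  vocab <- colnames(X)
  models <- list()
  acc <- c(h8 = NA_real_, h24 = NA_real_, h36 = NA_real_)
  for (hz in c("h8", "h24", "h36")) {
    y <- targets[[hz]]
    tr <- !is_test & !is.na(y)
    if (length(unique(y[tr])) < 2) {
      stop("training targets for horizon ", hz, " contain a single class")
    }
    fit <- glmnet::glmnet(X[tr, , drop = FALSE],
                          factor(y[tr], levels = 0:3),
                          family = "multinomial", alpha = 0,
                          lambda = lambda)
    models[[hz]] <- fit
    te <- is_test & !is.na(y)
    if (any(te)) {
      p <- predict(fit, X[te, , drop = FALSE], type = "response",
                   s = lambda)[, , 1]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      acc[hz] <- mean(max.col(p, ties.method = "first") - 1 == y[te])
    }
  }
  structure(list(models = models, vocab = vocab, lambda = lambda,
                 holdout_accuracy = acc),
            class = "standin_text_model")
}

#' Predict report class probabilities
#'
#' Produces the twelve report-probability features (4 classes x 3
#' horizons) per scan, either by applying stand-in classifiers to report
#' texts or by validating and passing through precomputed probabilities.
#' Each horizon's 4-vector must lie on the probability simplex (within
#' 1e-9).
#'
#' @param scans data.frame with a `hour` column and either a
#'   `report_text` column (classifier path) or the 12 precomputed
#'   probability columns (pass-through path).
#' @param classifiers a `standin_text_model`, required for the text
#'   path.
#' @return data.frame: `hour` plus the 12 named probability columns.
#' @export
report_probability_features <- function(scans, classifiers = NULL) {
  pcols <- report_prob_names()
  if (all(pcols %in% names(scans))) {
    P <- as.matrix(scans[, pcols])
    for (b in seq(1, 12, by = 4)) {
      block <- P[, b:(b + 3), drop = FALSE]
      if (any(block < 0, na.rm = TRUE) ||
          any(abs(rowSums(block) - 1) > 1e-9, na.rm = TRUE)) {
        stop("precomputed report probabilities are not on the simplex")
      }
    }
    return(cbind(data.frame(hour = scans$hour), as.data.frame(P)))
  }
  if (!"report_text" %in% names(scans)) {
    stop("scans carry neither report_text nor precomputed probabilities")
  }
  if (is.null(classifiers) || !inherits(classifiers, "standin_text_model")) {
    stop("classifier path requires a fitted standin_text_model")
  }
  if (any(is.na(scans$report_text) | !nzchar(scans$report_text))) {
    stop("scan with empty report_text while text features are enabled")
  }
  X <- dtm(vapply(scans$report_text, extract_sections, character(1)),
           vocab = classifiers$vocab)
  out <- data.frame(hour = scans$hour)
  for (hz in c("h8", "h24", "h36")) {
    p <- predict(classifiers$models[[hz]], X, type = "response",
                 s = classifiers$lambda)[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    w <- as.integer(sub("h", "", hz))
    colnames(p) <- sprintf("p%d_class%d", w, 0:3)
    out <- cbind(out, as.data.frame(p))
  }
  out[, c("hour", pcols)]
}
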