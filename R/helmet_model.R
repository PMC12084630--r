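#' Transition-weighted multiclass cross-entropy
#'
#' The HELMET training loss: plain categorical cross-entropy on
#' transition ("filtered") observations plus `w` times the
#' cross-entropy of non-transition observations,
#' \deqn{L(y,p) = -\sum_{i \in F} \sum_c y_{ic} \log p_{ic}
#'   - w \sum_{i \in NF} \sum_c y_{ic} \log p_{ic},}
#' with per-observation weight `u_i = 1` if filtered else `w`. The loss
#' is affine in `w` with slope equal to the non-filtered subset's
#' cross-entropy; `w = 1` recovers the unweighted loss. Probabilities
#' are clipped at 1e-12 inside the logarithm so a zero probability on
#' the true class never yields an infinite loss.
#'
#' Also returns the boosted-softmax derivative contract used during
#' training: gradient `u_i (p_ic - y_ic)` and curvature
#' `2 u_i p_ic (1 - p_ic)` with respect to the class margins (the
#' factor 2 matches the scaling of the standard softmax objective in
#' gradient-boosting libraries, so `w = 1` training coincides exactly
#' with the builtin multiclass log-loss).
#'
#' @param p numeric matrix (n x 4) of predicted class probabilities,
#'   rows on the simplex.
#' @param y integer class codes (0:3) or a one-hot matrix.
#' @param filtered logical vector: TRUE for transition observations.
#' @param w non-filtered weight, in (0, 1].
#' @return list with `loss` (scalar value of the loss), `weights`
#'   (`u_i`), `grad` and `hess` (n x 4 matrices).
#' @export
weighted_xent <- function(p, y, filtered, w) {
  if (!(is.numeric(w) && length(w) == 1 && w > 0 && w <= 1)) {
    stop("w must lie in (0, 1]")
  }
  if (is.matrix(y)) {
    Y <- y
  } else {
    Y <- matrix(0, nrow(p), ncol(p))
    Y[cbind(seq_len(nrow(p)), as.integer(y) + 1L)] <- 1
  }
  stopifnot(nrow(Y) == nrow(p), length(filtered) == nrow(p))
  if (any(abs(rowSums(p) - 1) > 1e-6) || any(p < -1e-9)) {
    stop("rows of p must lie on the probability simplex")
  }
  u <- ifelse(filtered, 1, w)
  pc <- pmax(p, 1e-12)
  loss <- -sum(u * rowSums(Y * log(pc)))
  list(loss = loss, weights = u,
       grad = u * (p - Y),
       hess = 2 * u * p * (1 - p))
}

#' Patient-level five-fold split plan
#'
#' Five independent seeded 80/20 partitions of the patient identifiers.
#' Splitting at the patient level guarantees that no patient contributes
#' observations to both sides of any split.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param seed integer seed.
#' @param n_splits number of independent partitions (default 5).
#' @param test_fraction fraction of patients on the test side.
#' @return object of class `split_plan`: a list of
#'   `list(train =, test =)` id vectors.
#' @export
make_splits <- function(patient_ids, seed, n_splits = 5,
                        test_fraction = 0.2) {
  patient_ids <- unique(as.character(patient_ids))
  if (length(patient_ids) < n_splits) {
    stop("need at least ", n_splits, " patients")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_test <- max(1, floor(test_fraction * length(patient_ids)))
  plan <- lapply(seq_len(n_splits), function(k) {
    test <- sample(patient_ids, n_test)
    list(train = setdiff(patient_ids, test), test = test)
  })
  structure(plan, class = "split_plan", seed = seed)
}

#' HELMET hyperparameters
#'
#' @param w non-filtered observation weight in (0, 1]; down-weights
#'   hours whose target class equals the current class so the boosted
#'   trees concentrate on transitions.
#' @param nrounds,max_depth,eta,subsample,colsample_bytree,min_child_weight
#'   gradient-boosting parameters.
#' @param seed integer seed for tree construction.
#' @export
helmet_hyperparams <- function(w = 0.5, nrounds = 150, max_depth = 4,
                               eta = 0.1, subsample = 0.8,
                               colsample_bytree = 0.8,
                               min_child_weight = 1, seed = 1L) {
  stopifnot(w > 0, w <= 1, nrounds >= 1, max_depth >= 1, eta > 0)
  structure(list(w = w, nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 min_child_weight = min_child_weight,
                 seed = as.integer(seed)),
            class = "helmet_hyperparams")
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Design matrix + targets from a targeted observation table: valid rows
# only, feature columns in schema order.
model_frame <- function(obs, feature_names) {
  keep <- which(obs$valid & !is.na(obs$target_class))
  missing_cols <- setdiff(feature_names, names(obs))
  if (length(missing_cols)) {
    stop("observation table lacks feature column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X <- as.matrix(obs[keep, feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(obs$target_class[keep]),
       filtered = as.logical(obs$filtered[keep]),
       current_class = as.integer(obs$current_class[keep]),
       patient_id = as.character(obs$patient_id[keep]),
       rows = keep)
}

impute_columns <- function(X, col_means) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- col_means[j]
  }
  X
}

#' Train a HELMET model
#'
#' Fits a 4-class gradient-boosted tree ensemble minimizing the
#' transition-weighted cross-entropy (see [weighted_xent()]) on the
#' valid observations of the training-split patients. Derived feature
#' columns are mean-imputed with training-split column means (stored in
#' the bundle and re-applied at prediction time). Training is
#' single-threaded and seeded, hence fully reproducible.
#'
#' @param obs targeted cohort observation table (see
#'   [attach_targets()]).
#' @param hp a [helmet_hyperparams()].
#' @param train_ids patient identifiers of the training side; default
#'   all patients.
#' @param feature_names model feature columns; default: the schema
#'   categories attached to `obs`.
#' @return object of class `model_bundle` (`model_type = "helmet"`).
#' @export
train_helmet <- function(obs, hp, train_ids = NULL, feature_names = NULL) {
  stopifnot(inherits(hp, "helmet_hyperparams"))
  cats <- attr(obs, "categories")
  if (is.null(feature_names)) feature_names <- names(cats)
  if (is.null(train_ids)) train_ids <- unique(obs$patient_id)
  mf <- model_frame(obs[obs$patient_id %in% train_ids, , drop = FALSE],
                    feature_names)
  if (length(unique(mf$y)) < 2) {
    stop("training data contain a single target class")
  }
  col_means <- colMeans(mf$X, na.rm = TRUE)
  col_means[!is.finite(col_means)] <- 0
  X <- impute_columns(mf$X, col_means)
  filtered <- mf$filtered
  w <- hp$w
  dtrain <- xgboost::xgb.DMatrix(X, label = mf$y, nthread = 1)
  obj <- function(preds, dtrain) {
    y <- xgboost::getinfo(dtrain, "label")
    p <- softmax_rows(preds)
    wx <- weighted_xent(p, y, filtered, w)
    list(grad = wx$grad, hess = wx$hess)
  }
  params <- list(num_class = 4, max_depth = hp$max_depth, eta = hp$eta,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 nthread = 1, seed = hp$seed,
                 disable_default_eval_metric = 1)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$nrounds, obj = obj,
                                verbose = 0)
  structure(list(model_type = "helmet", booster = booster,
                 feature_names = feature_names,
                 categories = cats[feature_names],
                 col_means = col_means, hp = hp),
            class = "model_bundle")
}

#' @method print model_bundle
#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle %s: %d features>\n", x$model_type,
              length(x$feature_names)))
  invisible(x)
}

#' Predict class probabilities from a model bundle
#'
#' @param bundle a `model_bundle` from [train_helmet()] or
#'   [train_edema()].
#' @param obs observation table containing the bundle's feature columns.
#' @return numeric matrix (n x 4) of class probabilities; rows sum to 1.
#'   Argmax ties break to the lowest class code.
#' @export
predict_proba <- function(bundle, obs) {
  stopifnot(inherits(bundle, "model_bundle"))
  missing_cols <- setdiff(bundle$feature_names, names(obs))
  if (length(missing_cols)) {
    stop("schema mismatch: observation table lacks ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X <- as.matrix(obs[, bundle$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X <- impute_columns(X, bundle$col_means)
  if (bundle$model_type == "helmet") {
    m <- predict(bundle$booster, xgboost::xgb.DMatrix(X, nthread = 1),
                 outputmargin = TRUE)
    p <- softmax_rows(m)
  } else {
    p <- predict(bundle$fit, X, type = "response",
                 s = bundle$lambda)[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  }
  colnames(p) <- mls_class_labels()
  unname(p)
}

#' Argmax class from a probability matrix (ties to the lowest code)
#' @param p numeric matrix of class probabilities.
#' @return integer class codes 0:3.
#' @export
argmax_class <- function(p) {
  max.col(p, ties.method = "first") - 1L
}

#' Random-search tuning of w and boosting parameters
#'
#' Seeded random search over the hyperparameter space, scored by
#' filtered AUROC on an inner patient-level 80/20 validation split of
#' the training patients (the tuning objective of the framework). If
#' the inner validation split contains no transition observations the
#' search falls back to overall AUROC with a warning.
#'
#' @param obs targeted observation table.
#' @param train_ids training-side patient identifiers.
#' @param budget number of random candidates to evaluate.
#' @param seed integer seed for candidate sampling and the inner split.
#' @param space named list of samplers, each a `function(n)` returning
#'   `n` values; defaults cover `w`, `eta`, `max_depth`, `nrounds`,
#'   `subsample`, `colsample_bytree`.
#' @return the winning [helmet_hyperparams()], with the search trace in
#'   attribute `"trace"`.
#' @export
tune_w_and_params <- function(obs, train_ids, budget = 8, seed = 1,
                              space = NULL) {
  stopifnot(budget >= 1)
  if (is.null(space)) {
    space <- list(
      w = function(n) stats::runif(n, 0.1, 1),
      eta = function(n) stats::runif(n, 0.05, 0.3),
      max_depth = function(n) sample(3:6, n, replace = TRUE),
      nrounds = function(n) sample(c(60L, 100L, 150L), n, replace = TRUE),
      subsample = function(n) stats::runif(n, 0.6, 1),
      colsample_bytree = function(n) stats::runif(n, 0.6, 1)
    )
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cand <- as.data.frame(lapply(space, function(f) f(budget)))
  inner_val <- sample(train_ids, max(1, floor(0.2 * length(train_ids))))
  inner_train <- setdiff(train_ids, inner_val)
  val_obs <- obs[obs$patient_id %in% inner_val & obs$valid, , drop = FALSE]
  has_filtered <- any(val_obs$filtered, na.rm = TRUE)
  if (!has_filtered) {
    warning("inner validation split has no transition observations; ",
            "tuning on overall AUROC instead of filtered AUROC")
  }
  trace <- cand
  trace$score <- NA_real_
  for (k in seq_len(budget)) {
    hp <- helmet_hyperparams(w = cand$w[k], nrounds = cand$nrounds[k],
                             max_depth = cand$max_depth[k],
                             eta = cand$eta[k],
                             subsample = cand$subsample[k],
                             colsample_bytree = cand$colsample_bytree[k],
                             seed = seed)
    bundle <- train_helmet(obs, hp, inner_train)
    sub <- if (has_filtered) {
      val_obs[val_obs$filtered %in% TRUE, , drop = FALSE]
    } else {
      val_obs
    }
    p <- predict_proba(bundle, sub)
    cv <- weighted_ovr_curves(p, sub$target_class)
    trace$score[k] <- cv$auroc
  }
  best <- which.max(trace$score)
  hp <- helmet_hyperparams(w = cand$w[best], nrounds = cand$nrounds[best],
                           max_depth = cand$max_depth[best],
                           eta = cand$eta[best],
                           subsample = cand$subsample[best],
                           colsample_bytree = cand$colsample_bytree[best],
                           seed = seed)
  attr(hp, "trace") <- trace
  hp
}
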