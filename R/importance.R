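#' Per-class Shapley attributions of a trained HELMET model
#'
#' Tree-path-dependent exact Shapley values of the boosted ensemble:
#' for every observation, feature and target class, the additive
#' contribution (on the margin scale) of that feature to the class
#' margin. Attributions satisfy local accuracy: the per-class base
#' value plus the feature contributions reconstructs the model's margin
#' output.
#'
#' @param bundle a `"helmet"` [train_helmet()] bundle.
#' @param obs observation table with the bundle's feature columns.
#' @return list with `values` (n x 4 x n_features array), `base`
#'   (n x 4 matrix of base values), `feature_names`, `categories`, and
#'   `current_class` (copied from `obs` when present, for
#'   stratification).
#' @export
shapley_values <- function(bundle, obs) {
  stopifnot(inherits(bundle, "model_bundle"),
            bundle$model_type == "helmet")
  missing_cols <- setdiff(bundle$feature_names, names(obs))
  if (length(missing_cols)) {
    stop("schema mismatch: observation table lacks ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X <- as.matrix(obs[, bundle$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X <- impute_columns(X, bundle$col_means)
  contrib <- predict(bundle$booster, xgboost::xgb.DMatrix(X, nthread = 1),
                     predcontrib = TRUE)
  nf <- length(bundle$feature_names)
  # last slice per class is the bias term
  vals <- contrib[, , seq_len(nf), drop = FALSE]
  base <- contrib[, , nf + 1]
  dimnames(vals) <- list(NULL, mls_class_labels(), bundle$feature_names)
  list(values = vals, base = base,
       feature_names = bundle$feature_names,
       categories = bundle$categories,
       current_class = obs$current_class)
}

#' Rank features and compose category proportions
#'
#' Aggregates per-class Shapley attributions into a single importance
#' score per feature - the mean absolute attribution over observations,
#' summed over the four classes - and reports, per stratum of the most
#' recent prior MLS class, the composition of the top-`k` features by
#' feature category (the four families: report-text probabilities,
#' human-extracted radiographic features, dynamic EHR variables, static
#' characteristics).
#'
#' @param shap result of [shapley_values()].
#' @param top_k number of top-ranked features per stratum (default 20).
#' @param by_current_class stratify by the observation's current MLS
#'   class (default TRUE); otherwise a single `"all"` stratum is used.
#' @return list with `ranking` (data.frame feature / category / score /
#'   rank over all observations) and `composition` (data.frame stratum /
#'   category / proportion; proportions sum to 1 within stratum).
#' @export
rank_and_compose <- function(shap, top_k = 20, by_current_class = TRUE) {
  cats <- shap$categories
  if (is.null(cats) || any(!shap$feature_names %in% names(cats))) {
    stop("every feature needs a category tag")
  }
  score_for <- function(rows) {
    v <- shap$values[rows, , , drop = FALSE]
    apply(abs(v), 3, mean) * 4   # mean |value| over obs, summed over classes
  }
  all_scores <- score_for(seq_len(dim(shap$values)[1]))
  ranking <- data.frame(feature = shap$feature_names,
                        category = unname(cats[shap$feature_names]),
                        score = unname(all_scores))
  ranking <- ranking[order(-ranking$score), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  k <- as.integer(min(top_k, nrow(ranking)))
  if (k < top_k) {
    warning("top_k exceeds the number of features; using all ", k)
  }
  strata <- if (by_current_class && !is.null(shap$current_class)) {
    split(seq_len(dim(shap$values)[1]), shap$current_class)
  } else {
    list(all = seq_len(dim(shap$values)[1]))
  }
  comp <- list()
  for (s in names(strata)) {
    sc <- score_for(strata[[s]])
    top <- names(sort(sc, decreasing = TRUE))[seq_len(k)]
    tb <- table(factor(cats[top],
                       levels = c("llm_text", "human_radiographic",
                                  "dynamic_ehr", "static")))
    comp[[s]] <- data.frame(stratum = s, category = names(tb),
                            proportion = as.numeric(tb) / k)
  }
  composition <- do.call(rbind, comp)
  rownames(composition) <- NULL
  list(ranking = ranking, composition = composition, top_k = k)
}
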