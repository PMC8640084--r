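# Attribution of the tuned tree ensemble: per-observation additive
# (SHAP-style) feature attributions from the xgboost TreeSHAP
# implementation, top-k ranking, and grouping by feature family, sensor and
# frequency band. This module owns only ranking, grouping and
# serialization; the attribution computation itself is delegated to the
# tree library.

#' Per-feature attribution summary for a tree ensemble
#'
#' Computes exact per-observation additive attributions (TreeSHAP) on the
#' given rows, ranks features by mean absolute attribution, and retains the
#' signed per-observation values. Positive values indicate contribution
#' toward the hit label. Attributions plus the base value reproduce the
#' model margin for every observation (additivity).
#'
#' @param model a `tuned_model` (tree ensemble)
#' @param features standardized feature matrix
#' @param idx observation row indices (the validation set in the reference
#'   flow)
#' @param k ranking length (the full ranking is returned when `k` exceeds
#'   the number of features)
#' @return an object of class `attribution_summary`: `shap` (observations x
#'   features), `base_value`, `ranking` (data.frame `feature`, `mean_abs`,
#'   `mean_signed`, `hit_mass`), `top` (first `k` rows), `additivity_error`
#'   (max over observations of |sum(attributions) + base - margin|)
#' @export
attribution_summary <- function(model, features, idx, k = 50) {
  if (!inherits(model, "tuned_model") ||
      !inherits(model$booster, "xgb.Booster"))
    stop("attribution requires a tree-ensemble (xgboost) model")
  if (length(idx) == 0) stop("no observations to attribute")
  X <- features[idx, , drop = FALSE]
  dm <- xgboost::xgb.DMatrix(X)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  colnames(contrib) <- c(colnames(X), "BIAS")
  margin <- predict(model$booster, dm, outputmargin = TRUE)
  add_err <- max(abs(rowSums(contrib) - margin))
  shap <- contrib[, colnames(X), drop = FALSE]
  base <- contrib[1, "BIAS"]
  mean_abs <- colMeans(abs(shap))
  ranking <- data.frame(
    feature = colnames(shap),
    mean_abs = mean_abs,
    mean_signed = colMeans(shap),
    hit_mass = colMeans(pmax(shap, 0)),  # mass pushing toward "hit"
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs), ]
  rownames(ranking) <- NULL
  structure(list(shap = shap, base_value = base, ranking = ranking,
                 top = head(ranking, min(k, nrow(ranking))),
                 k = as.integer(k), additivity_error = add_err),
            class = "attribution_summary")
}

#' Aggregate attributions by feature group
#'
#' Sums per-feature mean absolute attribution (and hit-direction mass) over
#' groups. Grouping modes: `family` (psd vs kernel), `sensor` (four
#' sensors), or `frequency_band` (PSD features only, split at 150 Hz into
#' `<150 Hz` and `>=150 Hz`). Each feature belongs to exactly one group per
#' mode, so group totals sum to the totals of their members.
#'
#' @param s an `attribution_summary`
#' @param grouping one of `"family"`, `"sensor"`, `"frequency_band"`
#' @return data.frame with `group`, `mean_abs` (summed), `hit_mass`
#'   (summed) and `share` (of the grouped total)
#' @export
aggregate_attributions <- function(s,
                                   grouping = c("family", "sensor",
                                                "frequency_band")) {
  grouping <- match.arg(grouping)
  info <- parse_feature_names(s$ranking$feature)
  r <- s$ranking
  grp <- switch(grouping,
    family = info$family,
    sensor = info$sensor,
    frequency_band = {
      r <- r[info$family == "psd", , drop = FALSE]
      info <- info[info$family == "psd", , drop = FALSE]
      ifelse(info$bin_lo < 150, "<150 Hz", ">=150 Hz")
    })
  agg <- aggregate(cbind(mean_abs, hit_mass) ~ group,
                   data = data.frame(r, group = grp), FUN = sum)
  agg$share <- if (sum(agg$mean_abs) > 0)
    agg$mean_abs / sum(agg$mean_abs) else 0
  agg[order(-agg$mean_abs), ]
}
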