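# Confusion-matrix metrics, bootstrap confidence intervals, and the
# per-subset evaluation report.

#' Confusion counts for binary hit / non-hit labels
#'
#' @param truth,predicted equal-length vectors with values in
#'   \{`positive`, `negative`\}
#' @param positive positive-class label (`"hit"`)
#' @param negative negative-class label (`"non_hit"`)
#' @return an object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `fn`, `tn`
#' @export
confusion_counts <- function(truth, predicted, positive = "hit",
                             negative = "non_hit") {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  lv <- c(positive, negative)
  if (!all(truth %in% lv) || !all(predicted %in% lv))
    stop("labels must be binary over the positive/negative vocabulary")
  structure(list(
    tp = sum(truth == positive & predicted == positive),
    fp = sum(truth == negative & predicted == positive),
    fn = sum(truth == positive & predicted == negative),
    tn = sum(truth == negative & predicted == negative)
  ), class = "confusion_counts")
}

# Vectorized metric evaluation over confusion-cell vectors. Degenerate
# denominators follow the 0-with-flag convention.
metric_from_counts <- function(tp, fp, fn, tn, metric) {
  div0 <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  switch(metric,
    tp_pct = 100 * div0(tp, tp + fn),
    tn_pct = 100 * div0(tn, tn + fp),
    sensitivity = div0(tp, tp + fn),
    precision = div0(tp, tp + fp),
    f1 = {
      p <- div0(tp, tp + fp); s <- div0(tp, tp + fn)
      div0(2 * p * s, p + s)
    },
    mcc = {
      den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      ifelse(den > 0, (tp * tn - fp * fn) / ifelse(den > 0, den, 1), 0)
    },
    stop(sprintf("unknown metric '%s'", metric)))
}

#' Classification metrics from confusion counts
#'
#' TP% = 100 tp/(tp+fn), TN% = 100 tn/(tn+fp), sensitivity = tp/(tp+fn),
#' precision = tp/(tp+fp), F1 = harmonic mean of precision and sensitivity,
#' and the Matthews correlation coefficient. Metrics with a zero
#' denominator are reported as 0 and flagged in the `degenerate` attribute.
#'
#' @param cc a [confusion_counts()]
#' @return named numeric vector of the six metrics
#' @export
compute_metrics <- function(cc) {
  ms <- c("tp_pct", "tn_pct", "sensitivity", "precision", "f1", "mcc")
  out <- vapply(ms, function(m)
    metric_from_counts(cc$tp, cc$fp, cc$fn, cc$tn, m), numeric(1))
  deg <- c(tp_pct = cc$tp + cc$fn == 0, tn_pct = cc$tn + cc$fp == 0,
           sensitivity = cc$tp + cc$fn == 0, precision = cc$tp + cc$fp == 0,
           f1 = cc$tp + cc$fp == 0 || cc$tp + cc$fn == 0,
           mcc = (cc$tp + cc$fp) * (cc$tp + cc$fn) *
                 (cc$tn + cc$fp) * (cc$tn + cc$fn) == 0)
  attr(out, "degenerate") <- deg
  out
}

#' Truncate a rate to two decimals for display
#'
#' Report tables print rates truncated (not rounded) to two decimals, e.g.
#' 229/238 = 96.218...% prints as 96.21 and an F1 of 0.9268 as 0.92. Full
#' precision is retained in serialized reports.
#'
#' @param x numeric
#' @param digits decimals kept
#' @return numeric truncated toward zero at `digits` decimals
#' @export
truncate_rate <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples (truth, predicted) pairs with replacement, uniformly, and takes
#' the percentile interval of the metric across resamples. For the built-in
#' confusion-matrix metrics the resampled confusion counts are drawn
#' directly from a multinomial distribution over the observed confusion
#' cells — distributionally identical to resampling pairs, and much faster.
#' A metric given as a function of `(truth, predicted)` uses explicit index
#' resampling.
#'
#' @param truth,predicted label vectors as in [confusion_counts()]
#' @param metric metric name (see [compute_metrics()]) or a function
#' @param n_boot number of bootstrap resamples
#' @param level confidence level
#' @param seed integer seed
#' @param positive,negative class vocabulary
#' @return numeric `c(lower, upper)` with the point estimate in attribute
#'   `point`
#' @export
bootstrap_ci <- function(truth, predicted, metric = "tp_pct",
                         n_boot = 10000, level = 0.95, seed = 1L,
                         positive = "hit", negative = "non_hit") {
  if (length(truth) < 1) stop("need at least one observation")
  set.seed(seed)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  n <- length(truth)
  if (is.character(metric)) {
    cc <- confusion_counts(truth, predicted, positive, negative)
    cells <- c(cc$tp, cc$fp, cc$fn, cc$tn)
    draws <- rmultinom(n_boot, n, cells / n)
    stat <- metric_from_counts(draws[1, ], draws[2, ], draws[3, ],
                               draws[4, ], metric)
    point <- metric_from_counts(cc$tp, cc$fp, cc$fn, cc$tn, metric)
  } else {
    stat <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(truth[idx], predicted[idx])
    }, numeric(1))
    point <- metric(truth, predicted)
  }
  ci <- unname(quantile(stat, probs))
  attr(ci, "point") <- point
  ci
}

#' Evaluate a tuned model on every data subset
#'
#' Computes the full metric block (TP%, TN%, sensitivity, precision, F1,
#' MCC) with bootstrap confidence intervals on each of the train,
#' validation, test, rest and holdout subsets. The rest subset contains no
#' positives by construction, so its TP% and F1 are 0 and flagged.
#'
#' @param model a `tuned_model` from [tune_estimator()]
#' @param features standardized feature matrix (all rows)
#' @param bundle a `dataset_bundle` from [split_dataset()]
#' @param n_boot bootstrap resamples per interval
#' @param seed integer seed for the bootstrap
#' @return an object of class `eval_report`: list with `subsets`, each a
#'   list of `n_pos`, `n_neg`, `counts`, `metrics`, `ci` (per-metric lower
#'   and upper) and `flags`
#' @export
evaluate_model <- function(model, features, bundle, n_boot = 10000,
                           seed = 1L) {
  subsets <- c("train", "validation", "test", "rest", "holdout")
  out <- list()
  for (s in subsets) {
    idx <- bundle[[s]]
    if (length(idx) == 0) {
      warning(sprintf("subset '%s' is empty; omitted from the report", s))
      next
    }
    truth <- bundle$labels[idx]
    pred <- predict(model, features[idx, , drop = FALSE])
    cc <- confusion_counts(truth, pred)
    met <- compute_metrics(cc)
    ci <- lapply(stats::setNames(names(met), names(met)), function(m)
      as.numeric(bootstrap_ci(truth, pred, m, n_boot = n_boot,
                              seed = derive_seed(seed, match(s, subsets)))))
    out[[s]] <- list(n_pos = cc$tp + cc$fn, n_neg = cc$tn + cc$fp,
                     counts = list(tp = cc$tp, fp = cc$fp, fn = cc$fn,
                                   tn = cc$tn),
                     metrics = as.list(met),
                     ci = ci,
                     flags = as.list(attr(met, "degenerate")))
  }
  structure(list(subsets = out, n_boot = n_boot, ci_seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%-11s %6s %8s %9s %9s %6s\n",
              "Subset", "Hits", "NonHits", "TP(%)", "TN(%)", "F1"))
  for (s in names(x$subsets)) {
    b <- x$subsets[[s]]
    cat(sprintf("%-11s %6d %8d %9.2f %9.2f %6.2f\n", s, b$n_pos, b$n_neg,
                truncate_rate(b$metrics$tp_pct),
                truncate_rate(b$metrics$tn_pct),
                truncate_rate(b$metrics$f1)))
  }
  invisible(x)
}

#' Serialize / deserialize an evaluation report
#'
#' Reports round-trip losslessly through JSON (full numeric precision).
#'
#' @param report an `eval_report`
#' @param path file path
#' @return `read_eval_report` returns an `eval_report`
#' @export
write_eval_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE),
            class = "eval_report")
}
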