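cc_of <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

test_that("confusion counts match a nested-loop oracle", {
  truth <- c("hit", "hit", "non_hit", "non_hit")
  expect_equal(unclass(confusion_counts(truth, truth))[1:4],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L),
               ignore_attr = TRUE)
  flipped <- ifelse(truth == "hit", "non_hit", "hit")
  cc <- confusion_counts(truth, flipped)
  expect_equal(cc$tp + cc$tn, 0)

  set.seed(10)
  tr <- sample(c("hit", "non_hit"), 200, replace = TRUE)
  pr <- sample(c("hit", "non_hit"), 200, replace = TRUE)
  cc <- confusion_counts(tr, pr)
  oracle <- c(0, 0, 0, 0)
  for (i in 1:200) {
    oracle <- oracle + c(tr[i] == "hit" & pr[i] == "hit",
                         tr[i] == "non_hit" & pr[i] == "hit",
                         tr[i] == "hit" & pr[i] == "non_hit",
                         tr[i] == "non_hit" & pr[i] == "non_hit")
  }
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), oracle)

  expect_error(confusion_counts(tr, pr[-1]), "lengths differ")
  expect_error(confusion_counts(c("hit", "maybe"), c("hit", "hit")),
               "binary")
})

test_that("metric formulas reproduce the worked examples", {
  # 57 hits all detected, 238 non-hits with 9 false alarms
  m <- compute_metrics(cc_of(57, 9, 0, 229))
  expect_equal(m[["sensitivity"]], 1)
  expect_equal(m[["f1"]], 114 / 123)
  expect_equal(truncate_rate(m[["f1"]]), 0.92)
  expect_equal(truncate_rate(m[["tn_pct"]]), 96.21)  # 229/238 truncated

  m2 <- compute_metrics(cc_of(231, 0, 13, 0))
  expect_equal(truncate_rate(m2[["tp_pct"]]), 94.67)  # 231/244

  m3 <- compute_metrics(cc_of(9, 2, 1, 8))
  expect_equal(m3[["mcc"]], 70 / sqrt(9900))
})

test_that("metrics agree with an independent formula oracle on random tables", {
  set.seed(11)
  for (i in 1:1000) {
    tp <- rpois(1, 20); fp <- rpois(1, 5)
    fn <- rpois(1, 5); tn <- rpois(1, 20)
    m <- compute_metrics(cc_of(tp, fp, fn, tn))
    if (tp + fn > 0) expect_equal(m[["tp_pct"]], 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m[["tn_pct"]], 100 * tn / (tn + fp))
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      p <- tp / (tp + fp); s <- tp / (tp + fn)
      expect_equal(m[["f1"]], 2 * p * s / (p + s))
    }
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0)
      expect_equal(m[["mcc"]], (tp * tn - fp * fn) / den, tolerance = 1e-12)
    # MCC is symmetric under a simultaneous class swap
    m_swap <- compute_metrics(cc_of(tn, fn, fp, tp))
    expect_equal(m_swap[["mcc"]], m[["mcc"]], tolerance = 1e-12)
  }
})

test_that("degenerate counts follow the 0-with-flag convention", {
  m <- compute_metrics(cc_of(0, 0, 0, 50))  # no positives at all
  expect_equal(m[["tp_pct"]], 0)
  expect_equal(m[["f1"]], 0)
  expect_true(attr(m, "degenerate")[["tp_pct"]])
  expect_false(attr(m, "degenerate")[["tn_pct"]])
})

test_that("rates print with two-decimal truncation", {
  expect_equal(truncate_rate(96.2184), 96.21)
  expect_equal(truncate_rate(0.9268), 0.92)
  expect_equal(truncate_rate(100), 100)
})

test_that("bootstrap intervals are reproducible and degenerate when exact", {
  truth <- rep("hit", 40)
  ci <- bootstrap_ci(truth, truth, "tp_pct", n_boot = 500, seed = 1)
  expect_equal(as.numeric(ci), c(100, 100))
  expect_equal(attr(ci, "point"), 100)

  set.seed(2)
  tr <- sample(c("hit", "non_hit"), 100, replace = TRUE)
  pr <- ifelse(runif(100) < 0.85, tr, ifelse(tr == "hit", "non_hit", "hit"))
  a <- bootstrap_ci(tr, pr, "mcc", n_boot = 1000, seed = 9)
  b <- bootstrap_ci(tr, pr, "mcc", n_boot = 1000, seed = 9)
  expect_identical(a, b)
  expect_lte(a[1], attr(a, "point"))
  expect_gte(a[2], attr(a, "point"))

  # function-valued metrics run through explicit pair resampling
  acc <- function(truth, pred) mean(truth == pred)
  cf <- bootstrap_ci(tr, pr, acc, n_boot = 400, seed = 3)
  expect_true(cf[1] <= mean(tr == pr) && cf[2] >= mean(tr == pr))
})

test_that("bootstrap interval width shrinks as 1/sqrt(n)", {
  width_at <- function(n) {
    # average over draws: a single width estimate is noisy at small n
    mean(vapply(1:5, function(r) {
      set.seed(20 + n + 1000 * r)
      truth <- rep(c("hit", "non_hit"), length.out = n)
      correct <- runif(n) < 0.9
      pred <- ifelse(correct, truth,
                     ifelse(truth == "hit", "non_hit", "hit"))
      ci <- bootstrap_ci(truth, pred, "tp_pct", n_boot = 4000,
                         seed = n + r)
      ci[2] - ci[1]
    }, numeric(1)))
  }
  w <- vapply(c(100, 400, 1600), width_at, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
  expect_equal(w[2] / w[3], 2, tolerance = 0.35)
})

test_that("evaluation reports cover all subsets with the rest-set convention", {
  dat <- make_separable_data(n_per_class = 40)
  # move some non-hits out of the balanced pool to form a rest set
  labels <- c(dat$labels, rep("non_hit", 30))
  X <- rbind(dat$X, dat$X[sample(which(dat$labels == "non_hit"), 30,
                                 replace = TRUE), ])
  rownames(X) <- sprintf("cap%03d", seq_len(nrow(X)))
  bal <- balance_by_downsampling(labels, seed = 1)
  bundle <- split_dataset(bal, labels, seed = 1)
  model <- tune_estimator(X, bundle, n_candidates = 2, folds = 2, seed = 2)
  expect_warning(
    rep_out <- evaluate_model(model, X, bundle, n_boot = 300, seed = 4),
    "holdout")  # no holdout session in this fixture
  expect_named(rep_out$subsets, c("train", "validation", "test", "rest"))
  expect_equal(rep_out$subsets$train$metrics$tp_pct, 100)
  expect_equal(rep_out$subsets$train$metrics$f1, 1)
  rest <- rep_out$subsets$rest
  expect_equal(rest$n_pos, 0)
  expect_equal(rest$metrics$tp_pct, 0)
  expect_equal(rest$metrics$f1, 0)
  expect_true(rest$flags$tp_pct)

  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_out, path)
  back <- read_eval_report(path)
  expect_equal(back$subsets$test$metrics, rep_out$subsets$test$metrics)
  expect_equal(back$subsets$rest$ci$tn_pct, rep_out$subsets$rest$ci$tn_pct)
})
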