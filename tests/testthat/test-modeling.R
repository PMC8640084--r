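test_that("balancing downsamples the majority class only", {
  labels <- c(rep("hit", 1580), rep("non_hit", 11837))
  bal <- balance_by_downsampling(labels, seed = 2)
  expect_length(bal, 3160)
  expect_true(all(which(labels == "hit") %in% bal))  # no minority dropped
  expect_equal(sum(labels[bal] == "non_hit"), 1580)
  expect_equal(bal, balance_by_downsampling(labels, seed = 2))

  even <- rep(c("hit", "non_hit"), each = 5)
  expect_equal(balance_by_downsampling(even, seed = 1), 1:10)
  expect_error(balance_by_downsampling(rep("hit", 10)), "both classes")
})

test_that("the stratified split reproduces the reference counts", {
  labels <- c(rep("hit", 1580), rep("non_hit", 11837))
  bal <- balance_by_downsampling(labels, seed = 2)
  b <- split_dataset(bal, labels, seed = 3)
  expect_equal(sum(labels[b$train] == "hit"), 1106)  # floor(0.70 x 1580)
  expect_equal(sum(labels[b$train] == "non_hit"), 1106)
  expect_length(b$rest, 10257)

  # partition invariants
  expect_setequal(c(b$train, b$validation, b$test), bal)
  expect_length(intersect(b$train, b$validation), 0)
  expect_length(intersect(b$train, b$test), 0)
  expect_length(intersect(b$validation, b$test), 0)
  expect_length(intersect(b$rest, bal), 0)

  all_train <- split_dataset(bal, labels, fractions = c(1, 0, 0), seed = 1)
  expect_setequal(all_train$train, bal)
  expect_length(all_train$validation, 0)

  expect_error(split_dataset(1:4, rep(c("hit", "non_hit"), 2),
                             seed = 1), "too small")
})

test_that("holdout indices stay out of every other subset", {
  labels <- rep(c("hit", "non_hit"), c(40, 160))
  hold <- c(1:5, 191:200)
  bal <- balance_by_downsampling(labels, seed = 5, exclude = hold)
  b <- split_dataset(bal, labels, seed = 5, holdout_idx = hold)
  expect_length(intersect(hold, c(b$train, b$validation, b$test, b$rest)), 0)
  expect_setequal(b$holdout, hold)
})

test_that("the baseline sweep scores algorithms and survives failures", {
  dat <- make_separable_data(n_per_class = 30)
  roster <- list(
    always_hit = list(fit = function(X, y) NULL,
                      predict = function(fit, X) rep("hit", nrow(X))),
    xgboost = default_roster()$xgboost,
    broken = list(fit = function(X, y) stop("boom"),
                  predict = function(fit, X) NULL))
  sw <- baseline_sweep(dat$X, dat$bundle, roster, seed = 1)
  expect_equal(sw$tp_pct[1], 100)
  expect_equal(sw$tn_pct[1], 0)
  expect_equal(sw$tp_pct[2], 100)  # separable -> perfect tree ensemble
  expect_equal(sw$tn_pct[2], 100)
  expect_true(sw$failed[3])
  expect_match(sw$error[3], "boom")
  sw2 <- baseline_sweep(dat$X, dat$bundle, roster, seed = 1)
  expect_identical(sw, sw2)
})

test_that("estimator selection maximizes mean(TP, TN) with |TP-TN| tie-break", {
  sw <- data.frame(algorithm = c("xgb", "hgb"),
                   tp_pct = c(95.66, 95.51), tn_pct = c(95.52, 95.65),
                   diff = c(0.14, -0.14), failed = FALSE, error = NA)
  expect_equal(select_estimator(sw), "xgb")  # mean 95.59 > 95.58

  sw2 <- data.frame(algorithm = c("degenerate", "balanced"),
                    tp_pct = c(0, 90), tn_pct = c(100, 90),
                    diff = c(-100, 0), failed = FALSE, error = NA)
  expect_equal(select_estimator(sw2), "balanced")

  tie <- data.frame(algorithm = c("a", "b"),
                    tp_pct = c(80, 85), tn_pct = c(90, 85),
                    diff = c(-10, 0), failed = FALSE, error = NA)
  expect_equal(select_estimator(tie), "b")  # equal means, smaller |TP-TN|

  one <- sw[1, ]
  expect_equal(select_estimator(one), "xgb")
  expect_error(select_estimator(sw[sw$failed, ]), "no successful")
})

test_that("randomized tuning finds a perfect model on separable data", {
  dat <- make_separable_data(n_per_class = 30)
  m <- tune_estimator(dat$X, dat$bundle, n_candidates = 3, folds = 2,
                      seed = 5)
  expect_equal(m$n_fits, 3 * 2 + 1)
  expect_equal(m$cv_mcc, 1)
  expect_equal(nrow(m$candidates), 3)
  m2 <- tune_estimator(dat$X, dat$bundle, n_candidates = 3, folds = 2,
                       seed = 5)
  expect_identical(m$params, m2$params)

  pred <- predict(m, dat$X[dat$bundle$test, , drop = FALSE])
  expect_equal(pred, dat$labels[dat$bundle$test])
})

test_that("tuning never scores below the default configuration", {
  default_cand <- list(nrounds = 100, max_depth = 6, eta = 0.3,
                       subsample = 1, colsample_bytree = 1,
                       min_child_weight = 1)
  cv_mcc_of <- function(dat, cand, seed) {
    space <- lapply(cand, function(v) function() v)
    tune_estimator(dat$X, dat$bundle, n_candidates = 1, folds = 3,
                   seed = seed, param_space = space,
                   include_default = FALSE)$cv_mcc
  }
  for (s in 1:5) {
    dat <- make_separable_data(n_per_class = 20, p = 6, seed = 100 + s)
    # make the problem noisy enough that candidates differ
    set.seed(s); dat$X[, 1] <- dat$X[, 1] + rnorm(nrow(dat$X), 0, 0.8)
    tuned <- tune_estimator(dat$X, dat$bundle, n_candidates = 6, folds = 3,
                            seed = s)
    expect_gte(tuned$cv_mcc, cv_mcc_of(dat, default_cand, s) - 1e-12)
  }
})

test_that("single-class training data is rejected", {
  dat <- make_separable_data(n_per_class = 10)
  dat$bundle$labels[] <- "hit"
  expect_error(tune_estimator(dat$X, dat$bundle, 2, 2, seed = 1),
               "single-class")
})
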