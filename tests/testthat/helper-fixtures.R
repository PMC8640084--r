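# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# A minimal valid capture: a 60 Hz damped pulse on the left accelerometer,
# quiet elsewhere, 321 samples at nominal rates (80 for the gyro).
make_test_capture <- function(capture_id = "c1", amp = 50, freq = 60,
                              label = "hit",
                              sublabel = if (label == "hit") "hit" else "none") {
  n_acc <- 321
  t_acc <- (0:(n_acc - 1)) / 3200
  w <- ifelse(t_acc >= 0.02,
              amp * exp(-(t_acc - 0.02) / 0.015) *
                sin(2 * pi * freq * (t_acc - 0.02)), 0)
  n_gyro <- 81
  zeros_g <- numeric(n_gyro)
  streams <- list(
    left_acc = sensor_stream("left_acc", w, numeric(n_acc), numeric(n_acc)),
    centre_acc = sensor_stream("centre_acc", 0.9 * w, numeric(n_acc),
                               numeric(n_acc)),
    right_acc = sensor_stream("right_acc", numeric(n_acc), 1.1 * w,
                              numeric(n_acc)),
    gyro = sensor_stream("gyro", zeros_g, zeros_g, zeros_g))
  capture(capture_id, "dev1", streams, trigger_index = 64,
          label = label, sublabel = sublabel)
}

# Small simulated corpus, memoized per (n, seed) within the session.
.corpus_cache <- new.env(parent = emptyenv())
small_corpus <- function(n = 40, seed = 7) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(.corpus_cache[[key]]))
    .corpus_cache[[key]] <- generate_corpus(sim_config(n_captures = n,
                                                       seed = seed))
  .corpus_cache[[key]]
}

# Linearly separable standardized feature matrix + labels + bundle, for
# modeling tests. Feature 1 separates the classes; the rest are noise.
make_separable_data <- function(n_per_class = 30, p = 8, seed = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("hit", "non_hit"), each = n_per_class)
  # exactly +/-1: histogram-based tree growers place their cut at a bin
  # boundary, so a jitter-free binary feature generalizes deterministically
  X[, 1] <- ifelse(labels == "hit", 1, -1)
  colnames(X) <- sprintf("psd|left_acc.x|%d", seq(20, by = 10,
                                                  length.out = p))
  rownames(X) <- sprintf("cap%03d", seq_len(n))
  bal <- balance_by_downsampling(labels, seed = seed)
  bundle <- split_dataset(bal, labels, seed = seed)
  list(X = X, labels = labels, bundle = bundle)
}

# A tiny fitted tuned_model on separable data (perfect classifier).
make_tiny_model <- function(dat = make_separable_data()) {
  tune_estimator(dat$X, dat$bundle, n_candidates = 2, folds = 2, seed = 1)
}
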