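# Independent oracles shared across test files.

# steady-state amplitude gain of the triage filter at one frequency,
# RMS-based so near-Nyquist tones are measured robustly
measured_gain <- function(freq, rate = 3200, n = 6400) {
  t <- (0:(n - 1)) / rate
  out <- butterworth_lowpass(sin(2 * pi * freq * t), rate)
  sqrt(2 * mean(out[(n / 2):n]^2))
}

# closed-form magnitude response of the discretized (bilinear, prewarped)
# second-order Butterworth low-pass
digital_gain <- function(freq, cutoff = 300, rate = 3200) {
  1 / sqrt(1 + (tan(pi * freq / rate) / tan(pi * cutoff / rate))^4)
}

# independent nested-loop convolution oracle, mirroring the published
# definition of the random-kernel transform
kernel_oracle <- function(signal, k) {
  n <- length(signal)
  z <- (signal - mean(signal)) /
    max(sd(signal) * sqrt((n - 1) / n), 1e-12)
  pad <- if (k$padding) ((k$length - 1) * k$dilation) %/% 2 else 0
  out_len <- n + 2 * pad - (k$length - 1) * k$dilation
  out <- numeric(out_len)
  for (i in seq_len(out_len)) {
    s <- k$bias
    for (j in seq_len(k$length)) {
      idx <- i - pad + (j - 1) * k$dilation
      if (idx >= 1 && idx <= n) s <- s + k$weights[j] * z[idx]
    }
    out[i] <- s
  }
  c(max = max(out), ppv = mean(out > 0))
}

# memoized reference end-to-end pipeline run shared by the synthetic
# classification and attribution acceptance checks
.e2e_cache <- new.env(parent = emptyenv())
e2e_result <- function() {
  if (is.null(.e2e_cache$res)) {
    cfg <- pipeline_config(sim = sim_config(n_captures = 2000, seed = 1),
                           n_kernels = 100, n_candidates = 15, folds = 3,
                           n_boot = 5000, seed = 1)
    .e2e_cache$res <- run_pipeline(cfg)
  }
  .e2e_cache$res
}
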