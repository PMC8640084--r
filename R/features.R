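# Feature generation: random convolutional kernel aggregates (max and
# proportion of positive values per kernel) and natural-log binned Welch
# power-spectral-density features, plus training-set standardization.

#' Generate random convolutional kernels
#'
#' Kernels follow the random-kernel (ROCKET-family) recipe: length drawn
#' from \{7, 9, 11\}, standard-normal weights mean-centred, bias uniform on
#' \[-1, 1\], dilation a power of two capped so the receptive field fits the
#' reference 320-sample capture, and zero padding with probability 1/2.
#'
#' @param n_kernels number of kernels (the reference configuration uses 300)
#' @param seed integer seed; the kernel sequence is reproducible from it
#' @param input_length reference signal length used to cap dilations
#' @return list of kernel specs (`kernel_id`, `length`, `weights`, `bias`,
#'   `dilation`, `padding`, `seed`)
#' @export
generate_kernels <- function(n_kernels, seed = 1L, input_length = 320L) {
  if (n_kernels < 1) stop("n_kernels must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_kernels), function(i) {
    len <- sample(c(7L, 9L, 11L), 1)
    w <- rnorm(len)
    w <- w - mean(w)
    a_max <- floor(log2((input_length - 1) / (len - 1)))
    dil <- 2L^sample.int(a_max + 1L, 1L) %/% 2L  # 2^a, a uniform on 0..a_max
    list(kernel_id = sprintf("k%03d", i), length = len, weights = w,
         bias = runif(1, -1, 1), dilation = as.integer(max(dil, 1L)),
         padding = runif(1) < 0.5, seed = seed)
  })
}

#' Apply random kernels to one signal
#'
#' The signal is first standardized to its own mean and standard deviation
#' (epsilon-guarded for constant signals), then convolved with each dilated
#' kernel plus bias; per kernel the maximum output value and the proportion
#' of positive output values are emitted.
#'
#' @param signal numeric series (length >= 2, finite)
#' @param kernels list of kernel specs from [generate_kernels()]
#' @return named numeric vector of `2 * length(kernels)` values, names
#'   `<kernel_id>|max` and `<kernel_id>|ppv`
#' @export
apply_kernels <- function(signal, kernels) {
  if (length(signal) < 2) stop("signal must have length >= 2")
  if (any(!is.finite(signal))) stop("signal must be finite")
  prep <- prepare_kernels(kernels)
  s <- sd(signal) * sqrt((length(signal) - 1) / length(signal))
  z <- (signal - mean(signal)) / max(s, 1e-12)
  vals <- rocket_features_cpp(z, prep$weights, prep$bias, prep$dilation,
                              prep$padding)
  names(vals) <- prep$names
  vals
}

# Unpack a kernel list into the flat vectors the C++ kernel expects, once
# per kernel set rather than once per signal.
prepare_kernels <- function(kernels) {
  p <- attr(kernels, "prepared")
  if (!is.null(p)) return(p)
  ids <- vapply(kernels, `[[`, character(1), "kernel_id")
  list(weights = lapply(kernels, `[[`, "weights"),
       bias = vapply(kernels, `[[`, numeric(1), "bias"),
       dilation = vapply(kernels, `[[`, integer(1), "dilation"),
       padding = vapply(kernels, `[[`, logical(1), "padding"),
       names = as.vector(rbind(paste0(ids, "|max"), paste0(ids, "|ppv"))))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a periodic Hann window, per-segment
#' constant detrend and one-sided density scaling (power per Hz). Signals
#' shorter than one segment fall back to a single-segment periodogram.
#'
#' @param signal numeric series
#' @param rate sampling rate in Hz
#' @param nperseg segment length in samples
#' @param noverlap overlap between segments in samples
#' @param nfft FFT length (zero-padded when larger than `nperseg`)
#' @return list with `freq` (Hz) and `psd` (one-sided density)
#' @export
welch_psd <- function(signal, rate, nperseg = 256, noverlap = 128,
                      nfft = 640) {
  n <- length(signal)
  if (n < nperseg) {
    nperseg <- n
    noverlap <- 0
    nfft <- max(nfft, n)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)
  step <- nperseg - noverlap
  starts <- seq(1, n - nperseg + 1, by = step)
  scale <- 1 / (rate * sum(win^2))
  nfreq <- nfft %/% 2 + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- signal[s0:(s0 + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    X <- fft(c(seg, numeric(nfft - nperseg)))[1:nfreq]
    p <- scale * (Mod(X)^2)
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]  # one-sided (not DC/Nyquist)
    acc <- acc + p
  }
  list(freq = (0:(nfreq - 1)) * rate / nfft, psd = acc / length(starts))
}

#' Binned log Welch PSD features for one signal
#'
#' The Welch PSD is grouped into 10-Hz bins spanning (10, Nyquist\] Hz (the
#' DC bin is excluded); the characteristic value of a bin is the mean PSD of
#' the frequencies inside it, natural-log transformed with a floor guard.
#' At the 3,200 Hz working rate this yields 159 features per signal.
#'
#' @param signal numeric series
#' @param rate sampling rate in Hz
#' @param bin_width bin width in Hz
#' @param ... passed to [welch_psd()]
#' @return named numeric vector, names = bin lower edges in Hz
#' @export
welch_psd_features <- function(signal, rate = 3200, bin_width = 10, ...) {
  w <- welch_psd(signal, rate, ...)
  lo <- seq(bin_width, rate / 2 - bin_width, by = bin_width)
  # bin id of frequency f over (lo, lo + bin_width] edges
  bin <- ceiling(w$freq / bin_width - 1e-9)
  keep <- bin >= 2 & bin <= length(lo) + 1
  sums <- rowsum(w$psd[keep], bin[keep])
  cnts <- rowsum(rep(1, sum(keep)), bin[keep])
  vals <- rep(NA_real_, length(lo))
  vals[as.integer(rownames(sums)) - 1L] <- sums / cnts
  vals <- log(pmax(vals, 1e-30))
  names(vals) <- as.character(lo)
  vals
}

signal_columns <- function() {
  as.vector(t(outer(sensor_ids(), c("x", "y", "z"), paste, sep = ".")))
}

#' Assemble the capture-by-feature matrix
#'
#' For every triage-passed processed capture, computes binned log Welch PSD
#' features and random-kernel features on each of the 12 aligned signals
#' (3 accelerometers x 3 axes + 3 gyroscope axes). Column names are
#' `psd|<signal>|<bin lower edge>` or `kernel|<signal>|<kernel id>|<stat>`
#' and are parseable for attribution grouping via [parse_feature_names()].
#'
#' @param processed list of `processed_capture`s (all triage-passed, same
#'   rate)
#' @param kernels kernel list from [generate_kernels()]
#' @param bin_width PSD bin width in Hz
#' @return numeric matrix, rows = capture ids, with attribute `provenance`
#' @export
assemble_feature_matrix <- function(processed, kernels, bin_width = 10) {
  if (length(processed) == 0) stop("no captures to featurize")
  rates <- unique(vapply(processed, `[[`, numeric(1), "rate"))
  if (length(rates) != 1)
    stop("captures have mixed rates; resample to a common rate first")
  sig_cols <- signal_columns()
  attr(kernels, "prepared") <- prepare_kernels(kernels)
  rows <- lapply(processed, function(p) {
    feats <- lapply(sig_cols, function(sc) {
      x <- p$signals[, sc]
      psd <- welch_psd_features(x, rate = p$rate, bin_width = bin_width)
      ker <- apply_kernels(x, kernels)
      v <- c(psd, ker)
      names(v) <- c(paste("psd", sc, names(psd), sep = "|"),
                    paste("kernel", sc, names(ker), sep = "|"))
      v
    })
    unlist(feats)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(processed, `[[`, character(1), "capture_id")
  if (anyNA(m)) stop("feature matrix contains missing values")
  attr(m, "provenance") <- list(n_kernels = length(kernels),
                                kernel_seed = kernels[[1]]$seed,
                                bin_width = bin_width, rate = rates)
  m
}

#' Parse feature names into family / signal / detail components
#'
#' @param nm character vector of feature-matrix column names
#' @return data.frame with columns `feature`, `family` (`psd`/`kernel`),
#'   `signal` (`<sensor>.<axis>`), `sensor`, `bin_lo` (Hz, PSD only),
#'   `kernel_id` and `stat` (kernel only)
#' @export
parse_feature_names <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop(sprintf("unparseable feature name '%s'", nm[which(bad)[1]]))
  family <- vapply(parts, `[[`, character(1), 1)
  if (!all(family %in% c("psd", "kernel")))
    stop(sprintf("unparseable feature name '%s'",
                 nm[which(!family %in% c("psd", "kernel"))[1]]))
  sig <- vapply(parts, `[[`, character(1), 2)
  data.frame(
    feature = nm, family = family, signal = sig,
    sensor = sub("\\.[xyz]$", "", sig),
    bin_lo = ifelse(family == "psd",
                    suppressWarnings(as.numeric(vapply(parts, `[[`,
                                                       character(1), 3))),
                    NA_real_),
    kernel_id = ifelse(family == "kernel",
                       vapply(parts, `[[`, character(1), 3), NA_character_),
    stat = ifelse(family == "kernel",
                  vapply(parts, function(p) p[[length(p)]], character(1)),
                  NA_character_),
    stringsAsFactors = FALSE)
}

#' Fit a training-set standardization model
#'
#' Per-column mean and (population) standard deviation estimated on the
#' training rows only.
#'
#' @param m feature matrix
#' @param train_idx training row indices (>= 2 rows)
#' @param epsilon guard for zero-SD columns on apply
#' @return an object of class `standardizer`
#' @export
fit_standardizer <- function(m, train_idx, epsilon = 1e-8) {
  if (length(train_idx) < 2) stop("need at least 2 training rows")
  tr <- m[train_idx, , drop = FALSE]
  mu <- colMeans(tr)
  va <- colMeans(sweep(tr, 2, mu)^2)
  structure(list(mean = mu, sd = sqrt(va), epsilon = epsilon,
                 columns = colnames(m)), class = "standardizer")
}

#' Apply a standardization model
#'
#' `(x - mean) / max(sd, epsilon)` per column. Zero-SD columns map to zero.
#'
#' @param model a `standardizer` from [fit_standardizer()]
#' @param m feature matrix with the model's columns
#' @return standardized matrix
#' @export
apply_standardizer <- function(model, m) {
  if (!identical(colnames(m), model$columns))
    stop("feature columns do not match the standardization model")
  sweep(sweep(m, 2, model$mean), 2, pmax(model$sd, model$epsilon), "/")
}
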