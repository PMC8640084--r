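# Capture-recording emulation and signal conditioning: onboard trigger,
# axis alignment, polyphase resampling to a common 3,200 Hz rate, norm
# computation, and 300 Hz Butterworth triage.

#' Trigger and triage configuration
#'
#' `trigger_config()` describes the onboard capture logic: a capture starts
#' 20 ms before the first sample whose raw left-accelerometer norm reaches
#' 10 g and ends 80 ms after the last such sample (triggers inside the tail
#' merge into one capture). `triage_config()` describes the offline filter
#' that removes vocalization/high-frequency captures: the norm is low-pass
#' filtered at 300 Hz with a causal (non-phase-corrected) second-order
#' Butterworth filter and re-thresholded at 10 g.
#'
#' @param threshold trigger/triage threshold in g
#' @param lead_in_ms,tail_ms capture window geometry in milliseconds
#' @return a `trigger_config` object
#' @export
trigger_config <- function(threshold = 10, lead_in_ms = 20, tail_ms = 80) {
  stopifnot(threshold > 0, lead_in_ms > 0, tail_ms > 0)
  structure(list(threshold = threshold, lead_in_ms = lead_in_ms,
                 tail_ms = tail_ms), class = "trigger_config")
}

#' @rdname trigger_config
#' @param cutoff low-pass cutoff in Hz
#' @param filter_order Butterworth order
#' @param phase_corrected must be `FALSE`: the filter is applied in a single
#'   causal pass
#' @export
triage_config <- function(cutoff = 300, filter_order = 2, threshold = 10,
                          phase_corrected = FALSE) {
  stopifnot(cutoff > 0, filter_order >= 1, threshold > 0,
            identical(phase_corrected, FALSE))
  structure(list(cutoff = cutoff, filter_order = as.integer(filter_order),
                 threshold = threshold, phase_corrected = phase_corrected),
            class = "triage_config")
}

#' Element-wise Euclidean norm of a triaxial signal
#'
#' @param x,y,z equal-length numeric channels
#' @return non-negative series `sqrt(x^2 + y^2 + z^2)`
#' @export
euclidean_norm <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("channel lengths differ")
  sqrt(x^2 + y^2 + z^2)
}

#' Causal Butterworth low-pass filter
#'
#' Single-pass (non-phase-corrected) Butterworth low-pass, gain 1 at DC and
#' -3 dB at the cutoff.
#'
#' @param series numeric series
#' @param rate sampling rate in Hz; must exceed twice the cutoff
#' @param cfg a [triage_config()]
#' @return filtered series, same length as the input
#' @export
butterworth_lowpass <- function(series, rate, cfg = triage_config()) {
  if (cfg$cutoff >= rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist rate %g Hz",
                 cfg$cutoff, rate / 2))
  bf <- signal::butter(cfg$filter_order, 2 * cfg$cutoff / rate, type = "low")
  as.numeric(signal::filter(bf, series))
}

#' Rotate a capture's sensor axes onto the cardinal axes
#'
#' Applies each sensor's calibration rotation matrix to its triaxial
#' samples. Rotations preserve per-sample norms.
#'
#' @param c a [capture()]
#' @param cal a [calibration_set()] (or named list of 3x3 rotation matrices)
#' @return the capture with rotated channels
#' @export
align_axes <- function(c, cal) {
  if (!inherits(cal, "calibration_set")) cal <- calibration_set(cal)
  for (id in names(c$streams)) {
    R <- cal$matrices[[id]]
    if (is.null(R)) stop(sprintf("no calibration matrix for sensor '%s'", id))
    s <- c$streams[[id]]
    v <- R %*% rbind(s$x, s$y, s$z)
    c$streams[[id]]$x <- v[1, ]
    c$streams[[id]]$y <- v[2, ]
    c$streams[[id]]$z <- v[3, ]
  }
  c
}

# Best rational approximation p/q to a ratio with bounded denominator,
# via continued fractions.
rational_approx <- function(ratio, max_den = 1000L) {
  stopifnot(ratio > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; x <- ratio
  repeat {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(p = as.integer(h1), q = as.integer(k1))
}

#' Resample a sensor stream to the common working rate
#'
#' Polyphase resampling of all three channels to `target_rate`. The
#' actual-to-target ratio is approximated by a rational number with bounded
#' denominator, so jittered rates (e.g. 3,180 Hz) are supported. Streams
#' already at the target rate pass through unchanged.
#'
#' @param s a [sensor_stream()]
#' @param target_rate target rate in Hz (3,200 in the reference pipeline)
#' @return a [sensor_stream()] at `target_rate`
#' @export
resample_to_common_rate <- function(s, target_rate = 3200) {
  stopifnot(s$actual_rate > 0)
  if (any(!is.finite(c(s$x, s$y, s$z))))
    stop(sprintf("%s: non-finite samples", s$sensor_id))
  if (identical(as.numeric(s$actual_rate), as.numeric(target_rate)))
    return(s)
  pq <- rational_approx(target_rate / s$actual_rate)
  for (ch in c("x", "y", "z"))
    s[[ch]] <- signal::resample(s[[ch]], pq[["p"]], pq[["q"]])
  s$actual_rate <- target_rate
  s
}

#' Emulate the onboard capture trigger
#'
#' Scans the raw (unfiltered) left-accelerometer norm for samples at or
#' above the threshold. Each run of triggers closer together than the tail
#' produces one capture spanning `[first_trigger - lead_in, last_trigger +
#' tail]`, clipped to the stream bounds; all four sensors are excerpted over
#' the same time span at their own rates.
#'
#' @param streams named list of four [sensor_stream()]s (continuous
#'   recording); `left_acc` must be present
#' @param cfg a [trigger_config()]
#' @return list of [capture()]s (possibly empty)
#' @export
emulate_onboard_trigger <- function(streams, cfg = trigger_config()) {
  left <- streams[["left_acc"]]
  if (is.null(left)) stop("left_acc stream is required for triggering")
  rate <- left$actual_rate
  nrm <- euclidean_norm(left$x, left$y, left$z)
  trig <- which(nrm >= cfg$threshold)
  if (length(trig) == 0) return(list())
  tail_n <- round(cfg$tail_ms / 1000 * rate)
  lead_n <- round(cfg$lead_in_ms / 1000 * rate)
  # triggers within the tail of the previous trigger extend the capture
  brk <- which(diff(trig) > tail_n)
  starts <- trig[c(1, brk + 1)]
  ends <- trig[c(brk, length(trig))]
  n_left <- length(nrm)
  lapply(seq_along(starts), function(g) {
    i0 <- max(1L, starts[g] - lead_n)
    i1 <- min(n_left, ends[g] + tail_n)
    t0 <- (i0 - 1) / rate
    t1 <- (i1 - 1) / rate
    excerpt <- lapply(streams, function(s) {
      j <- seq_along(s$x)
      tt <- (j - 1) / s$actual_rate
      keep <- tt >= t0 - 0.5 / s$actual_rate & tt <= t1 + 0.5 / s$actual_rate
      s$x <- s$x[keep]; s$y <- s$y[keep]; s$z <- s$z[keep]
      s
    })
    names(excerpt) <- names(streams)
    capture(sprintf("trig%03d", g), "dev", excerpt,
            trigger_index = starts[g] - i0,  # 0-based within the window
            lead_in_ms = cfg$lead_in_ms, tail_ms = cfg$tail_ms)
  })
}

#' Align, resample and triage one capture
#'
#' Produces the 12-channel representation the feature stage consumes: all
#' sensors rotated to cardinal axes, resampled to 3,200 Hz, trimmed to a
#' common length, with the left-accelerometer norm and the triage decision.
#'
#' @param c a [capture()]
#' @param cal a [calibration_set()]; identity by default
#' @param triage a [triage_config()]
#' @param target_rate common working rate in Hz
#' @return an object of class `processed_capture` with fields `capture_id`,
#'   `label`, `sublabel`, `session_id`, `signals` (samples x 12 matrix with
#'   columns `<sensor>.<axis>`), `rate`, `left_norm` and `triage_passed`
#' @export
preprocess_capture <- function(c, cal = calibration_set(),
                               triage = triage_config(),
                               target_rate = 3200) {
  c <- align_axes(c, cal)
  res <- lapply(c$streams[sensor_ids()], resample_to_common_rate,
                target_rate = target_rate)
  n <- min(vapply(res, function(s) length(s$x), integer(1)))
  cols <- unlist(lapply(sensor_ids(), function(id) {
    s <- res[[id]]
    list(s$x[1:n], s$y[1:n], s$z[1:n])
  }), recursive = FALSE)
  signals <- do.call(cbind, cols)
  colnames(signals) <- as.vector(t(outer(sensor_ids(), c("x", "y", "z"),
                                         paste, sep = ".")))
  left_norm <- euclidean_norm(signals[, "left_acc.x"],
                              signals[, "left_acc.y"],
                              signals[, "left_acc.z"])
  p <- structure(list(capture_id = c$capture_id, label = c$label,
                      sublabel = c$sublabel, session_id = c$session_id,
                      signals = signals, rate = target_rate,
                      left_norm = left_norm, triage_passed = NA),
                 class = "processed_capture")
  p$triage_passed <- triage_capture(p, triage)
  p
}

#' Triage decision for a processed capture
#'
#' `TRUE` iff the maximum of the 300 Hz low-pass filtered
#' left-accelerometer norm reaches the threshold. Designed to reject
#' vocalization and other high-frequency non-impact captures.
#'
#' @param p a `processed_capture`
#' @param cfg a [triage_config()]
#' @return logical scalar
#' @export
triage_capture <- function(p, cfg = triage_config()) {
  filtered <- butterworth_lowpass(p$left_norm, p$rate, cfg)
  max(filtered) >= cfg$threshold
}
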