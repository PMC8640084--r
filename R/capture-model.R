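#' @useDynLib impactkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile rmultinom fft nextn
#' @importFrom utils head tail
NULL

#' Sensor identifiers and nominal specifications
#'
#' The mouthguard carries three triaxial linear accelerometers (left, centre,
#' right; +/-200 g range, 12-bit, nominally 3,200 Hz) and one triaxial
#' gyroscope (+/-2,000 dps range, 16-bit, nominally 800 Hz).
#'
#' @return `sensor_ids()` returns the four sensor identifiers;
#'   `sensor_spec(sensor_id)` returns a list with `nominal_rate`,
#'   `range_limit` and `bit_depth` for one sensor.
#' @export
sensor_ids <- function() c("left_acc", "centre_acc", "right_acc", "gyro")

#' @rdname sensor_ids
#' @param sensor_id one of `sensor_ids()`
#' @export
sensor_spec <- function(sensor_id) {
  sensor_id <- match.arg(sensor_id, sensor_ids())
  if (sensor_id == "gyro") {
    list(nominal_rate = 800, range_limit = 2000, bit_depth = 16L)
  } else {
    list(nominal_rate = 3200, range_limit = 200, bit_depth = 12L)
  }
}

#' Label vocabulary for captures
#'
#' @return `capture_labels()` returns the binary label vocabulary;
#'   `capture_sublabels()` the activity sublabels assigned during video
#'   review (plus `"none"` for unlabelled captures).
#' @export
capture_labels <- function() c("hit", "non_hit", "unlabelled")

#' @rdname capture_labels
#' @export
capture_sublabels <- function() {
  c("hit", "biting", "chewing", "drinking", "insertion", "removal",
    "in_hand", "in_sock", "yelling", "no_footage", "unknown", "none")
}

#' Construct a sensor stream
#'
#' A `sensor_stream` holds one sensor's triaxial time series in physical
#' units (g for accelerometers, degrees per second for the gyroscope)
#' together with its nominal and actual sampling rates, range limit and bit
#' depth. Actual rates may deviate from nominal because of per-device clock
#' jitter.
#'
#' @param sensor_id one of `sensor_ids()`
#' @param x,y,z equal-length numeric channels
#' @param actual_rate achieved sampling rate in Hz (defaults to nominal)
#' @param nominal_rate,range_limit,bit_depth sensor constants; default to
#'   `sensor_spec(sensor_id)`
#' @return an object of class `sensor_stream`
#' @export
sensor_stream <- function(sensor_id, x, y, z, actual_rate = NULL,
                          nominal_rate = NULL, range_limit = NULL,
                          bit_depth = NULL) {
  spec <- sensor_spec(sensor_id)
  s <- structure(list(
    sensor_id = sensor_id,
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    nominal_rate = nominal_rate %||% spec$nominal_rate,
    actual_rate = actual_rate %||% nominal_rate %||% spec$nominal_rate,
    range_limit = range_limit %||% spec$range_limit,
    bit_depth = as.integer(bit_depth %||% spec$bit_depth)
  ), class = "sensor_stream")
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a capture
#'
#' A capture is one threshold-triggered recording: four sensor streams, the
#' trigger metadata (0-based index of the first 10 g crossing on the left
#' accelerometer, 20 ms lead-in, 80 ms tail), and the video-review label.
#'
#' @param capture_id,device_id,session_id identifiers; `session_id` names
#'   the match/session the capture came from (used to build holdout sets)
#' @param streams named list of four `sensor_stream`s, one per sensor id
#' @param trigger_index 0-based sample index of the first threshold crossing
#'   in the stored left-accelerometer stream, at its actual rate
#' @param lead_in_ms,tail_ms capture window geometry in milliseconds
#' @param label one of `capture_labels()`
#' @param sublabel one of `capture_sublabels()`
#' @return an object of class `capture`
#' @export
capture <- function(capture_id, device_id, streams, trigger_index,
                    lead_in_ms = 20, tail_ms = 80,
                    label = "unlabelled", sublabel = "none",
                    session_id = "s1") {
  structure(list(
    capture_id = as.character(capture_id),
    device_id = as.character(device_id),
    session_id = as.character(session_id),
    streams = streams,
    trigger_index = as.integer(trigger_index),
    lead_in_ms = lead_in_ms,
    tail_ms = tail_ms,
    label = label,
    sublabel = sublabel
  ), class = "capture")
}

#' Validate a capture against its type invariants
#'
#' Checks that the capture holds exactly one stream per sensor id, that each
#' stream's three channels are equal-length and at least one sample long,
#' that sampling rates are positive, that samples respect the sensor range
#' limit, and that the label/sublabel vocabulary is consistent (a capture
#' labelled `hit` must carry sublabel `hit`).
#'
#' @param c a `capture`
#' @return character vector of violation descriptions; empty if the capture
#'   is valid. Violations are returned, never raised.
#' @export
validate_capture <- function(c) {
  v <- character()
  if (!inherits(c, "capture")) return("object is not a capture")
  have <- vapply(c$streams, function(s) s$sensor_id, character(1))
  missing <- setdiff(sensor_ids(), have)
  if (length(missing))
    v <- c(v, sprintf("streams: missing sensor '%s'", missing))
  if (anyDuplicated(have))
    v <- c(v, sprintf("streams: duplicated sensor '%s'",
                      unique(have[duplicated(have)])))
  for (s in c$streams) {
    id <- s$sensor_id
    n <- c(length(s$x), length(s$y), length(s$z))
    if (length(unique(n)) != 1L)
      v <- c(v, sprintf("%s: channel lengths differ (%s)", id,
                        paste(n, collapse = "/")))
    if (min(n) < 1L)
      v <- c(v, sprintf("%s: empty channel", id))
    if (!is.finite(s$actual_rate) || s$actual_rate <= 0)
      v <- c(v, sprintf("%s: actual_rate must be > 0", id))
    vals <- c(s$x, s$y, s$z)
    if (length(vals) && any(!is.finite(vals)))
      v <- c(v, sprintf("%s: non-finite samples", id))
    else if (length(vals) && max(abs(vals)) > s$range_limit + 1e-9)
      v <- c(v, sprintf("%s: sample magnitude %.4g exceeds range_limit %g",
                        id, max(abs(vals)), s$range_limit))
  }
  if (!c$label %in% capture_labels())
    v <- c(v, sprintf("label: unknown label '%s'", c$label))
  if (!c$sublabel %in% capture_sublabels())
    v <- c(v, sprintf("sublabel: unknown sublabel '%s'", c$sublabel))
  if (identical(c$label, "hit") && !identical(c$sublabel, "hit"))
    v <- c(v, "sublabel: label 'hit' requires sublabel 'hit'")
  if (!is.finite(c$trigger_index) || c$trigger_index < 0)
    v <- c(v, "trigger_index: must be a non-negative sample index")
  v
}

#' Construct a calibration set
#'
#' A calibration set maps each sensor's device axes onto the cardinal axes
#' through a proper rotation matrix (orthonormal, determinant +1). The
#' derivation of these matrices is outside the package: they are treated as
#' given inputs.
#'
#' @param matrices named list of 3x3 rotation matrices, one per sensor id;
#'   defaults to identity matrices for all four sensors
#' @return an object of class `calibration_set`
#' @export
calibration_set <- function(matrices = NULL) {
  if (is.null(matrices)) {
    matrices <- stats::setNames(
      replicate(4, diag(3), simplify = FALSE), sensor_ids())
  }
  for (id in names(matrices)) {
    R <- matrices[[id]]
    if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
      stop(sprintf("calibration for '%s' is not a 3x3 matrix", id))
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      stop(sprintf("calibration for '%s' is not orthonormal", id))
    if (abs(det(R) - 1) > 1e-9)
      stop(sprintf("calibration for '%s' has determinant != +1", id))
  }
  structure(list(matrices = matrices), class = "calibration_set")
}

# --- capture file dialect -----------------------------------------------
#
# One file holds one session: a JSON header (format tag, version, label
# vocabulary) plus a list of capture records with columnar sample blocks.
# Samples are stored in physical units at full precision.

CAPTURE_FORMAT <- "impactkit.captures"
CAPTURE_FORMAT_VERSION <- 1L

stream_to_record <- function(s) {
  list(sensor_id = s$sensor_id,
       nominal_rate = s$nominal_rate, actual_rate = s$actual_rate,
       range_limit = s$range_limit, bit_depth = s$bit_depth,
       x = s$x, y = s$y, z = s$z)
}

record_to_stream <- function(r) {
  sensor_stream(r$sensor_id, r$x, r$y, r$z,
                actual_rate = r$actual_rate, nominal_rate = r$nominal_rate,
                range_limit = r$range_limit, bit_depth = r$bit_depth)
}

#' Write captures to a `.captures.json` file
#'
#' @param captures non-empty list of valid `capture` objects
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [read_capture_file()]
#' @export
write_capture_file <- function(captures, path) {
  if (length(captures) == 0)
    stop("cannot write an empty capture sequence")
  for (c in captures) {
    v <- validate_capture(c)
    if (length(v))
      stop(sprintf("invalid capture '%s': %s", c$capture_id, v[1]))
  }
  recs <- lapply(captures, function(c) {
    list(capture_id = c$capture_id, device_id = c$device_id,
         session_id = c$session_id, trigger_index = c$trigger_index,
         lead_in_ms = c$lead_in_ms, tail_ms = c$tail_ms,
         label = c$label, sublabel = c$sublabel,
         streams = lapply(c$streams, stream_to_record))
  })
  doc <- list(header = list(format = CAPTURE_FORMAT,
                            version = CAPTURE_FORMAT_VERSION,
                            labels = capture_labels(),
                            sublabels = capture_sublabels()),
              captures = recs)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                           null = "null")
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write capture file '%s'", path))
  invisible(path)
}

#' Read captures from a `.captures.json` file
#'
#' @param path path to a capture file written by [write_capture_file()]
#' @return list of `capture` objects; every returned capture satisfies the
#'   type invariants
#' @export
read_capture_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e))))
  if (!identical(doc$header$format, CAPTURE_FORMAT))
    stop(sprintf("parse error in '%s': not an %s file", path, CAPTURE_FORMAT))
  captures <- lapply(doc$captures, function(r) {
    streams <- lapply(r$streams, record_to_stream)
    names(streams) <- vapply(streams, function(s) s$sensor_id, character(1))
    capture(r$capture_id, r$device_id, streams, r$trigger_index,
            lead_in_ms = r$lead_in_ms, tail_ms = r$tail_ms,
            label = r$label, sublabel = r$sublabel,
            session_id = r$session_id %||% "s1")
  })
  for (c in captures) {
    v <- validate_capture(c)
    if (length(v))
      stop(sprintf("validation error for capture '%s': %s",
                   c$capture_id, paste(v, collapse = "; ")))
  }
  captures
}
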