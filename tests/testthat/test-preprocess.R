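rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

test_that("axis alignment rotates channels and preserves norms", {
  c1 <- make_test_capture()
  expect_equal(align_axes(c1, calibration_set()), c1)

  mats <- stats::setNames(replicate(4, rot_z(pi / 2), simplify = FALSE),
                          sensor_ids())
  c2 <- make_test_capture()
  c2$streams$left_acc$x <- rep(1, 321)
  c2$streams$left_acc$y <- numeric(321)
  r <- align_axes(c2, calibration_set(mats))
  expect_equal(r$streams$left_acc$x, rep(0, 321), tolerance = 1e-12)
  expect_equal(r$streams$left_acc$y, rep(1, 321), tolerance = 1e-12)

  set.seed(5)
  mats <- stats::setNames(replicate(4, random_rotation(), simplify = FALSE),
                          sensor_ids())
  c3 <- make_test_capture()
  r3 <- align_axes(c3, calibration_set(mats))
  for (id in sensor_ids()) {
    before <- with(c3$streams[[id]], euclidean_norm(x, y, z))
    after <- with(r3$streams[[id]], euclidean_norm(x, y, z))
    expect_lt(max(abs(before - after)), 1e-9)
  }

  bad <- stats::setNames(replicate(4, diag(3) * 1.5, simplify = FALSE),
                         sensor_ids())
  expect_error(align_axes(c1, bad), "orthonormal")
})

test_that("euclidean_norm matches a per-element oracle", {
  expect_equal(euclidean_norm(3, 4, 0), 5)
  expect_equal(euclidean_norm(numeric(4), numeric(4), numeric(4)),
               numeric(4))
  expect_error(euclidean_norm(1:3, 1:2, 1:3), "lengths differ")
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  oracle <- vapply(1:50, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2),
                   numeric(1))
  expect_equal(euclidean_norm(x, y, z), oracle)
})

test_that("triage filter matches the analytic Butterworth response", {
  dc <- butterworth_lowpass(rep(5, 2000), 3200)
  expect_equal(dc[2000], 5, tolerance = 1e-6)

  # -3 dB at the cutoff
  expect_equal(measured_gain(300), 1 / sqrt(2), tolerance = 0.02)

  # in the lower stopband the discrete filter still tracks the analog
  # roll-off 1/sqrt(1 + (f/fc)^4)
  g500 <- measured_gain(500)
  expect_lt(abs(g500 - 1 / sqrt(1 + (500 / 300)^4)) /
            (1 / sqrt(1 + (500 / 300)^4)), 0.2)

  # near Nyquist the prewarped closed form is the exact reference
  g1500 <- measured_gain(1500)
  expect_lt(abs(g1500 - digital_gain(1500)) / digital_gain(1500), 0.2)

  expect_error(butterworth_lowpass(1:10, rate = 500), "Nyquist")
})

test_that("filter magnitude response is monotone in frequency", {
  gains <- vapply(seq(10, 1590, by = 10), measured_gain, numeric(1))
  expect_true(all(diff(gains) < 1e-3))
})

test_that("resampling preserves band-limited content and stream length arithmetic", {
  s0 <- make_test_capture()$streams$left_acc
  expect_identical(resample_to_common_rate(s0, 3200), s0)

  t800 <- (0:799) / 800
  gy <- sensor_stream("gyro", sin(2 * pi * 50 * t800), numeric(800),
                      numeric(800))
  up <- resample_to_common_rate(gy, 3200)
  expect_equal(up$actual_rate, 3200)
  expect_length(up$x, 3200)
  core <- up$x[400:2800]
  expect_equal(max(abs(core)), 1, tolerance = 0.01)

  n <- 3180
  jit <- sensor_stream("left_acc", sin(2 * pi * 40 * (0:(n - 1)) / 3180),
                       numeric(n), numeric(n), actual_rate = 3180)
  rj <- resample_to_common_rate(jit, 3200)
  expect_lte(abs(length(rj$x) - n * 3200 / 3180), 1)

  bad <- s0; bad$x[3] <- NA
  expect_error(resample_to_common_rate(bad, 3200), "non-finite")
})

make_continuous_streams <- function(norm_pulse_at, n = 3200, amp = 30) {
  x <- numeric(n)
  x[norm_pulse_at] <- amp
  list(left_acc = sensor_stream("left_acc", x, numeric(n), numeric(n)),
       centre_acc = sensor_stream("centre_acc", numeric(n), numeric(n),
                                  numeric(n)),
       right_acc = sensor_stream("right_acc", numeric(n), numeric(n),
                                 numeric(n)),
       gyro = sensor_stream("gyro", numeric(n %/% 4), numeric(n %/% 4),
                            numeric(n %/% 4)))
}

test_that("onboard trigger windows are 20 ms lead-in / 80 ms tail", {
  # trigger at 0-based sample 640 -> window [576, 896], 321 samples
  caps <- emulate_onboard_trigger(make_continuous_streams(641))
  expect_length(caps, 1)
  expect_length(caps[[1]]$streams$left_acc$x, 321)
  expect_equal(caps[[1]]$trigger_index, 64L)
  expect_equal(which(caps[[1]]$streams$left_acc$x == 30), 65)

  # two triggers 50 ms apart merge (50 < 80)
  streams <- make_continuous_streams(641)
  streams$left_acc$x[641 + 160] <- 25
  caps <- emulate_onboard_trigger(streams)
  expect_length(caps, 1)
  expect_length(caps[[1]]$streams$left_acc$x, 321 + 160)

  # sub-threshold peaks never trigger
  expect_length(emulate_onboard_trigger(make_continuous_streams(641,
                                                               amp = 9.9)),
                0)
})

test_that("re-triggering a captured window reproduces it", {
  corp <- small_corpus(n = 20, seed = 9)
  for (c in corp$captures[1:8]) {
    again <- emulate_onboard_trigger(c$streams)
    expect_length(again, 1)
    expect_equal(again[[1]]$streams$left_acc$x, c$streams$left_acc$x)
  }
})

fake_processed <- function(norm_series, rate = 3200) {
  structure(list(left_norm = norm_series, rate = rate),
            class = "processed_capture")
}

test_that("triage keeps low-frequency impacts and drops high-frequency bursts", {
  t <- (0:320) / 3200
  expect_true(triage_capture(fake_processed(abs(50 * sin(2 * pi * 60 * t)))))
  # a 12 g 500 Hz burst crosses the 10 g raw trigger, but its rectified
  # norm carries only ~0.64 x 12 g of sub-cutoff content
  expect_false(triage_capture(fake_processed(abs(12 * sin(2 * pi * 500 *
                                                          t)))))
  expect_false(triage_capture(fake_processed(numeric(321))))
})

test_that("resample and norm commute for band-limited signals", {
  t800 <- (0:799) / 800
  x <- 3 * sin(2 * pi * 40 * t800)
  y <- 2 * cos(2 * pi * 65 * t800)
  z <- sin(2 * pi * 110 * t800) + 4
  s <- sensor_stream("gyro", x, y, z)
  norm_then_resample <- signal::resample(euclidean_norm(x, y, z), 4, 1)
  r <- resample_to_common_rate(s, 3200)
  resample_then_norm <- euclidean_norm(r$x, r$y, r$z)
  core <- 200:3000
  expect_lt(max(abs(norm_then_resample[core] - resample_then_norm[core])) /
            max(resample_then_norm), 0.02)
})
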