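test_that("estimate_delay recovers known shifts and matches brute force", {
  # shifted impulses: x at 5, y at 8 -> x leads by 3
  x <- numeric(20); x[5] <- 1
  y <- numeric(20); y[8] <- 1
  expect_identical(estimate_delay(x, y), 3L)

  # identity -> zero lag
  z <- rnorm(64)
  expect_identical(estimate_delay(z, z), 0L)

  # sinusoid shifted by 37 samples, N = 1000
  s <- sin(2 * pi * (0:999) / 125)
  expect_identical(estimate_delay(s, circshift_by(s, 37)), 37L)
  expect_identical(brute_delay(s, circshift_by(s, 37)), 37L)

  # oracle equivalence on random signals, odd and even N, both signs
  set.seed(42)
  for (n in c(32L, 97L, 256L)) {
    x <- cumsum(rnorm(n))  # smooth-ish random series
    for (k in c(-11L, 0L, 5L)) {
      # shifting y right by k delays it, so x leads y by k
      y <- circshift_by(x, k)
      expect_identical(estimate_delay(x, y), brute_delay(x, y))
      expect_identical(estimate_delay(x, y), k)
    }
  }
})

test_that("estimate_delay flags constant input and checks lengths", {
  expect_error(estimate_delay(1:5, 1:6), "equal length")
  expect_warning(d <- estimate_delay(rep(1, 10), rnorm(10)), "constant")
  expect_identical(as.integer(d), 0L)
  expect_true(attr(d, "undefined"))
})

test_that("smooth_and_resample obeys its window, edge and length contracts", {
  # constant series unchanged, any window
  expect_equal(smooth_and_resample(rep(3.5, 50), 7), rep(3.5, 50))

  # unit impulse, window 40: interior plateau of height 1/40 over 40 samples
  x <- numeric(200); x[100] <- 1
  sm <- smooth_and_resample(x, 40)
  expect_equal(sum(sm > 1e-12), 40)
  expect_equal(unique(round(sm[sm > 1e-12], 12)), round(1 / 40, 12))

  # length contract under decimation
  expect_length(smooth_and_resample(rnorm(100), 5, 10), 10)
  expect_length(smooth_and_resample(rnorm(101), 5, 10), 11)

  # direct brute-force oracle, shrinking windows at the edges
  set.seed(7)
  y <- rnorm(30)
  w <- 8L; h2 <- w %/% 2L; h1 <- w - 1L - h2
  oracle <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - h1):min(length(y), i + h2)]), numeric(1))
  expect_equal(smooth_and_resample(y, w), oracle)

  # mean of a periodic signal over whole periods is conserved
  per <- rep(sin(2 * pi * (0:49) / 50), 8)
  expect_equal(mean(smooth_and_resample(per, 25)), mean(per),
               tolerance = 1e-3)

  expect_error(smooth_and_resample(rnorm(10), 11), "window")
})

test_that("compute_q_inst applies the piston kinematics", {
  t <- seq(0, 1, by = 1e-3)
  # 10 cm/s ramp through a 10 cm^2 piston: 100 ml/s
  q <- compute_q_inst(10 * t, 10, 0, rate = 1000)
  expect_equal(q, rep(100, length(t)))
  # frozen piston: flow is minus the retrograde flow
  qr <- abs(rnorm(length(t)))
  expect_equal(compute_q_inst(rep(2, length(t)), 10, qr, rate = 1000), -qr)
  expect_error(compute_q_inst(t, 10, qr[1:5], rate = 1000), "length")
})

test_that("detect_ejection_window finds the flow support", {
  n <- 1000
  t <- (0:(n - 1)) / n
  # half-sine pulse on [0.2, 0.5]: window matches the 2% support
  q <- ifelse(t >= 0.2 & t <= 0.5, sin(pi * (t - 0.2) / 0.3), 0)
  w <- detect_ejection_window(q)
  sup <- range(which(q > 0.02 * max(q)))
  expect_lte(abs(w[["start"]] - sup[1]), 2)
  expect_lte(abs(w[["end"]] - 1 - sup[2]), 2)

  # constant positive flow: the whole beat
  expect_equal(unname(detect_ejection_window(rep(5, 100))), c(1, 101))

  # two pulses: the longer (second) one wins
  q2 <- c(rep(0, 10), rep(1, 20), rep(0, 30), rep(1, 50), rep(0, 10))
  w2 <- detect_ejection_window(q2)
  expect_equal(unname(w2), c(61, 111))

  # short sub-threshold dips are bridged by the hysteresis
  q3 <- c(rep(0, 10), rep(1, 30), rep(0, 3), rep(1, 30), rep(0, 10))
  expect_equal(unname(detect_ejection_window(q3)), c(11, 74))

  expect_error(detect_ejection_window(rep(0, 50)), "nonpositive")
})

test_that("select_peak_points matches brute-force 97% filtering", {
  # constant flow and AVA: the point is (Q0, A0)
  syn <- fake_synced(rep(400, 100), rep(0.3, 100))
  pt <- select_peak_points(syn)
  expect_equal(pt$q_peak_mlps, 400)
  expect_equal(pt$ava_peak_frac, 0.3)
  expect_equal(pt$q_peak_idx_mps, 400 / 500)

  # half-sine peak 500 ml/s: selection is exactly q > 485, means match
  # direct enumeration
  n <- 2000
  q <- 500 * sin(pi * (0:(n - 1)) / (n - 1))
  a <- 0.1 + 0.4 * (q / 500)^2
  syn <- fake_synced(q, a)
  pt <- select_peak_points(syn)
  sel <- q > 0.97 * max(q)
  expect_identical(sum(sel), sum(q > 485))
  expect_equal(pt$q_peak_mlps, mean(q[sel]))
  expect_equal(pt$ava_peak_frac, mean(a[sel]))

  # invariant to beat concatenation order
  b1 <- 300 * sin(pi * (0:999) / 999)
  b2 <- 500 * sin(pi * (0:999) / 999)
  mk <- function(qq) fake_synced(qq, qq / 1000,
                                 beats = list(c(start = 1L, end = 1001L),
                                              c(start = 1001L, end = 2001L)))
  p12 <- select_peak_points(mk(c(b1, b2)))
  p21 <- select_peak_points(mk(c(b2, b1)))
  expect_equal(p12$q_peak_mlps, p21$q_peak_mlps)
  expect_equal(p12$ava_peak_frac, p21$ava_peak_frac)

  # per-beat option pools each beat's own top 3%
  pb <- select_peak_points(mk(c(b1, b2)), pooled = FALSE)
  sel1 <- b1 > 0.97 * max(b1); sel2 <- b2 > 0.97 * max(b2)
  expect_equal(pb$q_peak_mlps, mean(c(b1[sel1], b2[sel2])))
})

test_that("synchronize undoes injected channel leads", {
  cfg <- tiny_config()
  tr <- ground_truth()

  # no leads: synchronizing a lead-free recording equals synchronizing
  # with explicit zero delays
  rec0 <- generate_recording(synth_config(n_valves = 3, seed = 1,
                                          delays_ms = c(camera = 0,
                                                        q_retro = 0)),
                             tr, "A001", "a", 2.5)
  s0a <- synchronize(rec0)
  s0b <- synchronize(rec0, delays_ms = c(camera = 0, q_retro = 0))
  expect_equal(s0a$ava_frac, s0b$ava_frac)

  # +14 ms camera lead: synchronizing the delayed recording restores the
  # lead-free recording exactly (28 frames at 2 kHz); skipping the
  # correction leaves the AVA channel 28 frames early
  rec <- generate_recording(cfg, tr, "A001", "a", 2.5)
  syn <- synchronize(rec)
  expect_equal(syn$ava_frac, s0a$ava_frac, tolerance = 1e-12)
  expect_equal(syn$q_inst_mlps, s0a$q_inst_mlps, tolerance = 1e-12)
  raw <- synchronize(rec, delays_ms = c(camera = 0, q_retro = 0))
  ii <- 100:(length(s0a$ava_frac) - 100)   # interior: away from the
  expect_equal(raw$ava_frac[ii],           # non-circular smoothing edges
               circshift_by(s0a$ava_frac, -28)[ii], tolerance = 1e-12)

  # round trip: the lead measured from the camera copy of the pump
  # position feeds back into synchronize and restores alignment within
  # one frame
  pos_cam_ref <- rec$channels$pump_position[seq(1, cfg$daq_rate * 3,
                                                by = 10)]
  meas <- estimate_delay(rec$pump_position_cam, pos_cam_ref)
  expect_lte(abs(as.integer(meas) - 28L), 1L)
  syn2 <- synchronize(rec, delays_ms = c(camera = meas / 2, q_retro = 11))
  # meas is in frames at 2 kHz; /2 converts to ms
  expect_equal(syn2$ava_frac, syn$ava_frac, tolerance = 1e-9)
})

test_that("pixel calibration and mask areas follow the counting arithmetic", {
  expect_equal(calibrate_pixel_area(100, 10000), 0.01)
  expect_equal(calibrate_pixel_area(3 * 100, 3 * 10000),
               calibrate_pixel_area(100, 10000))
  expect_error(calibrate_pixel_area(100, 0), "positive")

  expect_equal(area_from_mask(matrix(0, 5, 5), 0.01), 0)
  expect_equal(area_from_mask(matrix(1, 20, 20), 0.01), 4)

  # synthetic disc raster: recovered pixel area times count reproduces
  # the true disc area within 1%
  r <- 50
  xy <- expand.grid(x = -60:60, y = -60:60)
  disc <- matrix((xy$x^2 + xy$y^2) <= r^2, 121, 121)
  true_area <- pi * r^2 * 0.01   # per-pixel area 0.01 mm^2
  ppx <- calibrate_pixel_area(true_area, sum(disc))
  expect_equal(ppx * sum(disc), true_area, tolerance = 1e-12)
  expect_equal(area_from_mask(disc, 0.01), true_area, tolerance = 0.01)

  # ellipse mask: area matches pi*a*b within rasterization error
  a <- 40; b <- 25
  ell <- matrix((xy$x / a)^2 + (xy$y / b)^2 <= 1, 121, 121)
  expect_equal(area_from_mask(ell, 1), pi * a * b, tolerance = 0.01)
})
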