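test_that("peak dataset has one point per factorial cell and is seed-deterministic", {
  cfg <- synth_config(seed = 11)
  tr <- ground_truth()
  d <- generate_peak_dataset(cfg, tr)
  expect_equal(nrow(d), 11 * 3 * 10)
  expect_setequal(names(d), c("valve_id", "grade", "co_lpm",
                              "q_peak_idx_mps", "q_peak_mlps",
                              "ava_peak_frac", "s", "lvot_area_mm2"))
  expect_equal(nrow(unique(d[, c("valve_id", "grade", "co_lpm")])), nrow(d))
  expect_true(all(d$ava_peak_frac >= 0 & d$ava_peak_frac <= 1))
  expect_true(all(d$q_peak_idx_mps > 0))

  expect_identical(d, generate_peak_dataset(cfg, tr))
  d2 <- generate_peak_dataset(synth_config(seed = 12), tr)
  expect_false(all(d$ava_peak_frac == d2$ava_peak_frac))
})

test_that("noise-free AVA equals the sigmoid ground truth exactly", {
  tr <- noise_free_truth()
  d <- generate_peak_dataset(tiny_config(), tr)
  expect_equal(d$ava_peak_frac,
               ava_sigmoid(d$q_peak_idx_mps, d$s, tr$theta_star),
               tolerance = 1e-12)
})

test_that("invalid configurations and truths are rejected", {
  expect_error(synth_config(n_valves = 1), ">= 2")
  expect_error(synth_config(cardiac_outputs = c(2, 1)), "increasing")
  expect_error(synth_config(cardiac_outputs = numeric(0)))
  expect_error(synth_config(daq_rate = 20000, camera_rate = 1500),
               "divide")
  expect_error(ground_truth(noise_sd_ava = -0.1), "non-negative")
  expect_error(ground_truth(s_star_per_grade = c(a = 1.1, b = 1.2)),
               "native")
  expect_error(ground_truth(theta_star = c(-1, 3, 2)), "positive")
})

test_that("inject_missing removes the requested rows and protects valves", {
  d <- generate_peak_dataset(synth_config(seed = 5), ground_truth())
  expect_identical(inject_missing(d, 0), d)
  d4 <- inject_missing(d, 4, seed = 2)
  expect_equal(nrow(d4), 326)
  expect_setequal(unique(d4$valve_id), unique(d$valve_id))
  expect_error(inject_missing(d, nrow(d)), "smaller")

  # wiping out a whole valve is rejected: with 3 of 4 points removed one
  # of the two valves must lose both its points
  small <- d[d$valve_id %in% c("A001", "A002") & d$grade == "a" &
               d$co_lpm %in% c(0.5, 1.0), ]
  expect_error(inject_missing(small, 3, seed = 1), "every point")
})

test_that("recordings are periodic, deterministic and carry the configured leads", {
  cfg <- tiny_config()
  tr <- ground_truth()
  rec <- generate_recording(cfg, tr, "A001", "a", 2.5)
  n_daq <- cfg$daq_rate * 60 / cfg$heart_rate_bpm * cfg$n_beats
  expect_length(rec$channels$pump_position, n_daq)
  expect_length(rec$ava_series, n_daq / 10)

  # pump position returns to its start each cycle (periodic piston)
  pos <- rec$channels$pump_position
  cyc <- length(pos) / cfg$n_beats
  expect_equal(pos[1:cyc], pos[(cyc + 1):(2 * cyc)], tolerance = 1e-9)

  # camera channel leads the DAQ by the configured 14 ms: the camera copy
  # of the pump position is 28 frames (at 2 kHz) ahead of the decimated
  # DAQ copy
  pos_daq_cam <- pos[seq(1, length(pos), by = 10)]
  expect_equal(as.integer(estimate_delay(rec$pump_position_cam,
                                         pos_daq_cam)),
               28L)

  expect_identical(rec, generate_recording(cfg, tr, "A001", "a", 2.5))
})

test_that("zero retrograde amplitude removes the notch from the flow", {
  tr <- ground_truth()
  rec0 <- generate_recording(tiny_config(retro_frac = 0), tr,
                             "A001", "a", 2.5)
  expect_true(all(rec0$channels$q_retro == 0))
  # pump-derived flow then IS the transvalvular flow
  q0 <- compute_q_inst(rec0$channels$pump_position,
                       rec0$piston_area_cm2, rec0$channels$q_retro,
                       rate = rec0$daq_rate)
  q0b <- compute_q_inst(rec0$channels$pump_position,
                        rec0$piston_area_cm2, 0, rate = rec0$daq_rate)
  expect_equal(q0, q0b)

  # with the default amplitude the notch shows as a dip inside early
  # ejection of the unsmoothed flow: locally non-monotone before the peak
  rec <- generate_recording(tiny_config(), tr, "A001", "a", 2.5)
  syn <- synchronize(rec, flow_window = 1L, ava_window = 1L)
  b <- syn$beats[[2]]
  q <- syn$q_inst_mlps[b[1]:(b[2] - 1)]
  pre_peak <- q[seq_len(max(which(q > 0.99 * max(q))))]
  dip_depth <- max(cummax(pre_peak) - pre_peak)
  expect_gt(dip_depth, 0.05 * max(q))   # dip before the plateau end
})

test_that("generated flow integrates to the cardiac-output setpoint within 1%", {
  tr <- ground_truth()
  for (co in c(0.5, 3.0, 5.0)) {
    rec <- generate_recording(tiny_config(), tr, "A002", "b", co)
    syn <- synchronize(rec)
    b <- syn$beats[[2]]
    q_pos <- pmax(syn$q_inst_mlps[b[1]:(b[2] - 1)], 0)
    co_rec <- sum(q_pos) / syn$rate * rec$heart_rate_bpm / 1000
    expect_equal(co_rec, co, tolerance = 0.01)
  }
})

test_that("aortic pressure meets the 110/70 afterload targets", {
  rec <- generate_recording(tiny_config(), ground_truth(), "A001", "c", 4.0)
  expect_equal(max(rec$channels$p_ao), 110, tolerance = 0.01)
  expect_equal(min(rec$channels$p_ao), 70, tolerance = 0.01)
  # LV pressure exceeds aortic pressure during ejection (positive gradient)
  syn <- synchronize(rec)
  ej <- syn$ejection[[2]]
  mid <- floor(mean(ej))
  expect_gt(syn$p_lv[mid], syn$p_ao[mid])
})
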