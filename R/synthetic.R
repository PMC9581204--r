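#' Configuration of the synthetic flow-loop experiment
#'
#' Describes the factorial design of the in-vitro study that the generator
#' emulates: `n_valves` valves, each measured at every stiffness grade and
#' cardiac-output setpoint, on a pulsatile left-heart simulator with a
#' 20 kHz data-acquisition system and a 2 kHz high-speed camera. Defaults
#' reproduce the reference experiment: 11 valves, grades a/b/c, cardiac
#' outputs 0.5--5.0 L/min in steps of 0.5, afterload 110/70 mmHg, camera
#' channel leading the DAQ by 14 ms and the flow probe by 11 ms.
#'
#' @param n_valves number of valves (>= 2, cross-validation needs >= 2 folds).
#' @param grades ordered character vector of stiffness grade labels; the
#'   first is the native grade.
#' @param cardiac_outputs strictly increasing setpoints in L/min.
#' @param seed integer; fully determines all generator output.
#' @param daq_rate,camera_rate sampling rates in Hz; `daq_rate` must be an
#'   integer multiple of `camera_rate` so decimation is exact.
#' @param heart_rate_bpm pump rate; the design fixes the rate and varies
#'   the stroke volume with the cardiac output.
#' @param n_beats beats per recording.
#' @param delays_ms named channel leads relative to the DAQ time base, in
#'   ms; `camera` applies to the valve-area series (and the camera copy of
#'   the pump position), `q_retro` to the flow probe.
#' @param p_systolic,p_diastolic afterload targets in mmHg.
#' @param lvot_area_mm2 optional per-valve LVOT areas (mm^2); by default
#'   drawn once from the seed around 530 mm^2.
#' @param piston_area_cm2 pump piston area.
#' @param retro_frac amplitude of the retrograde-flow notch as a fraction
#'   of the peak transvalvular flow.
#' @param ramp_frac cosine ramp fraction of the ejection flow pulse.
#' @param ava_lag_s time constant of the first-order valve
#'   opening/closing lag applied to the static AVA response.
#' @param valve_sd,cell_sd relative spread of the valve-specific and
#'   cell-specific jitter on the peak indexed flow.
#' @return a list of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' @export
synth_config <- function(n_valves = 11L,
                         grades = c("a", "b", "c"),
                         cardiac_outputs = seq(0.5, 5.0, by = 0.5),
                         seed = 1L,
                         daq_rate = 20000,
                         camera_rate = 2000,
                         heart_rate_bpm = 60,
                         n_beats = 3L,
                         delays_ms = c(camera = 14, q_retro = 11),
                         p_systolic = 110,
                         p_diastolic = 70,
                         lvot_area_mm2 = NULL,
                         piston_area_cm2 = 10,
                         retro_frac = 0.08,
                         ramp_frac = 0.1,
                         ava_lag_s = 0.015,
                         valve_sd = 0.08,
                         cell_sd = 0.02) {
  stop_if_not(is_count(n_valves) && n_valves >= 2,
              "'n_valves' must be an integer >= 2")
  stop_if_not(length(grades) >= 1L && !anyDuplicated(grades),
              "'grades' must be non-empty unique labels")
  stop_if_not(length(cardiac_outputs) >= 1L &&
                all(diff(cardiac_outputs) > 0) && all(cardiac_outputs > 0),
              "'cardiac_outputs' must be positive and strictly increasing")
  stop_if_not(is_count(seed), "'seed' must be a non-negative integer")
  stop_if_not(daq_rate > 0 && camera_rate > 0 &&
                daq_rate %% camera_rate == 0,
              "camera rate must divide the DAQ rate for exact decimation")
  stop_if_not(heart_rate_bpm > 0 && is_count(n_beats) && n_beats >= 1,
              "invalid heart rate or beat count")
  stop_if_not(p_systolic > p_diastolic && p_diastolic > 0,
              "afterload targets must satisfy systolic > diastolic > 0")
  if (!is.null(lvot_area_mm2))
    stop_if_not(length(lvot_area_mm2) == n_valves && all(lvot_area_mm2 > 0),
                "'lvot_area_mm2' must hold one positive area per valve")
  structure(list(
    n_valves = as.integer(n_valves), grades = as.character(grades),
    cardiac_outputs = as.numeric(cardiac_outputs), seed = as.integer(seed),
    daq_rate = daq_rate, camera_rate = camera_rate,
    heart_rate_bpm = heart_rate_bpm, n_beats = as.integer(n_beats),
    delays_ms = delays_ms, p_systolic = p_systolic,
    p_diastolic = p_diastolic, lvot_area_mm2 = lvot_area_mm2,
    piston_area_cm2 = piston_area_cm2, retro_frac = retro_frac,
    ramp_frac = ramp_frac, ava_lag_s = ava_lag_s,
    valve_sd = valve_sd, cell_sd = cell_sd), class = "synth_config")
}

## anchors tying the cardiac-output setpoint to the indexed mean systolic
## flow observed on the loop (L/min -> m/s); the default linear map is the
## least-squares line through them
CO_FLOW_ANCHORS <- data.frame(co_lpm = c(0.5, 2.5, 5.0),
                              q_idx_mps = c(0.24, 0.57, 0.96))

#' Ground truth of the synthetic AVA--flow relation
#'
#' Holds the sigmoid hyperparameters, the per-grade relative stiffness,
#' the AVA noise level, and the linear map from cardiac-output setpoint to
#' indexed peak flow. Defaults place the synthetic data in the reference regime:
#' \eqn{\theta = (0.72, 3.14, 2.80)}, \eqn{s = (1, 1.16, 1.34)} for grades
#' a/b/c, and a CO-to-flow map calibrated by least squares to the observed
#' indexed flows (0.24, 0.57, 0.96 m/s at 0.5, 2.5, 5.0 L/min), giving
#' slope ~0.160 and intercept ~0.164.
#'
#' @param theta_star sigmoid hyperparameters (all positive);
#'   \eqn{\theta_5} in s/m.
#' @param s_star_per_grade named relative stiffness per grade; the native
#'   (first) grade must equal exactly 1.
#' @param noise_sd_ava additive Gaussian noise on the AVA fraction (>= 0).
#' @param co_to_qidx_slope,co_to_qidx_intercept linear map from cardiac
#'   output (L/min) to indexed peak flow (m/s); defaults calibrated from
#'   the anchors above.
#' @return a list of class `"ground_truth"`.
#' @examples
#' tr <- ground_truth()
#' tr$co_to_qidx_slope
#' @export
ground_truth <- function(theta_star = c(0.72, 3.14, 2.80),
                         s_star_per_grade = c(a = 1, b = 1.16, c = 1.34),
                         noise_sd_ava = 0.02,
                         co_to_qidx_slope = NULL,
                         co_to_qidx_intercept = NULL) {
  stop_if_not(length(theta_star) == 3L && all(theta_star > 0),
              "'theta_star' must be three positive values")
  stop_if_not(length(s_star_per_grade) >= 1L && all(s_star_per_grade > 0),
              "'s_star_per_grade' must be positive")
  stop_if_not(s_star_per_grade[[1L]] == 1,
              "the native (first) grade must have relative stiffness 1")
  stop_if_not(is.numeric(noise_sd_ava) && noise_sd_ava >= 0,
              "'noise_sd_ava' must be non-negative")
  if (is.null(co_to_qidx_slope) || is.null(co_to_qidx_intercept)) {
    cf <- coef(lm(q_idx_mps ~ co_lpm, data = CO_FLOW_ANCHORS))
    if (is.null(co_to_qidx_slope)) co_to_qidx_slope <- unname(cf[2L])
    if (is.null(co_to_qidx_intercept)) co_to_qidx_intercept <- unname(cf[1L])
  }
  structure(list(theta_star = theta_star,
                 s_star_per_grade = s_star_per_grade,
                 noise_sd_ava = noise_sd_ava,
                 co_to_qidx_slope = co_to_qidx_slope,
                 co_to_qidx_intercept = co_to_qidx_intercept),
            class = "ground_truth")
}

## One deterministic draw of the whole factorial cell grid. All randomness
## of the generator lives here, in a fixed order, so the point-level and
## waveform-level generators see identical ground truth for a given seed.
synth_cells <- function(config, truth) {
  stop_if_not(inherits(config, "synth_config"), "invalid 'config'")
  stop_if_not(inherits(truth, "ground_truth"), "invalid 'truth'")
  grades <- config$grades
  stop_if_not(all(grades %in% names(truth$s_star_per_grade)),
              "every configured grade needs a ground-truth stiffness")
  set.seed(config$seed)
  nv <- config$n_valves
  valves <- sprintf("A%03d", seq_len(nv))
  lvot <- config$lvot_area_mm2
  if (is.null(lvot)) lvot <- pmax(300, rnorm(nv, 530, 40))
  valve_eff <- pmax(0.5, rnorm(nv, 1, config$valve_sd))
  grid <- expand.grid(valve_id = valves, grade = grades,
                      co_lpm = config$cardiac_outputs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$valve_id, grid$grade, grid$co_lpm), ]
  rownames(grid) <- NULL
  ncell <- nrow(grid)
  cell_eff <- pmax(0.5, rnorm(ncell, 1, config$cell_sd))
  ava_noise <- rnorm(ncell, 0, truth$noise_sd_ava)
  iv <- match(grid$valve_id, valves)
  base_q <- truth$co_to_qidx_intercept + truth$co_to_qidx_slope * grid$co_lpm
  grid$q_peak_idx_mps <- base_q * valve_eff[iv] * cell_eff
  grid$lvot_area_mm2 <- lvot[iv]
  ## q[ml/s] = q_idx[m/s] * LVOT[mm^2] (1e-6 m^3/s per m/s * mm^2)
  grid$q_peak_mlps <- grid$q_peak_idx_mps * grid$lvot_area_mm2
  grid$s <- unname(truth$s_star_per_grade[grid$grade])
  grid$ava_true_frac <- ava_sigmoid(grid$q_peak_idx_mps, grid$s,
                                    truth$theta_star)
  grid$ava_peak_frac <- pmin(1, pmax(0, grid$ava_true_frac + ava_noise))
  grid
}

#' Generate the point-level peak dataset
#'
#' One \eqn{(\bar Q_{peak}, \bar{AVA}_{peak})} point per (valve, grade,
#' cardiac-output) cell: the indexed peak flow follows the linear
#' CO-to-flow map with valve- and cell-specific jitter, and the AVA
#' fraction is the sigmoid ground truth plus Gaussian noise, clipped to
#' \[0, 1\]. With the defaults (11 valves, 3 grades, 10 outputs) the
#' dataset has 330 points. Output is byte-identical for a given seed.
#'
#' @param config a [synth_config()].
#' @param truth a [ground_truth()].
#' @return a data frame of class `"valve_dataset"` with columns
#'   `valve_id`, `grade`, `co_lpm`, `q_peak_idx_mps`, `q_peak_mlps`,
#'   `ava_peak_frac`, `s` (assigned relative stiffness) and
#'   `lvot_area_mm2`.
#' @examples
#' d <- generate_peak_dataset(synth_config(seed = 7), ground_truth())
#' nrow(d)  # 330
#' @export
generate_peak_dataset <- function(config, truth) {
  g <- synth_cells(config, truth)
  out <- g[, c("valve_id", "grade", "co_lpm", "q_peak_idx_mps",
               "q_peak_mlps", "ava_peak_frac", "s", "lvot_area_mm2")]
  class(out) <- c("valve_dataset", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "config_seed") <- config$seed
  out
}

#' Remove random points from a peak dataset
#'
#' Emulates missing experiment cells (e.g. a camera failure at one
#' setpoint) by deleting `n_missing` rows uniformly at random under the
#' given seed. A draw that would remove every point of a valve is
#' rejected with an error, since leave-one-valve-out folds need each
#' valve to retain data; removing all points of one grade of one valve is
#' allowed.
#'
#' @param dataset a `"valve_dataset"` data frame.
#' @param n_missing number of rows to remove (< total rows).
#' @param seed integer seed for the uniform draw.
#' @return the reduced dataset, same class and attributes.
#' @export
inject_missing <- function(dataset, n_missing, seed = 1L) {
  stop_if_not(is.data.frame(dataset), "'dataset' must be a data frame")
  stop_if_not(is_count(n_missing), "'n_missing' must be a count")
  n <- nrow(dataset)
  stop_if_not(n_missing < n,
              "'n_missing' must be smaller than the number of points")
  if (n_missing == 0L) return(dataset)
  set.seed(seed)
  drop <- sample.int(n, n_missing)
  out <- dataset[-drop, , drop = FALSE]
  lost <- setdiff(unique(dataset$valve_id), unique(out$valve_id))
  if (length(lost) > 0L)
    stop("removal would delete every point of valve(s): ",
         paste(lost, collapse = ", "))
  rownames(out) <- NULL
  out
}

## ---- waveform-level generator ---------------------------------------------

## Build one cycle of each channel for one cell. The ejection pulse is a
## cosine-tapered plateau whose peak equals the cell's ground-truth peak
## flow and whose duration is set by the stroke volume; a Gaussian
## retrograde notch is carved near ejection onset and compensated in the
## stroke volume so the transvalvular cycle volume still matches the
## cardiac output. The camera channel applies a first-order opening lag
## and is amplitude-calibrated so that the full measurement chain
## (smoothing, decimation, 97 % peak pooling) reproduces the cell's
## ground-truth AVA point.
build_cell_waveforms <- function(config, truth, cell) {
  fs <- config$daq_rate
  dec <- as.integer(config$daq_rate / config$camera_rate)
  t_cyc <- 60 / config$heart_rate_bpm
  n1 <- round(t_cyc * fs)
  stop_if_not(abs(n1 - t_cyc * fs) < 1e-9,
              "cycle length must be an integer number of DAQ samples")
  dt <- 1 / fs
  t <- (seq_len(n1) - 1L) * dt

  sv_ml <- cell$co_lpm * 1000 / config$heart_rate_bpm
  qp <- cell$q_peak_mlps
  r <- config$ramp_frac
  mean_frac <- 1 - r                    # mean/peak of the tapered plateau
  ## retrograde notch, compensated in the ejected volume
  t_ej0 <- sv_ml / (mean_frac * qp)
  amp_retro <- config$retro_frac * qp
  sig_retro <- min(0.006, t_ej0 / 20)
  v_notch <- amp_retro * sig_retro * sqrt(2 * pi)
  t_ej <- (sv_ml + v_notch) / (mean_frac * qp)
  t0 <- 0.1
  stop_if_not(t0 + t_ej < t_cyc - 0.2,
              "ejection does not fit into the cycle at this heart rate")

  shape <- tukey_pulse((t - t0) / t_ej, r)
  q_ej <- qp * shape
  tn <- t0 + 0.18 * t_ej   # just past the opening ramp: the subtraction
                           # carves a visible notch into early ejection
  q_retro <- amp_retro * exp(-(t - tn)^2 / (2 * sig_retro^2))
  q_inst <- q_ej - q_retro

  ## diastolic refill returning exactly the ejected (discrete) volume so
  ## the piston position is periodic to machine precision
  f0 <- t0 + t_ej + 0.1
  f1 <- t_cyc - 0.05
  fill_shape <- ifelse(t >= f0 & t <= f1,
                       (1 - cos(2 * pi * (t - f0) / (f1 - f0))) / 2, 0)
  fill_scale <- sum(q_ej) / sum(fill_shape)
  q_pump <- q_ej - fill_scale * fill_shape
  position <- cumsum(q_pump) * dt / config$piston_area_cm2   # cm

  ## aortic pressure: tapered systolic bump 70 -> 110 -> 70 mmHg over the
  ## ejection, flat diastolic runoff at the diastolic target
  p_ao <- config$p_diastolic +
    (config$p_systolic - config$p_diastolic) * shape
  ## transvalvular gradient grows with flow^2 and stiffness grade
  grad_target <- pressure_gradient_target(cell$co_lpm, cell$grade,
                                          config$grades)
  msq <- mean(shape[shape > 0]^2)
  kg <- grad_target / (msq * qp^2)
  dp <- kg * q_inst^2 * (shape > 0)
  p_lv_dia <- 8
  p_lv <- ifelse(shape > 0, p_ao + dp, p_lv_dia)
  ## short isovolumic ramps so the LV trace is continuous
  ramp_n <- round(0.015 * fs)
  i_on <- which(shape > 0)[1L]
  i_off <- max(which(shape > 0))
  up <- seq_len(ramp_n)
  pre <- i_on - rev(up)
  pre_ok <- pre >= 1L
  p_lv[pre[pre_ok]] <- p_lv_dia +
    (p_lv[i_on] - p_lv_dia) * (up[pre_ok] / (ramp_n + 1))
  post <- i_off + up
  post_ok <- post <= n1
  p_lv[post[post_ok]] <- p_lv[i_off] -
    (p_lv[i_off] - p_lv_dia) * (up[post_ok] / (ramp_n + 1))

  ## camera channel: static sigmoid response of the instantaneous indexed
  ## flow, first-order lag, periodic steady state via one warm-up cycle
  q_idx_inst <- pmax(q_inst, 0) / cell$lvot_area_mm2
  ava_static <- ava_sigmoid(q_idx_inst, cell$s, truth$theta_star)
  alpha <- dt / (config$ava_lag_s + dt)
  lagged <- stats::filter(alpha * rep(ava_static, 2L), 1 - alpha,
                          method = "recursive")
  ava_daq <- as.numeric(lagged[(n1 + 1L):(2L * n1)])
  ava_cam <- ava_daq[seq(1L, n1, by = dec)]

  ## amplitude calibration of the camera gain: the processed pool mean of
  ## the generated series must equal the cell's ground-truth AVA point
  q_proc <- smooth_and_resample(q_inst, window_samples = 800L,
                                decimate = dec)
  ava_proc <- smooth_and_resample(ava_cam, window_samples = 40L,
                                  decimate = 1L)
  pool <- q_proc > 0.97 * max(q_proc)
  ava_cam <- ava_cam * (cell$ava_peak_frac / mean(ava_proc[pool]))

  list(t = t, position = position, q_pump = q_pump, q_retro = q_retro,
       p_lv = p_lv, p_ao = p_ao, ava_cam = ava_cam)
}

## mean-gradient target (mmHg) as a function of cardiac output and grade;
## affine growth with CO scaled by per-grade factors mirroring the observed
## gradient ratios at high output
pressure_gradient_target <- function(co_lpm, grade, grades) {
  gfac <- c(1, 1.82, 2.68)[match(grade, grades)]
  if (is.na(gfac)) gfac <- 1
  (6 + 3.44 * co_lpm) * gfac
}

#' Generate one multi-beat flow-loop recording
#'
#' Builds the raw multi-channel recording for a single (valve, grade,
#' cardiac-output) cell: periodic pump position, pump-derived flow with a
#' retrograde notch near ejection onset, LV and aortic pressures meeting
#' the 110/70 mmHg afterload targets, a camera-rate valve-area series
#' with first-order opening/closing dynamics, and a camera-rate copy of
#' the pump position (the reference used to measure the camera delay).
#' Channels are circularly advanced by the configured leads
#' (`delays_ms`).
#'
#' @param config a [synth_config()].
#' @param truth a [ground_truth()].
#' @param valve_id,grade,co_lpm cell coordinates; must match the
#'   configured factorial design.
#' @return a list of class `"signal_recording"` with elements `channels`
#'   (named list: `pump_position` cm, `q_pump` ml/s, `q_retro` ml/s,
#'   `p_lv` mmHg, `p_ao` mmHg at `daq_rate`), `ava_series` and
#'   `pump_position_cam` (at `camera_rate`), sampling rates, LVOT and
#'   piston areas, the cell coordinates, and the generating delays.
#' @examples
#' cfg <- synth_config(n_valves = 2, seed = 1)
#' rec <- generate_recording(cfg, ground_truth(), "A001", "a", 5.0)
#' @export
generate_recording <- function(config, truth, valve_id, grade, co_lpm) {
  cells <- synth_cells(config, truth)
  row <- cells[cells$valve_id == valve_id & cells$grade == grade &
                 abs(cells$co_lpm - co_lpm) < 1e-9, ]
  stop_if_not(nrow(row) == 1L, "cell not found in the configured design")
  cell <- as.list(row[1L, ])
  wf <- build_cell_waveforms(config, truth, cell)
  nb <- config$n_beats
  tile <- function(x) rep(x, nb)
  ch <- list(pump_position = tile(wf$position), q_pump = tile(wf$q_pump),
             q_retro = tile(wf$q_retro), p_lv = tile(wf$p_lv),
             p_ao = tile(wf$p_ao))
  ava <- tile(wf$ava_cam)
  pos_cam <- tile(wf$position[seq(1L, length(wf$position),
                                  by = config$daq_rate / config$camera_rate)])
  ## apply channel leads: a channel that leads by d shows at time t the
  ## value the reference shows at t + d, i.e. it is advanced
  d <- config$delays_ms
  adv <- function(x, ms, rate) circshift(x, -round(ms / 1000 * rate))
  if (!is.na(d["q_retro"]) && d["q_retro"] != 0)
    ch$q_retro <- adv(ch$q_retro, d[["q_retro"]], config$daq_rate)
  if (!is.na(d["camera"]) && d["camera"] != 0) {
    ava <- adv(ava, d[["camera"]], config$camera_rate)
    pos_cam <- adv(pos_cam, d[["camera"]], config$camera_rate)
  }
  structure(list(valve_id = valve_id, grade = grade, co_lpm = co_lpm,
                 channels = ch, ava_series = ava,
                 pump_position_cam = pos_cam,
                 daq_rate = config$daq_rate,
                 camera_rate = config$camera_rate,
                 heart_rate_bpm = config$heart_rate_bpm,
                 n_beats = config$n_beats,
                 lvot_area_mm2 = cell$lvot_area_mm2,
                 piston_area_cm2 = config$piston_area_cm2,
                 delays_ms = config$delays_ms,
                 s = cell$s),
            class = "signal_recording")
}

#' Generate recordings for a set of cells
#'
#' Convenience wrapper around [generate_recording()] looping over a subset
#' of the factorial design (defaults to all of it). Recordings at the
#' nominal 20 kHz are sizeable, so restrict `valves`/`grades`/`cos` when
#' only part of the design is needed.
#'
#' @inheritParams generate_recording
#' @param valves,grades,cos optional subsets of valve ids, grade labels
#'   and cardiac outputs.
#' @return a list of `"signal_recording"` objects.
#' @export
generate_recordings <- function(config, truth, valves = NULL,
                                grades = NULL, cos = NULL) {
  all_valves <- sprintf("A%03d", seq_len(config$n_valves))
  if (is.null(valves)) valves <- all_valves
  if (is.null(grades)) grades <- config$grades
  if (is.null(cos)) cos <- config$cardiac_outputs
  stop_if_not(all(valves %in% all_valves) &&
                all(grades %in% config$grades) &&
                all(cos %in% config$cardiac_outputs),
              "requested cells outside the configured design")
  out <- list()
  for (v in valves) for (g in grades) for (co in cos)
    out[[sprintf("%s_%s_%.1f", v, g, co)]] <-
      generate_recording(config, truth, v, g, co)
  out
}

#' @export
print.signal_recording <- function(x, ...) {
  cat("Flow-loop recording: valve", x$valve_id, "grade", x$grade,
      "at", x$co_lpm, "L/min\n")
  cat("  ", length(x$channels$q_pump), "DAQ samples at", x$daq_rate,
      "Hz,", length(x$ava_series), "camera frames at", x$camera_rate,
      "Hz,", x$n_beats, "beats\n")
  invisible(x)
}
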