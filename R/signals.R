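#' Estimate the delay between two series by circular cross-correlation
#'
#' Computes the circular cross-correlation
#' \deqn{\hat r_{xy}(l) = \frac{1}{N}\sum_{n=0}^{N-1} x(n)\, y(n+l)}
#' (series demeaned first; indices modulo N, evaluated via the FFT) and
#' returns the lag maximizing it, mapped to the signed range
#' \eqn{(-N/2, N/2]}. A positive lag means the first argument leads the
#' second. Ties are broken toward the smallest absolute lag (and toward
#' the positive lag if still tied). Constant inputs leave the correlation
#' undefined up to scale; the function then warns and returns 0 with
#' attribute `undefined = TRUE`.
#'
#' @param x,y numeric series of equal length N >= 2.
#' @return signed integer lag in samples.
#' @examples
#' x <- sin(2 * pi * (0:999) / 200)
#' estimate_delay(x, circshift_by(x, 37))  # x leads the shifted copy: +37
#' @export
estimate_delay <- function(x, y) {
  n <- length(x)
  stop_if_not(n == length(y), "'x' and 'y' must have equal length")
  stop_if_not(n >= 2L, "need at least two samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: delay undefined, returning 0", call. = FALSE)
    return(structure(0L, undefined = TRUE))
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- Re(stats::fft(Conj(stats::fft(xc)) * stats::fft(yc),
                     inverse = TRUE)) / n
  lags <- 0:(n - 1L)
  lags[lags > n / 2] <- lags[lags > n / 2] - n
  cand <- which(r >= max(r) - 1e-9 * max(abs(r)))
  cand <- cand[order(abs(lags[cand]), -sign(lags[cand]))]
  as.integer(lags[cand[1L]])
}

#' Circularly shift a series
#'
#' Positive `k` moves samples toward higher indices (delays the series);
#' negative `k` advances it. Exposed mainly to construct test signals and
#' to undo measured channel leads.
#'
#' @param x numeric series.
#' @param k integer shift in samples.
#' @export
circshift_by <- function(x, k) circshift(x, k)

#' Centered moving average with decimation
#'
#' Smooths with a centered moving average of `window_samples` points
#' (windows shrink symmetrically at the edges rather than padding, so the
#' series length is preserved and no data are invented), then keeps every
#' `decimate`-th sample starting at the first. For an even window the
#' extra sample is taken on the right, so a window of 40 spans indices
#' \eqn{i-19, \ldots, i+20}.
#'
#' @param x numeric series of length N.
#' @param window_samples moving-average window (>= 1, <= N).
#' @param decimate decimation factor (>= 1); output length is
#'   `ceiling(N / decimate)`.
#' @return the smoothed, decimated series.
#' @examples
#' smooth_and_resample(rep(1, 100), 40, 10)  # constant in, constant out
#' @export
smooth_and_resample <- function(x, window_samples, decimate = 1L) {
  n <- length(x)
  stop_if_not(is_count(window_samples) && window_samples >= 1,
              "'window_samples' must be a positive integer")
  stop_if_not(window_samples <= n, "window larger than the series")
  stop_if_not(is_count(decimate) && decimate >= 1,
              "'decimate' must be a positive integer")
  w <- as.integer(window_samples)
  h2 <- w %/% 2L
  h1 <- w - 1L - h2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  sm[seq(1L, n, by = decimate)]
}

#' Instantaneous transvalvular flow from the pump kinematics
#'
#' \eqn{Q_{inst}(t) = \dot x(t) A_{piston} - Q_{retro}(t)}: the piston
#' velocity (central differences; one-sided at the ends) times the piston
#' area, minus the retrograde flow measured at the mitral probe. With the
#' position in cm, the area in cm^2 and the rate in Hz the result is in
#' ml/s. Subtracting the retrograde bump near ejection onset produces the
#' characteristic notch in the flow signal.
#'
#' @param pump_position piston position series in cm.
#' @param piston_area_cm2 piston cross-section in cm^2.
#' @param q_retro retrograde flow in ml/s (same length, or scalar 0).
#' @param rate sampling rate in Hz.
#' @return flow series in ml/s.
#' @export
compute_q_inst <- function(pump_position, piston_area_cm2, q_retro = 0,
                           rate) {
  n <- length(pump_position)
  stop_if_not(n >= 2L, "need at least two position samples")
  if (length(q_retro) == 1L) q_retro <- rep(q_retro, n)
  stop_if_not(length(q_retro) == n,
              "'q_retro' must match the position series length")
  dt <- 1 / rate
  v <- numeric(n)
  v[2:(n - 1L)] <- (pump_position[3:n] - pump_position[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (pump_position[2L] - pump_position[1L]) / dt
  v[n] <- (pump_position[n] - pump_position[n - 1L]) / dt
  v * piston_area_cm2 - q_retro
}

#' Detect the ejection window of one beat
#'
#' Longest contiguous interval where the flow exceeds 2 % of the beat
#' maximum. Sub-threshold gaps shorter than `hysteresis` samples do not
#' break the interval, so brief dips (e.g. the retrograde notch) are
#' bridged.
#'
#' @param q_inst flow series of one beat (ml/s).
#' @param threshold_frac detection threshold as a fraction of the beat
#'   maximum.
#' @param hysteresis maximum bridged gap length in samples.
#' @return half-open index interval `c(start, end)` (1-based; the window
#'   is `start:(end - 1)`).
#' @export
detect_ejection_window <- function(q_inst, threshold_frac = 0.02,
                                   hysteresis = 5L) {
  stop_if_not(length(q_inst) >= 1L, "empty series")
  qmax <- max(q_inst)
  if (qmax <= 0) stop("all-nonpositive flow: no ejection detectable")
  above <- q_inst > threshold_frac * qmax
  r <- rle(above)
  ## bridge short FALSE runs strictly between TRUE runs
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    bridge <- interior[!r$values[interior] & r$lengths[interior] < hysteresis]
    r$values[bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(start = starts[best], end = ends[best] + 1L)
}

#' Synchronize a multi-channel recording onto the camera time base
#'
#' Undoes the configured (or measured) channel leads by circular shifts,
#' derives the instantaneous transvalvular flow from the pump position
#' and the retrograde flow, smooths the flow with a centered moving
#' average of 800 DAQ samples (0.04 s at 20 kHz) and decimates it by the
#' DAQ/camera rate ratio, smooths the valve-area series over 40 frames
#' (0.02 s at 2 kHz), carries the pressures onto the same time base, and
#' detects the ejection window of every beat.
#'
#' @param recording a `"signal_recording"` (see [generate_recording()]).
#' @param delays_ms named channel leads in ms (positive = channel leads
#'   the DAQ); defaults to the delays stored in the recording.
#' @param flow_window,ava_window moving-average windows in samples at the
#'   DAQ and camera rates respectively.
#' @return a list of class `"synced_recording"` with the common
#'   camera-rate time base: `time` (s), `q_inst_mlps`, `q_inst_idx_mps`,
#'   `ava_frac`, `p_lv`, `p_ao`, per-beat index ranges `beats`, per-beat
#'   ejection windows `ejection`, and metadata.
#' @export
synchronize <- function(recording, delays_ms = NULL,
                        flow_window = 800L, ava_window = 40L) {
  stop_if_not(inherits(recording, "signal_recording"),
              "'recording' must be a signal_recording")
  fs <- recording$daq_rate
  fc <- recording$camera_rate
  stop_if_not(fs %% fc == 0,
              "camera rate must divide the DAQ rate")
  dec <- as.integer(fs / fc)
  if (is.null(delays_ms)) delays_ms <- recording$delays_ms
  ch <- recording$channels
  ava <- recording$ava_series
  lag_of <- function(name) {
    if (!is.null(delays_ms) && name %in% names(delays_ms))
      delays_ms[[name]] else 0
  }
  if (lag_of("q_retro") != 0)
    ch$q_retro <- circshift(ch$q_retro, round(lag_of("q_retro") / 1000 * fs))
  if (lag_of("camera") != 0)
    ava <- circshift(ava, round(lag_of("camera") / 1000 * fc))

  q_raw <- compute_q_inst(ch$pump_position, recording$piston_area_cm2,
                          ch$q_retro, rate = fs)
  q <- smooth_and_resample(q_raw, flow_window, dec)
  a <- smooth_and_resample(ava, ava_window, 1L)
  nc <- min(length(q), length(a))
  idx <- seq_len(nc)
  keep <- seq(1L, by = dec, length.out = nc)
  time <- (idx - 1L) / fc

  spb <- round(fc * 60 / recording$heart_rate_bpm)
  nb <- max(1L, nc %/% spb)
  beats <- lapply(seq_len(nb), function(b)
    c(start = (b - 1L) * spb + 1L, end = min(nc, b * spb) + 1L))
  ejection <- lapply(beats, function(bw) {
    qq <- q[bw["start"]:(bw["end"] - 1L)]
    win <- detect_ejection_window(qq)
    win + bw[["start"]] - 1L
  })
  structure(list(time = time, q_inst_mlps = q[idx],
                 q_inst_idx_mps = q[idx] / recording$lvot_area_mm2,
                 ava_frac = a[idx],
                 p_lv = ch$p_lv[keep], p_ao = ch$p_ao[keep],
                 rate = fc, beats = beats, ejection = ejection,
                 valve_id = recording$valve_id, grade = recording$grade,
                 co_lpm = recording$co_lpm,
                 lvot_area_mm2 = recording$lvot_area_mm2,
                 s = recording$s),
            class = "synced_recording")
}

#' Extract the peak-flow point of one experiment cell
#'
#' Pools every sample whose flow exceeds 97 % of the maximum flow over
#' all beats of the cell (the phase of the cycle where flow is least
#' pulsatile) and returns the means of the flow (both unit systems) and
#' of the corresponding AVA over that pool. With `pooled = FALSE` the
#' 97 % threshold is applied within each beat separately before pooling.
#'
#' @param synced a `"synced_recording"` from [synchronize()].
#' @param threshold fraction of the maximum defining the pool.
#' @param pooled apply the threshold to the max over all beats (default)
#'   or per beat.
#' @return one-row data frame with `valve_id`, `grade`, `co_lpm`,
#'   `q_peak_idx_mps`, `q_peak_mlps`, `ava_peak_frac`.
#' @export
select_peak_points <- function(synced, threshold = 0.97, pooled = TRUE) {
  stop_if_not(inherits(synced, "synced_recording"),
              "'synced' must come from synchronize()")
  q <- synced$q_inst_mlps
  a <- synced$ava_frac
  if (pooled) {
    sel <- q > threshold * max(q)
  } else {
    sel <- logical(length(q))
    for (bw in synced$beats) {
      ii <- bw[["start"]]:(bw[["end"]] - 1L)
      sel[ii] <- q[ii] > threshold * max(q[ii])
    }
  }
  data.frame(valve_id = synced$valve_id, grade = synced$grade,
             co_lpm = synced$co_lpm,
             q_peak_idx_mps = mean(q[sel]) / synced$lvot_area_mm2,
             q_peak_mlps = mean(q[sel]),
             ava_peak_frac = mean(a[sel]))
}

#' Recover the peak dataset from waveform recordings
#'
#' Runs the full waveform path --- [generate_recording()],
#' [synchronize()], [select_peak_points()] --- for a subset of the
#' factorial design, cell by cell (recordings are not retained, keeping
#' memory flat). The result has the same layout as
#' [generate_peak_dataset()] and should agree with it within a few
#' percent.
#'
#' @inheritParams generate_recordings
#' @return a `"valve_dataset"` data frame.
#' @export
recover_peak_dataset <- function(config, truth, valves = NULL,
                                 grades = NULL, cos = NULL) {
  all_valves <- sprintf("A%03d", seq_len(config$n_valves))
  if (is.null(valves)) valves <- all_valves
  if (is.null(grades)) grades <- config$grades
  if (is.null(cos)) cos <- config$cardiac_outputs
  rows <- list()
  for (v in valves) for (g in grades) for (co in cos) {
    rec <- generate_recording(config, truth, v, g, co)
    syn <- synchronize(rec)
    pt <- select_peak_points(syn)
    pt$s <- rec$s
    pt$lvot_area_mm2 <- rec$lvot_area_mm2
    rows[[length(rows) + 1L]] <- pt
  }
  out <- do.call(rbind, rows)
  class(out) <- c("valve_dataset", "data.frame")
  attr(out, "truth") <- truth
  out
}

#' Pixel-size calibration from a reference of known area
#'
#' The pixel size is calibrated by counting the pixels of the inner
#' portion of a circular hole of known area: one pixel covers
#' `known_area / pixel_count`.
#'
#' @param known_area_mm2 reference area in mm^2 (> 0).
#' @param pixel_count number of pixels covering it (> 0).
#' @return area per pixel in mm^2.
#' @export
calibrate_pixel_area <- function(known_area_mm2, pixel_count) {
  stop_if_not(is.numeric(known_area_mm2) && known_area_mm2 > 0,
              "'known_area_mm2' must be positive")
  stop_if_not(is.numeric(pixel_count) && pixel_count > 0,
              "'pixel_count' must be positive")
  known_area_mm2 / pixel_count
}

#' Area of a binarized valve image
#'
#' Counts the foreground pixels of a binarized frame and scales by the
#' calibrated pixel area.
#'
#' @param mask logical or 0/1 matrix (foreground = open valve).
#' @param pixel_area_mm2 area of one pixel in mm^2.
#' @return area in mm^2.
#' @export
area_from_mask <- function(mask, pixel_area_mm2) {
  sum(mask != 0) * pixel_area_mm2
}
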