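#' Cumulative left-ventricular work over a beat
#'
#' Trapezoidal cumulative integral of \eqn{P_{LV}\, dV_{LV}/dt}, with the
#' ejection-positive sign convention for the volume change (positive flow
#' out of the ventricle contributes positive work). Pressure is converted
#' from mmHg to Pa (factor 133.322) and flow from ml/s to m^3/s, so the
#' result is in joules.
#'
#' @param p_lv_mmhg LV pressure series (mmHg).
#' @param dvdt_mlps ejection-positive volume change rate (ml/s).
#' @param time_s time base in s; must be (near) uniformly spaced.
#' @param tol relative tolerance on time-step uniformity.
#' @return cumulative work series in J (first element 0).
#' @examples
#' t <- seq(0, 0.3, by = 1e-3)
#' w <- cumulative_lv_work(rep(100, length(t)), rep(250, length(t)), t)
#' @export
cumulative_lv_work <- function(p_lv_mmhg, dvdt_mlps, time_s, tol = 1e-6) {
  n <- length(time_s)
  stop_if_not(length(p_lv_mmhg) == n && length(dvdt_mlps) == n,
              "series must share one time base")
  stop_if_not(n >= 2L, "need at least two samples")
  dts <- diff(time_s)
  stop_if_not(all(abs(dts - dts[1L]) <= tol * abs(dts[1L])),
              "nonuniform time step beyond tolerance")
  power_w <- p_lv_mmhg * MMHG_TO_PA * dvdt_mlps * ML_TO_M3
  cumtrapz1(time_s, power_w)
}

#' Maximum of the cumulative LV work
#'
#' \eqn{W_{max} = \max_{0 \le T \le T_{cycle}} W_{LV}(T)}: the largest
#' value of the cumulative work over the cycle (not necessarily the
#' end-of-cycle value, since diastolic filling at low pressure can reduce
#' the running integral).
#'
#' @param w_cum_j cumulative work series in J.
#' @return scalar J.
#' @export
max_lv_work <- function(w_cum_j) {
  stop_if_not(length(w_cum_j) >= 1L, "empty work series")
  max(w_cum_j)
}

#' Relative stiffness from LV-work ratios
#'
#' The relative stiffness of a stiffened grade is the ratio `k` between
#' its maximal LV work and that of the native grade, evaluated at the
#' four highest cardiac outputs and averaged:
#' \deqn{s_{b,c} = \frac{k_{5.0} + k_{4.5} + k_{4.0} + k_{3.5}}{4}.}
#' The native grade compared with itself gives exactly 1. `method = "ls"`
#' replaces the mean of per-output ratios by the single least-squares
#' ratio across the four outputs (regression through the origin), an
#' alternative reading of the same definition.
#'
#' @param w_max_a named (or `co_lpm`-aligned) vector of native-grade
#'   \eqn{W_{max}} values in J.
#' @param w_max_bc same for the compared grade.
#' @param co_lpm cardiac outputs corresponding to the entries.
#' @param n_top number of highest outputs used (default 4).
#' @param method `"mean"` (default) or `"ls"`.
#' @return a list of class `"stiffness_assignment"` with elements `s`,
#'   `k_per_co` (named per-output ratios) and `co_used`.
#' @examples
#' co <- c(3.5, 4.0, 4.5, 5.0)
#' relative_stiffness(c(1, 1.1, 1.2, 1.3), 1.2 * c(1, 1.1, 1.2, 1.3), co)$s
#' @export
relative_stiffness <- function(w_max_a, w_max_bc, co_lpm, n_top = 4L,
                               method = c("mean", "ls")) {
  method <- match.arg(method)
  stop_if_not(length(w_max_a) == length(co_lpm) &&
                length(w_max_bc) == length(co_lpm),
              "work vectors and 'co_lpm' must align")
  stop_if_not(length(co_lpm) >= n_top,
              "need at least 'n_top' cardiac outputs")
  ord <- order(co_lpm, decreasing = TRUE)[seq_len(n_top)]
  wa <- w_max_a[ord]
  wb <- w_max_bc[ord]
  stop_if_not(all(wa > 0), "zero or negative reference work")
  k <- wb / wa
  names(k) <- format(co_lpm[ord])
  s <- if (method == "mean") mean(k) else sum(wa * wb) / sum(wa^2)
  structure(list(s = s, k_per_co = k, co_used = co_lpm[ord],
                 method = method),
            class = "stiffness_assignment")
}

#' @export
print.stiffness_assignment <- function(x, digits = 4, ...) {
  cat("Relative stiffness s =", signif(x$s, digits),
      "(", x$method, "of work ratios at",
      paste(format(sort(x$co_used)), collapse = ", "), "L/min )\n")
  invisible(x)
}

#' Mean systolic flow over the ejection window
#'
#' Arithmetic mean of the instantaneous flow over the ejection window,
#' reported both in ml/s and indexed to the LVOT area in m/s (the indexed
#' value accounts for different valve sizes).
#'
#' @param q_inst_mlps flow series in ml/s.
#' @param window half-open index interval `c(start, end)` (from
#'   [detect_ejection_window()]).
#' @param lvot_area_mm2 LVOT area in mm^2.
#' @return list with `q_syst_mlps` and `q_syst_idx_mps`.
#' @export
mean_systolic_flow <- function(q_inst_mlps, window, lvot_area_mm2) {
  stop_if_not(window[2L] > window[1L], "empty ejection window")
  ii <- window[1L]:(window[2L] - 1L)
  m <- mean(q_inst_mlps[ii])
  list(q_syst_mlps = m, q_syst_idx_mps = m / lvot_area_mm2)
}

#' Mean transvalvular gradient during valve patency
#'
#' \eqn{\Delta P = P_{LV} - P_{ao}}, averaged over the strictly positive
#' samples within the patency window. If no positive samples exist the
#' function warns and returns 0 (attribute `undefined = TRUE`).
#'
#' @param p_lv_mmhg,p_ao_mmhg pressure series on a common time base.
#' @param window half-open index interval of valve patency (defaults to
#'   the whole series).
#' @return mean positive gradient in mmHg.
#' @export
mean_transvalvular_gradient <- function(p_lv_mmhg, p_ao_mmhg,
                                        window = NULL) {
  stop_if_not(length(p_lv_mmhg) == length(p_ao_mmhg),
              "pressure series must share one time base")
  if (is.null(window)) window <- c(1L, length(p_lv_mmhg) + 1L)
  stop_if_not(window[2L] > window[1L], "empty patency window")
  ii <- window[1L]:(window[2L] - 1L)
  dp <- p_lv_mmhg[ii] - p_ao_mmhg[ii]
  pos <- dp[dp > 0]
  if (length(pos) == 0L) {
    warning("no positive gradient samples in the patency window",
            call. = FALSE)
    return(structure(0, undefined = TRUE))
  }
  mean(pos)
}

#' Beat-level hemodynamic summary of a synchronized recording
#'
#' Computes, on an interior beat (away from smoothing edge effects), the
#' maximal cumulative LV work, the mean systolic flow (both unit
#' systems) and the mean transvalvular gradient, using the detected
#' ejection window as the patency window.
#'
#' @param synced a `"synced_recording"` from [synchronize()].
#' @param beat which beat to summarize; defaults to the middle one.
#' @return one-row data frame with `valve_id`, `grade`, `co_lpm`,
#'   `w_max_J`, `q_syst_mlps`, `q_syst_idx_mps`, `mean_gradient_mmHg`.
#' @export
beat_hemodynamics <- function(synced, beat = NULL) {
  stop_if_not(inherits(synced, "synced_recording"),
              "'synced' must come from synchronize()")
  nb <- length(synced$beats)
  if (is.null(beat)) beat <- (nb + 1L) %/% 2L
  stop_if_not(beat >= 1L && beat <= nb, "no such beat")
  bw <- synced$beats[[beat]]
  ii <- bw[["start"]]:(bw[["end"]] - 1L)
  ej <- synced$ejection[[beat]] - bw[["start"]] + 1L
  q <- synced$q_inst_mlps[ii]
  w <- cumulative_lv_work(synced$p_lv[ii], q, synced$time[ii])
  flow <- mean_systolic_flow(q, ej, synced$lvot_area_mm2)
  grad <- mean_transvalvular_gradient(synced$p_lv[ii], synced$p_ao[ii], ej)
  data.frame(valve_id = synced$valve_id, grade = synced$grade,
             co_lpm = synced$co_lpm, w_max_J = max_lv_work(w),
             q_syst_mlps = flow$q_syst_mlps,
             q_syst_idx_mps = flow$q_syst_idx_mps,
             mean_gradient_mmHg = as.numeric(grad))
}
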