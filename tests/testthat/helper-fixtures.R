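# shared fixtures: small designs keep the unit tests fast; the
# study-scale design (11 valves) is used only where the contract is about
# the factorial size itself

tiny_config <- function(seed = 1L, ...) {
  synth_config(n_valves = 3L, cardiac_outputs = seq(0.5, 5.0, by = 0.5),
               seed = seed, ...)
}

noise_free_truth <- function(...) ground_truth(noise_sd_ava = 0, ...)

# hand-built synced recording for unit tests of the peak selector
fake_synced <- function(q_mlps, ava, lvot = 500, beats = NULL) {
  n <- length(q_mlps)
  if (is.null(beats)) beats <- list(c(start = 1L, end = n + 1L))
  structure(list(time = (seq_len(n) - 1) / 2000, q_inst_mlps = q_mlps,
                 q_inst_idx_mps = q_mlps / lvot, ava_frac = ava,
                 p_lv = rep(100, n), p_ao = rep(90, n), rate = 2000,
                 beats = beats,
                 ejection = lapply(beats, function(b)
                   c(start = b[["start"]], end = b[["end"]])),
                 valve_id = "T001", grade = "a", co_lpm = 5,
                 lvot_area_mm2 = lvot, s = 1),
            class = "synced_recording")
}

# brute-force circular cross-correlation delay search (independent oracle)
brute_delay <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- vapply(0:(n - 1L), function(l)
    sum(xc * yc[((seq_len(n) - 1L + l) %% n) + 1L]) / n, numeric(1))
  lags <- 0:(n - 1L)
  lags[lags > n / 2] <- lags[lags > n / 2] - n
  cand <- which(r >= max(r) - 1e-9 * max(abs(r)))
  cand <- cand[order(abs(lags[cand]), -sign(lags[cand]))]
  as.integer(lags[cand[1L]])
}
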