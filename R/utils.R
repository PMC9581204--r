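## internal helpers shared by the signal and synthetic modules

## circular shift: positive k moves samples to the right (delays the series)
circshift <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

## cumulative trapezoidal integral; first element is 0
cumtrapz1 <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(t) * (y[-1L] + y[-n]) / 2))
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

## cosine-tapered (Tukey) pulse on u in [0, 1], ramp fraction r each side
tukey_pulse <- function(u, r) {
  y <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  yi <- rep(1, length(ui))
  lo <- ui < r
  hi <- ui > 1 - r
  yi[lo] <- (1 - cos(pi * ui[lo] / r)) / 2
  yi[hi] <- (1 - cos(pi * (1 - ui[hi]) / r)) / 2
  y[inside] <- yi
  y
}
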