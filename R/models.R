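#' Linear AVA--flow model
#'
#' Predicts the aortic valve opening area (as a fraction of the LVOT area)
#' from the indexed peak transvalvular flow `q` (m/s) under the linear
#' model \eqn{F_1(Q, s, \theta_1, \theta_2) = \theta_1 Q \theta_2 / s}.
#' The model is proportional in `Q` (it passes through the origin) and the
#' relative stiffness `s` scales the slope down. An alternative reading of
#' the stiffness coupling, \eqn{\theta_1 Q \theta_2^{s}}, is available via
#' `form = "power"`; both are strictly decreasing in `s` for
#' \eqn{\theta_2 < 1}.
#'
#' @param q indexed flow in m/s (vector).
#' @param s relative stiffness, dimensionless, must be positive
#'   (scalar or vector recycled against `q`).
#' @param theta numeric length-2 vector \eqn{(\theta_1, \theta_2)}.
#' @param form `"ratio"` (default) for \eqn{\theta_1 Q \theta_2/s},
#'   `"power"` for \eqn{\theta_1 Q \theta_2^{s}}.
#' @return predicted AVA as a fraction of LVOT area.
#' @examples
#' ava_linear(1.0, s = 1, theta = c(3.69, 0.066))
#' @seealso [ava_sigmoid()], [ava_model()]
#' @export
ava_linear <- function(q, s, theta, form = c("ratio", "power")) {
  form <- match.arg(form)
  stop_if_not(length(theta) == 2L && all(is.finite(theta)),
              "'theta' must be a finite length-2 vector")
  stop_if_not(all(s > 0), "stiffness 's' must be positive")
  if (form == "ratio") theta[1L] * q * theta[2L] / s
  else theta[1L] * q * theta[2L]^s
}

#' Sigmoid (saturating) AVA--flow model
#'
#' Predicts the AVA fraction from indexed flow under the saturating model
#' \deqn{F_2(Q, s, \theta_3, \theta_4, \theta_5) =
#'   \frac{\theta_3}{s^{\theta_4}}
#'   \left(\frac{1}{1 + e^{-Q\theta_5}} - \frac{1}{2}\right).}
#' The curve is 0 at `Q = 0`, strictly increasing in `Q`, and saturates at
#' \eqn{\theta_3 / (2 s^{\theta_4})} as `Q` grows, encoding the physical
#' constraint that a valve cannot open beyond a finite area however large
#' the flow.
#'
#' @inheritParams ava_linear
#' @param theta numeric length-3 vector \eqn{(\theta_3, \theta_4,
#'   \theta_5)}, all positive; \eqn{\theta_5} has units s/m.
#' @return predicted AVA as a fraction of LVOT area.
#' @examples
#' ava_sigmoid(0.96, s = 1, theta = c(0.72, 3.14, 2.80))
#' @export
ava_sigmoid <- function(q, s, theta) {
  stop_if_not(length(theta) == 3L && all(is.finite(theta)),
              "'theta' must be a finite length-3 vector")
  stop_if_not(all(s > 0), "stiffness 's' must be positive")
  theta[1L] / s^theta[2L] * (stats::plogis(q * theta[3L]) - 0.5)
}

ava_predict_kind <- function(kind, q, s, theta, form = "ratio") {
  if (kind == "linear") ava_linear(q, s, theta, form = form)
  else ava_sigmoid(q, s, theta)
}

model_init <- function(kind) {
  if (kind == "linear") c(1, 0.1) else c(0.5, 1, 1)
}

model_lower <- function(kind) {
  ## sigmoid parameters are physically positive; linear ones unconstrained
  if (kind == "linear") c(-Inf, -Inf) else rep(1e-8, 3L)
}

#' Fit an AVA--flow model to peak-flow points
#'
#' The central fitting function of the package. Given a set of
#' \eqn{(Q_{peak}, AVA_{peak})} points with known relative stiffness
#' per point, estimates the model hyperparameters \eqn{\theta} by
#' least squares,
#' \deqn{\hat\theta = \arg\min_\theta \sum_i
#'   [AVA_i - F(Q_i, s_i, \theta)]^2,}
#' using the Levenberg--Marquardt algorithm
#' ([minpack.lm::nls.lm()]). Initialization is fixed
#' (`c(1, 0.1)` linear, `c(0.5, 1, 1)` sigmoid) so fits are reproducible.
#'
#' @param data a data frame with columns `q_peak_idx_mps` (indexed flow,
#'   m/s), `ava_peak_frac` (AVA fraction of LVOT) and `s` (relative
#'   stiffness per point), e.g. from [generate_peak_dataset()].
#' @param kind `"sigmoid"` (3 hyperparameters) or `"linear"` (2).
#' @param form stiffness coupling of the linear model, see [ava_linear()].
#' @param init optional numeric start values for \eqn{\theta}.
#' @param control a [minpack.lm::nls.lm.control()] list; the default uses
#'   tight tolerances (`ftol = ptol = 1e-15`) so that noise-free data are
#'   fitted to machine precision.
#' @return an object of class `"ava_model"` with methods [coef()],
#'   [predict()], [fitted()], [residuals()], [summary()], [print()],
#'   [simulate()] and [plot()].
#' @examples
#' d <- generate_peak_dataset(synth_config(seed = 1), ground_truth())
#' fit <- ava_model(d, kind = "sigmoid")
#' coef(fit)
#' @export
ava_model <- function(data, kind = c("sigmoid", "linear"),
                      form = c("ratio", "power"), init = NULL,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-15, ptol = 1e-15, maxiter = 1000)) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  cols <- c("q_peak_idx_mps", "ava_peak_frac", "s")
  stop_if_not(is.data.frame(data) && all(cols %in% names(data)),
              paste("'data' must contain columns",
                    paste(cols, collapse = ", ")))
  q <- data$q_peak_idx_mps
  a <- data$ava_peak_frac
  s <- data$s
  stop_if_not(all(is.finite(q)) && all(is.finite(a)) && all(s > 0),
              "non-finite flow/AVA values or non-positive stiffness")
  n_hyper <- if (kind == "linear") 2L else 3L
  stop_if_not(nrow(data) > n_hyper,
              "underdetermined fit: need more points than hyperparameters")
  if (length(unique(s)) < 2L && kind == "sigmoid")
    warning("training points carry a single stiffness value; ",
            "the stiffness exponent is not identifiable", call. = FALSE)
  if (is.null(init)) init <- model_init(kind)
  stop_if_not(length(init) == n_hyper, "wrong length for 'init'")
  resid_fn <- function(theta) a - ava_predict_kind(kind, q, s, theta, form)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            lower = model_lower(kind), control = control)
  if (fit$info == 0L || fit$info == 9L)
    stop("Levenberg-Marquardt did not converge (info = ", fit$info, ")")
  theta <- unname(fit$par)
  names(theta) <- if (kind == "linear") c("theta1", "theta2")
                  else c("theta3", "theta4", "theta5")
  structure(list(kind = kind, form = form, theta = theta,
                 n_hyper = n_hyper, data = data,
                 fitted = ava_predict_kind(kind, q, s, theta, form),
                 deviance = fit$deviance, niter = fit$niter,
                 info = fit$info, call = match.call()),
            class = "ava_model")
}

#' Fit the relative stiffness of one valve grade with frozen hyperparameters
#'
#' One-dimensional least squares over the relative stiffness `s > 0`,
#' \deqn{\hat s = \arg\min_s \sum_i [AVA_i - F(Q_i, s, \hat\theta)]^2,}
#' with \eqn{\hat\theta} kept fixed (the test step of the modified
#' leave-one-valve-out cross-validation). Solved by Levenberg--Marquardt
#' initialized at `s = 1`, bounded below at `1e-3` to avoid division
#' blow-up (physical stiffness ratios are near 1).
#'
#' @param data data frame of the held-out points (columns
#'   `q_peak_idx_mps`, `ava_peak_frac`); the `s` column, if present, is
#'   ignored.
#' @param object a fitted [ava_model()] (or a list with elements `kind`,
#'   `theta`, `form`).
#' @param init start value for `s`.
#' @param lower lower bound for `s`.
#' @param control optimizer control, as in [ava_model()].
#' @return the estimated stiffness \eqn{\hat s} (numeric scalar) with
#'   attributes `deviance` and `niter`.
#' @export
fit_stiffness <- function(data, object, init = 1, lower = 1e-3,
                          control = minpack.lm::nls.lm.control(
                            ftol = 1e-15, ptol = 1e-15, maxiter = 1000)) {
  stop_if_not(is.data.frame(data) && nrow(data) >= 1L,
              "need at least one held-out point")
  stop_if_not(all(c("q_peak_idx_mps", "ava_peak_frac") %in% names(data)),
              "'data' must contain q_peak_idx_mps and ava_peak_frac")
  q <- data$q_peak_idx_mps
  a <- data$ava_peak_frac
  form <- if (is.null(object$form)) "ratio" else object$form
  fit <- minpack.lm::nls.lm(
    par = init,
    fn = function(s) a - ava_predict_kind(object$kind, q, s, object$theta, form),
    lower = lower, control = control)
  structure(unname(fit$par), deviance = fit$deviance, niter = fit$niter)
}

#' @export
coef.ava_model <- function(object, ...) object$theta

#' @export
print.ava_model <- function(x, digits = 4, ...) {
  cat("AVA-flow model (", x$kind,
      if (x$kind == "linear") paste0(", ", x$form, " form"), ")\n", sep = "")
  cat("  theta:", paste(names(x$theta), signif(x$theta, digits),
                        sep = " = ", collapse = ", "), "\n")
  cat("  points:", nrow(x$data), "  residual SS:",
      signif(x$deviance, digits), "\n")
  invisible(x)
}

#' @export
summary.ava_model <- function(object, ...) {
  r <- residuals(object)
  n <- length(r)
  m <- mean(r^2)
  out <- list(kind = object$kind, theta = object$theta, n = n,
              mse = m, rmse = sqrt(m),
              aic = aic_from_mse(m, n, object$n_hyper),
              sigma = sqrt(object$deviance / max(1L, n - object$n_hyper)))
  class(out) <- "summary.ava_model"
  out
}

#' @export
print.summary.ava_model <- function(x, digits = 4, ...) {
  cat("AVA-flow model (", x$kind, "), n = ", x$n, "\n", sep = "")
  cat("  theta:", paste(names(x$theta), signif(x$theta, digits),
                        sep = " = ", collapse = ", "), "\n")
  cat("  MSE:", signif(x$mse, digits), "  AIC:", signif(x$aic, digits),
      "  residual sigma:", signif(x$sigma, digits), "\n")
  invisible(x)
}

#' Predict AVA from a fitted model
#'
#' @param object an [ava_model()] fit.
#' @param newdata data frame with columns `q_peak_idx_mps` and `s`;
#'   defaults to the training data.
#' @param ... unused.
#' @return predicted AVA fractions.
#' @export
predict.ava_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stop_if_not(all(c("q_peak_idx_mps", "s") %in% names(newdata)),
              "'newdata' must contain q_peak_idx_mps and s")
  ava_predict_kind(object$kind, newdata$q_peak_idx_mps, newdata$s,
                   object$theta, object$form)
}

#' @export
fitted.ava_model <- function(object, ...) object$fitted

#' @export
residuals.ava_model <- function(object, ...) {
  object$data$ava_peak_frac - object$fitted
}

#' Simulate AVA observations from a fitted model
#'
#' Draws Gaussian observations around the fitted curve with the residual
#' standard deviation of the fit; values are clipped to the physical
#' range \[0, 1\].
#'
#' @param object an [ava_model()] fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns of simulated AVA fractions.
#' @export
simulate.ava_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  sig <- sqrt(object$deviance / max(1L, n - object$n_hyper))
  out <- as.data.frame(replicate(
    nsim, pmin(1, pmax(0, object$fitted + rnorm(n, 0, sig)))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted AVA--flow model
#'
#' Scatter of the training points with the fitted curve drawn at each
#' distinct stiffness value in the data.
#'
#' @param x an [ava_model()] fit.
#' @param q_grid flow grid (m/s) for the curves.
#' @param ... passed to [plot()].
#' @export
plot.ava_model <- function(x, q_grid = seq(0.05, 1.2, by = 0.01), ...) {
  d <- x$data
  s_vals <- sort(unique(d$s))
  cols <- grDevices::hcl.colors(max(3L, length(s_vals)), "Dark 3")
  plot(d$q_peak_idx_mps, d$ava_peak_frac,
       col = cols[match(d$s, s_vals)], pch = 16,
       xlab = "indexed peak flow [m/s]", ylab = "AVA [fraction of LVOT]",
       ...)
  for (i in seq_along(s_vals))
    lines(q_grid, ava_predict_kind(x$kind, q_grid, s_vals[i], x$theta, x$form),
          col = cols[i], lwd = 2)
  legend("topleft", bty = "n", lwd = 2, col = cols[seq_along(s_vals)],
         legend = sprintf("s = %.3g", s_vals))
  invisible(x)
}
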