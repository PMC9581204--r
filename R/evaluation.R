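#' Mean squared error
#'
#' @param true,pred numeric vectors of equal, nonzero length.
#' @return mean of squared differences.
#' @export
mse <- function(true, pred) {
  stop_if_not(length(true) == length(pred), "length mismatch")
  stop_if_not(length(true) >= 1L, "empty input")
  mean((pred - true)^2)
}

#' Akaike information criterion from an MSE
#'
#' \eqn{AIC = n \log(MSE) + 2k} with the natural logarithm and
#' \eqn{k = } number of hyperparameters plus one (the residual-variance
#' estimate). A non-positive MSE corresponds to a perfect fit, for which
#' the criterion is unbounded below; the function then warns and returns
#' `-Inf` with attribute `perfect = TRUE`.
#'
#' @param mse_value mean squared error (> 0).
#' @param n number of data points.
#' @param n_hyper number of model hyperparameters.
#' @return the AIC (lower is better).
#' @examples
#' aic_from_mse(1, 10, 2)  # 6
#' @export
aic_from_mse <- function(mse_value, n, n_hyper) {
  stop_if_not(is_count(n) && n >= 1, "'n' must be a positive count")
  stop_if_not(is_count(n_hyper), "'n_hyper' must be a count")
  if (mse_value <= 0) {
    warning("non-positive MSE: perfect fit, AIC unbounded below",
            call. = FALSE)
    return(structure(-Inf, perfect = TRUE))
  }
  n * log(mse_value) + 2 * (n_hyper + 1)
}

#' Agreement between measured and predicted values
#'
#' Summarizes the agreement of paired measurements the way method
#' comparisons are reported: ordinary least-squares regression of
#' predicted on measured (slope, intercept), Pearson correlation, bias
#' (mean difference) with its confidence interval
#' \eqn{\bar d \pm t_{n-1}\, sd(d)/\sqrt n}, Bland--Altman limits of
#' agreement \eqn{\bar d \pm 1.96\, sd(d)}, the coefficient of variation
#' (sd of the differences over the mean measured value, in percent), the
#' MSE and, when `n_hyper` is supplied, the AIC.
#'
#' @param measured,predicted finite numeric vectors, n >= 3.
#' @param confidence confidence level of the bias interval.
#' @param n_hyper optional hyperparameter count for the AIC.
#' @return a list of class `"eval_report"` with elements `n`, `mse`,
#'   `aic`, `pearson_r`, `slope`, `intercept`, `bias`, `bias_interval`,
#'   `limits_of_agreement`, `cv_percent`.
#' @export
agreement_stats <- function(measured, predicted, confidence = 0.95,
                            n_hyper = NULL) {
  n <- length(measured)
  stop_if_not(n == length(predicted), "length mismatch")
  stop_if_not(n >= 3L, "need at least 3 pairs")
  stop_if_not(all(is.finite(measured)) && all(is.finite(predicted)),
              "non-finite values")
  stop_if_not(sd(measured) > 0, "zero variance in measured values")
  d <- predicted - measured
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(1 - (1 - confidence) / 2, df = n - 1L)
  fit <- lm(predicted ~ measured)
  m <- mse(measured, predicted)
  structure(list(
    n = n, mse = m,
    aic = if (is.null(n_hyper)) NA_real_ else aic_from_mse(m, n, n_hyper),
    pearson_r = cor(measured, predicted),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    bias = bias,
    bias_interval = c(lower = bias - tq * sdd / sqrt(n),
                      upper = bias + tq * sdd / sqrt(n)),
    limits_of_agreement = c(lower = bias - 1.96 * sdd,
                            upper = bias + 1.96 * sdd),
    cv_percent = 100 * sdd / mean(measured),
    confidence = confidence), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Agreement over n =", x$n, "pairs\n")
  cat("  regression: slope =", signif(x$slope, digits),
      " intercept =", signif(x$intercept, digits),
      " r =", signif(x$pearson_r, digits), "\n")
  cat("  bias =", signif(x$bias, digits), " ",
      sprintf("%g%% CI [%s; %s]", 100 * x$confidence,
              signif(x$bias_interval[1L], digits),
              signif(x$bias_interval[2L], digits)), "\n")
  cat("  limits of agreement [",
      signif(x$limits_of_agreement[1L], digits), ";",
      signif(x$limits_of_agreement[2L], digits), "]  CV =",
      signif(x$cv_percent, digits), "%\n")
  cat("  MSE =", signif(x$mse, digits),
      if (!is.na(x$aic)) paste(" AIC =", signif(x$aic, digits)), "\n")
  invisible(x)
}

#' Rank models by AIC
#'
#' Orders evaluation reports for the same prediction task by ascending
#' AIC (lower indicates the superior model) and reports the differences
#' to the best. All reports must refer to the same number of points;
#' exact ties are flagged and kept in input order.
#'
#' @param reports named list of `"eval_report"` objects with non-`NA`
#'   AIC entries.
#' @return data frame with `model`, `n`, `mse`, `aic`, `delta_aic`,
#'   ordered best first; attribute `tied` flags exact AIC ties.
#' @export
compare_models <- function(reports) {
  stop_if_not(is.list(reports) && length(reports) >= 2L,
              "need at least two reports")
  if (is.null(names(reports)) || any(names(reports) == ""))
    names(reports) <- paste0("model", seq_along(reports))
  ns <- vapply(reports, function(r) r$n, numeric(1L))
  stop_if_not(length(unique(ns)) == 1L,
              "reports compare different numbers of points")
  aics <- vapply(reports, function(r) as.numeric(r$aic), numeric(1L))
  stop_if_not(!anyNA(aics), "every report needs an AIC (supply n_hyper)")
  ord <- order(aics)   # stable: ties keep input order
  out <- data.frame(model = names(reports)[ord], n = ns[ord],
                    mse = vapply(reports, function(r) r$mse,
                                 numeric(1L))[ord],
                    aic = aics[ord], delta_aic = aics[ord] - min(aics),
                    row.names = NULL)
  attr(out, "tied") <- anyDuplicated(aics) > 0L
  out
}
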