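#' Leave-one-valve-out fold splits
#'
#' One fold per valve: the held-out valve forms the test set, all other
#' valves the training set. Point counts (`m1` for training, `m2` per
#' grade of the test valve) are computed from the rows actually present,
#' so datasets with missing cells simply yield reduced counts. On the
#' complete default design (11 valves, 3 grades, 10 outputs) every fold
#' has `m1 = 300` and `m2 = 10` per grade.
#'
#' @param dataset a `"valve_dataset"` data frame (>= 2 valves).
#' @return a list of folds; each fold is a list with `fold`,
#'   `test_valve`, `train_valves`, `m1` and named per-grade `m2`.
#' @export
make_folds <- function(dataset) {
  stop_if_not(is.data.frame(dataset) && "valve_id" %in% names(dataset),
              "'dataset' must contain a valve_id column")
  valves <- unique(dataset$valve_id)
  stop_if_not(length(valves) >= 2L,
              "cross-validation needs at least 2 valves")
  lapply(seq_along(valves), function(j) {
    test <- dataset$valve_id == valves[j]
    m2 <- table(dataset$grade[test])
    list(fold = j, test_valve = valves[j],
         train_valves = setdiff(valves, valves[j]),
         m1 = sum(!test),
         m2 = setNames(as.integer(m2), names(m2)))
  })
}

#' Modified leave-one-valve-out cross-validation
#'
#' The two-stage scheme: for each fold, the model hyperparameters
#' \eqn{\hat\theta^j} are fitted on all points of the K-1 training valves
#' with their assigned stiffness ([ava_model()]); then, with
#' \eqn{\hat\theta^j} frozen, the relative stiffness \eqn{\hat s} of the
#' held-out valve is fitted separately for each of its grades
#' ([fit_stiffness()]). No assumption is made about the ordering of the
#' stiffness grades.
#'
#' @param dataset a `"valve_dataset"` data frame with columns
#'   `q_peak_idx_mps`, `ava_peak_frac`, `s`, `valve_id`, `grade`,
#'   `co_lpm`.
#' @param kind `"sigmoid"` or `"linear"`.
#' @param form linear-model stiffness coupling, see [ava_linear()].
#' @return an object of class `"ava_cv"`: list with `kind`, `folds`
#'   (fold splits), `theta` (K x p matrix of per-fold estimates),
#'   `theta_mean`, `theta_sd`, `s_table` (data frame: fold, valve_id,
#'   grade, m2, s_true, s_hat) and the dataset.
#' @examples
#' d <- generate_peak_dataset(synth_config(n_valves = 3, seed = 1),
#'                            ground_truth(noise_sd_ava = 0))
#' cv <- ava_crossval(d, kind = "sigmoid")
#' cv$theta_mean
#' @export
ava_crossval <- function(dataset, kind = c("sigmoid", "linear"),
                         form = c("ratio", "power")) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  folds <- make_folds(dataset)
  theta <- NULL
  rows <- list()
  models <- vector("list", length(folds))
  for (f in folds) {
    train <- dataset[dataset$valve_id != f$test_valve, , drop = FALSE]
    test <- dataset[dataset$valve_id == f$test_valve, , drop = FALSE]
    fit <- tryCatch(ava_model(train, kind = kind, form = form),
                    error = function(e)
                      stop("fold ", f$fold, " (test valve ", f$test_valve,
                           "): ", conditionMessage(e), call. = FALSE))
    models[[f$fold]] <- fit
    theta <- rbind(theta, coef(fit))
    for (g in unique(test$grade)) {
      tg <- test[test$grade == g, , drop = FALSE]
      s_hat <- tryCatch(fit_stiffness(tg, fit),
                        error = function(e)
                          stop("fold ", f$fold, ", grade ", g, ": ",
                               conditionMessage(e), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f$fold, valve_id = f$test_valve, grade = g,
        m2 = nrow(tg), s_true = tg$s[1L], s_hat = as.numeric(s_hat))
    }
  }
  rownames(theta) <- NULL
  structure(list(kind = kind, form = form, folds = folds,
                 models = models, theta = theta,
                 theta_mean = colMeans(theta),
                 theta_sd = apply(theta, 2L, sd),
                 s_table = do.call(rbind, rows), dataset = dataset),
            class = "ava_cv")
}

#' @export
print.ava_cv <- function(x, digits = 4, ...) {
  cat("Leave-one-valve-out cross-validation (", x$kind, " model), K = ",
      length(x$folds), "\n", sep = "")
  cat("  theta (mean +/- SD over folds):\n")
  for (j in seq_along(x$theta_mean))
    cat("    ", names(x$theta_mean)[j], " = ",
        signif(x$theta_mean[j], digits), " +/- ",
        signif(x$theta_sd[j], digits), "\n", sep = "")
  ag <- agreement_stats(x$s_table$s_true, x$s_table$s_hat)
  cat("  stiffness agreement: r =", signif(ag$pearson_r, digits),
      " slope =", signif(ag$slope, digits),
      " bias =", signif(ag$bias, digits), "\n")
  invisible(x)
}

#' @export
summary.ava_cv <- function(object, ...) {
  ag <- agreement_stats(object$s_table$s_true, object$s_table$s_hat,
                        n_hyper = ncol(object$theta))
  out <- list(kind = object$kind, K = length(object$folds),
              theta_mean = object$theta_mean, theta_sd = object$theta_sd,
              agreement = ag)
  class(out) <- "summary.ava_cv"
  out
}

#' @export
print.summary.ava_cv <- function(x, digits = 4, ...) {
  cat("Cross-validated", x$kind, "model, K =", x$K, "folds\n")
  for (j in seq_along(x$theta_mean))
    cat("  ", names(x$theta_mean)[j], " = ",
        signif(x$theta_mean[j], digits), " +/- ",
        signif(x$theta_sd[j], digits), "\n", sep = "")
  print(x$agreement, digits = digits)
  invisible(x)
}

#' Measured-vs-predicted stiffness plot
#'
#' Scatter of the cross-validated stiffness estimates against the
#' work-ratio (assigned) stiffness, with the identity and the regression
#' line.
#'
#' @param x an `"ava_cv"` object.
#' @param ... passed to [plot()].
#' @export
plot.ava_cv <- function(x, ...) {
  st <- x$s_table
  plot(st$s_true, st$s_hat, pch = 16,
       xlab = "measured relative stiffness s",
       ylab = "predicted relative stiffness s-hat", ...)
  abline(0, 1, col = "grey40")
  fit <- lm(s_hat ~ s_true, data = st)
  abline(fit, col = "steelblue", lwd = 2)
  legend("topleft", bty = "n", lwd = c(1, 2),
         col = c("grey40", "steelblue"),
         legend = c("identity", sprintf("fit: slope %.2f",
                                        coef(fit)[2L])))
  invisible(x)
}

#' Project AVA from low-flow to high-flow states
#'
#' The clinically motivated experiment: for each fold and each grade of
#' its held-out valve, the relative stiffness is re-fitted using only the
#' points of the lowest `n_f - n_holdout` cardiac outputs (with the
#' fold's frozen \eqn{\hat\theta^j}), and the model then predicts the AVA
#' at the `n_holdout` highest-output points. This mimics projecting the
#' valve area of a low-flow, low-gradient stenosis to normal flow.
#'
#' @param cv an `"ava_cv"` object from [ava_crossval()].
#' @param n_holdout number of highest cardiac outputs held out (3 or 5).
#' @return data frame with one row per projected point: `fold`,
#'   `valve_id`, `grade`, `co_lpm`, `q_peak_idx_mps`, `s_hat_lowflow`,
#'   `ava_true`, `ava_pred`, `n_train`, `model`, `n_holdout`.
#' @export
project_high_flow <- function(cv, n_holdout = 3L) {
  stop_if_not(inherits(cv, "ava_cv"), "'cv' must come from ava_crossval()")
  stop_if_not(is_count(n_holdout) && n_holdout >= 1,
              "'n_holdout' must be a positive integer")
  dataset <- cv$dataset
  rows <- list()
  for (f in cv$folds) {
    fit <- cv$models[[f$fold]]
    test <- dataset[dataset$valve_id == f$test_valve, , drop = FALSE]
    for (g in unique(test$grade)) {
      tg <- test[test$grade == g, , drop = FALSE]
      tg <- tg[order(tg$co_lpm), , drop = FALSE]
      n <- nrow(tg)
      if (n < n_holdout + 1L)
        stop("valve ", f$test_valve, " grade ", g, " has ", n,
             " points; need at least n_holdout + 1 = ", n_holdout + 1L)
      low <- tg[seq_len(n - n_holdout), , drop = FALSE]
      high <- tg[(n - n_holdout + 1L):n, , drop = FALSE]
      s_hat <- as.numeric(fit_stiffness(low, fit))
      pred <- ava_predict_kind(cv$kind, high$q_peak_idx_mps, s_hat,
                               fit$theta, cv$form)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f$fold, valve_id = f$test_valve, grade = g,
        co_lpm = high$co_lpm, q_peak_idx_mps = high$q_peak_idx_mps,
        s_hat_lowflow = s_hat, ava_true = high$ava_peak_frac,
        ava_pred = pred, n_train = nrow(low), model = cv$kind,
        n_holdout = as.integer(n_holdout))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
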