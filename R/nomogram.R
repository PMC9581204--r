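#' Isostiffness lines over a flow grid
#'
#' Evaluates an AVA--flow model on a grid of indexed flows for a set of
#' stiffness values, yielding one "isostiffness line" per stiffness: the
#' model-predicted AVA-vs-flow curve at fixed valve stiffness. A family
#' of such lines forms a nomogram from which the stiffness of a valve can
#' be read off at any flow state.
#'
#' @param object an [ava_model()] fit (or a list with `kind`, `theta`,
#'   `form`).
#' @param s_values stiffness values, one line each.
#' @param q_grid increasing positive flow grid in m/s; the default
#'   0.05--1.2 m/s covers the experiment's indexed-flow range with
#'   margin.
#' @param provenance optional label attached to the lines (e.g. the fold
#'   or valve they come from).
#' @return data frame with columns `s`, `q_idx_mps`, `ava_frac`,
#'   `provenance`.
#' @export
isostiffness_lines <- function(object, s_values,
                               q_grid = seq(0.05, 1.2, by = 0.01),
                               provenance = NA_character_) {
  stop_if_not(length(q_grid) >= 1L, "empty flow grid")
  stop_if_not(all(q_grid > 0) && all(diff(q_grid) > 0),
              "'q_grid' must be positive and increasing")
  stop_if_not(all(s_values > 0), "stiffness values must be positive")
  form <- if (is.null(object$form)) "ratio" else object$form
  out <- do.call(rbind, lapply(s_values, function(s)
    data.frame(s = s, q_idx_mps = q_grid,
               ava_frac = ava_predict_kind(object$kind, q_grid, s,
                                           object$theta, form),
               provenance = provenance)))
  rownames(out) <- NULL
  out
}

#' Grade-level mean isostiffness lines with uncertainty bands
#'
#' Pointwise mean across per-valve lines of the same grade, with a band
#' of plus/minus one standard error of the mean (sample SD over valves
#' divided by the square root of the number of valves). Grouping is by
#' grade label, not by stiffness value. A grade represented by a single
#' line yields its mean without a band, with a warning.
#'
#' @param lines data frame with columns `grade`, `provenance` (one value
#'   per contributing line), `q_idx_mps`, `ava_frac`, e.g. stacked
#'   per-fold output of [isostiffness_lines()].
#' @return data frame with `grade`, `q_idx_mps`, `ava_mean`, `band_lo`,
#'   `band_hi`, `n_lines`.
#' @export
grade_mean_lines <- function(lines) {
  need <- c("grade", "provenance", "q_idx_mps", "ava_frac")
  stop_if_not(is.data.frame(lines) && all(need %in% names(lines)),
              paste("'lines' must contain", paste(need, collapse = ", ")))
  out <- list()
  for (g in unique(lines$grade)) {
    lg <- lines[lines$grade == g, , drop = FALSE]
    qs <- sort(unique(lg$q_idx_mps))
    mat <- tapply(lg$ava_frac,
                  list(match(lg$q_idx_mps, qs), lg$provenance), mean)
    nlines <- ncol(mat)
    mu <- rowMeans(mat)
    if (nlines < 2L) {
      warning("grade ", g, " has a single line: band omitted",
              call. = FALSE)
      se <- rep(NA_real_, length(mu))
    } else {
      se <- apply(mat, 1L, sd) / sqrt(nlines)
    }
    out[[g]] <- data.frame(grade = g, q_idx_mps = qs, ava_mean = mu,
                           band_lo = mu - se, band_hi = mu + se,
                           n_lines = nlines)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the isostiffness nomogram from a cross-validation result
#'
#' For every fold and every grade of its held-out valve, draws the
#' isostiffness line at the fold's fitted stiffness using the fold's
#' hyperparameters (the per-fold \eqn{\hat\theta^j} differ, which is why
#' individual lines may cross), then averages the lines pointwise per
#' grade with a plus/minus one standard error band.
#'
#' @param cv an `"ava_cv"` from [ava_crossval()].
#' @param q_grid flow grid in m/s.
#' @return an object of class `"ava_nomogram"`: list with `lines`
#'   (per-valve lines, with `grade` and `provenance`), `mean_lines`
#'   (per-grade mean and band) and `kind`.
#' @export
nomogram <- function(cv, q_grid = seq(0.05, 1.2, by = 0.01)) {
  stop_if_not(inherits(cv, "ava_cv"), "'cv' must come from ava_crossval()")
  st <- cv$s_table
  all_lines <- list()
  for (i in seq_len(nrow(st))) {
    fit <- cv$models[[st$fold[i]]]
    li <- isostiffness_lines(fit, st$s_hat[i], q_grid,
                             provenance = paste0(st$valve_id[i], "/fold",
                                                 st$fold[i]))
    li$grade <- st$grade[i]
    all_lines[[i]] <- li
  }
  lines <- do.call(rbind, all_lines)
  structure(list(lines = lines, mean_lines = grade_mean_lines(lines),
                 kind = cv$kind), class = "ava_nomogram")
}

#' @export
print.ava_nomogram <- function(x, ...) {
  cat("Isostiffness nomogram (", x$kind, " model): ",
      length(unique(x$lines$provenance)), " valve lines, ",
      length(unique(x$mean_lines$grade)), " grade mean lines\n", sep = "")
  invisible(x)
}

#' Plot an isostiffness nomogram
#'
#' Per-valve lines colored by grade (thin) with the grade mean lines and
#' their standard-error bands (thick).
#'
#' @param x an `"ava_nomogram"`.
#' @param ... passed to [plot()].
#' @export
plot.ava_nomogram <- function(x, ...) {
  grades <- unique(x$mean_lines$grade)
  cols <- setNames(grDevices::hcl.colors(max(3L, length(grades)),
                                         "Dark 3")[seq_along(grades)],
                   grades)
  plot(NA, xlim = range(x$lines$q_idx_mps),
       ylim = range(c(x$lines$ava_frac, x$mean_lines$band_hi,
                      x$mean_lines$band_lo), na.rm = TRUE),
       xlab = "indexed flow [m/s]", ylab = "AVA [fraction of LVOT]", ...)
  for (p in unique(x$lines$provenance)) {
    lp <- x$lines[x$lines$provenance == p, ]
    lines(lp$q_idx_mps, lp$ava_frac,
          col = adjustcolor(cols[lp$grade[1L]], 0.3))
  }
  for (g in grades) {
    mg <- x$mean_lines[x$mean_lines$grade == g, ]
    if (!anyNA(mg$band_lo))
      polygon(c(mg$q_idx_mps, rev(mg$q_idx_mps)),
              c(mg$band_lo, rev(mg$band_hi)),
              col = adjustcolor(cols[g], 0.15), border = NA)
    lines(mg$q_idx_mps, mg$ava_mean, col = cols[g], lwd = 3)
  }
  legend("topleft", bty = "n", lwd = 3, col = cols,
         legend = paste("grade", grades))
  invisible(x)
}
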