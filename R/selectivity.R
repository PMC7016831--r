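#' Build EV-versus-cell abundance pairs
#'
#' For one condition (model x phenotype), raw counts are summed across the
#' replicates of each compartment, converted to reads per million of the
#' summed totals, and log2-transformed. Only features with a positive
#' summed count in both compartments enter the pairs; features detected on
#' one side only are counted (`n_unique_cell`, `n_unique_ev`). On data
#' honoring the EV-subset-of-cell structure, `n_unique_ev` is 0.
#'
#' @param cell A [count_matrix()] subset of cell samples (one condition).
#' @param ev The matching EV subset; must share the feature universe.
#' @return An object of class `abundance_pairs`: list with `pairs`
#'   (data.frame `feature_id`, `x` = cell log2 RPM, `y` = EV log2 RPM),
#'   `n_unique_cell`, `n_unique_ev`, `n_features`.
#' @export
build_pairs <- function(cell, ev) {
  stopifnot(inherits(cell, "count_matrix"), inherits(ev, "count_matrix"))
  if (!identical(rownames(cell$counts), rownames(ev$counts)))
    stop("cell and EV matrices must share the same feature universe", call. = FALSE)
  sc <- rowSums(cell$counts)
  se <- rowSums(ev$counts)
  if (sum(sc) == 0 || sum(se) == 0)
    stop("a compartment has zero total counts", call. = FALSE)
  both <- sc > 0 & se > 0
  x <- log2(sc[both] / sum(sc) * 1e6)
  y <- log2(se[both] / sum(se) * 1e6)
  structure(list(pairs = data.frame(feature_id = rownames(cell$counts)[both],
                                    x = as.numeric(x), y = as.numeric(y),
                                    row.names = NULL, stringsAsFactors = FALSE),
                 n_unique_cell = sum(sc > 0 & se == 0),
                 n_unique_ev = sum(se > 0 & sc == 0),
                 n_features = length(sc)),
            class = "abundance_pairs")
}

#' Construct abundance pairs from explicit coordinates
#'
#' Low-level constructor for analyses on pre-computed (or constructed)
#' log2 RPM coordinates.
#'
#' @param x,y Numeric vectors: cell and EV log2 RPM.
#' @param feature_id Optional ids.
#' @param n_unique_cell,n_unique_ev Unique-to-one-side species counts.
#' @return An `abundance_pairs` object.
#' @export
abundance_pairs <- function(x, y, feature_id = NULL,
                            n_unique_cell = 0L, n_unique_ev = 0L) {
  stopifnot(length(x) == length(y))
  if (is.null(feature_id)) feature_id <- sprintf("f%05d", seq_along(x))
  structure(list(pairs = data.frame(feature_id = feature_id, x = as.numeric(x),
                                    y = as.numeric(y), row.names = NULL,
                                    stringsAsFactors = FALSE),
                 n_unique_cell = as.integer(n_unique_cell),
                 n_unique_ev = as.integer(n_unique_ev),
                 n_features = length(x) + n_unique_cell + n_unique_ev),
            class = "abundance_pairs")
}

#' @export
print.abundance_pairs <- function(x, ...) {
  cat(sprintf("abundance_pairs: %d shared species, %d unique to cells, %d unique to EVs\n",
              nrow(x$pairs), x$n_unique_cell, x$n_unique_ev))
  invisible(x)
}

#' Ordinary least squares of EV on cell abundance above a noise threshold
#'
#' Fits `y ~ x` on the pairs whose coordinates exceed `threshold` (strictly,
#' on the log2 RPM scale; by default on both axes). With fewer than 3
#' retained points the fit is flagged undefined rather than failing.
#'
#' @param pairs An [abundance_pairs()] object.
#' @param threshold Noise threshold on the log2 RPM scale.
#' @param axes `"both"` (default), `"x"` or `"y"`: which coordinates the
#'   threshold filters.
#' @return A list `(threshold, n_points, slope, intercept, r_squared,
#'   defined)`; `slope`/`intercept`/`r_squared` are `NA` when undefined.
#' @export
fit_regression <- function(pairs, threshold, axes = c("both", "x", "y")) {
  stopifnot(inherits(pairs, "abundance_pairs"))
  axes <- match.arg(axes)
  p <- pairs$pairs
  keep <- switch(axes,
                 both = p$x > threshold & p$y > threshold,
                 x = p$x > threshold,
                 y = p$y > threshold)
  n <- sum(keep)
  out <- list(threshold = threshold, n_points = n, slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_, defined = FALSE)
  if (n < 3L) return(out)
  x <- p$x[keep]; y <- p$y[keep]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(out)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  r <- stats::cor(x, y)
  out$slope <- slope
  out$intercept <- mean(y) - slope * mean(x)
  out$r_squared <- r^2
  out$defined <- is.finite(out$r_squared)
  out
}

#' Grid search for the noise threshold maximizing R-squared
#'
#' Evaluates [fit_regression()] at every threshold from `lo` to `hi` in
#' steps of `step` (101 thresholds for the defaults 0, 10, 0.1) and selects
#' Tmax, the smallest threshold attaining the maximal defined R-squared.
#' The fit at threshold `lo` (conventionally 0, i.e. all log2 RPM values
#' above zero) is reported alongside as the unoptimized baseline.
#'
#' @param pairs An [abundance_pairs()] object.
#' @param lo,hi,step Grid limits and increment on the log2 RPM scale.
#' @param axes Threshold filtering mode, see [fit_regression()].
#' @return An object of class `selectivity_result`: list with `fit0` (the
#'   threshold-`lo` fit), `t_max`, `r_squared_at_tmax`, `n_points_at_tmax`,
#'   `slope_at_tmax`, `intercept_at_tmax`, `grid` (data.frame `threshold`,
#'   `n_points`, `r_squared`), `n_unique_cell`, `n_unique_ev`, `axes`.
#' @export
grid_search_threshold <- function(pairs, lo = 0, hi = 10, step = 0.1,
                                  axes = c("both", "x", "y")) {
  stopifnot(inherits(pairs, "abundance_pairs"))
  axes <- match.arg(axes)
  if (!(lo < hi) || step <= 0) stop("need lo < hi and step > 0", call. = FALSE)
  thresholds <- seq(lo, hi, by = step)
  fits <- lapply(thresholds, function(t) fit_regression(pairs, t, axes))
  grid <- data.frame(threshold = thresholds,
                     n_points = vapply(fits, `[[`, numeric(1), "n_points"),
                     r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  defined <- !is.na(grid$r_squared)
  if (!any(defined))
    stop("no threshold on the grid yields a defined regression (need >= 3 points)",
         call. = FALSE)
  # ties in the argmax break to the smallest threshold (least data discarded);
  # equality up to 1e-12 so exactly collinear data is not split by rounding
  best <- which(defined & grid$r_squared >= max(grid$r_squared[defined]) - 1e-12)[1L]
  structure(list(fit0 = fits[[1L]],
                 t_max = grid$threshold[best],
                 r_squared_at_tmax = grid$r_squared[best],
                 n_points_at_tmax = grid$n_points[best],
                 slope_at_tmax = fits[[best]]$slope,
                 intercept_at_tmax = fits[[best]]$intercept,
                 grid = grid,
                 n_unique_cell = pairs$n_unique_cell,
                 n_unique_ev = pairs$n_unique_ev,
                 axes = axes),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("Selectivity regression (EV ~ cell, log2 RPM)\n")
  cat(sprintf("  threshold %g: R^2 = %.4f, slope = %.3f, n = %d\n",
              x$fit0$threshold, x$fit0$r_squared, x$fit0$slope, x$fit0$n_points))
  cat(sprintf("  Tmax = %g: R^2 = %.4f, n = %d\n",
              x$t_max, x$r_squared_at_tmax, x$n_points_at_tmax))
  cat(sprintf("  unique to cells: %d; unique to EVs: %d\n",
              x$n_unique_cell, x$n_unique_ev))
  invisible(x)
}

#' @export
plot.selectivity_result <- function(x, pairs = NULL, ...) {
  if (!is.null(pairs)) {
    plot(pairs$pairs$x, pairs$pairs$y, pch = 16, cex = 0.4,
         col = grDevices::grey(0.4),
         xlab = "cell log2 RPM", ylab = "EV log2 RPM", ...)
    graphics::abline(x$intercept_at_tmax, x$slope_at_tmax, col = "red")
    graphics::abline(v = x$t_max, lty = 2)
  } else {
    plot(x$grid$threshold, x$grid$r_squared, type = "l",
         xlab = "noise threshold (log2 RPM)", ylab = expression(R^2), ...)
    graphics::abline(v = x$t_max, lty = 2)
  }
  invisible(x)
}

#' Verdict on EV packaging selectivity
#'
#' Labels the dataset "selective" when even the best threshold-filtered
#' regression explains less than `r2_ceiling` of the variance (strict
#' inequality; a maximal R-squared at or above the ceiling reads as
#' proportional packaging).
#'
#' @param result A [grid_search_threshold()] result.
#' @param r2_ceiling R-squared ceiling (default 0.8).
#' @return A list `(verdict, max_r_squared, r2_ceiling)` where `verdict` is
#'   `"selective"` or `"proportional"`.
#' @export
selectivity_report <- function(result, r2_ceiling = 0.8) {
  stopifnot(inherits(result, "selectivity_result"))
  max_r2 <- max(result$grid$r_squared, na.rm = TRUE)
  list(verdict = if (max_r2 < r2_ceiling) "selective" else "proportional",
       max_r_squared = max_r2, r2_ceiling = r2_ceiling)
}
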