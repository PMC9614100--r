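# Threshold-dependent detection-performance model of one heterogeneous
# source: empirical TPR/TNR/FPR over a threshold grid, smoothed curves
# g (TPR) and f (TNR), and the selected operating threshold t_best.

#' Empirical rate curves over a threshold grid
#'
#' At each threshold `t` a trial is predicted target iff its posterior
#' exceeds `t`; `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`,
#' `FPR = 1 - TNR`.
#'
#' @param scores a [score_set()] with both classes present.
#' @param grid ascending thresholds in \[0, 1\] (default 101 evenly spaced).
#' @return data.frame with columns `threshold`, `tpr`, `tnr`, `fpr`.
#' @export
sweep_thresholds <- function(scores, grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(scores, "score_set"))
  check_two_classes(scores$labels, "score set")
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0 | grid > 1))
    stop_dpifuse("grid must be strictly ascending within [0, 1]",
                 "dpifuse_config_error")
  pos <- scores$posteriors[scores$labels == 1L]
  neg <- scores$posteriors[scores$labels == 0L]
  tpr <- vapply(grid, function(t) mean(pos > t), numeric(1))
  tnr <- vapply(grid, function(t) mean(neg <= t), numeric(1))
  data.frame(threshold = grid, tpr = tpr, tnr = tnr, fpr = 1 - tnr)
}

# Local-linear smooth over the grid with fixed span, then isotonic
# projection in the requested direction, clipped to [0, 1].
smooth_monotone <- function(x, y, span, direction = c("nonincreasing",
                                                      "nondecreasing")) {
  direction <- match.arg(direction)
  if (length(unique(y)) == 1L) return(y)   # smoothing preserves constants
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  yy <- pmin(1, pmax(0, stats::predict(fit, x)))
  if (direction == "nonincreasing") rev(stats::isoreg(rev(yy))$yf)
  else stats::isoreg(yy)$yf
}

#' Fit a detection-performance model
#'
#' Smooths the empirical TPR and TNR curves separately over the threshold
#' grid (local linear regression, fixed span), clips to \[0, 1\], enforces
#' the shape constraints (TPR non-increasing, TNR non-decreasing in the
#' threshold) by isotonic projection, and selects the operating threshold
#' `t_best = argmax(TPR_smooth - FPR_smooth)` (ties towards the smallest
#' threshold).
#'
#' @param scores a [score_set()] of validation posteriors.
#' @param grid ascending thresholds in \[0, 1\] (at least 5 points).
#' @param span loess span for the smoother.
#' @return an object of class `detection_performance` with the raw and
#'   smoothed curves, the grid and `t_best`.
#' @export
detection_performance <- function(scores,
                                  grid = seq(0, 1, length.out = 101),
                                  span = 0.25) {
  if (length(grid) < 5L)
    stop_dpifuse("threshold grid needs at least 5 points",
                 "dpifuse_config_error")
  raw <- sweep_thresholds(scores, grid)
  tpr_s <- smooth_monotone(grid, raw$tpr, span, "nonincreasing")
  tnr_s <- smooth_monotone(grid, raw$tnr, span, "nondecreasing")
  tpr_s <- pmin(1, pmax(0, tpr_s))
  tnr_s <- pmin(1, pmax(0, tnr_s))
  obj <- structure(list(
    source_id = scores$source_id, threshold_grid = grid,
    tpr_raw = raw$tpr, tnr_raw = raw$tnr, fpr_raw = raw$fpr,
    tpr_smooth = tpr_s, tnr_smooth = tnr_s,
    t_best = NA_real_), class = "detection_performance")
  obj$t_best <- select_threshold(obj)
  obj
}

#' Select the operating threshold of a detection-performance model
#'
#' @param model a `detection_performance` object.
#' @return the grid threshold maximising `TPR_smooth - FPR_smooth`
#'   (`FPR = 1 - TNR`); ties broken towards the smallest threshold.
#' @export
select_threshold <- function(model) {
  stopifnot(inherits(model, "detection_performance"))
  j <- model$tpr_smooth - (1 - model$tnr_smooth)
  model$threshold_grid[which.max(j)]   # which.max takes the first maximum
}

#' Evaluate the smoothed curves of a performance model
#'
#' Linear interpolation between grid points; constant beyond the grid ends.
#'
#' @param model a `detection_performance` object.
#' @param t threshold(s) in \[0, 1\].
#' @return for `performance_tpr` the smoothed target-detection curve `g(t)`;
#'   for `performance_tnr` the smoothed non-target curve `f(t)`.
#' @export
performance_tpr <- function(model, t = model$t_best) {
  stats::approx(model$threshold_grid, model$tpr_smooth, xout = t,
                rule = 2)$y
}

#' @rdname performance_tpr
#' @export
performance_tnr <- function(model, t = model$t_best) {
  stats::approx(model$threshold_grid, model$tnr_smooth, xout = t,
                rule = 2)$y
}

#' @export
print.detection_performance <- function(x, ...) {
  cat(sprintf(
    "<detection_performance> source '%s': t_best = %.3f, g(t_best) = %.3f, f(t_best) = %.3f\n",
    x$source_id, x$t_best, performance_tpr(x), performance_tnr(x)))
  invisible(x)
}

#' Plot a detection-performance model
#'
#' Raw and smoothed TPR/TNR curves over the threshold grid with the selected
#' operating threshold marked.
#'
#' @param x a `detection_performance` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.detection_performance <- function(x, ...) {
  graphics::plot(x$threshold_grid, x$tpr_raw, type = "p", pch = 1,
                 cex = 0.5, col = "grey40", xlab = "decision threshold",
                 ylab = "rate", ylim = c(0, 1),
                 main = sprintf("Detection performance: %s", x$source_id),
                 ...)
  graphics::points(x$threshold_grid, x$tnr_raw, pch = 2, cex = 0.5,
                   col = "grey70")
  graphics::lines(x$threshold_grid, x$tpr_smooth, col = "firebrick", lwd = 2)
  graphics::lines(x$threshold_grid, x$tnr_smooth, col = "steelblue", lwd = 2)
  graphics::abline(v = x$t_best, lty = 2)
  graphics::legend("right", legend = c("TPR g(t)", "TNR f(t)", "t_best"),
                   col = c("firebrick", "steelblue", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}

# Precision / recall curves over the grid (for the dynamic belief fusion
# baseline). Precision at thresholds where nothing is predicted positive is
# carried forward from the last defined value.
precision_recall_curves <- function(scores,
                                    grid = seq(0, 1, length.out = 101),
                                    span = 0.25) {
  stopifnot(inherits(scores, "score_set"))
  check_two_classes(scores$labels, "score set")
  pos <- scores$posteriors[scores$labels == 1L]
  neg <- scores$posteriors[scores$labels == 0L]
  prec <- vapply(grid, function(t) {
    tp <- sum(pos > t); fp <- sum(neg > t)
    if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  }, numeric(1))
  if (all(is.na(prec))) prec[] <- mean(scores$labels)
  last <- max(which(!is.na(prec)))
  if (last < length(prec)) prec[(last + 1L):length(prec)] <- prec[last]
  if (anyNA(prec)) prec[is.na(prec)] <- prec[which(!is.na(prec))[1L]]
  rec <- vapply(grid, function(t) mean(pos > t), numeric(1))
  prec_s <- pmin(1, pmax(0, smooth_monotone(grid, prec, span,
                                            "nondecreasing")))
  rec_s <- pmin(1, pmax(0, smooth_monotone(grid, rec, span,
                                           "nonincreasing")))
  list(threshold_grid = grid, precision = prec_s, recall = rec_s,
       source_id = scores$source_id)
}
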