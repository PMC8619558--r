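# Dual-energy HU calibration: a density line in the (low-kVp, high-kVp)
# value plane plus an affine map from the line coordinate to Hounsfield
# units. Region means of a phantom with known-HU inserts anchor both fits.

#' Per-region mean values from a paired low/high-kVp acquisition
#'
#' The calibration operates on region means, not raw voxels: one sample per
#' labeled region, carrying the mean value in each channel and, where the
#' table provides it, the region's reference HU.
#'
#' @param vol_low,vol_high `voxel_volume`s on an identical grid.
#' @param masks named list of region masks: linear voxel indices or logical
#'   arrays on that grid (see [region_masks()]).
#' @param known_hu_table optional named numeric vector (or data.frame with
#'   `name`, `known_hu`) of reference HU per region label.
#' @param min_voxels minimum voxels per region (default 10).
#' @return data.frame of class `region_samples`: `label`, `n_voxels`,
#'   `mean_low`, `mean_high`, `known_hu` (NA where unknown).
#' @export
extract_region_samples <- function(vol_low, vol_high, masks,
                                   known_hu_table = NULL, min_voxels = 10) {
  if (!same_geometry(vol_low, vol_high))
    stop("vol_low and vol_high must share an identical voxel grid")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("`masks` must be a named list of regions")
  if (is.data.frame(known_hu_table))
    known_hu_table <- stats::setNames(known_hu_table$known_hu,
                                      known_hu_table$name)
  rows <- lapply(names(masks), function(lab) {
    m <- masks[[lab]]
    idx <- if (is.logical(m)) which(m) else as.integer(m)
    if (length(idx) == 0L) stop("empty region mask: '", lab, "'")
    if (length(idx) < min_voxels)
      stop(sprintf("region '%s' has %d voxels (< %d required)",
                   lab, length(idx), min_voxels))
    data.frame(label = lab, n_voxels = length(idx),
               mean_low = mean(vol_low$values[idx]),
               mean_high = mean(vol_high$values[idx]),
               known_hu = if (!is.null(known_hu_table) &&
                              lab %in% names(known_hu_table))
                 unname(known_hu_table[[lab]]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$mean_low)) || any(!is.finite(out$mean_high)))
    stop("non-finite region means")
  class(out) <- c("region_samples", "data.frame")
  out
}

#' Fit the density line through region means
#'
#' Total least squares (orthogonal regression) by default: the line passes
#' through the centroid of the `(mean_low, mean_high)` points with direction
#' equal to their first principal axis, minimizing orthogonal residuals —
#' appropriate because both channels are noisy measurements. Ordinary
#' regression of high on low is available for comparison.
#'
#' @param samples `region_samples` (or data.frame with `mean_low`,
#'   `mean_high`); at least 2 non-coincident points.
#' @param method `"tls"` (orthogonal, default) or `"ols_high_on_low"`.
#' @return object of class `density_line`: `p0` (centroid), `u` (unit
#'   direction, oriented toward increasing low-channel values), `rss`
#'   (orthogonal residual sum of squares).
#' @export
fit_density_line <- function(samples, method = c("tls", "ols_high_on_low")) {
  method <- match.arg(method)
  X <- cbind(samples$mean_low, samples$mean_high)
  if (nrow(X) < 2L) stop("need at least 2 region samples to fit a line")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (max(abs(Xc)) < 1e-12)
    stop("degenerate fit: all region samples coincide")
  if (method == "tls") {
    sv <- svd(Xc)
    u <- sv$v[, 1]
    rss <- sv$d[2]^2
  } else {
    b <- sum(Xc[, 1] * Xc[, 2]) / sum(Xc[, 1]^2)
    u <- c(1, b) / sqrt(1 + b^2)
    res <- Xc[, 2] - b * Xc[, 1]
    rss <- sum(res^2) / (1 + b^2)  # orthogonal residuals of the same line
  }
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  structure(list(p0 = as.numeric(ctr), u = as.numeric(u / sqrt(sum(u^2))),
                 rss = rss, method = method),
            class = "density_line")
}

#' @export
print.density_line <- function(x, ...) {
  cat(sprintf("<density_line> p0 = (%.4g, %.4g), u = (%.6f, %.6f)  [%s]\n",
              x$p0[1], x$p0[2], x$u[1], x$u[2], x$method))
  invisible(x)
}

#' Project (low, high) value pairs onto the density line
#'
#' Signed orthogonal-projection coordinate `u . (pair - p0)`: the density
#' surrogate mapped to HU by the calibration.
#'
#' @param pair length-2 vector `(low, high)` or an n x 2 matrix of pairs.
#' @param line a `density_line`.
#' @return scalar (or length-n vector) line coordinate.
#' @export
project_to_density <- function(pair, line) {
  p <- if (is.matrix(pair)) pair else matrix(as.numeric(pair), ncol = 2)
  t <- sweep(p, 2, line$p0) %*% line$u
  if (is.matrix(pair)) drop(t) else as.numeric(t)
}

#' Fit the HU map from known-HU regions
#'
#' Ordinary least squares of reference HU against the projected line
#' coordinate of each known-HU region (air plus the HA inserts by default).
#'
#' @param samples `region_samples` with at least 2 rows having `known_hu`.
#' @param line a `density_line`.
#' @return object of class `hu_map`: `slope` (HU per line-coordinate unit),
#'   `intercept` (HU), `fitted`, `residuals`.
#' @export
fit_hu_map <- function(samples, line) {
  known <- samples[!is.na(samples$known_hu), , drop = FALSE]
  if (nrow(known) < 2L)
    stop("need at least 2 regions with known HU to anchor the map")
  t <- project_to_density(cbind(known$mean_low, known$mean_high), line)
  if (stats::sd(t) < 1e-12)
    stop("degenerate HU map: zero variance in projected coordinates")
  fit <- stats::lm.fit(cbind(1, t), known$known_hu)
  co <- unname(fit$coefficients)
  structure(list(slope = co[2], intercept = co[1],
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals),
                 labels = known$label),
            class = "hu_map")
}

#' @export
print.hu_map <- function(x, ...) {
  cat(sprintf("<hu_map> HU = %.6g * t + %.6g  (fit on %d known-HU regions)\n",
              x$slope, x$intercept, length(x$labels)))
  invisible(x)
}

#' Fit the full dual-energy HU calibration
#'
#' The calibration model: region means are fitted with a density line in the
#' (low-kVp, high-kVp) value plane ([fit_density_line()]); voxel pairs are
#' orthogonally projected onto it; the signed line coordinate is mapped to
#' Hounsfield units by an affine fit anchored on regions of known HU
#' ([fit_hu_map()]), conventionally air (-1000 HU) and the hydroxyapatite
#' inserts.
#'
#' @param samples `region_samples` from [extract_region_samples()].
#' @param line_method passed to [fit_density_line()].
#' @return object of class `de_calibration` with components `line`, `hu_map`,
#'   `samples`; supports `print`, `summary`, `coef`, `predict`,
#'   `residuals` and `plot`.
#' @examples
#' s <- data.frame(label = c("air", "a", "b"),
#'                 mean_low = c(-1000, 150, 1300),
#'                 mean_high = c(-1000, -50, 870),
#'                 known_hu = c(-1000, 0, 1000))
#' fit <- de_calibration(s)
#' predict(fit, data.frame(low = 150, high = -50))
#' @export
de_calibration <- function(samples, line_method = c("tls", "ols_high_on_low")) {
  line <- fit_density_line(samples, method = line_method)
  hu_map <- fit_hu_map(samples, line)
  structure(list(line = line, hu_map = hu_map, samples = samples),
            class = "de_calibration")
}

#' @export
print.de_calibration <- function(x, ...) {
  cat("Dual-energy HU calibration\n")
  print(x$line)
  print(x$hu_map)
  invisible(x)
}

#' @export
coef.de_calibration <- function(object, ...) {
  c(p0_low = object$line$p0[1], p0_high = object$line$p0[2],
    u_low = object$line$u[1], u_high = object$line$u[2],
    slope = object$hu_map$slope, intercept = object$hu_map$intercept)
}

#' @export
summary.de_calibration <- function(object, ...) {
  res <- object$hu_map$residuals
  structure(list(coef = coef(object), n_regions = nrow(object$samples),
                 n_known = length(object$hu_map$labels),
                 line_rss = object$line$rss,
                 hu_rmse = sqrt(mean(res^2)), hu_max_abs = max(abs(res))),
            class = "summary.de_calibration")
}

#' @export
print.summary.de_calibration <- function(x, ...) {
  cat("Dual-energy HU calibration\n")
  cat(sprintf("  regions: %d (%d with known HU)\n", x$n_regions, x$n_known))
  cat(sprintf("  density line: u = (%.6f, %.6f), orthogonal RSS = %.4g\n",
              x$coef[["u_low"]], x$coef[["u_high"]], x$line_rss))
  cat(sprintf("  HU map: slope %.6g HU/unit, intercept %.6g HU\n",
              x$coef[["slope"]], x$coef[["intercept"]]))
  cat(sprintf("  known-HU residuals: RMSE %.4g HU, max |res| %.4g HU\n",
              x$hu_rmse, x$hu_max_abs))
  invisible(x)
}

#' @export
residuals.de_calibration <- function(object, ...) {
  stats::setNames(object$hu_map$residuals, object$hu_map$labels)
}

#' Predict HU from (low, high) value pairs
#'
#' @param object a `de_calibration`.
#' @param newdata data.frame (or 2-column matrix) with columns `low`, `high`.
#' @param ... unused.
#' @return numeric HU vector.
#' @export
predict.de_calibration <- function(object, newdata, ...) {
  p <- if (is.data.frame(newdata)) cbind(newdata$low, newdata$high)
       else as.matrix(newdata)
  t <- project_to_density(p, object$line)
  object$hu_map$slope * t + object$hu_map$intercept
}

#' @export
plot.de_calibration <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$mean_low, s$mean_high, pch = 19,
                 xlab = "low-kVp region mean (CT number)",
                 ylab = "high-kVp region mean (CT number)",
                 main = "Density line in the dual-energy value plane", ...)
  dir <- x$line$u; p0 <- x$line$p0
  tt <- range(project_to_density(cbind(s$mean_low, s$mean_high), x$line))
  tt <- tt + c(-0.1, 0.1) * diff(tt)
  graphics::lines(p0[1] + tt * dir[1], p0[2] + tt * dir[2], col = 2)
  graphics::text(s$mean_low, s$mean_high, s$label, pos = 3, cex = 0.7)
  invisible(x)
}

#' Apply a calibration voxel-by-voxel to a low/high-kVp volume pair
#'
#' `HU = slope * (u . ((low, high) - p0)) + intercept` per voxel. The two
#' input volumes must live on an identical grid ("the same coordinate");
#' no resampling is ever performed here.
#'
#' @param vol_low,vol_high `voxel_volume`s with identical geometry.
#' @param calibration a `de_calibration`, or a `density_line` when `hu_map`
#'   is given separately.
#' @param hu_map optional `hu_map` (when `calibration` is a bare line).
#' @return `voxel_volume` with `value_kind = "hu"`.
#' @export
apply_calibration <- function(vol_low, vol_high, calibration, hu_map = NULL) {
  if (inherits(calibration, "de_calibration")) {
    line <- calibration$line; hm <- calibration$hu_map
  } else {
    line <- calibration; hm <- hu_map
    if (is.null(hm)) stop("supply a de_calibration or a line plus hu_map")
  }
  if (!same_geometry(vol_low, vol_high))
    stop("vol_low and vol_high must share an identical voxel grid")
  t <- (as.vector(vol_low$values) - line$p0[1]) * line$u[1] +
       (as.vector(vol_high$values) - line$p0[2]) * line$u[2]
  hu <- hm$slope * t + hm$intercept
  voxel_volume(array(hu, vol_low$dims), vol_low$spacing, vol_low$origin,
               vol_low$direction, value_kind = "hu")
}
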