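# Oriented cylindrical ROIs: membership on a volume's native grid,
# descriptive statistics, rigid transfer between image spaces, and the
# paired-means table feeding the agreement analysis.

#' Oriented cylindrical region of interest
#'
#' A cylinder placed in world space: center (mm), height (mm) along its axis,
#' diameter (mm), and three rotation angles (degrees, about the world x, y
#' and z axes, composed in z*y*x order) applied to the +z axis. Default
#' validation enforces the clinical adjustment ranges — height 4.0–5.0 mm,
#' diameter 1.0–1.4 mm, angles within ±90° — as warnings unless
#' `validate = FALSE`.
#'
#' @param center length-3 world point, mm.
#' @param height cylinder height, mm.
#' @param diameter cylinder diameter, mm.
#' @param angles length-3 rotation angles `(alpha, beta, gamma)` in degrees.
#' @param label anchor/ROI name.
#' @param validate warn when geometry leaves the default clinical ranges.
#' @export
cylinder_roi <- function(center, height = 5, diameter = 1.2,
                         angles = c(0, 0, 0), label = "roi",
                         validate = TRUE) {
  center <- as.numeric(center); angles <- as.numeric(angles)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be 3 finite numbers (mm)")
  if (!is.finite(height) || height <= 0 || !is.finite(diameter) || diameter <= 0)
    stop("height and diameter must be positive")
  if (isTRUE(validate)) {
    if (height < 4 || height > 5)
      warning("ROI height ", height, " mm outside the default 4.0-5.0 mm range")
    if (diameter < 1 || diameter > 1.4)
      warning("ROI diameter ", diameter, " mm outside the default 1.0-1.4 mm range")
    if (any(abs(angles) > 90))
      warning("ROI rotation angles outside the default +/-90 degree range")
  }
  structure(list(label = as.character(label), center = center,
                 height = height, diameter = diameter, angles = angles),
            class = "cylinder_roi")
}

#' @export
print.cylinder_roi <- function(x, ...) {
  cat(sprintf(
    "<cylinder_roi '%s'> center (%.3g, %.3g, %.3g) mm, h %.3g mm, d %.3g mm, angles (%.3g, %.3g, %.3g) deg\n",
    x$label, x$center[1], x$center[2], x$center[3], x$height, x$diameter,
    x$angles[1], x$angles[2], x$angles[3]))
  invisible(x)
}

roi_rotation <- function(roi) euler_zyx_rotation(roi$angles)
roi_axis <- function(roi) drop(roi_rotation(roi) %*% c(0, 0, 1))

roi_member_points <- function(roi, pts) {
  a <- roi_axis(roi)
  d <- sweep(pts, 2, roi$center)
  ax <- d %*% a
  rad2 <- rowSums(d * d) - ax^2
  abs(ax) <= roi$height / 2 & rad2 <= (roi$diameter / 2)^2 + 1e-12
}

#' Voxel membership of a cylindrical ROI
#'
#' A voxel belongs to the ROI when its center lies within `height/2` of the
#' cylinder's central plane along the axis and within `diameter/2` of the
#' axis — voxel-center inclusion, no partial-volume weighting.
#'
#' @param volume a `voxel_volume`.
#' @param roi a `cylinder_roi`.
#' @return integer vector of linear (1-based, column-major) voxel indices.
#' @export
cylinder_mask <- function(volume, roi) {
  g <- as_grid_geometry(volume)
  # conservative index bounding box from the cylinder's world bounding sphere
  r_sph <- sqrt((roi$height / 2)^2 + (roi$diameter / 2)^2)
  corners <- as.matrix(expand.grid(roi$center[1] + c(-r_sph, r_sph),
                                   roi$center[2] + c(-r_sph, r_sph),
                                   roi$center[3] + c(-r_sph, r_sph)))
  ci <- world_to_continuous_index(g, corners)
  lo <- pmax(floor(apply(ci, 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(ci, 2, max)) + 1, g$dims - 1)
  if (any(hi < lo)) stop("ROI '", roi$label, "' lies outside the volume extent")
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  sub <- cbind(rep.int(ii, length(jj) * length(kk)),
               rep.int(rep(jj, each = length(ii)), length(kk)),
               rep(kk, each = length(ii) * length(jj)))
  pts <- index_to_world(g, sub)
  keep <- roi_member_points(roi, pts)
  if (!any(keep)) stop("empty ROI: '", roi$label,
                       "' contains no voxel centers of this volume")
  sub <- sub[keep, , drop = FALSE]
  as.integer(1 + sub[, 1] + g$dims[1] * (sub[, 2] + g$dims[2] * sub[, 3]))
}

#' Descriptive statistics of a cylindrical ROI
#'
#' Mean, sample SD (n-1 denominator), min and max over the member voxels'
#' native-grid values; the mean is the ROI's representative value in the
#' agreement analysis. No interpolation is performed.
#'
#' @param volume a `voxel_volume`.
#' @param roi a `cylinder_roi`.
#' @return object of class `roi_statistics` (a one-row data.frame): `label`,
#'   `n_voxels`, `mean`, `sd`, `min`, `max`.
#' @export
roi_statistics <- function(volume, roi) {
  idx <- cylinder_mask(volume, roi)
  v <- volume$values[idx]
  sdv <- if (length(v) > 1L) stats::sd(v) else {
    warning("single-voxel ROI '", roi$label, "': sd reported as 0")
    0
  }
  out <- data.frame(label = roi$label, n_voxels = length(v), mean = mean(v),
                    sd = sdv, min = min(v), max = max(v),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_statistics", "data.frame")
  out
}

#' Carry a cylindrical ROI through a rigid transform
#'
#' The center is mapped through the transform and the cylinder's orientation
#' is left-composed with the transform's rotation; height and diameter are
#' unchanged (a rigid map preserves the shape, hence also the volume).
#'
#' @param roi a `cylinder_roi`.
#' @param transform a `rigid_transform`.
#' @return the transformed `cylinder_roi` (angles re-expressed in z*y*x
#'   Euler form).
#' @export
transform_cylinder <- function(roi, transform) {
  if (!inherits(transform, "rigid_transform"))
    stop("unsupported transform: ROIs can only be carried rigidly")
  R <- transform$rotation %*% roi_rotation(roi)
  cylinder_roi(center = transform_points(transform, roi$center),
               height = roi$height, diameter = roi$diameter,
               angles = rotation_to_euler_zyx(R), label = roi$label,
               validate = FALSE)
}

#' Paired ROI means across DE-CBCT and MDCT spaces
#'
#' For each ROI (defined in DE-CBCT world space): statistics in the DE-CBCT
#' volume; the ROI carried through `inverse_transform` (DE-CBCT world to
#' MDCT world, i.e. the inverted registration) and evaluated on the MDCT
#' volume's native grid; one row of paired means. ROIs whose mask is empty
#' in either volume are reported in the `excluded` attribute, never silently
#' dropped.
#'
#' @param vol_decbct calibrated DE-CBCT `voxel_volume`.
#' @param vol_mdct MDCT `voxel_volume`.
#' @param rois list of `cylinder_roi` in DE-CBCT space.
#' @param inverse_transform `rigid_transform`, DE-CBCT world to MDCT world.
#' @param group optional character vector (e.g. `"mandible"`/`"maxilla"`)
#'   per ROI; defaults to the text before the last `_` in each label.
#' @return data.frame of class `measurement_pairs`: `label`, `group`,
#'   `mean_mdct`, `mean_decbct`, plus per-space voxel counts; excluded ROIs
#'   (label + reason) in `attr(, "excluded")`.
#' @export
paired_roi_means <- function(vol_decbct, vol_mdct, rois, inverse_transform,
                             group = NULL) {
  if (inherits(rois, "cylinder_roi")) rois <- list(rois)
  if (is.null(group))
    group <- vapply(rois, function(r) sub("_[^_]*$", "", r$label), "")
  rows <- list(); excluded <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    res <- tryCatch({
      s_cb <- roi_statistics(vol_decbct, roi)
      roi_md <- transform_cylinder(roi, inverse_transform)
      s_md <- roi_statistics(vol_mdct, roi_md)
      data.frame(label = roi$label, group = group[i],
                 mean_mdct = s_md$mean, mean_decbct = s_cb$mean,
                 n_voxels_mdct = s_md$n_voxels,
                 n_voxels_decbct = s_cb$n_voxels,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(label = roi$label, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), group = character(),
               mean_mdct = numeric(), mean_decbct = numeric(),
               n_voxels_mdct = integer(), n_voxels_decbct = integer())
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(label = character(), reason = character())
  class(out) <- c("measurement_pairs", "data.frame")
  out
}

#' ROIs at the named anchors of a synthetic scene
#'
#' Convenience builder: one default-geometry cylinder per scene anchor.
#'
#' @param scene a `phantom_scene`.
#' @param height,diameter,angles cylinder geometry (see [cylinder_roi()]).
#' @return list of `cylinder_roi`.
#' @export
anchor_rois <- function(scene, height = 4.5, diameter = 1.2,
                        angles = c(0, 0, 0)) {
  lapply(seq_len(nrow(scene$anchors)), function(i) {
    a <- scene$anchors[i, ]
    cylinder_roi(center = c(a$x, a$y, a$z), height = height,
                 diameter = diameter, angles = angles, label = a$label)
  })
}
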