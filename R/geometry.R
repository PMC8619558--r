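# World-coordinate voxel grids, rigid transforms and resampling.
#
# Conventions: world frame is LPS (DICOM patient coordinates), units mm;
# voxel indices are 0-based and refer to voxel centers.

#' Construct a voxel volume with world geometry
#'
#' A `voxel_volume` couples a 3D scalar array with its world-space geometry:
#' voxel spacing, the world position of the center of voxel `(0,0,0)`, and a
#' 3x3 orthonormal direction-cosine matrix whose columns are the world
#' directions of the three index axes. Values are either raw CT numbers
#' (uncalibrated scanner output) or Hounsfield units.
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm, LPS) of the center of
#'   voxel index `(0,0,0)`.
#' @param direction 3x3 orthonormal direction-cosine matrix (columns = world
#'   directions of the index axes). Default identity.
#' @param value_kind `"raw_ct"` or `"hu"`.
#' @return An object of class `voxel_volume` with fields `values`, `dims`,
#'   `spacing`, `origin`, `direction`, `value_kind`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 2)), spacing = c(0.3, 0.3, 0.3))
#' index_to_world(v, c(1, 0, 0))
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         direction = diag(3), value_kind = c("raw_ct", "hu")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  direction <- as.matrix(direction)
  check_orthonormal(direction, "direction")
  structure(list(values = values, dims = dim(values), spacing = spacing,
                 origin = origin, direction = direction,
                 value_kind = value_kind),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %d x %d x %d voxels (%s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$value_kind))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin:  (%.4g, %.4g, %.4g) mm [LPS]\n",
              x$origin[1], x$origin[2], x$origin[3]))
  rng <- range(x$values)
  cat(sprintf("  values:  [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

check_orthonormal <- function(M, what, tol = 1e-9, proper = FALSE) {
  if (!is.matrix(M) || any(dim(M) != c(3L, 3L)))
    stop(sprintf("`%s` must be a 3x3 matrix", what))
  if (max(abs(crossprod(M) - diag(3))) > 1e-7)
    stop(sprintf("`%s` must be orthonormal", what))
  d <- det(M)
  if (proper) {
    if (abs(d - 1) > tol * 1e3 && abs(d - 1) > 1e-6)
      stop(sprintf("`%s` must be a proper rotation (det = +1)", what))
  } else if (abs(abs(d) - 1) > 1e-6) {
    stop(sprintf("`%s` must have |det| = 1", what))
  }
  invisible(TRUE)
}

#' Same voxel grid (geometry) check
#'
#' TRUE when two volumes share dims, spacing, origin and direction within
#' `tol`; voxel-wise operations such as [apply_calibration()] require it.
#'
#' @param a,b `voxel_volume` objects.
#' @param tol numeric tolerance (mm / absolute).
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Grid geometry specification
#'
#' A geometry without values, used as the target of [resample_volume()] and by
#' the synthetic renderers.
#'
#' @inheritParams voxel_volume
#' @param dims integer length-3 voxel counts.
#' @export
grid_geometry <- function(dims, spacing, origin = c(0, 0, 0),
                          direction = diag(3)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("degenerate target geometry: `dims` must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate target geometry: `spacing` must be positive")
  direction <- as.matrix(direction)
  check_orthonormal(direction, "direction")
  structure(list(dims = dims, spacing = spacing, origin = as.numeric(origin),
                 direction = direction),
            class = "grid_geometry")
}

as_grid_geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (inherits(x, "voxel_volume"))
    return(grid_geometry(x$dims, x$spacing, x$origin, x$direction))
  stop("expected a grid_geometry or voxel_volume")
}

#' Map voxel indices to world coordinates
#'
#' World position of a voxel center: `origin + direction %*% (spacing * index)`
#' with 0-based indices.
#'
#' @param volume a `voxel_volume` or `grid_geometry`.
#' @param index integer length-3 0-based voxel index, or an n x 3 matrix of
#'   indices.
#' @return length-3 world point (mm), or n x 3 matrix.
#' @export
index_to_world <- function(volume, index) {
  g <- as_grid_geometry(volume)
  idx <- if (is.matrix(index)) index else matrix(as.numeric(index), ncol = 3)
  if (ncol(idx) != 3L) stop("`index` must have 3 columns")
  if (any(idx < -0.5) || any(idx > matrix(g$dims - 0.5, nrow(idx), 3, byrow = TRUE)))
    stop("index out of bounds for this volume")
  w <- sweep(idx, 2, g$spacing, `*`) %*% t(g$direction)
  w <- sweep(w, 2, g$origin, `+`)
  if (is.matrix(index)) w else drop(w)
}

#' Map world coordinates to continuous voxel indices
#'
#' Exact algebraic inverse of [index_to_world()]; the result may lie outside
#' `[0, dims)` — callers decide membership.
#'
#' @param volume a `voxel_volume` or `grid_geometry`.
#' @param point length-3 world point (mm) or n x 3 matrix of points.
#' @return continuous 0-based index triple (or n x 3 matrix).
#' @export
world_to_continuous_index <- function(volume, point) {
  g <- as_grid_geometry(volume)
  p <- if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3)
  if (ncol(p) != 3L) stop("`point` must have 3 columns")
  loc <- sweep(p, 2, g$origin, `-`) %*% g$direction  # = t(direction^-1) for orthonormal
  idx <- sweep(loc, 2, g$spacing, `/`)
  if (is.matrix(point)) idx else drop(idx)
}

#' Rigid (6-DOF) world-to-world transform
#'
#' Maps a world point `p` to `R p + t`. The pipeline convention is
#' MDCT-world to DE-CBCT-world for registration results.
#'
#' @param rotation 3x3 proper rotation matrix (det = +1).
#' @param translation length-3 translation (mm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  check_orthonormal(rotation, "rotation", proper = TRUE)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite numbers (mm)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_to_euler_zyx(x$rotation)
  cat("<rigid_transform>  p -> R p + t\n")
  cat(sprintf("  translation: (%.4g, %.4g, %.4g) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (z*y*x Euler): (%.4g, %.4g, %.4g) deg\n",
              ang[1], ang[2], ang[3]))
  invisible(x)
}

#' Rotation matrix from Euler angles, z*y*x order
#'
#' Angles `(alpha, beta, gamma)` in degrees are rotations about the world x, y
#' and z axes, composed as `Rz(gamma) %*% Ry(beta) %*% Rx(alpha)` (x applied
#' first).
#'
#' @param angles numeric length-3, degrees.
#' @export
euler_zyx_rotation <- function(angles) {
  a <- as.numeric(angles) * pi / 180
  ca <- cos(a); sa <- sin(a)
  Rx <- matrix(c(1, 0, 0, 0, ca[1], sa[1], 0, -sa[1], ca[1]), 3, 3)
  Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
  Rz <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

rotation_to_euler_zyx <- function(R) {
  # inverse of euler_zyx_rotation (beta in (-90, 90) branch)
  beta <- asin(-R[3, 1])
  if (abs(cos(beta)) > 1e-12) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal: fold gamma into alpha
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' Apply a rigid transform to world points
#'
#' @param transform a `rigid_transform`.
#' @param points length-3 point or n x 3 matrix (mm).
#' @export
transform_points <- function(transform, points) {
  p <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 3)
  w <- p %*% t(transform$rotation)
  w <- sweep(w, 2, transform$translation, `+`)
  if (is.matrix(points)) w else drop(w)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the map `p -> a(b(p))`.
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform (or registration result)
#'
#' Exact algebraic inverse `(R^T, -R^T t)`. For a registration result this is
#' the DE-CBCT-world to MDCT-world map used to carry ROIs into MDCT space.
#'
#' @param transform a `rigid_transform` or `rigid_registration` result.
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "rigid_registration")) transform <- transform$transform
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Trilinear / nearest-neighbour sampling of a volume at continuous indices
#'
#' Internal workhorse shared by resampling, the registration metric, and ROI
#' transfer diagnostics. Points outside the grid get `fill_value`.
#'
#' @param values 3D array.
#' @param idx n x 3 matrix of continuous 0-based indices.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill_value scalar for out-of-grid points.
#' @return numeric vector of length n.
#' @keywords internal
sample_at_index <- function(values, idx, interpolation = "trilinear",
                            fill_value = -1000) {
  d <- dim(values)
  n <- nrow(idx)
  out <- rep(fill_value, n)
  if (interpolation == "nearest") {
    i <- round(idx)
    ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
          i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
          i[, 3] >= 0 & i[, 3] <= d[3] - 1
    if (any(ok))
      out[ok] <- values[1 + i[ok, 1] + d[1] * (i[ok, 2] + d[2] * i[ok, 3])]
    return(out)
  }
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  f <- floor(p)
  # clamp the upper corner so points exactly on the last plane stay in range
  f <- pmin(f, matrix(d - 2, nrow(f), 3, byrow = TRUE))
  f <- pmax(f, 0)
  w <- p - f
  i0 <- f[, 1]; j0 <- f[, 2]; k0 <- f[, 3]
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  lin <- function(i, j, k) values[1 + i + d[1] * (j + d[2] * k)]
  v <- (1 - wz) * ((1 - wy) * ((1 - wx) * lin(i0,     j0,     k0) +
                               wx       * lin(i0 + 1, j0,     k0)) +
                   wy       * ((1 - wx) * lin(i0,     j0 + 1, k0) +
                               wx       * lin(i0 + 1, j0 + 1, k0))) +
       wz       * ((1 - wy) * ((1 - wx) * lin(i0,     j0,     k0 + 1) +
                               wx       * lin(i0 + 1, j0,     k0 + 1)) +
                   wy       * ((1 - wx) * lin(i0,     j0 + 1, k0 + 1) +
                               wx       * lin(i0 + 1, j0 + 1, k0 + 1)))
  out[ok] <- v
  out
}

all_voxel_centers <- function(g) {
  # n x 3 matrix of 0-based indices in array (column-major) order
  d <- g$dims
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' Resample a volume onto a target grid through a rigid transform
#'
#' Each target voxel center is mapped through `transform` (target world to
#' source world) and interpolated from the source volume; points outside the
#' source extent get `fill_value` (default -1000, air in CT numbers).
#'
#' @param volume source `voxel_volume`.
#' @param target_geometry `grid_geometry` (or `voxel_volume` used as one).
#' @param transform `rigid_transform` mapping target world space into source
#'   world space; identity by default.
#' @param interpolation `"trilinear"` (exact on affine fields) or `"nearest"`.
#' @param fill_value scalar for out-of-field voxels.
#' @return `voxel_volume` on the target geometry.
#' @export
resample_volume <- function(volume, target_geometry,
                            transform = rigid_transform(),
                            interpolation = c("trilinear", "nearest"),
                            fill_value = -1000) {
  interpolation <- match.arg(interpolation)
  g <- as_grid_geometry(target_geometry)
  tw <- index_to_world(g, all_voxel_centers(g))
  sw <- transform_points(transform, tw)
  sidx <- world_to_continuous_index(volume, sw)
  vals <- sample_at_index(volume$values, sidx, interpolation, fill_value)
  voxel_volume(array(vals, g$dims), g$spacing, g$origin, g$direction,
               value_kind = volume$value_kind)
}
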