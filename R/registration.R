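# Intensity-based rigid registration of the MDCT volume into DE-CBCT space.
#
# Multiresolution (mean-pooled pyramid), deterministic strided sampling of
# the fixed volume, mean-squared-error (default) or joint-histogram mutual
# information metric, derivative-free simplex optimization over the 6 rigid
# parameters. The estimated transform is reported in the pipeline's
# MDCT-world -> DE-CBCT-world convention; its inverse carries ROIs from
# DE-CBCT space into MDCT space.

pool_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- vol$dims
  df <- d %/% f
  if (any(df < 2L)) stop("volume too small for pooling factor ", f)
  a <- vol$values[seq_len(df[1] * f), seq_len(df[2] * f), seq_len(df[3] * f)]
  dim(a) <- c(f, df[1], f, df[2], f, df[3])
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  pooled <- array(rowMeans(matrix(a, prod(df), f^3)), df)
  origin <- vol$origin + drop(vol$direction %*% (vol$spacing * (f - 1) / 2))
  voxel_volume(pooled, vol$spacing * f, origin, vol$direction,
               value_kind = vol$value_kind)
}

reg_metric_mse <- function(fixed_vals, moving_vals) mean((fixed_vals - moving_vals)^2)

reg_metric_nmi <- function(fixed_vals, moving_vals, nbins = 32L) {
  # negative mutual information from a joint histogram (to be minimized)
  fr <- range(fixed_vals); mr <- range(moving_vals)
  if (diff(fr) == 0 || diff(mr) == 0) return(0)
  fi <- pmin(pmax(1L + floor((fixed_vals - fr[1]) / diff(fr) * nbins), 1L), nbins)
  mi <- pmin(pmax(1L + floor((moving_vals - mr[1]) / diff(mr) * nbins), 1L), nbins)
  jo <- tabulate(fi + nbins * (mi - 1L), nbins * nbins) / length(fi)
  pf <- rowSums(matrix(jo, nbins)); pm <- colSums(matrix(jo, nbins))
  nz <- jo > 0
  -sum(jo[nz] * log(jo[nz] / (pf[(seq_len(nbins * nbins) - 1L) %% nbins + 1L][nz] *
                              pm[(seq_len(nbins * nbins) - 1L) %/% nbins + 1L][nz])))
}

reg_params_to_transform <- function(theta, center, t0) {
  # fixed-world -> moving-world map: p -> R (p - c) + c + t0 + dt
  R <- euler_zyx_rotation(theta[1:3])
  rigid_transform(R, center - drop(R %*% center) + t0 + theta[4:6])
}

strided_points <- function(vol, keep, max_points) {
  idx <- which(keep)
  if (length(idx) > max_points) {
    stride <- ceiling(length(idx) / max_points)
    idx <- idx[seq(1L, length(idx), by = stride)]
  }
  d <- vol$dims
  i0 <- idx - 1L
  sub <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  list(points = index_to_world(vol, sub), values = vol$values[idx])
}

world_centroid <- function(vol, threshold) {
  keep <- vol$values > threshold
  if (!any(keep)) stop("registration failure: no voxels above the ",
                       "initialization threshold (", threshold, ")")
  sp <- strided_points(vol, keep, 200000L)
  colMeans(sp$points)
}

#' Estimate the rigid transform from MDCT space to DE-CBCT space
#'
#' Three-level multiresolution intensity-based rigid registration:
#' initialization aligns the world centroids of thresholded bone voxels
#' (> 300 CT number by default) and then scans a deterministic coarse grid
#' over the three rotation angles at the coarsest level (multi-start simplex
#' from the best candidates — the similarity surface of piecewise-constant
#' anatomy has nearby local minima). The 6 parameters (three z*y*x Euler
#' angles in degrees about the fixed bone centroid, three translations in
#' mm) are refined per level with a Nelder-Mead simplex on a strided sample
#' of fixed-volume voxel centers; the metric averages only over points that
#' land inside the moving volume, with a penalty when the overlap fraction
#' collapses. Everything is deterministic: no random sampling is used.
#'
#' @param fixed DE-CBCT `voxel_volume` (reference space).
#' @param moving MDCT `voxel_volume`.
#' @param params list of optional settings: `metric` (`"mse"` default, or
#'   `"mi"`), `levels` (pooling factors, default `c(4, 2, 1)`),
#'   `bone_threshold` (init centroid threshold, default 300),
#'   `sample_threshold` (fixed voxels entering the metric, default -500:
#'   everything denser than air), `max_points` (per level, default 100000),
#'   `maxit` (simplex iterations per level, default 1000),
#'   `min_overlap` (fraction of sample points that must land inside the
#'   moving volume at initialization, default 0.25), `init_rot_range` /
#'   `init_rot_steps` (rotation-grid initialization, default +/-10 degrees
#'   in 9 steps).
#' @return object of class `rigid_registration`: `transform` (the
#'   MDCT-world to DE-CBCT-world `rigid_transform`), `final_metric`,
#'   `iterations`, `converged`, `level_metrics`.
#' @export
estimate_rigid <- function(fixed, moving, params = list()) {
  p <- utils::modifyList(list(metric = "mse", levels = c(4L, 2L, 1L),
                              bone_threshold = 300, sample_threshold = -500,
                              max_points = 100000L, maxit = 1000L,
                              min_overlap = 0.25, init_rot_range = 10,
                              init_rot_steps = 9L), params)
  metric_fun <- switch(p$metric, mse = reg_metric_mse, mi = reg_metric_nmi,
                       stop("unknown metric: ", p$metric))
  c_fix <- world_centroid(fixed, p$bone_threshold)
  c_mov <- world_centroid(moving, p$bone_threshold)
  t0 <- c_mov - c_fix        # initial fixed->moving translation
  theta <- rep(0, 6)
  iterations <- 0L; converged <- FALSE
  level_metrics <- numeric(0); level_initial <- numeric(0)
  for (li in seq_along(p$levels)) {
    f <- p$levels[li]
    fx <- pool_volume(fixed, f)
    mv <- pool_volume(moving, f)
    sp <- strided_points(fx, fx$values > p$sample_threshold, p$max_points)
    # the metric averages over the points that land inside the moving
    # volume (out-of-field fill would otherwise bias the optimum toward
    # small motions on thin stacks); a penalty kicks in only when the
    # overlapping fraction collapses
    overlap_scale <- stats::var(sp$values)
    eval_metric <- function(th) {
      M <- reg_params_to_transform(th, c_fix, t0)
      mi <- world_to_continuous_index(mv, transform_points(M, sp$points))
      inside <- mi[, 1] >= 0 & mi[, 1] <= mv$dims[1] - 1 &
                mi[, 2] >= 0 & mi[, 2] <= mv$dims[2] - 1 &
                mi[, 3] >= 0 & mi[, 3] <= mv$dims[3] - 1
      frac <- mean(inside)
      if (frac < 0.05) return(1e12)
      m <- metric_fun(sp$values[inside],
                      sample_at_index(mv$values, mi[inside, , drop = FALSE],
                                      "trilinear", -1000))
      m + 8 * overlap_scale * max(0, 0.7 - frac)^2
    }
    if (li == 1L) {
      M0 <- reg_params_to_transform(theta, c_fix, t0)
      ci <- world_to_continuous_index(mv, transform_points(M0, sp$points))
      inside <- ci[, 1] >= 0 & ci[, 1] <= mv$dims[1] - 1 &
                ci[, 2] >= 0 & ci[, 2] <= mv$dims[2] - 1 &
                ci[, 3] >= 0 & ci[, 3] <= mv$dims[3] - 1
      if (mean(inside) < p$min_overlap)
        stop("registration failure: volumes do not overlap after ",
             "centroid initialization")
      # deterministic coarse search over rotations at the coarsest level
      # (centroid alignment fixes translation but not orientation), followed
      # by multi-start simplex from the best grid candidates: the similarity
      # surface of piecewise-constant anatomy has nearby local minima
      if (p$init_rot_steps > 1L && p$init_rot_range > 0) {
        angles <- seq(-p$init_rot_range, p$init_rot_range,
                      length.out = p$init_rot_steps)
        grid <- as.matrix(expand.grid(angles, angles, angles))
        vals <- apply(grid, 1, function(a) eval_metric(c(a, 0, 0, 0)))
        iterations <- iterations + nrow(grid)
        starts <- grid[order(vals)[seq_len(min(3L, nrow(grid)))], ,
                       drop = FALSE]
        cand <- lapply(seq_len(nrow(starts)), function(s)
          stats::optim(c(starts[s, ], 0, 0, 0), eval_metric,
                       method = "Nelder-Mead",
                       control = list(maxit = p$maxit, reltol = 1e-12)))
        best <- which.min(vapply(cand, `[[`, 0, "value"))
        iterations <- iterations +
          sum(vapply(cand, function(o) o$counts[["function"]], 0))
        theta <- cand[[best]]$par
      }
    }
    level_initial <- c(level_initial, eval_metric(theta))
    opt <- stats::optim(theta, eval_metric, method = "Nelder-Mead",
                        control = list(maxit = p$maxit, reltol = 1e-12))
    # simplex restart from the optimum guards against premature collapse
    opt <- stats::optim(opt$par, eval_metric, method = "Nelder-Mead",
                        control = list(maxit = p$maxit, reltol = 1e-12))
    theta <- opt$par
    iterations <- iterations + opt$counts[["function"]]
    converged <- opt$convergence == 0L
    level_metrics <- c(level_metrics, opt$value)
  }
  M <- reg_params_to_transform(theta, c_fix, t0)  # fixed -> moving
  structure(list(transform = invert_transform(M), final_metric = opt$value,
                 iterations = iterations, converged = converged,
                 level_metrics = level_metrics, level_initial = level_initial,
                 params = p,
                 theta = theta),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> %s metric %.6g after %d evaluations (%s)\n",
              x$params$metric, x$final_metric, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}
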