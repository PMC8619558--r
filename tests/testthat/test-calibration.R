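# Independent oracles used here:
#  - density line: direct 1-D minimization of the orthogonal SSE over the
#    line angle (the line passes through the centroid for any fixed angle)
#  - HU map: closed-form normal equations
#  - projection: fine grid search of the nearest point on the line

orthogonal_sse <- function(X, angle) {
  u <- c(cos(angle), sin(angle))
  Xc <- sweep(X, 2, colMeans(X))
  sum((Xc - outer(drop(Xc %*% u), u))^2)
}

test_that("region sample extraction reports per-region channel means", {
  g <- centered_grid(c(6L, 6L, 4L), c(1, 1, 1))
  low <- voxel_volume(array(100, g$dims), g$spacing, g$origin)
  high <- voxel_volume(array(80, g$dims), g$spacing, g$origin)
  masks <- list(blob = 1:20)
  s <- extract_region_samples(low, high, masks)
  expect_equal(s$mean_low, 100)
  expect_equal(s$mean_high, 80)
  expect_true(is.na(s$known_hu))

  other <- voxel_volume(array(80, c(6, 6, 5)), g$spacing, g$origin)
  expect_error(extract_region_samples(low, other, masks), "identical")
  expect_error(extract_region_samples(low, high, list(tiny = 1:3)), "tiny")
  expect_error(extract_region_samples(low, high, list(empty = integer())),
               "empty")
})

test_that("noiseless phantom samples equal the analytic CT-number pairs", {
  ph <- fx_phantom()
  mats <- ph$scene$materials
  mu_w <- attr(mats, "mu_water")
  for (i in seq_len(nrow(ph$samples))) {
    m <- mats[mats$name == ph$samples$label[i], ]
    expect_equal(ph$samples$mean_low[i],
                 1000 * (m$mu_low - mu_w[["low"]]) / mu_w[["low"]],
                 tolerance = 1e-9)
    expect_equal(ph$samples$mean_high[i],
                 1000 * (m$mu_high - mu_w[["high"]]) / mu_w[["high"]],
                 tolerance = 1e-9)
  }
})

test_that("density-line fit matches the angle-minimization oracle", {
  # two points: exact interpolation
  two <- data.frame(mean_low = c(0, 1), mean_high = c(0, 2))
  fit <- fit_density_line(two)
  expect_equal(fit$u, c(1, 2) / sqrt(5), tolerance = 1e-12)
  expect_lt(fit$rss, 1e-18)

  # collinear points: zero residual, direction (1,2)/sqrt(5)
  col3 <- data.frame(mean_low = c(0, 1, 2), mean_high = c(0, 2, 4))
  fit <- fit_density_line(col3)
  expect_equal(fit$u, c(1, 2) / sqrt(5), tolerance = 1e-12)
  expect_lt(fit$rss, 1e-18)

  # noisy points: SSE within 1e-9 of direct minimization over the angle
  set.seed(11)
  for (rep in 1:5) {
    X <- cbind(runif(6, -500, 2000), runif(6, -500, 1500))
    X[, 2] <- 0.8 * X[, 1] + rnorm(6, sd = 60)
    fit <- fit_density_line(data.frame(mean_low = X[, 1], mean_high = X[, 2]))
    oracle <- stats::optimize(function(a) orthogonal_sse(X, a),
                              c(0, pi), tol = 1e-14)
    expect_lt(abs(fit$rss - oracle$objective), 1e-9 * max(1, oracle$objective))
  }
  expect_error(fit_density_line(data.frame(mean_low = c(1, 1),
                                           mean_high = c(2, 2))),
               "degenerate")
})

test_that("projection returns the distance-minimizing line coordinate", {
  line <- fit_density_line(data.frame(mean_low = c(0, 10),
                                      mean_high = c(0, 5)))
  expect_equal(project_to_density(line$p0, line), 0)
  expect_equal(project_to_density(line$p0 + 3 * line$u, line), 3,
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:10) {
    pair <- runif(2, -1000, 2000)
    t_hat <- project_to_density(pair, line)
    tt <- seq(t_hat - 50, t_hat + 50, length.out = 100001)
    d2 <- (pair[1] - (line$p0[1] + tt * line$u[1]))^2 +
          (pair[2] - (line$p0[2] + tt * line$u[2]))^2
    expect_lt(abs(tt[which.min(d2)] - t_hat), 1e-2)
  }
})

test_that("HU map matches closed-form least squares", {
  line <- structure(list(p0 = c(0, 0), u = c(1, 0) , rss = 0, method = "tls"),
                    class = "density_line")
  # two anchors: unique interpolating line through (t_air, -1000), (t_1, h_1)
  s2 <- data.frame(label = c("air", "HA"), mean_low = c(-1000, 500),
                   mean_high = c(0, 0), known_hu = c(-1000, 300))
  hm <- fit_hu_map(s2, line)
  expect_equal(hm$slope, (300 + 1000) / 1500, tolerance = 1e-12)
  expect_equal(hm$intercept, -1000 + hm$slope * 1000, tolerance = 1e-9)

  # already affine in t: exact recovery
  t <- c(-3, -1, 0, 2, 5)
  s5 <- data.frame(label = letters[1:5], mean_low = t,
                   mean_high = 0, known_hu = 7 * t + 11)
  hm <- fit_hu_map(s5, line)
  expect_equal(c(hm$slope, hm$intercept), c(7, 11), tolerance = 1e-9)
  expect_lt(max(abs(hm$residuals)), 1e-9)

  # 5 noisy samples vs normal equations
  set.seed(9)
  s5$known_hu <- 7 * t + 11 + rnorm(5, sd = 4)
  hm <- fit_hu_map(s5, line)
  A <- cbind(1, t)
  beta <- solve(t(A) %*% A, t(A) %*% s5$known_hu)
  expect_equal(c(hm$intercept, hm$slope), drop(beta), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(fit_hu_map(s5[1, ], line), "at least 2")
  s_same <- data.frame(label = c("a", "b"), mean_low = c(1, 1),
                       mean_high = c(0, 0), known_hu = c(0, 100))
  expect_error(fit_hu_map(s_same, line), "degenerate")
})

test_that("noiseless calibration recovers every material's reference HU", {
  ph <- fx_phantom()
  hu <- apply_calibration(ph$low, ph$high, ph$fit)
  expect_equal(hu$value_kind, "hu")
  for (m in names(ph$masks)) {
    vals <- hu$values[ph$masks[[m]]]
    expect_lt(max(abs(vals - ph$known[[m]])),
              1e-6, label = paste("HU recovery for", m))
  }
})

test_that("calibration is order-invariant and self-consistent", {
  ph <- fx_phantom()
  # permuting the regions changes nothing
  set.seed(2)
  perm <- sample(nrow(ph$samples))
  fit_p <- de_calibration(ph$samples[perm, ])
  expect_equal(abs(fit_p$line$u), abs(ph$fit$line$u), tolerance = 1e-12)
  hu_a <- predict(ph$fit, data.frame(low = c(100, 900), high = c(50, 700)))
  hu_b <- predict(fit_p, data.frame(low = c(100, 900), high = c(50, 700)))
  expect_equal(hu_a, hu_b, tolerance = 1e-9)

  # recalibration after per-channel affine remapping reproduces the same HU
  remap <- function(vol, a, b) voxel_volume(a * vol$values + b, vol$spacing,
                                            vol$origin, vol$direction)
  low2 <- remap(ph$low, 1.7, 120); high2 <- remap(ph$high, 0.6, -300)
  s2 <- extract_region_samples(low2, high2, ph$masks, ph$known)
  fit2 <- de_calibration(s2)
  hu1 <- apply_calibration(ph$low, ph$high, ph$fit)
  hu2 <- apply_calibration(low2, high2, fit2)
  expect_lt(max(abs(hu1$values - hu2$values)), 1e-6)
})

test_that("noisy calibration recovers insert HU within 3 HU at ROI scale", {
  scene <- build_calibration_phantom()
  g <- cbct_geometry(n_slices = 40)  # clinical in-plane grid, 12 mm stack
  low <- render_ct(scene, g, "low", noise_sd = 30, seed = 21)
  high <- render_ct(scene, g, "high", noise_sd = 30, seed = 22)
  masks <- scene_region_masks(scene, g,
                              c("acrylic", "air", "HA200", "HA400",
                                "HA800", "HA1200"))
  known <- stats::setNames(scene$materials$known_hu, scene$materials$name)
  fit <- de_calibration(extract_region_samples(low, high, masks, known))
  hu <- apply_calibration(low, high, fit)
  # insert-sized ROI (the insert radius is 6 mm; stay inside its boundary)
  for (a in which(scene$anchors$label != "air")) {
    roi <- cylinder_roi(unlist(scene$anchors[a, c("x", "y", "z")]),
                        height = 4.5, diameter = 9,
                        label = scene$anchors$label[a], validate = FALSE)
    got <- roi_statistics(hu, roi)$mean
    expect_lt(abs(got - known[[scene$anchors$label[a]]]), 3)
  }
})
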