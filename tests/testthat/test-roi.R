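test_that("cylinder membership follows the axis/radius rule", {
  g <- centered_grid(c(21L, 21L, 21L), c(0.5, 0.5, 0.5))
  vol <- voxel_volume(array(0, g$dims), g$spacing, g$origin)
  roi <- cylinder_roi(c(0, 0, 0), height = 4, diameter = 1.4)
  idx <- cylinder_mask(vol, roi)
  center_lin <- 1 + 10 + 21 * (10 + 21 * 10)  # voxel at the roi center
  expect_true(center_lin %in% idx)
  pts <- index_to_world(g, decbct:::all_voxel_centers(g))
  inside <- abs(pts[, 3]) <= 2 & pts[, 1]^2 + pts[, 2]^2 <= 0.7^2 + 1e-12
  expect_setequal(idx, which(inside))
  # a voxel one spacing beyond the half-height is excluded
  expect_false((1 + 10 + 21 * (10 + 21 * 15)) %in% idx)
  expect_error(cylinder_mask(vol, cylinder_roi(c(50, 0, 0), label = "far",
                                               validate = FALSE)),
               "outside|empty")
})

test_that("mask volume approximates the analytic cylinder volume", {
  g <- centered_grid(c(80L, 80L, 120L), c(0.05, 0.05, 0.05))
  vol <- voxel_volume(array(0, g$dims), g$spacing, g$origin)
  roi <- cylinder_roi(c(0, 0, 0), height = 5, diameter = 1.4,
                      angles = c(20, -10, 45))
  got <- length(cylinder_mask(vol, roi)) * prod(g$spacing)
  analytic <- pi * 0.7^2 * 5
  expect_lt(abs(got - analytic) / analytic, 0.02)
})

test_that("roi statistics are the sample moments of member voxels", {
  g <- centered_grid(c(11L, 11L, 11L), c(1, 1, 1))
  vol <- voxel_volume(array(700, g$dims), g$spacing, g$origin)
  roi <- cylinder_roi(c(0, 0, 0), height = 4, diameter = 1.4)
  s <- roi_statistics(vol, roi)
  expect_equal(s$mean, 700)
  expect_equal(s$sd, 0)
  expect_equal(s$min, 700)

  # two-voxel ROI with values 600/800
  g2 <- grid_geometry(c(2L, 1L, 1L), c(1, 1, 1))
  v2 <- voxel_volume(array(c(600, 800), c(2, 1, 1)), g2$spacing, g2$origin)
  s2 <- roi_statistics(v2, cylinder_roi(c(0.5, 0, 0), height = 4,
                                        diameter = 1.2, angles = c(0, 90, 0),
                                        label = "pair"))
  expect_equal(s2$n_voxels, 2)
  expect_equal(s2$mean, 700)
  expect_equal(s2$sd, sqrt(2) * 100, tolerance = 1e-6)

  expect_warning(
    roi_statistics(v2, cylinder_roi(c(0, 0, 0), height = 1, diameter = 1,
                                    label = "single", validate = FALSE)),
    "single-voxel")
})

test_that("membership is invariant under simultaneous rigid motion", {
  g <- centered_grid(c(30L, 30L, 30L), c(0.5, 0.5, 0.5))
  vol <- voxel_volume(array(0, g$dims), g$spacing, g$origin)
  roi <- cylinder_roi(c(0.3, -0.2, 0.1), height = 4.5, diameter = 1.4,
                      angles = c(15, -30, 60))
  tr <- rigid_transform(random_rotation(8), c(1.1, -0.7, 0.4))
  g_t <- grid_geometry(g$dims, g$spacing,
                       origin = transform_points(tr, g$origin),
                       direction = tr$rotation %*% g$direction)
  vol_t <- voxel_volume(vol$values, g_t$spacing, g_t$origin, g_t$direction)
  expect_setequal(cylinder_mask(vol, roi),
                  cylinder_mask(vol_t, transform_cylinder(roi, tr)))
})

test_that("transformed cylinders contain exactly the mapped point set", {
  roi <- cylinder_roi(c(2, -1, 3), height = 5, diameter = 1.4,
                      angles = c(25, 40, -60))
  tr <- rigid_transform(random_rotation(3), c(-4, 2, 7))
  roi_t <- transform_cylinder(roi, tr)
  expect_equal(roi_t$height, roi$height)
  expect_equal(roi_t$diameter, roi$diameter)
  # Monte-Carlo membership oracle on 1e4 points around the cylinder
  set.seed(14)
  q <- cbind(rnorm(10000, roi$center[1], 2), rnorm(10000, roi$center[2], 2),
             rnorm(10000, roi$center[3], 3))
  in_src <- decbct:::roi_member_points(roi, q)
  in_dst <- decbct:::roi_member_points(roi_t, transform_points(tr, q))
  expect_identical(in_src, in_dst)

  # identity and pure translation leave geometry untouched
  expect_equal(transform_cylinder(roi, rigid_transform())$angles, roi$angles)
  sh <- transform_cylinder(roi, rigid_transform(translation = c(1, 2, 3)))
  expect_equal(sh$center, roi$center + c(1, 2, 3))
  expect_equal(sh$angles, roi$angles)
  expect_error(transform_cylinder(roi, list(rotation = diag(3))),
               "unsupported")
})

test_that("shrinking an ROI never adds voxels", {
  g <- centered_grid(c(25L, 25L, 25L), c(0.4, 0.4, 0.4))
  vol <- voxel_volume(array(0, g$dims), g$spacing, g$origin)
  base <- cylinder_roi(c(0.1, 0.2, -0.1), height = 5, diameter = 1.4,
                       angles = c(10, 20, 30))
  idx_base <- cylinder_mask(vol, base)
  for (h in c(4.5, 4)) for (d in c(1.2, 1.0)) {
    smaller <- cylinder_roi(base$center, height = h, diameter = d,
                            angles = base$angles)
    expect_true(all(cylinder_mask(vol, smaller) %in% idx_base))
  }
})

test_that("paired means couple the two image spaces through the inverse", {
  jaw <- fx_jaw_study()
  rois <- anchor_rois(jaw$scene)
  expect_length(rois, 15)

  # identity transform on identical volumes: pairs are exactly equal
  pr <- paired_roi_means(jaw$vol_hu, jaw$vol_hu, rois, rigid_transform())
  expect_equal(pr$mean_mdct, pr$mean_decbct)
  expect_setequal(unique(pr$group), c("mandible", "maxilla"))
  expect_equal(sum(pr$group == "mandible"), 9)
  expect_equal(sum(pr$group == "maxilla"), 6)

  # known misalignment used as the inverse: cortical ROI means agree up to
  # the injected -5% MDCT bone bias, i.e. mdct/decbct = 0.95 exactly
  inv <- invert_transform(jaw$study$true_transform)
  pr <- paired_roi_means(jaw$vol_hu, jaw$study$vol_mdct, rois, inv)
  expect_equal(nrow(pr), 15)
  expect_equal(pr$mean_mdct / pr$mean_decbct, rep(0.95, 15),
               tolerance = 2 / 1330)
  expect_equal(nrow(attr(pr, "excluded")), 0)

  # an ROI outside the MDCT extent is excluded and recorded
  far <- cylinder_roi(c(0, 0, 100), label = "mandible_far", validate = FALSE)
  pr2 <- paired_roi_means(jaw$vol_hu, jaw$study$vol_mdct,
                          c(rois, list(far)), inv)
  expect_equal(nrow(pr2), 15)
  expect_equal(attr(pr2, "excluded")$label, "mandible_far")
})
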