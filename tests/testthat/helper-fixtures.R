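# Shared fixtures. Test volumes use reduced grids (coarser than the
# clinical 334x334 @ 0.3 mm / 512x512 @ 0.332 mm defaults) so the suite
# stays fast; expensive renders are cached across test files.

.fx <- new.env(parent = emptyenv())

centered_grid <- function(dims, spacing) {
  grid_geometry(dims, spacing, origin = -(dims - 1) * spacing / 2)
}

test_cbct_geom <- function() centered_grid(c(120L, 120L, 40L), c(0.8, 0.8, 0.6))
test_mdct_geom <- function() centered_grid(c(150L, 150L, 30L),
                                           c(0.664, 0.664, 0.9))

fx_cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# noiseless calibration phantom on the test CBCT grid, with samples and fit
fx_phantom <- function() {
  fx_cached("phantom", {
    scene <- build_calibration_phantom()
    g <- test_cbct_geom()
    low <- render_ct(scene, g, "low")
    high <- render_ct(scene, g, "high")
    masks <- scene_region_masks(
      scene, g, c("acrylic", "air", "HA200", "HA400", "HA800", "HA1200"))
    known <- stats::setNames(scene$materials$known_hu, scene$materials$name)
    samples <- extract_region_samples(low, high, masks, known)
    list(scene = scene, geom = g, low = low, high = high, masks = masks,
         known = known, samples = samples, fit = de_calibration(samples))
  })
}

fx_misalignment <- function() {
  rigid_transform(euler_zyx_rotation(c(0, 0, 5)), c(3, -2, 1))
}

# noiseless jaw study with the standard test misalignment
fx_jaw_study <- function() {
  fx_cached("jaw_study", {
    scene <- build_jaw_scene()
    study <- simulate_paired_study(scene, fx_misalignment(),
                                   noise = list(cbct_sd = 0, mdct_sd = 0),
                                   cbct_geom = test_cbct_geom(),
                                   mdct_geom = test_mdct_geom())
    list(scene = scene, study = study,
         vol_hu = apply_calibration(study$vol_low, study$vol_high,
                                    fx_phantom()$fit))
  })
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_R <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_R)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_angle_deg <- function(Ra, Rb) {
  tr <- sum(diag(t(Ra) %*% Rb))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# deviation values realizing given per-band counts (closed at the outer edge)
deviations_with_counts <- function(n_within10, n_10_15, n_15_20,
                                   n_over20 = 0) {
  c(rep(5, n_within10), rep(12.5, n_10_15), rep(-17.5, n_15_20),
    rep(25, n_over20))
}
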