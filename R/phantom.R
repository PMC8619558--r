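# Synthetic dual-energy phantom and jaw-scene generator.
#
# Volumes are rendered directly in the image domain from analytic scenes
# (no projection/reconstruction physics): per voxel,
# CT = 1000 * (mu_material - mu_water) / mu_water at the requested energy
# channel, plus an optional radially-quadratic bias field (a cupping
# surrogate) and seeded Gaussian noise. Every downstream stage therefore has
# exact ground truth.

#' Default material table for the synthetic phantoms
#'
#' Linear attenuation (1/cm) is assigned per energy channel from each
#' material's reference Hounsfield unit through a two-channel model:
#' `raw_c = -1000 + b_c * (HU + 1000)` and `mu_c = mu_water_c * (1 + raw_c/1000)`,
#' where `b_c` is the channel's bone-sensitivity slope. This keeps air at
#' exactly -1000 in every channel and places all material `(low, high)`
#' raw-value pairs exactly on one line in the value plane — the geometry the
#' density-line calibration assumes. The MDCT channel reads true HU except
#' for an optional multiplicative offset on bone-class materials
#' (`mdct_bone_bias`, default -0.05: DE-CBCT reads ~5% higher than MDCT on
#' bone, giving the agreement analysis a realistic bias to detect).
#'
#' @param b_low,b_high bone-sensitivity slope of the low/high-kVp channel.
#' @param mdct_bone_bias multiplicative offset applied to MDCT CT numbers of
#'   bone-class materials (HA, cortical, trabecular).
#' @param ha_densities hydroxyapatite insert densities (mg/cm^3).
#' @param ha_hu reference HU of each insert (same length).
#' @return data.frame with columns `name`, `known_hu`, `mu_low`, `mu_high`,
#'   `mu_mdct`, `bone`; water attenuation per channel in
#'   `attr(, "mu_water")`.
#' @export
default_materials <- function(b_low = 1.15, b_high = 0.92,
                              mdct_bone_bias = -0.05,
                              ha_densities = c(200, 400, 800, 1200),
                              ha_hu = 1.5 * ha_densities) {
  stopifnot(length(ha_densities) == length(ha_hu))
  name <- c("air", "water", "acrylic", "soft_tissue",
            "trabecular", "cortical", paste0("HA", ha_densities))
  hu <- c(-1000, 0, 120, 40, 300, 1400, ha_hu)
  bone <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, rep(TRUE, length(ha_hu)))
  mu_water <- c(low = 0.206, high = 0.180, mdct = 0.192)
  raw <- function(b) -1000 + b * (hu + 1000)
  hu_mdct <- ifelse(bone, hu * (1 + mdct_bone_bias), hu)
  tab <- data.frame(
    name = name, known_hu = hu, bone = bone,
    mu_low  = mu_water[["low"]]  * (1 + raw(b_low) / 1000),
    mu_high = mu_water[["high"]] * (1 + raw(b_high) / 1000),
    mu_mdct = mu_water[["mdct"]] * (1 + hu_mdct / 1000),
    stringsAsFactors = FALSE
  )
  attr(tab, "mu_water") <- mu_water
  tab
}

new_scene <- function(primitives, background, anchors, materials) {
  labs <- vapply(primitives, `[[`, "", "material")
  bad <- setdiff(c(labs, background), materials$name)
  if (length(bad))
    stop("scene references undefined material(s): ", paste(bad, collapse = ", "))
  structure(list(primitives = primitives, background = background,
                 anchors = anchors, materials = materials),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d primitives on '%s' background, %d anchors\n",
              length(x$primitives), x$background, nrow(x$anchors)))
  invisible(x)
}

prim_cylinder <- function(material, center, radius, height) {
  list(shape = "cylinder", material = material, center = center,
       radius = radius, height = height)
}
prim_arch <- function(material, center, r_inner, r_outer, height,
                      theta_deg = c(-120, 120)) {
  list(shape = "arch_segment", material = material, center = center,
       r_inner = r_inner, r_outer = r_outer, height = height,
       theta = theta_deg)
}
prim_box <- function(material, center, size) {
  list(shape = "box", material = material, center = center, size = size)
}
prim_tube <- function(material, center, r_inner, r_outer, height) {
  list(shape = "tube", material = material, center = center,
       r_inner = r_inner, r_outer = r_outer, height = height)
}

prim_member <- function(prim, pts) {
  dx <- pts[, 1] - prim$center[1]
  dy <- pts[, 2] - prim$center[2]
  dz <- pts[, 3] - prim$center[3]
  switch(prim$shape,
    cylinder = (dx * dx + dy * dy <= prim$radius^2) &
               (abs(dz) <= prim$height / 2),
    tube = {
      r2 <- dx * dx + dy * dy
      r2 <= prim$r_outer^2 & r2 >= prim$r_inner^2 & abs(dz) <= prim$height / 2
    },
    box = abs(dx) <= prim$size[1] / 2 & abs(dy) <= prim$size[2] / 2 &
          abs(dz) <= prim$size[3] / 2,
    arch_segment = {
      r2 <- dx * dx + dy * dy
      th <- atan2(dy, dx) * 180 / pi
      r2 >= prim$r_inner^2 & r2 <= prim$r_outer^2 &
        abs(dz) <= prim$height / 2 &
        th >= prim$theta[1] & th <= prim$theta[2]
    },
    stop("unknown primitive shape: ", prim$shape)
  )
}

#' Material label at world points of a scene
#'
#' Later primitives override earlier ones (painter's order); points in no
#' primitive get the background material.
#'
#' @param scene a `phantom_scene`.
#' @param points n x 3 matrix (or length-3 vector) of world points, mm.
#' @return character vector of material names.
#' @export
scene_material_at <- function(scene, points) {
  pts <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 3)
  lab <- rep(scene$background, nrow(pts))
  for (prim in scene$primitives) lab[prim_member(prim, pts)] <- prim$material
  lab
}

#' Build the HU calibration phantom scene
#'
#' An acrylic cylinder base holding one air insert plus hydroxyapatite (HA)
#' inserts of the given densities, arranged on a ring; one anchor per insert
#' center. Insert materials are named `HA<density>` and must exist in the
#' material table (see [default_materials()]).
#'
#' @param densities HA insert densities (mg/cm^3); at least 2.
#' @param base_radius acrylic base radius, mm.
#' @param insert_radius insert radius, mm.
#' @param height phantom height, mm.
#' @param materials material table.
#' @return `phantom_scene` with anchors at each insert center.
#' @export
build_calibration_phantom <- function(densities = c(200, 400, 800, 1200),
                                      base_radius = 40, insert_radius = 6,
                                      height = 16,
                                      materials = default_materials(ha_densities = densities)) {
  if (length(densities) < 2L)
    stop("need at least 2 HA inserts (plus air) to define the density line")
  n_ins <- length(densities) + 1L  # + air
  ring <- 0.55 * base_radius
  # nearest-neighbour center distance on the ring, and fit inside the base
  if (2 * ring * sin(pi / n_ins) <= 2 * insert_radius ||
      ring + insert_radius >= base_radius)
    stop("overlapping inserts: reduce insert_radius or density count")
  theta <- 2 * pi * (seq_len(n_ins) - 1) / n_ins
  centers <- cbind(ring * cos(theta), ring * sin(theta), 0)
  labels <- c("air", paste0("HA", densities))
  prims <- c(
    list(prim_cylinder("acrylic", c(0, 0, 0), base_radius, height)),
    lapply(seq_len(n_ins), function(i)
      prim_cylinder(labels[i], centers[i, ], insert_radius, height))
  )
  anchors <- data.frame(label = labels, x = centers[, 1], y = centers[, 2],
                        z = centers[, 3], stringsAsFactors = FALSE)
  new_scene(prims, background = "air", anchors = anchors,
            materials = materials)
}

#' Build a jaw-like test scene
#'
#' Two horseshoe-shaped arches (mandible below, maxilla above), each a
#' cortical shell around a trabecular core, embedded in a soft-tissue
#' cylinder. Named anchors (`mandible_1..9`, `maxilla_1..6` by default) sit
#' at mid-thickness of the outer cortical shell, where a default-size
#' cylindrical ROI (diameter <= 1.4 mm, height <= 5 mm, axis along z) fits
#' entirely in cortical bone.
#'
#' @param arch_radius outer trabecular radius of the mandibular arch, mm.
#' @param cortical_thickness cortical shell thickness, mm (>= 2 so the
#'   largest ROI diameter 1.4 mm fits with margin).
#' @param n_mandible_anchors,n_maxilla_anchors reference-position counts.
#' @param materials material table.
#' @return `phantom_scene` with `n_mandible_anchors + n_maxilla_anchors`
#'   anchors.
#' @export
build_jaw_scene <- function(arch_radius = 30, cortical_thickness = 3,
                            n_mandible_anchors = 9, n_maxilla_anchors = 6,
                            materials = default_materials()) {
  t <- cortical_thickness
  if (t < 2)
    stop("geometry too thin for ROI placement: cortical_thickness must be >= 2 mm")
  arch <- function(material, r_out, z0, h, span) {
    prim_arch(material, c(0, 0, z0), r_inner = r_out - 5, r_outer = r_out,
              height = h, theta_deg = span)
  }
  # cortical = full-thickness arch painted first, trabecular core painted over
  jaw_prims <- function(r_out, z0, h, span) {
    list(
      prim_arch("cortical", c(0, 0, z0), r_out - 5 - t, r_out + t, h + 2 * t, span),
      arch("trabecular", r_out, z0, h, span)
    )
  }
  mand_span <- c(-120, 120); max_span <- c(-100, 100)
  r_max <- arch_radius - 4
  prims <- c(
    list(prim_cylinder("soft_tissue", c(0, 0, 0), arch_radius + t + 6, 23)),
    jaw_prims(arch_radius, -6, 4, mand_span),
    jaw_prims(r_max, 6, 4, max_span)
  )
  anchor_ring <- function(prefix, n, r_out, z0, span) {
    th <- seq(span[1] + 12, span[2] - 12, length.out = n) * pi / 180
    r <- r_out + t / 2
    data.frame(label = paste0(prefix, "_", seq_len(n)),
               x = r * cos(th), y = r * sin(th), z = z0,
               stringsAsFactors = FALSE)
  }
  anchors <- rbind(
    anchor_ring("mandible", n_mandible_anchors, arch_radius, -6, mand_span),
    anchor_ring("maxilla", n_maxilla_anchors, r_max, 6, max_span)
  )
  new_scene(prims, background = "air", anchors = anchors,
            materials = materials)
}

#' Default DE-CBCT grid geometry
#'
#' 334 x 334 in-plane voxels at 0.3 x 0.3 mm pixel pitch, 0.3 mm slices,
#' centered on the world origin.
#' @param n_slices number of axial slices.
#' @export
cbct_geometry <- function(n_slices = 80) {
  dims <- c(334L, 334L, as.integer(n_slices))
  sp <- c(0.3, 0.3, 0.3)
  grid_geometry(dims, sp, origin = -(dims - 1) * sp / 2)
}

#' Default MDCT grid geometry
#'
#' 512 x 512 in-plane voxels at 0.332 x 0.332 mm pixel spacing, 0.75 mm
#' slices, centered on the world origin.
#' @param n_slices number of axial slices.
#' @export
mdct_geometry <- function(n_slices = 32) {
  dims <- c(512L, 512L, as.integer(n_slices))
  sp <- c(0.332, 0.332, 0.75)
  grid_geometry(dims, sp, origin = -(dims - 1) * sp / 2)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render a CT volume of a scene at one energy channel
#'
#' Per voxel center, `CT = 1000 * (mu - mu_water) / mu_water` at the channel,
#' plus an optional radially-quadratic in-plane bias field (a CBCT-cupping
#' surrogate) and seeded Gaussian noise.
#'
#' @param scene a `phantom_scene`.
#' @param geometry `grid_geometry` to render on.
#' @param channel `"low"`, `"high"` (CBCT kVp channels) or `"mdct"`.
#' @param noise_sd Gaussian noise SD in CT numbers (0 = noiseless).
#' @param bias_amplitude CT-number amplitude of the radial bias field at the
#'   in-plane grid corner radius (0 disables).
#' @param seed RNG seed; required when `noise_sd > 0` (renders are
#'   deterministic for a fixed seed).
#' @param view_transform optional `rigid_transform` mapping this grid's world
#'   points into scene coordinates (used to image a rigidly displaced scene).
#' @return `voxel_volume`; `value_kind` is `"raw_ct"` for the CBCT channels
#'   and `"hu"` for the MDCT channel.
#' @export
render_ct <- function(scene, geometry, channel = c("low", "high", "mdct"),
                      noise_sd = 0, bias_amplitude = 0, seed = NULL,
                      view_transform = NULL) {
  channel <- match.arg(channel)
  g <- as_grid_geometry(geometry)
  mu_col <- paste0("mu_", channel)
  if (!mu_col %in% names(scene$materials))
    stop("material table defines no attenuation for channel '", channel, "'")
  mu_water <- attr(scene$materials, "mu_water")[[channel]]
  if (is.null(mu_water) || !is.finite(mu_water) || mu_water <= 0)
    stop("water attenuation not configured for channel '", channel, "'")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  pts <- index_to_world(g, all_voxel_centers(g))
  if (!is.null(view_transform)) pts <- transform_points(view_transform, pts)
  lab <- scene_material_at(scene, pts)
  mu <- scene$materials[[mu_col]][match(lab, scene$materials$name)]
  if (anyNA(mu)) stop("scene references materials missing from the table")
  ct <- 1000 * (mu - mu_water) / mu_water
  if (bias_amplitude != 0) {
    ctr <- index_to_world(g, (g$dims - 1) / 2)
    r2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
    r2max <- sum(((g$dims[1:2] - 1) * g$spacing[1:2] / 2)^2)
    ct <- ct + bias_amplitude * r2 / r2max
  }
  if (noise_sd > 0)
    ct <- ct + with_seed(seed, stats::rnorm(length(ct), 0, noise_sd))
  voxel_volume(array(ct, g$dims), g$spacing, g$origin, g$direction,
               value_kind = if (channel == "mdct") "hu" else "raw_ct")
}

#' Simulate a paired DE-CBCT / MDCT study with known ground truth
#'
#' Renders the scene as low- and high-kVp CBCT volumes on one shared CBCT
#' grid ("voxel-by-voxel in the same coordinate"), and as a single-energy
#' MDCT volume on a coarser MDCT grid after displacing the scene by a known
#' rigid misalignment. The misalignment is recorded as `true_transform`
#' (MDCT-world to CBCT-world): a structure at scene/CBCT point `s` appears at
#' MDCT world point `inv(true_transform)(s)`.
#'
#' @param scene a `phantom_scene`.
#' @param misalignment `rigid_transform`, MDCT-world to CBCT-world.
#' @param noise list with `cbct_sd` and `mdct_sd` (CT numbers).
#' @param seed integer seed for all rendering noise.
#' @param cbct_geom,mdct_geom grid geometries.
#' @return object of class `simulated_study`: `vol_low`, `vol_high`,
#'   `vol_mdct`, `true_transform`, `region_labels` + `region_ids` (material
#'   id array on the CBCT grid), `scene`, `seed`.
#' @export
simulate_paired_study <- function(scene, misalignment = rigid_transform(),
                                  noise = list(cbct_sd = 30, mdct_sd = 15),
                                  seed = 1,
                                  cbct_geom = cbct_geometry(),
                                  mdct_geom = mdct_geometry()) {
  cbct_geom <- as_grid_geometry(cbct_geom)
  mdct_geom <- as_grid_geometry(mdct_geom)
  cb_sd <- noise$cbct_sd %||% 0
  md_sd <- noise$mdct_sd %||% 0
  vol_low <- render_ct(scene, cbct_geom, "low", noise_sd = cb_sd,
                       seed = if (cb_sd > 0) seed + 1L else NULL)
  vol_high <- render_ct(scene, cbct_geom, "high", noise_sd = cb_sd,
                        seed = if (cb_sd > 0) seed + 2L else NULL)
  # the MDCT grid images the displaced scene: grid world -> scene coords
  vol_mdct <- render_ct(scene, mdct_geom, "mdct", noise_sd = md_sd,
                        seed = if (md_sd > 0) seed + 3L else NULL,
                        view_transform = misalignment)
  pts <- index_to_world(cbct_geom, all_voxel_centers(cbct_geom))
  lab <- scene_material_at(scene, pts)
  labels <- scene$materials$name
  ids <- array(match(lab, labels), cbct_geom$dims)
  structure(list(vol_low = vol_low, vol_high = vol_high, vol_mdct = vol_mdct,
                 true_transform = misalignment, region_labels = labels,
                 region_ids = ids, scene = scene, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study>\n  CBCT grid:",
      paste(x$vol_low$dims, collapse = " x "), "\n  MDCT grid:",
      paste(x$vol_mdct$dims, collapse = " x "), "\n")
  cat(sprintf("  true misalignment |t| = %.3g mm\n",
              sqrt(sum(x$true_transform$translation^2))))
  invisible(x)
}

#' Region masks of a simulated study
#'
#' Named list of linear voxel-index vectors on the CBCT grid, one per
#' material present in the rendered scene.
#'
#' @param study a `simulated_study`.
#' @param materials optional subset of material names.
#' @export
region_masks <- function(study, materials = NULL) {
  ids <- study$region_ids
  present <- sort(unique(as.vector(ids)))
  labs <- study$region_labels[present]
  if (!is.null(materials)) {
    missing <- setdiff(materials, labs)
    if (length(missing))
      stop("materials absent from the rendered scene: ",
           paste(missing, collapse = ", "))
    keep <- labs %in% materials
    present <- present[keep]; labs <- labs[keep]
  }
  masks <- lapply(present, function(i) which(ids == i))
  names(masks) <- labs
  masks
}

#' Analytic region masks of a scene on a grid
#'
#' Named list of linear voxel-index vectors (one per material) obtained by
#' evaluating the scene's analytic geometry at the grid's voxel centers —
#' the noiseless ground-truth segmentation.
#'
#' @param scene a `phantom_scene`.
#' @param geometry `grid_geometry` or `voxel_volume`.
#' @param materials optional subset of material names.
#' @export
scene_region_masks <- function(scene, geometry, materials = NULL) {
  g <- as_grid_geometry(geometry)
  lab <- scene_material_at(scene, index_to_world(g, all_voxel_centers(g)))
  present <- unique(lab)
  if (!is.null(materials)) {
    missing <- setdiff(materials, present)
    if (length(missing))
      stop("materials absent from the rendered scene: ",
           paste(missing, collapse = ", "))
    present <- intersect(materials, present)
  }
  masks <- lapply(present, function(m) which(lab == m))
  names(masks) <- present
  masks
}

`%||%` <- function(a, b) if (is.null(a)) b else a
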