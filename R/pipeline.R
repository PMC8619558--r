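# End-to-end simulated study: calibration phantom -> HU calibration;
# jaw scene -> paired DE-CBCT/MDCT volumes; registration; ROI transfer;
# agreement report. Used by the CLI `pipeline` command and by the
# reproduction script.

#' Run the full pipeline on a simulated paired study
#'
#' 1. Renders the calibration phantom at both kVp channels and fits the
#'    dual-energy HU calibration from its region means (air + HA inserts as
#'    known-HU anchors).
#' 2. Simulates the jaw study: low/high-kVp CBCT volumes plus a rigidly
#'    misaligned MDCT volume.
#' 3. Applies the calibration voxel-by-voxel to obtain the DE-CBCT HU
#'    volume.
#' 4. Registers the MDCT volume into DE-CBCT space, inverts the transform,
#'    and evaluates every anchor ROI in both native grids.
#' 5. Produces the agreement report (deviation bands, normality gate,
#'    Bland-Altman).
#'
#' @param seed integer; all rendering noise derives from it.
#' @param misalignment true MDCT-world to CBCT-world `rigid_transform`.
#' @param noise list with `cbct_sd`, `mdct_sd` (CT numbers).
#' @param jaw_scene,phantom_scene scenes (defaults [build_jaw_scene()],
#'   [build_calibration_phantom()]).
#' @param cbct_geom,mdct_geom grid geometries.
#' @param registration `"estimate"` (default: run [estimate_rigid()]) or
#'   `"true"` (use the known misalignment, isolating the analysis stages
#'   from registration error).
#' @param reg_params passed to [estimate_rigid()].
#' @param roi_height,roi_diameter anchor ROI geometry (mm).
#' @return list: `study`, `calibration`, `vol_hu`, `registration`, `pairs`,
#'   `report`.
#' @export
run_simulated_pipeline <- function(seed = 1,
                                   misalignment = rigid_transform(
                                     euler_zyx_rotation(c(0, 0, 5)),
                                     c(3, -2, 1)),
                                   noise = list(cbct_sd = 30, mdct_sd = 15),
                                   jaw_scene = build_jaw_scene(),
                                   phantom_scene = build_calibration_phantom(),
                                   cbct_geom = cbct_geometry(),
                                   mdct_geom = mdct_geometry(),
                                   registration = c("estimate", "true"),
                                   reg_params = list(),
                                   roi_height = 4.5, roi_diameter = 1.2) {
  registration <- match.arg(registration)
  cb_sd <- noise$cbct_sd %||% 0
  ph_low <- render_ct(phantom_scene, cbct_geom, "low", noise_sd = cb_sd,
                      seed = if (cb_sd > 0) seed + 11L else NULL)
  ph_high <- render_ct(phantom_scene, cbct_geom, "high", noise_sd = cb_sd,
                       seed = if (cb_sd > 0) seed + 12L else NULL)
  labels <- intersect(
    c("acrylic", "air", grep("^HA", phantom_scene$materials$name, value = TRUE)),
    unique(vapply(phantom_scene$primitives, `[[`, "", "material")))
  masks <- scene_region_masks(phantom_scene, cbct_geom, labels)
  known <- stats::setNames(phantom_scene$materials$known_hu,
                           phantom_scene$materials$name)
  known <- known[c("air", grep("^HA", names(known), value = TRUE))]
  samples <- extract_region_samples(ph_low, ph_high, masks, known)
  calibration <- de_calibration(samples)

  study <- simulate_paired_study(jaw_scene, misalignment = misalignment,
                                 noise = noise, seed = seed,
                                 cbct_geom = cbct_geom, mdct_geom = mdct_geom)
  vol_hu <- apply_calibration(study$vol_low, study$vol_high, calibration)
  reg <- if (registration == "estimate")
    estimate_rigid(vol_hu, study$vol_mdct, params = reg_params)
  else
    structure(list(transform = misalignment, final_metric = NA_real_,
                   iterations = 0L, converged = TRUE,
                   level_metrics = numeric(0),
                   params = list(metric = "true")),
              class = "rigid_registration")
  inverse <- invert_transform(reg)
  rois <- anchor_rois(jaw_scene, height = roi_height, diameter = roi_diameter)
  pairs <- paired_roi_means(vol_hu, study$vol_mdct, rois, inverse)
  report <- agreement_report(pairs)
  list(study = study, calibration = calibration, vol_hu = vol_hu,
       registration = reg, pairs = pairs, report = report)
}
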