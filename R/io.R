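# Report/model serialization: JSON transform files (4x4 homogeneous,
# row-major, mm, LPS), calibration model JSON, ROI tables and paired-means
# CSV, agreement reports as JSON/CSV, optional NIfTI export.

#' Serialize a rigid transform as a 4x4 homogeneous JSON matrix
#'
#' Row-major, millimetres, LPS world frame; the pipeline convention is
#' MDCT-world to DE-CBCT-world.
#'
#' @param transform `rigid_transform` (or `rigid_registration`).
#' @param path output file.
#' @export
write_transform_json <- function(transform, path) {
  if (inherits(transform, "rigid_registration")) transform <- transform$transform
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(type = "rigid", frame = "LPS", units = "mm",
         matrix_row_major = as.vector(t(H))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from its JSON serialization
#' @param path file written by [write_transform_json()].
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(j$matrix_row_major, 4, 4, byrow = TRUE)
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}

#' Serialize a fitted calibration model to JSON
#' @param fit a `de_calibration`.
#' @param path output file.
#' @export
write_calibration_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = "dual_energy_hu_calibration",
         line = list(p0 = fit$line$p0, u = fit$line$u,
                     method = fit$line$method),
         hu_map = list(slope = fit$hu_map$slope,
                       intercept = fit$hu_map$intercept),
         regions = fit$samples[, c("label", "n_voxels", "mean_low",
                                   "mean_high", "known_hu")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path file written by [write_calibration_json()].
#' @return a `de_calibration` object.
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  line <- structure(list(p0 = as.numeric(j$line$p0), u = as.numeric(j$line$u),
                         rss = NA_real_, method = j$line$method),
                    class = "density_line")
  hu_map <- structure(list(slope = j$hu_map$slope,
                           intercept = j$hu_map$intercept,
                           fitted = numeric(0), residuals = numeric(0),
                           labels = character(0)),
                      class = "hu_map")
  samples <- as.data.frame(j$regions)
  class(samples) <- c("region_samples", "data.frame")
  structure(list(line = line, hu_map = hu_map, samples = samples),
            class = "de_calibration")
}

#' Read cylindrical ROI definitions from CSV
#'
#' Expected columns: `label`, `x`, `y`, `z` (mm), `height`, `diameter` (mm),
#' `alpha`, `beta`, `gamma` (degrees; optional, default 0).
#'
#' @param path CSV file.
#' @param validate passed to [cylinder_roi()].
#' @return list of `cylinder_roi`.
#' @export
read_roi_table <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "height", "diameter")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  for (a in c("alpha", "beta", "gamma")) if (is.null(df[[a]])) df[[a]] <- 0
  lapply(seq_len(nrow(df)), function(i)
    cylinder_roi(center = c(df$x[i], df$y[i], df$z[i]), height = df$height[i],
                 diameter = df$diameter[i],
                 angles = c(df$alpha[i], df$beta[i], df$gamma[i]),
                 label = df$label[i], validate = validate))
}

#' Write ROI definitions to CSV
#' @param rois list of `cylinder_roi`.
#' @param path output CSV.
#' @export
write_roi_table <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, x = r$center[1], y = r$center[2],
               z = r$center[3], height = r$height, diameter = r$diameter,
               alpha = r$angles[1], beta = r$angles[2], gamma = r$angles[3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read measurement pairs from CSV
#'
#' Columns: `label`, `group`, `mean_mdct`, `mean_decbct`.
#' @param path CSV file.
#' @return `measurement_pairs` data.frame.
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "group", "mean_mdct", "mean_decbct")
  if (!all(need %in% names(df)))
    stop("pairs CSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("measurement_pairs", "data.frame")
  df
}

#' Write measurement pairs to CSV
#' @param pairs `measurement_pairs` data.frame.
#' @param path output CSV.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

agreement_report_list <- function(report) {
  groups <- lapply(report$groups, function(g) {
    ba <- g$ba
    list(shapiro_wilk = list(W = g$shapiro$W, p_value = g$shapiro$p_value,
                             n = g$shapiro$n, passes = g$shapiro$passes),
         bland_altman = list(
           n = ba$n, bias = ba$bias, sd = ba$sd, gap = ba$gap,
           loa_low = ba$loa_low, loa_high = ba$loa_high,
           ci_bias_halfwidth = ba$ci_bias_halfwidth,
           ci_loa_fullwidth = ba$ci_loa_fullwidth,
           n_outside_loa = ba$n_outside_loa,
           n_outside_outer_ci = ba$n_outside_outer_ci),
         display = list(
           bias = round(ba$bias, 2), gap = round(ba$gap, 2),
           ci_loa_fullwidth = round(ba$ci_loa_fullwidth, 2)))
  })
  bands <- as.data.frame(report$bands)
  bands_display <- bands
  for (cn in grep("^pct_", names(bands_display), value = TRUE))
    bands_display[[cn]] <- round(bands_display[[cn]], 1)
  list(deviation_mode = report$deviation_mode,
       sw_alpha = report$sw_alpha,
       bands = bands, bands_display = bands_display,
       groups = groups,
       excluded = as.data.frame(report$excluded))
}

#' Write an agreement report as JSON
#'
#' Full-precision values plus a `display` section using the conventional
#' rounding (one decimal for band percentages, two decimals for
#' Bland-Altman quantities).
#'
#' @param report an `agreement_report`.
#' @param path output JSON file.
#' @export
write_agreement_json <- function(report, path) {
  jsonlite::write_json(agreement_report_list(report), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write the band report of an agreement report as CSV
#' @param report an `agreement_report`.
#' @param path output CSV file.
#' @export
write_agreement_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report$bands), path, row.names = FALSE)
  invisible(path)
}

#' Export a volume as NIfTI (debugging convenience)
#'
#' Requires the suggested RNifti package.
#' @param volume a `voxel_volume`.
#' @param path output `.nii` / `.nii.gz` file.
#' @export
write_nifti_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(volume$values)
  # LPS -> RAS flip of the first two axes for the NIfTI affine
  S <- diag(c(-1, -1, 1))
  A <- rbind(cbind(S %*% volume$direction %*% diag(volume$spacing),
                   S %*% volume$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(A, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
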