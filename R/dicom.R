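# Minimal single-frame CT DICOM series I/O (explicit VR little endian).
#
# Scope: the dialect this package writes — one file per axial slice,
# MONOCHROME2, 16-bit signed pixels with rescale slope/intercept — plus
# ordinary single-frame CT slices using the same transfer syntax. Not a
# general DICOM toolkit: sequences are skipped, implicit VR and compressed
# transfer syntaxes are rejected.

DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10.474"
UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

dicom_uid <- function(...) {
  parts <- vapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 99991
    else as.numeric(x) %% 99991
  }, 0)
  paste(c(DICOM_UID_ROOT, format(parts, scientific = FALSE, trim = TRUE)),
        collapse = ".")
}

uint16_bytes <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
uint32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
int16_raw <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                  endian = "little")

dicom_element <- function(group, elem, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2L == 1L)
      payload <- c(payload, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  head <- c(uint16_bytes(group), uint16_bytes(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0L, 0L)), uint32_bytes(length(payload)), payload)
  else
    c(head, uint16_bytes(length(payload)), payload)
}

ds_string <- function(x) paste(formatC(x, format = "g", digits = 10),
                               collapse = "\\")

#' Write a volume as a single-frame CT DICOM series
#'
#' One explicit-VR little-endian file per axial slice, with consistent
#' geometry tags (ImagePositionPatient, ImageOrientationPatient,
#' PixelSpacing, SliceThickness) and 16-bit signed stored pixels mapped
#' through the rescale slope/intercept. Round-trips through
#' [read_dicom_series()] up to rescale quantization.
#'
#' @param volume a `voxel_volume`.
#' @param directory output directory (created if needed).
#' @param series_description free-text series label (also seeds the
#'   deterministic UIDs).
#' @param rescale_slope,rescale_intercept stored-value mapping
#'   (`value = stored * slope + intercept`); defaults 1 and -1024.
#' @return invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(volume, directory,
                               series_description = "decbct",
                               rescale_slope = 1, rescale_intercept = -1024) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- volume$dims
  stored_all <- round((as.vector(volume$values) - rescale_intercept) /
                      rescale_slope)
  if (min(stored_all) < -32768 || max(stored_all) > 32767)
    stop("values outside the representable int16 range after rescale; ",
         "adjust rescale_slope/rescale_intercept")
  dim(stored_all) <- d
  study_uid <- dicom_uid(series_description, 1)
  series_uid <- dicom_uid(series_description, 2, d[1], d[3])
  iop <- c(volume$direction[, 1], volume$direction[, 2])
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- dicom_uid(series_description, 3, k)
    ipp <- index_to_world(volume, c(0, 0, k - 1))
    meta <- c(
      dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      dicom_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      dicom_element(0x0002, 0x0003, "UI", sop_uid),
      dicom_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
      dicom_element(0x0002, 0x0012, "UI", paste0(DICOM_UID_ROOT, ".1"))
    )
    pix <- int16_raw(stored_all[, , k])
    body <- c(
      dicom_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      dicom_element(0x0008, 0x0018, "UI", sop_uid),
      dicom_element(0x0008, 0x0060, "CS", "CT"),
      dicom_element(0x0008, 0x103E, "LO", series_description),
      dicom_element(0x0018, 0x0050, "DS", ds_string(volume$spacing[3])),
      dicom_element(0x0020, 0x000D, "UI", study_uid),
      dicom_element(0x0020, 0x000E, "UI", series_uid),
      dicom_element(0x0020, 0x0013, "IS", as.character(k)),
      dicom_element(0x0020, 0x0032, "DS", ds_string(ipp)),
      dicom_element(0x0020, 0x0037, "DS", ds_string(iop)),
      dicom_element(0x0028, 0x0002, "US", uint16_bytes(1)),
      dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dicom_element(0x0028, 0x0010, "US", uint16_bytes(d[2])),  # Rows
      dicom_element(0x0028, 0x0011, "US", uint16_bytes(d[1])),  # Columns
      dicom_element(0x0028, 0x0030, "DS",
                    ds_string(volume$spacing[c(2, 1)])),
      dicom_element(0x0028, 0x0100, "US", uint16_bytes(16)),
      dicom_element(0x0028, 0x0101, "US", uint16_bytes(16)),
      dicom_element(0x0028, 0x0102, "US", uint16_bytes(15)),
      dicom_element(0x0028, 0x0103, "US", uint16_bytes(1)),
      dicom_element(0x0028, 0x1052, "DS", ds_string(rescale_intercept)),
      dicom_element(0x0028, 0x1053, "DS", ds_string(rescale_slope)),
      dicom_element(0x7FE0, 0x0010, "OW", pix)
    )
    group_len <- dicom_element(0x0002, 0x0000, "UL",
                               uint32_bytes(length(meta)))
    files[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(files[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), group_len, meta, body), con)
    close(con)
  }
  invisible(files)
}

read_uint16 <- function(buf, off) {
  as.integer(buf[off]) + 256L * as.integer(buf[off + 1L])
}
read_uint32 <- function(buf, off) {
  as.numeric(buf[off]) + 256 * as.numeric(buf[off + 1L]) +
    65536 * as.numeric(buf[off + 2L]) + 16777216 * as.numeric(buf[off + 3L])
}

parse_dicom_file <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  off <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  while (off + 7L <= length(buf)) {
    group <- read_uint16(buf, off); elem <- read_uint16(buf, off + 2L)
    vr <- rawToChar(buf[(off + 4L):(off + 5L)])
    if (vr %in% long_vrs) {
      len <- read_uint32(buf, off + 8L); data_off <- off + 12L
    } else {
      len <- read_uint16(buf, off + 6L); data_off <- off + 8L
    }
    if (len == 4294967295) stop("undefined-length element unsupported: ", path)
    key <- sprintf("%04X%04X", group, elem)
    if (vr != "SQ")
      elements[[key]] <- list(vr = vr,
                              data = buf[seq(data_off, length.out = len)])
    off <- data_off + len
  }
  elements
}

el_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$data[el$data != as.raw(0L)]))
}
el_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(el_string(el), "\\\\", fixed = FALSE)[[1]])
}

#' Read a single-frame CT DICOM series
#'
#' Reads every `.dcm` file in the directory, checks they form one series
#' with a uniform, strictly ordered slice stack (slices are sorted by
#' projected position along the orientation normal, not by filename), maps
#' stored values through the rescale slope/intercept, and assembles the
#' LPS-world geometry into a [voxel_volume()].
#'
#' @param directory directory holding one series.
#' @param value_kind value semantics of the result (`"hu"` default).
#' @return a `voxel_volume`; series-level tags in `attr(, "metadata")`.
#' @export
read_dicom_series <- function(directory, value_kind = "hu") {
  paths <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(paths) == 0L) stop("no .dcm files in ", directory)
  slices <- lapply(paths, parse_dicom_file)
  ts <- unique(vapply(slices, function(s) el_string(s[["00020010"]]) %||% "",
                      ""))
  if (!all(ts %in% c("", UID_EXPLICIT_VR_LE)))
    stop("unsupported transfer syntax: ", paste(setdiff(ts, UID_EXPLICIT_VR_LE),
                                                collapse = ", "))
  series <- vapply(slices, function(s) el_string(s[["0020000E"]]) %||% "", "")
  if (length(unique(series)) != 1L)
    stop("directory mixes multiple DICOM series")
  iop <- el_numeric(slices[[1]][["00200037"]])
  if (is.null(iop) || length(iop) != 6L)
    stop("missing ImageOrientationPatient")
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  ipp <- t(vapply(slices, function(s) el_numeric(s[["00200032"]]), numeric(3)))
  pos <- drop(ipp %*% normal)
  ord <- order(pos)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]; pos <- pos[ord]
  if (length(pos) > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0))
      stop("slices are not strictly ordered along the normal")
    if (max(gaps) - min(gaps) > 1e-3)
      stop(sprintf("non-uniform slice spacing: gaps range %.6g to %.6g mm",
                   min(gaps), max(gaps)))
    dz <- mean(gaps)
  } else dz <- el_numeric(slices[[1]][["00180050"]]) %||% 1
  s1 <- slices[[1]]
  rows <- read_uint16(s1[["00280010"]]$data, 1L)
  cols <- read_uint16(s1[["00280011"]]$data, 1L)
  psp <- el_numeric(s1[["00280030"]])       # (row spacing, column spacing)
  slope <- el_numeric(s1[["00281053"]]) %||% 1
  inter <- el_numeric(s1[["00281052"]]) %||% 0
  signed <- (read_uint16(s1[["00280103"]]$data, 1L)) == 1L
  nz <- length(slices)
  vals <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    raw_pix <- slices[[k]][["7FE00010"]]$data
    stored <- readBin(raw_pix, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    vals[, , k] <- stored * slope + inter
  }
  direction <- cbind(rdir, cdir, normal)
  # re-orthonormalize against DS-string rounding
  direction <- svd(direction)$u %*% t(svd(direction)$v)
  vol <- voxel_volume(vals, spacing = c(psp[2], psp[1], dz),
                      origin = ipp[1, ], direction = direction,
                      value_kind = value_kind)
  attr(vol, "metadata") <- list(
    modality = el_string(s1[["00080060"]]),
    series_uid = unique(series),
    series_description = el_string(s1[["0008103E"]]),
    rescale_slope = slope, rescale_intercept = inter,
    n_slices = nz)
  vol
}
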