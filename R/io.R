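# File interchange: NIfTI-1 volumes (RNifti), JSON calibration models and
# ground-truth sidecars (jsonlite), CSV tables.

#' Write a generated scan to disk
#'
#' Writes the HU volume and the ground-truth label volume as NIfTI-1
#' (`<prefix>.nii.gz`, `<prefix>_labels.nii.gz`) with the voxel spacing in
#' the header, plus a JSON sidecar (`<prefix>_truth.json`) holding the
#' scalar ground truth (true densities, true SAT/VAT volumes over the L4/5
#' window, applied offset and noise, the internal density-to-HU line, the
#' seed) and the spine geometry for provenance.
#'
#' @param x A `qct_scan` from [generate_scan()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_scan <- function(x, prefix) {
  stopifnot(inherits(x, "qct_scan"))
  scan <- x$scan; truth <- x$truth
  img <- RNifti::asNifti(scan$hu, pixdim = scan$spacing)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  limg <- RNifti::asNifti(truth$labels, pixdim = scan$spacing)
  RNifti::writeNifti(limg, paste0(prefix, "_labels.nii.gz"))
  side <- list(
    spacing = scan$spacing, origin = scan$origin, axes = scan$axes,
    true_densities = as.list(truth$true_densities),
    sat_cm3 = truth$sat_cm3, vat_cm3 = truth$vat_cm3,
    l45_window = truth$l45_window, hu_offset = truth$hu_offset,
    noise_sd = truth$noise_sd, hu_slope = truth$hu_slope,
    hu_intercept = truth$hu_intercept, seed = truth$seed,
    geometry = list(levels = scan$geometry$levels, gap = scan$geometry$gap,
                    center_x = scan$geometry$center_x,
                    center_y = scan$geometry$center_y),
    z_extents = scan$z_extents
  )
  jsonlite::write_json(side, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(prefix)
}

#' Read a scan written by [write_scan()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `qct_scan` (HU volume, labels and scalar ground truth
#'   reconstructed; spacing from the NIfTI header).
#' @export
read_scan <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                              simplifyVector = TRUE)
  hu <- array(as.numeric(img), dim = dim(img))
  spacing <- as.numeric(side$spacing)
  g <- list(levels = as.data.frame(side$geometry$levels),
            gap = side$geometry$gap, center_x = side$geometry$center_x,
            center_y = side$geometry$center_y)
  class(g) <- "spine_geometry"
  scan <- structure(list(hu = hu, spacing = spacing,
                         origin = as.numeric(side$origin), axes = side$axes,
                         geometry = g,
                         z_extents = as.data.frame(side$z_extents)),
                    class = "scan_volume")
  labels <- NULL
  lp <- paste0(prefix, "_labels.nii.gz")
  if (file.exists(lp)) {
    limg <- RNifti::readNifti(lp)
    labels <- array(as.integer(limg), dim = dim(limg))
  }
  truth <- structure(list(
    labels = labels,
    true_densities = unlist(side$true_densities),
    sat_cm3 = side$sat_cm3, vat_cm3 = side$vat_cm3,
    l45_window = as.integer(side$l45_window), hu_offset = side$hu_offset,
    noise_sd = side$noise_sd, hu_slope = side$hu_slope,
    hu_intercept = side$hu_intercept, seed = side$seed
  ), class = "scan_truth")
  structure(list(scan = scan, truth = truth), class = "qct_scan")
}

#' Write / read a calibration model as JSON
#'
#' Slope and intercept round-trip at full double precision.
#'
#' @param model A `qct_calibration`.
#' @param path File path.
#' @return `read_calibration` returns a `qct_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "qct_calibration"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         pairs = model$pairs, scan_id = model$scan_id),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$slope) || is.null(j$intercept))
    stop("format error: calibration JSON lacks field 'slope' or 'intercept'")
  structure(list(slope = j$slope, intercept = j$intercept,
                 pairs = as.data.frame(j$pairs),
                 scan_id = if (is.null(j$scan_id)) NA_character_ else j$scan_id),
            class = "qct_calibration")
}
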