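#' Vertebral levels covered by the pipeline
#'
#' The thirteen levels measured opportunistically in routine thoraco-abdominal
#' CT, in anatomical (cranial to caudal) order.
#'
#' @return Character vector `c("Th5", ..., "Th12", "L1", ..., "L5")`.
#' @export
vertebral_levels <- function() {
  c(paste0("Th", 5:12), paste0("L", 1:5))
}

#' Ground-truth label codes used by the synthetic-scan generator
#'
#' Every voxel of a generated scan carries exactly one of these labels.
#'
#' @return Named integer vector of label codes.
#' @export
scan_labels <- function() {
  c(background = 0L, trabecular = 1L, cortical = 2L, endplate = 3L,
    plexus = 4L, sat = 5L, vat = 6L, muscle = 7L, organ = 8L,
    phantom1 = 9L, phantom2 = 10L, cutis = 11L)
}

#' Spine geometry specification
#'
#' Describes the Th5-L5 column as a stack of elliptic-cylinder vertebral
#' bodies with flat endplates, a lateral cortical shell, and a posterior
#' midline basivertebral venous channel. All lengths in mm. The coordinate
#' convention is x = sagittal (left-right), y = coronal (posterior to
#' anterior, +y anterior), z = axial (caudal to cranial, +z cranial).
#'
#' Defaults grow gently from Th5 to L5 and keep the 2/3-height trabecular
#' ROI circle (see [place_roi()]) inside the anterior trabecular half with
#' a safety margin.
#'
#' @param heights Per-level vertebral body height (mm), length 13.
#' @param radius_ap Per-level coronal (antero-posterior) semi-axis (mm);
#'   default derived from `heights` so the ROI rule fits.
#' @param radius_lr Per-level sagittal (left-right) semi-axis (mm).
#' @param shell Cortical shell thickness (mm).
#' @param endplate Endplate thickness (mm).
#' @param plexus_radius Radius of the basivertebral channel (mm).
#' @param plexus_frac Fraction of the AP diameter the channel penetrates
#'   from the posterior wall (must stay in the posterior half for ROI
#'   placement to succeed).
#' @param gap Intervertebral gap (mm).
#' @param center_x,center_y Column axis position (mm).
#' @return Object of class `spine_geometry`: a list with a per-level
#'   data frame `$levels` and scalar placement fields.
#' @export
spine_geometry <- function(heights = c(22, 22.5, 23, 23.5, 24, 24.5, 25, 25.5,
                                       26, 26.5, 27, 27, 26),
                           radius_ap = NULL,
                           radius_lr = NULL,
                           shell = 2.5,
                           endplate = 1.5,
                           plexus_radius = 2,
                           plexus_frac = 0.3,
                           gap = 4,
                           center_x = 0,
                           center_y = -38) {
  lv <- vertebral_levels()
  if (length(heights) != 13L) stop("exactly 13 vertebral heights required (Th5-L5)")
  if (is.null(radius_ap)) radius_ap <- round(shell + 2 * heights / 3 + 2.5, 1)
  if (is.null(radius_lr)) radius_lr <- radius_ap - 3
  g <- list(
    levels = data.frame(level = lv, height = heights,
                        radius_ap = radius_ap, radius_lr = radius_lr,
                        shell = shell, endplate = endplate,
                        plexus_radius = plexus_radius,
                        plexus_length = plexus_frac * 2 * radius_ap,
                        stringsAsFactors = FALSE),
    gap = gap, center_x = center_x, center_y = center_y
  )
  class(g) <- "spine_geometry"
  validate_spine_geometry(g)
  g
}

validate_spine_geometry <- function(g) {
  d <- g$levels
  stopifnot(nrow(d) == 13L)
  if (!identical(d$level, vertebral_levels()))
    stop("levels must be Th5..L5 in anatomical order")
  if (any(d$height <= 0)) stop("vertebral heights must be positive")
  if (any(d$shell >= d$radius_ap) || any(d$shell >= d$radius_lr))
    stop("cortical shell thickness must be smaller than the body radius")
  if (any(d$endplate >= d$height / 2))
    stop("endplate thickness must be smaller than half the body height")
  if (g$gap < 0) stop("intervertebral gap must be non-negative")
  invisible(g)
}

# z extent of each vertebral body (bottom, top), stacked caudal -> cranial
# with L5 at the bottom; returns a data frame aligned with g$levels.
spine_z_extents <- function(g, z0 = 6) {
  d <- g$levels
  n <- nrow(d)
  bottom <- numeric(n)
  z <- z0
  for (i in rev(seq_len(n))) {  # L5 first (bottom of the stack)
    bottom[i] <- z
    z <- z + d$height[i] + g$gap
  }
  data.frame(level = d$level, z_bottom = bottom, z_top = bottom + d$height)
}

#' Abdominal body-composition specification
#'
#' Concentric elliptic compartments of the abdominal cross-section: cutis
#' (skin) as the outer border, a subcutaneous fat ring (SAT), the abdominal /
#' paravertebral muscle wall, and the visceral space inside it (VAT, with
#' contrast-filled bowel loops as high-attenuation organ disks). The spine
#' is embedded in the visceral space posteriorly. HU values are the rendered
#' (pre-noise, pre-contrast-offset) tissue attenuations.
#'
#' @param semi_lr,semi_ap Outer body ellipse semi-axes (mm).
#' @param cutis Cutis thickness (mm).
#' @param sat_thickness Subcutaneous fat ring thickness (mm).
#' @param muscle_thickness Muscle wall thickness (mm).
#' @param adipose_hu,muscle_hu,organ_hu,cutis_hu Tissue attenuations (HU).
#' @param organs Data frame of visceral organ disks (columns `x`, `y`, `r`
#'   in mm) emulating contrast-filled bowel; may have zero rows.
#' @return Object of class `body_spec`.
#' @export
body_spec <- function(semi_lr = 150, semi_ap = 105,
                      cutis = 2, sat_thickness = 25, muscle_thickness = 12,
                      adipose_hu = -100, muscle_hu = 50, organ_hu = 240,
                      cutis_hu = 20,
                      organs = data.frame(x = c(60, -55), y = c(15, 25),
                                          r = c(25, 20))) {
  if (adipose_hu >= muscle_hu)
    stop("adipose HU must be strictly below muscle HU")
  if (cutis <= 0 || sat_thickness <= 0 || muscle_thickness <= 0)
    stop("compartment thicknesses must be positive")
  b <- list(semi_lr = semi_lr, semi_ap = semi_ap, cutis = cutis,
            sat_thickness = sat_thickness, muscle_thickness = muscle_thickness,
            adipose_hu = adipose_hu, muscle_hu = muscle_hu,
            organ_hu = organ_hu, cutis_hu = cutis_hu, organs = organs)
  class(b) <- "body_spec"
  b
}

#' Density reference phantom specification
#'
#' A two-phase density reference phantom lying in the scanner table mat
#' under the patient's back: two cylinders running the full scan length
#' (along z), each of known hydroxyapatite-equivalent density. Scanned
#' synchronously with the patient, it anchors the per-scan linear HU-to-BMD
#' conversion.
#'
#' @param densities Known phase densities (mg/cm^3), strictly increasing,
#'   length 2 (more phases are permitted; the calibration fit generalizes).
#' @param radius Phase cylinder radius (mm).
#' @param x_offsets Lateral positions of the phase cylinders (mm).
#' @param y_center Vertical position (mm); must clear the body outline.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(densities = c(0, 200), radius = 9,
                         x_offsets = NULL, y_center = -118) {
  if (length(densities) < 2L) stop("at least two phantom phases required")
  if (any(diff(sort(densities)) == 0)) stop("phantom phase densities must differ")
  if (is.null(x_offsets)) x_offsets <- seq(-30, 30, length.out = length(densities))
  if (length(x_offsets) != length(densities))
    stop("one lateral offset per phantom phase required")
  p <- list(densities = sort(densities), radius = radius,
            x_offsets = x_offsets, y_center = y_center)
  class(p) <- "phantom_spec"
  p
}
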