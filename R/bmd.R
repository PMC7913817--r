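# Vertebral trabecular ROI densitometry.
#
# The ROI rule: in the most central sagittal slice through the vertebral
# body, a circular ROI of diameter two-thirds of the vertebral height is
# placed in the anterior half of the trabecular compartment, equidistant to
# both endplates, excluding the cortical shell, the endplates and the
# basivertebral venous channel. HU is averaged over a 3 mm sagittal
# reformation (the contiguous native slices covering 3 mm, centered on the
# mid-sagittal slice) and converted to BMD with the per-scan calibration.

#' Locate the mid-sagittal slice of a vertebral body
#'
#' The sagittal slice whose center is closest to the vertebral body center;
#' ties are broken toward the lower index.
#'
#' @param volume A `scan_volume`.
#' @param level Vertebral level label, e.g. `"Th7"`.
#' @return Sagittal slice index (1-based).
#' @export
locate_midsagittal_slice <- function(volume, level) {
  if (!level %in% volume$geometry$levels$level)
    stop("lookup error: level ", level, " absent from scan geometry")
  sagittal_index(volume, volume$geometry$center_x)
}

# number of native sagittal slices covering `thickness` mm: the largest odd
# integer <= round(thickness / dx), at least 1
reformation_slices <- function(dx, thickness = 3) {
  n <- max(1L, as.integer(floor(thickness / dx + 0.5)))
  if (n %% 2L == 0L) n <- n - 1L
  max(1L, n)
}

#' Place the standardized trabecular ROI for one vertebral level
#'
#' Centers a circle of diameter two-thirds of the vertebral height at the
#' centroid of the anterior trabecular half, at mid-height (equidistant to
#' both endplates). Placement is validated against the continuous geometry
#' across the full sagittal reformation slab: the circle must stay inside
#' the trabecular compartment and clear the venous channel. If the
#' standardized diameter does not fit, the ROI is shrunk to the largest
#' fitting diameter and flagged (`shrunk = TRUE`); if no usable ROI exists
#' (e.g. the channel occupies the anterior body) a placement error is
#' raised.
#'
#' @param volume A `scan_volume`.
#' @param level Vertebral level label.
#' @param slice Mid-sagittal slice index; default from
#'   [locate_midsagittal_slice()].
#' @param reformation_mm Sagittal reformation thickness (mm, default 3).
#' @return Object of class `vertebra_roi`: level, slice index, slice
#'   indices of the reformation slab, circle center (y, z in mm), diameter
#'   (mm), and a `shrunk` flag.
#' @export
place_roi <- function(volume, level, slice = NULL, reformation_mm = 3) {
  g <- volume$geometry
  i <- match(level, g$levels$level)
  if (is.na(i)) stop("lookup error: level ", level, " absent from scan geometry")
  if (is.null(slice)) slice <- locate_midsagittal_slice(volume, level)
  d <- g$levels[i, ]
  ze <- volume$z_extents[i, ]
  ys <- g$center_y
  h <- d$height
  diameter <- 2 * h / 3
  r_req <- diameter / 2

  n_sl <- reformation_slices(volume$spacing[1], reformation_mm)
  slab <- slice + seq(-(n_sl - 1L) %/% 2L, (n_sl - 1L) %/% 2L)
  xcen <- sagittal_centers(volume)
  if (any(slab < 1L) || any(slab > length(xcen)))
    stop("placement error: reformation slab exceeds the volume extent")
  u_max <- max(abs(xcen[slab] - g$center_x)) + volume$spacing[1] / 2

  # trabecular half-extent in y at the slab edge (elliptic cylinder section)
  bt <- d$radius_ap - d$shell
  at <- d$radius_lr - d$shell
  if (u_max >= at)
    stop("placement error: reformation slab wider than the trabecular body")
  b_u <- bt * sqrt(1 - (u_max / at)^2)

  cy <- ys + bt / 2                       # anterior-half centroid
  cz <- (ze$z_bottom + ze$z_top) / 2      # equidistant to both endplates
  # fit limits for the radius at this fixed center:
  r_z <- h / 2 - d$endplate               # endplate clearance
  r_ant <- b_u - bt / 2                   # anterior cortical clearance
  y_plexus_end <- ys - d$radius_ap + d$plexus_length
  r_post <- cy - max(ys - b_u, y_plexus_end)   # posterior cortex / channel
  r_fit <- min(r_z, r_ant, r_post)
  min_r <- max(volume$spacing[2:3])       # need at least ~one voxel of radius
  if (r_fit < min_r)
    stop("placement error: no usable trabecular ROI at ", level,
         " (venous channel or cortex encroaches on the anterior body)")
  shrunk <- FALSE
  r_use <- r_req
  if (r_req > r_fit) {
    r_use <- r_fit
    shrunk <- TRUE
    warning("ROI at ", level, " shrunk from ", signif(2 * r_req, 4), " to ",
            signif(2 * r_use, 4), " mm diameter to fit the trabecular compartment")
  }
  structure(list(level = level, slice = slice, slab = slab,
                 center_y = cy, center_z = cz, diameter = 2 * r_use,
                 standard_diameter = diameter, shrunk = shrunk,
                 excluded = c("cortical shell", "endplates", "venous channel")),
            class = "vertebra_roi")
}

# logical 2-D (y, z) mask of voxel centers inside the ROI circle
roi_mask_yz <- function(volume, roi) {
  ycen <- coronal_centers(volume); zcen <- axial_centers(volume)
  r <- roi$diameter / 2
  outer((ycen - roi$center_y)^2, (zcen - roi$center_z)^2, "+") <= r^2
}

#' Measure trabecular BMD in one vertebral ROI
#'
#' Averages HU over the ROI circle on the sagittal reformation slab and
#' converts the mean with the per-scan calibration.
#'
#' @param volume A `scan_volume`.
#' @param roi A [place_roi()] result.
#' @param model A [fit_calibration()] model.
#' @return One-row data frame: `level`, `mean_hu`, `bmd`, `n_vox`,
#'   `diameter_mm`, `slice`, `shrunk`, `status`.
#' @export
measure_vertebral_bmd <- function(volume, roi, model) {
  stopifnot(inherits(roi, "vertebra_roi"))
  m <- roi_mask_yz(volume, roi)
  if (!any(m)) stop("measurement error: empty ROI at ", roi$level)
  block <- volume$hu[roi$slab, , , drop = FALSE]
  sel <- rep(as.vector(m), each = length(roi$slab))
  vals <- block[array(sel, dim = dim(block))]
  mean_hu <- mean(vals)
  data.frame(level = roi$level, mean_hu = mean_hu,
             bmd = hu_to_bmd(model, mean_hu),
             n_vox = length(vals), diameter_mm = roi$diameter,
             slice = roi$slice, shrunk = roi$shrunk,
             status = "measured", stringsAsFactors = FALSE)
}

#' Measure the whole spine and the QCT-standard L1-L3 mean
#'
#' Applies the ROI rule at every level Th5-L5, skipping vertebrae with a
#' prevalent fracture (their BMD is not measured), and reports the
#' arithmetic mean over the available L1, L2, L3 measurements as the QCT
#' standard. If some but not all of L1-L3 are skipped the mean is computed
#' over the remaining levels and flagged partial; if all three are skipped
#' it is flagged missing.
#'
#' @param volume A `scan_volume`.
#' @param model A [fit_calibration()] model.
#' @param prevalent_fractures Character vector of level labels with a
#'   prevalent fracture at baseline.
#' @return Object of class `bmd_table`: a 13-row data frame (one per level,
#'   anatomical order) with attributes `mean_l1_l3` and `l1_l3_status`
#'   (`"complete"`, `"partial"` or `"missing"`).
#' @export
measure_spine <- function(volume, model, prevalent_fractures = character()) {
  lv <- vertebral_levels()
  bad <- setdiff(prevalent_fractures, lv)
  if (length(bad)) stop("unknown vertebral level(s): ", paste(bad, collapse = ", "))
  rows <- vector("list", length(lv))
  for (i in seq_along(lv)) {
    if (lv[i] %in% prevalent_fractures) {
      rows[[i]] <- data.frame(level = lv[i], mean_hu = NA_real_, bmd = NA_real_,
                              n_vox = NA_integer_, diameter_mm = NA_real_,
                              slice = NA_integer_, shrunk = NA,
                              status = "skipped-prevalent-fracture",
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- tryCatch(
        measure_vertebral_bmd(volume, place_roi(volume, lv[i]), model),
        error = function(e) data.frame(level = lv[i], mean_hu = NA_real_,
                                       bmd = NA_real_, n_vox = NA_integer_,
                                       diameter_mm = NA_real_, slice = NA_integer_,
                                       shrunk = NA, status = "failed",
                                       stringsAsFactors = FALSE))
    }
  }
  tab <- do.call(rbind, rows)
  l13 <- tab$bmd[tab$level %in% c("L1", "L2", "L3") & tab$status == "measured"]
  attr(tab, "mean_l1_l3") <- if (length(l13)) mean(l13) else NA_real_
  attr(tab, "l1_l3_status") <- if (length(l13) == 3L) "complete"
                               else if (length(l13) > 0L) "partial" else "missing"
  class(tab) <- c("bmd_table", "data.frame")
  tab
}

#' @export
print.bmd_table <- function(x, digits = 1, ...) {
  cat("Vertebral trabecular BMD (mg/cm^3)\n")
  df <- as.data.frame(x)
  df$mean_hu <- round(df$mean_hu, digits)
  df$bmd <- round(df$bmd, digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Mean L1-L3: %s mg/cm^3 (%s)\n",
              format(round(attr(x, "mean_l1_l3"), digits)),
              attr(x, "l1_l3_status")))
  invisible(x)
}
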