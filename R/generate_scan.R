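# Voxel renderer for synthetic thoraco-abdominal CT.
#
# Geometry is continuous (mm); a voxel belongs to a structure iff its center
# lies inside the structure. Labels and HU are rendered from the same
# continuous geometry, so mask/intensity consistency is exact by construction.

# assign `value` to voxels of `arr` in slices `kidx` selected by 2-D mask,
# optionally restricted to voxels currently labeled in `only_over`
assign_slices <- function(arr, kidx, mask2d, value, only_over = NULL) {
  if (!length(kidx) || !any(mask2d)) return(arr)
  block <- arr[, , kidx, drop = FALSE]
  sel <- rep(as.vector(mask2d), times = length(kidx))
  if (!is.null(only_over)) sel <- sel & (as.vector(block) %in% only_over)
  block[sel] <- value
  arr[, , kidx] <- block
  arr
}

ellipse_mask <- function(xc, yc, cx, cy, a, b) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, length(xc), length(yc)))
  outer(((xc - cx) / a)^2, ((yc - cy) / b)^2, "+") <= 1
}

#' Generate a synthetic CT scan with voxel-level ground truth
#'
#' Renders a Th5-L5 spine (trabecular core, cortical shell, endplates,
#' posterior basivertebral venous channel), concentric abdominal soft-tissue
#' compartments (cutis / SAT / muscle wall / visceral space with
#' contrast-filled bowel), and a two-phase density reference phantom in the
#' table mat, onto a regular voxel grid. Trabecular and phantom voxels get
#' their HU from an internal linear density-to-HU map; a scan-wide additive
#' HU offset emulating intravenous contrast enhancement is applied to all
#' anatomy but not to the phantom (which sits outside the vascular
#' compartment); i.i.d. Gaussian HU noise is added everywhere.
#'
#' @param geometry A [spine_geometry()].
#' @param body A [body_spec()].
#' @param phantom A [phantom_spec()] with exactly two phases.
#' @param true_densities Per-level true trabecular density (mg/cm^3); either
#'   unnamed length-13 (Th5..L5 order) or named by level.
#' @param hu_offset Scan-level additive HU offset applied to anatomy (HU).
#' @param noise_sd Additive Gaussian HU noise SD (HU), `>= 0`.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in mm for the (sagittal,
#'   coronal, axial) axes.
#' @param hu_slope,hu_intercept Internal density-to-HU line:
#'   `HU = hu_intercept + hu_slope * density` (before contrast offset and
#'   noise). The calibration stage must recover this line from the phantom.
#' @return A list of class `qct_scan` with elements `scan` (class
#'   `scan_volume`: `hu` array, `spacing`, `origin`, `geometry`, per-level
#'   z extents) and `truth` (class `scan_truth`: `labels` array,
#'   `true_densities`, true SAT/VAT volumes over the L4/5 window, the offset,
#'   noise SD, internal line and seed actually used).
#' @export
generate_scan <- function(geometry = spine_geometry(),
                          body = body_spec(),
                          phantom = phantom_spec(),
                          true_densities = NULL,
                          hu_offset = 0,
                          noise_sd = 15,
                          seed = 1L,
                          spacing = c(2, 2, 3),
                          hu_slope = 1.05,
                          hu_intercept = 5) {
  validate_spine_geometry(geometry)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(phantom$densities) != 2L)
    stop("the renderer supports exactly two phantom phases")
  lv <- vertebral_levels()
  if (is.null(true_densities))
    true_densities <- stats::setNames(seq(170, 120, length.out = 13), lv)
  if (is.null(names(true_densities))) {
    if (length(true_densities) != 13L) stop("true_densities must cover 13 levels")
    names(true_densities) <- lv
  }
  if (!all(lv %in% names(true_densities)))
    stop("true_densities must be named by vertebral level Th5..L5")
  true_densities <- true_densities[lv]

  lab <- scan_labels()
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  margin <- 6
  zext <- spine_z_extents(geometry)
  xr <- c(-body$semi_lr - margin, body$semi_lr + margin)
  yr <- c(phantom$y_center - phantom$radius - margin, body$semi_ap + margin)
  zr <- c(0, max(zext$z_top) + margin)
  xc <- seq(xr[1] + dx / 2, xr[2], by = dx)
  yc <- seq(yr[1] + dy / 2, yr[2], by = dy)
  zc <- seq(zr[1] + dz / 2, zr[2], by = dz)
  nx <- length(xc); ny <- length(yc); nz <- length(zc)

  ## ---- 2-D abdominal template (constant along z) ----
  A <- body$semi_lr; B <- body$semi_ap
  shrink <- function(t) ellipse_mask(xc, yc, 0, 0, A - t, B - t)
  m_body   <- shrink(0)
  m_cutis  <- shrink(body$cutis)
  m_sat    <- shrink(body$cutis + body$sat_thickness)
  m_muscle <- shrink(body$cutis + body$sat_thickness + body$muscle_thickness)
  tmpl <- matrix(lab["background"], nx, ny)
  tmpl[m_body & !m_cutis]   <- lab["cutis"]
  tmpl[m_cutis & !m_sat]    <- lab["sat"]
  tmpl[m_sat & !m_muscle]   <- lab["muscle"]
  tmpl[m_muscle]            <- lab["vat"]
  if (nrow(body$organs)) {
    for (i in seq_len(nrow(body$organs))) {
      o <- body$organs[i, ]
      m_org <- ellipse_mask(xc, yc, o$x, o$y, o$r, o$r)
      if (any(m_org & !m_muscle))
        stop("geometry error: organ disk ", i,
             " collides with labels outside the visceral space")
      tmpl[m_org] <- lab["organ"]
    }
  }
  ph_masks <- vector("list", 2L)
  for (i in 1:2) {
    m_ph <- ellipse_mask(xc, yc, phantom$x_offsets[i], phantom$y_center,
                         phantom$radius, phantom$radius)
    if (any(m_ph & tmpl != lab["background"]))
      stop("geometry error: phantom phase ", i,
           " collides with labels: ",
           paste(names(lab)[match(unique(tmpl[m_ph & tmpl != lab["background"]]),
                                  lab)], collapse = ", "))
    tmpl[m_ph] <- lab[paste0("phantom", i)]
    ph_masks[[i]] <- m_ph
  }

  labels <- array(rep(tmpl, nz), dim = c(nx, ny, nz))

  ## ---- per-level vertebral bodies ----
  xs <- geometry$center_x; ys <- geometry$center_y
  d <- geometry$levels
  for (i in seq_len(13L)) {
    a <- d$radius_lr[i]; b <- d$radius_ap[i]
    s <- d$shell[i]; ep <- d$endplate[i]; h <- d$height[i]
    z0 <- zext$z_bottom[i]; z1 <- zext$z_top[i]
    m_ell <- ellipse_mask(xc, yc, xs, ys, a, b)
    m_in  <- ellipse_mask(xc, yc, xs, ys, a - s, b - s)
    m_shell <- m_ell & !m_in
    kidx <- which(zc >= z0 & zc <= z1)
    if (!length(kidx)) next
    over <- labels[, , kidx[1]][m_ell]
    bad <- setdiff(unique(over), c(lab["vat"]))
    if (length(bad))
      stop("geometry error: vertebra ", d$level[i], " overlaps labels: ",
           paste(names(lab)[match(bad, lab)], collapse = ", "))
    k_ep <- kidx[zc[kidx] < z0 + ep | zc[kidx] > z1 - ep]
    k_tb <- setdiff(kidx, k_ep)
    labels <- assign_slices(labels, kidx, m_shell, lab[["cortical"]])
    labels <- assign_slices(labels, k_ep, m_in, lab[["endplate"]])
    labels <- assign_slices(labels, k_tb, m_in, lab[["trabecular"]])
    # basivertebral venous channel: cylinder along y at mid-height,
    # penetrating from the posterior wall into the posterior body
    rp <- d$plexus_radius[i]; lp <- d$plexus_length[i]
    zmid <- (z0 + z1) / 2
    k_px <- kidx[abs(zc[kidx] - zmid) <= rp]
    y_px <- yc >= ys - b & yc <= ys - b + lp
    for (k in k_px) {
      w <- sqrt(max(rp^2 - (zc[k] - zmid)^2, 0))
      m_px <- outer(abs(xc - xs) <= w, y_px, "&") & m_ell
      sl <- labels[, , k]
      sl[m_px] <- lab[["plexus"]]
      labels[, , k] <- sl
    }
  }

  ## ---- HU rendering ----
  hu_of <- c(background = -1000, trabecular = NA, cortical = 600,
             endplate = 600, plexus = 120,
             sat = body$adipose_hu, vat = body$adipose_hu,
             muscle = body$muscle_hu, organ = body$organ_hu,
             phantom1 = hu_intercept + hu_slope * phantom$densities[1],
             phantom2 = hu_intercept + hu_slope * phantom$densities[2],
             cutis = body$cutis_hu)
  lut <- numeric(length(lab))
  lut[lab + 1L] <- hu_of[names(lab)]
  hu2d <- matrix(lut[tmpl + 1L], nx, ny)   # bone labels only occur per level
  hu <- array(rep(hu2d, nz), dim = dim(labels))
  for (i in seq_len(13L)) {
    z0 <- zext$z_bottom[i]; z1 <- zext$z_top[i]
    kidx <- which(zc >= z0 & zc <= z1)
    block <- labels[, , kidx, drop = FALSE]
    lut_i <- lut
    lut_i[lab[["trabecular"]] + 1L] <- hu_intercept + hu_slope * true_densities[i]
    hu[, , kidx] <- lut_i[block + 1L]
  }
  if (hu_offset != 0) {
    anatomy <- !(labels == lab["background"] | labels == lab["phantom1"] |
                   labels == lab["phantom2"])
    hu[anatomy] <- hu[anatomy] + hu_offset
  }
  set.seed(as.integer(seed))
  if (noise_sd > 0)
    hu <- hu + array(stats::rnorm(length(hu), 0, noise_sd), dim = dim(hu))

  ## ---- containers ----
  scan <- structure(list(
    hu = hu, spacing = spacing, origin = c(xc[1], yc[1], zc[1]),
    axes = c("sagittal", "coronal", "axial"),
    geometry = geometry, z_extents = zext,
    hu_range_note = "air -1000; adipose/muscle/bone per body_spec"
  ), class = "scan_volume")

  l45 <- l45_center_index(scan)
  win <- (l45 - 2):(l45 + 2)
  win <- win[win >= 1 & win <= nz]
  voxvol <- prod(spacing)
  n_sat <- sum(labels[, , win] == lab["sat"])
  n_vat <- sum(labels[, , win] == lab["vat"])
  truth <- structure(list(
    labels = labels, true_densities = true_densities,
    sat_cm3 = n_sat * voxvol / 1000, vat_cm3 = n_vat * voxvol / 1000,
    l45_window = win, hu_offset = hu_offset, noise_sd = noise_sd,
    hu_slope = hu_slope, hu_intercept = hu_intercept, seed = as.integer(seed)
  ), class = "scan_truth")

  structure(list(scan = scan, truth = truth), class = "qct_scan")
}

# axial index of the L4/5 intervertebral disc plane (gap center)
l45_center_index <- function(scan) {
  ze <- scan$z_extents
  z_disc <- (ze$z_bottom[ze$level == "L4"] + ze$z_top[ze$level == "L5"]) / 2
  axial_index(scan, z_disc)
}

# grid index helpers: nearest voxel center, ties toward the lower index
nearest_index <- function(centers, pos) {
  d <- abs(centers - pos)
  which(d <= min(d) + 1e-9)[1]
}
sagittal_index <- function(scan, x) nearest_index(sagittal_centers(scan), x)
axial_index <- function(scan, z) nearest_index(axial_centers(scan), z)

sagittal_centers <- function(scan)
  scan$origin[1] + (seq_len(dim(scan$hu)[1]) - 1) * scan$spacing[1]
coronal_centers <- function(scan)
  scan$origin[2] + (seq_len(dim(scan$hu)[2]) - 1) * scan$spacing[2]
axial_centers <- function(scan)
  scan$origin[3] + (seq_len(dim(scan$hu)[3]) - 1) * scan$spacing[3]

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat("Synthetic CT volume:", paste(d, collapse = " x "), "voxels,",
      paste(x$spacing, collapse = " x "), "mm spacing",
      sprintf("(%s)\n", paste(x$axes, collapse = ", ")))
  cat("HU range:", paste(round(range(x$hu), 1), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.qct_scan <- function(x, ...) {
  print(x$scan)
  cat("Ground truth: SAT", round(x$truth$sat_cm3, 1), "cm^3, VAT",
      round(x$truth$vat_cm3, 1), "cm^3 over the L4/5 window; noise_sd",
      x$truth$noise_sd, "HU; contrast offset", x$truth$hu_offset, "HU\n")
  invisible(x)
}
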