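test_that("mid-sagittal slice lands on the vertebral center with the stated tie-break", {
  x <- default_clean_scan()
  xc <- spineqct:::sagittal_centers(x$scan)
  k <- locate_midsagittal_slice(x$scan, "Th7")
  # the column axis sits exactly between two 2 mm slices; ties go lower
  expect_equal(abs(xc[k]), min(abs(xc)))
  expect_true(xc[k] <= 0)
  expect_identical(locate_midsagittal_slice(x$scan, "L5"), k)
  expect_error(locate_midsagittal_slice(x$scan, "Th4"), "lookup error")
})

test_that("ROI diameter follows the two-thirds-of-height rule", {
  x <- default_clean_scan()
  g <- x$scan$geometry$levels
  for (lv in c("Th5", "Th10", "L3")) {
    roi <- place_roi(x$scan, lv)
    expect_equal(roi$diameter, 2 * g$height[g$level == lv] / 3)
    expect_false(roi$shrunk)
  }
})

test_that("ROIs contain only trabecular voxels at all 13 levels", {
  x <- default_clean_scan()
  lab <- scan_labels()
  for (lv in vertebral_levels()) {
    roi <- place_roi(x$scan, lv)
    m <- spineqct:::roi_mask_yz(x$scan, roi)
    block <- x$truth$labels[roi$slab, , , drop = FALSE]
    vals <- as.vector(block)[rep(as.vector(m), each = length(roi$slab))]
    expect_true(all(vals == lab["trabecular"]), label = paste("purity at", lv))
  }
})

test_that("a venous channel filling the anterior body defeats ROI placement", {
  g <- spine_geometry(plexus_frac = 0.98)
  x <- coarse_scan(seed = 1, geometry = g)
  expect_error(place_roi(x$scan, "Th7"), "placement error")
})

test_that("an oversized ROI request is shrunk to fit and flagged", {
  g <- spine_geometry(heights = rep(30, 13), radius_ap = rep(18, 13),
                      radius_lr = rep(15, 13))
  x <- coarse_scan(seed = 1, geometry = g)
  expect_warning(roi <- place_roi(x$scan, "Th7"), "shrunk")
  expect_true(roi$shrunk)
  expect_lt(roi$diameter, roi$standard_diameter)
})

test_that("noise-free measurement reproduces true density through the calibration chain", {
  x <- default_clean_scan()
  cal <- calibrate_scan(x$scan, phantom_spec())
  tab <- measure_spine(x$scan, cal)
  expect_equal(tab$bmd, unname(x$truth$true_densities), tolerance = 1e-10)
  expect_true(all(tab$status == "measured"))
  # a model fitted from (20,50),(180,200): ROI mean HU of 100 converts to 125
  m <- fit_calibration(data.frame(mean_hu = c(20, 180), density = c(50, 200)))
  roi <- place_roi(x$scan, "Th7")
  meas <- measure_vertebral_bmd(x$scan, roi, m)
  expect_equal(meas$bmd, 0.9375 * meas$mean_hu + 31.25)
})

test_that("prevalent fractures are skipped and the L1-L3 mean degrades gracefully", {
  x <- default_clean_scan()
  cal <- calibrate_scan(x$scan, phantom_spec())
  tab <- measure_spine(x$scan, cal, prevalent_fractures = "Th12")
  expect_identical(tab$status[tab$level == "Th12"], "skipped-prevalent-fracture")
  expect_true(is.na(tab$bmd[tab$level == "Th12"]))
  expect_identical(sum(tab$status == "measured"), 12L)

  t2 <- measure_spine(x$scan, cal, prevalent_fractures = "L2")
  l1 <- t2$bmd[t2$level == "L1"]; l3 <- t2$bmd[t2$level == "L3"]
  expect_equal(attr(t2, "mean_l1_l3"), mean(c(l1, l3)))
  expect_identical(attr(t2, "l1_l3_status"), "partial")

  t3 <- measure_spine(x$scan, cal, prevalent_fractures = c("L1", "L2", "L3"))
  expect_true(is.na(attr(t3, "mean_l1_l3")))
  expect_identical(attr(t3, "l1_l3_status"), "missing")

  full <- measure_spine(x$scan, cal)
  expect_equal(attr(full, "mean_l1_l3"),
               mean(full$bmd[full$level %in% c("L1", "L2", "L3")]))
})

test_that("doubling the internal density-to-HU slope leaves measured BMD invariant", {
  a <- coarse_scan(seed = 1, hu_slope = 1.05)
  b <- coarse_scan(seed = 1, hu_slope = 2.10)
  ta <- measure_spine(a$scan, calibrate_scan(a$scan, phantom_spec()))
  tb <- measure_spine(b$scan, calibrate_scan(b$scan, phantom_spec()))
  expect_equal(ta$bmd, tb$bmd, tolerance = 1e-9)
})
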