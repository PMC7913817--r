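test_that("the L4/5 window is five contiguous slices centered on the disc plane", {
  x <- default_clean_scan()
  win <- select_l45_window(x$scan)
  expect_length(win, 5L)
  expect_identical(diff(win), rep(1L, 4))
  ze <- x$scan$z_extents
  z_disc <- (ze$z_bottom[ze$level == "L4"] + ze$z_top[ze$level == "L5"]) / 2
  zc <- spineqct:::axial_centers(x$scan)
  expect_lte(abs(zc[win[3]] - z_disc), x$scan$spacing[3])
  expect_identical(win, x$truth$l45_window)
})

test_that("a disc too close to the volume edge raises a windowing error", {
  x <- default_clean_scan()
  short <- x$scan
  ze <- short$z_extents
  z_disc <- (ze$z_bottom[ze$level == "L4"] + ze$z_top[ze$level == "L5"]) / 2
  k <- spineqct:::axial_index(short, z_disc)
  short$hu <- short$hu[, , k:(dim(short$hu)[3]), drop = FALSE]
  short$origin[3] <- spineqct:::axial_centers(x$scan)[k]
  expect_error(select_l45_window(short), "windowing error")
})

test_that("segmentation recovers the ground-truth masks exactly on clean scans", {
  x <- default_clean_scan()
  lab <- scan_labels()
  masks <- segment_fat(x$scan)
  win <- masks$window
  expect_identical(sum(masks$sat), sum(x$truth$labels[, , win] == lab["sat"]))
  expect_identical(sum(masks$vat), sum(x$truth$labels[, , win] == lab["vat"]))
  expect_false(any(masks$sat & masks$vat))
  fc <- quantify_fat(masks)
  expect_equal(fc$sat_cm3, x$truth$sat_cm3)
  expect_equal(fc$vat_cm3, x$truth$vat_cm3)
})

test_that("fat-range voxels inside the cutis are partitioned without double counting", {
  x <- default_clean_scan()
  masks <- segment_fat(x$scan)
  win <- masks$window
  hu <- x$scan$hu[, , win]
  body <- hu > -400
  fat <- hu >= -190 & hu <= -30 & body
  expect_identical(unname(sum(masks$sat) + sum(masks$vat)), unname(sum(fat)))
})

test_that("an image without fat-range voxels yields two empty masks, not an error", {
  sl <- toy_fat_slice()
  sl[sl == -100] <- 50       # replace all fat with muscle
  out <- segment_fat_slice(sl)
  expect_false(any(out$sat) || any(out$vat))
})

test_that("a one-voxel gap in the muscle wall raises a leak error", {
  expect_error(segment_fat_slice(toy_fat_slice(wall_gap = TRUE)), "leak error")
  out <- segment_fat_slice(toy_fat_slice(wall_gap = FALSE))
  expect_true(any(out$sat) && any(out$vat))
  expect_false(any(out$sat & out$vat))
})

test_that("volumes follow voxel arithmetic and are scale-equivariant", {
  masks <- list(sat = array(TRUE, c(10, 10, 10)), vat = array(FALSE, c(10, 10, 10)))
  fc <- quantify_fat(masks, voxel_volume_mm3 = 2 * 2 * 5)
  expect_equal(fc$sat_cm3, 1000 * 20 / 1000)
  half <- list(sat = array(TRUE, c(10, 10, 5)), vat = array(FALSE, c(10, 10, 5)))
  expect_equal(quantify_fat(half, voxel_volume_mm3 = 40)$sat_cm3, fc$sat_cm3)
})

test_that("the VAT/SAT ratio follows the per-subject formula and flags SAT = 0", {
  masks <- list(sat = array(rep(c(TRUE, FALSE), c(300, 700)), c(10, 10, 10)),
                vat = array(rep(c(FALSE, TRUE, FALSE), c(300, 154, 546)),
                            c(10, 10, 10)))
  fc <- quantify_fat(masks, voxel_volume_mm3 = 1000)   # 1 cm^3 voxels
  expect_equal(fc$vat_sat, 154 / 300)
  eq_vat <- array(FALSE, c(10, 10, 10)); eq_vat[, , 6:10] <- TRUE
  eq_sat <- array(FALSE, c(10, 10, 10)); eq_sat[, , 1:5] <- TRUE
  expect_equal(quantify_fat(list(sat = eq_sat, vat = eq_vat),
                            voxel_volume_mm3 = 10)$vat_sat, 1.0)
  expect_error(quantify_fat(list(sat = eq_sat, vat = eq_sat),
                            voxel_volume_mm3 = 10), "disjoint")
  none <- quantify_fat(list(sat = masks$sat & FALSE, vat = masks$vat),
                       voxel_volume_mm3 = 10)
  expect_false(none$ratio_defined)
  expect_true(is.na(none$vat_sat))
})
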