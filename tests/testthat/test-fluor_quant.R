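make_test_stack <- function(arr, ps = 0.1, zs = 0.5) image_stack(arr, ps, zs)

test_that("projections reduce to the slice, scale with n, and match a loop oracle", {
  set.seed(1)
  one <- array(runif(25), dim = c(5, 5, 1, 1))
  st1 <- make_test_stack(one)
  expect_equal(project(st1, 1, "sum"), one[, , 1, 1])
  expect_equal(project(st1, 1, "max"), one[, , 1, 1])

  const <- array(3, dim = c(4, 4, 6, 1))
  stc <- make_test_stack(const)
  expect_equal(project(stc, 1, "sum"), matrix(18, 4, 4))
  expect_equal(project(stc, 1, "max"), matrix(3, 4, 4))

  rnd <- array(rpois(5 * 6 * 4, 20), dim = c(5, 6, 4, 1))
  str <- make_test_stack(rnd)
  oracle <- matrix(0, 5, 6)
  for (z in 1:4) oracle <- oracle + rnd[, , z, 1]
  expect_equal(project(str, 1, "sum"), oracle)
  expect_error(project(str, 1, "sum", integer(0)), "empty z_range")
  expect_error(project(str, 3), "unknown channel")
})

test_that("paired-ROI background subtraction recovers planted signal exactly", {
  roi1 <- rect_roi(10, 10, 6, 6)
  roi2 <- rect_roi(7, 7, 12, 12)
  uniform <- matrix(7.3, 30, 30)
  expect_equal(roi_background_subtracted_intensity(uniform, roi1, roi2), 0)

  img <- matrix(5, 30, 30)          # uniform cytoplasmic background
  sig <- matrix(0, 30, 30)
  sig[12:15, 12:15] <- 40           # signal wholly inside roi1
  expect_equal(
    roi_background_subtracted_intensity(img + sig, roi1, roi2), sum(sig))

  # ROI2 of exactly twice ROI1's area, background-only annulus:
  # corrected = I1 - I(annulus)
  roi2b <- rect_roi(10, 10, 12, 6)  # annulus is the right-hand half
  i1 <- sum((img + sig)[11:16, 11:16])
  iann <- sum(img[11:16, 17:22])
  expect_equal(roi_background_subtracted_intensity(img + sig, roi1, roi2b),
               i1 - iann)

  expect_error(roi_background_subtracted_intensity(img, roi2, roi1),
               "inside")
  expect_error(
    roi_background_subtracted_intensity(img, roi1,
                                        rect_roi(10, 10, 6, 6)),
    "larger")
})

test_that("axial colocalization profile is a per-column mean in micrometres", {
  img <- matrix(2, 40, 40)
  roi <- rect_roi(5, 10, 35, 15)
  prof <- axial_colocalization_profile(img, roi, pixel_size = 0.1)
  expect_true(all(prof$values == 2))
  expect_equal(length(prof$values), 35)
  set.seed(2)
  img2 <- matrix(runif(1600), 40, 40)
  prof2 <- axial_colocalization_profile(img2, roi, 0.1)
  oracle <- colMeans(img2[11:25, 6:40])
  expect_equal(prof2$values, unname(oracle))
  expect_equal(prof2$positions, (5 + 1:35 - 0.5) * 0.1)
})

test_that("two-channel ring stacks report the planted axial offset", {
  st <- make_division_stack("ring", second_channel_offset_um = 0.4,
                            poisson_noise = FALSE, seed = 3)
  ps <- st$stack$pixel_size
  c_px <- st$truth$centre_um / ps
  r_px <- st$truth$cell_radius_um / ps
  # profile over the right-hand rim only: one peak per channel
  roi <- rect_roi(floor(c_px + r_px - 7), floor(c_px - 15), 14, 30)
  peaks <- vapply(1:2, function(ch) {
    img <- project(st$stack, ch, "max")
    p <- axial_colocalization_profile(img, roi, ps)
    p$positions[which.max(p$values)]
  }, numeric(1))
  expect_equal(peaks[2] - peaks[1], 0.4, tolerance = ps + 1e-9)
})

test_that("line scans reduce to pixel rows and decompose over width", {
  img <- matrix(4.2, 20, 20)
  prof <- line_scan(img, c(2, 10), c(17, 10), 3)
  expect_true(all(prof$values == 4.2))

  set.seed(3)
  img2 <- matrix(runif(400), 20, 20)
  w1 <- line_scan(img2, c(2, 8), c(17, 8), 1)
  expect_equal(w1$values, img2[9, 3:18])
  w3 <- line_scan(img2, c(2, 8), c(17, 8), 3)
  rows <- (img2[8, 3:18] + img2[9, 3:18] + img2[10, 3:18]) / 3
  expect_equal(w3$values, rows)
  expect_error(line_scan(img2, c(2, 8), c(2, 8), 3), "zero-length")
})

test_that("alignment strategies centre planted peaks", {
  gauss_profile <- function(centre, n = 81, ps = 0.1) {
    x <- (1:n - 0.5) * ps
    line_profile(x, exp(-((x - centre) / 0.3)^2))
  }
  # planted peak on a sampled position (pixel centre) at +1.25 um
  ref <- gauss_profile(1.25)
  moved <- align_profiles(list(gauss_profile(2.0), gauss_profile(3.1)),
                          "reference_peak", reference = ref)
  # every profile shifted by the same -1.25 um
  expect_equal(moved[[1]]$positions, gauss_profile(2)$positions - 1.25,
               tolerance = 1e-9)
  expect_equal(moved[[2]]$positions, gauss_profile(3.1)$positions - 1.25,
               tolerance = 1e-9)
  expect_equal(moved[[1]]$alignment$origin, 1.25, tolerance = 1e-9)

  own <- align_profiles(list(gauss_profile(2.0)), "brightest_pixel")
  expect_equal(own[[1]]$positions[which.max(own[[1]]$values)], 0,
               tolerance = 0.1)

  # symmetric double peak: midpoint at the symmetry centre
  x <- (1:101 - 0.5) * 0.1
  two <- line_profile(x, exp(-((x - 2) / 0.4)^2) + exp(-((x - 8) / 0.4)^2))
  mid <- align_profiles(list(two), "two_peak_midpoint")
  expect_equal(mid[[1]]$alignment$origin, 5, tolerance = 0.1)
  single <- line_profile(x, exp(-((x - 5) / 0.4)^2))
  expect_error(align_profiles(list(single), "two_peak_midpoint"),
               "fewer than two")

  ext <- align_profiles(list(two), "external_center", reference = 5)
  expect_equal(ext[[1]]$positions, x - 5)
  # an already-centred profile is unchanged
  again <- align_profiles(ext, "external_center", reference = 0)
  expect_equal(again[[1]]$positions, ext[[1]]$positions)
})

test_that("rim-spread index separates rim rings from centre disks", {
  scan_stack <- function(st) {
    ps <- st$stack$pixel_size
    c_px <- st$truth$centre_um / ps
    r_px <- st$truth$cell_radius_um / ps
    img <- project(st$stack, 1, "max")
    line_scan(img, c(c_px - r_px - 2, c_px), c(c_px + r_px + 2, c_px),
              3, ps)
  }
  ring <- make_division_stack("ring", poisson_noise = TRUE, seed = 4)
  disk <- make_division_stack("disk", poisson_noise = TRUE, seed = 4)
  expect_lt(rim_spread_index(scan_stack(ring)), 0.2)
  expect_gt(rim_spread_index(scan_stack(disk)), 0.6)
  zero <- line_profile(1:10, rep(0, 10))
  expect_error(rim_spread_index(zero), "all-zero")
})

test_that("quantifications are linear in intensity and translation-equivariant", {
  set.seed(9)
  img <- matrix(rpois(900, 30), 30, 30)
  roi1 <- rect_roi(8, 8, 8, 8); roi2 <- rect_roi(5, 5, 14, 14)
  v1 <- roi_background_subtracted_intensity(img, roi1, roi2)
  expect_equal(roi_background_subtracted_intensity(img * 3.7, roi1, roi2),
               3.7 * v1)
  p1 <- line_scan(img, c(2, 15), c(27, 15), 3)
  p2 <- line_scan(img * 3.7, c(2, 15), c(27, 15), 3)
  expect_equal(p2$values, 3.7 * p1$values)

  shifted <- matrix(0, 32, 32)
  shifted[3:32, 3:32] <- img
  roi1s <- rect_roi(10, 10, 8, 8); roi2s <- rect_roi(7, 7, 14, 14)
  expect_equal(roi_background_subtracted_intensity(shifted, roi1s, roi2s), v1)
  p3 <- line_scan(shifted, c(4, 17), c(29, 17), 3)
  expect_equal(p3$values, p1$values)
})

test_that("stacks round-trip through TIFF plus sidecar", {
  set.seed(5)
  arr <- array(runif(5 * 6 * 3 * 2) * 800, dim = c(5, 6, 3, 2))
  st <- image_stack(arr, 0.1, 0.5, channels = c("GFP", "tdTomato"))
  path <- file.path(tempdir(), "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$intensities, arr, tolerance = 1e-6)
  expect_identical(back$channels, c("GFP", "tdTomato"))
  expect_identical(back$pixel_size, 0.1)
  unlink(c(path, paste0(path, ".json")))
})
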