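# Diameter tracking on rendered frames.

test_that("disc means follow raster semantics", {
  fr <- matrix(7, 50, 50)
  expect_equal(discMean(fr, c(25, 25), 10), 7)
  # radius below one pixel: only the centre pixel qualifies
  fr2 <- matrix(0, 20, 20); fr2[10, 10] <- 3
  expect_equal(discMean(fr2, c(10, 10), 0.5), 3)
  # half-plane image, disc on the boundary: mean near the midpoint
  fr3 <- cbind(matrix(0, 40, 20), matrix(10, 40, 20))
  m <- discMean(fr3, c(20.5, 20), 8)
  expect_gte(m, 4.5); expect_lte(m, 5.5)
  expect_error(discMean(fr, c(500, 500), 3), "outside")
})

test_that("moving threshold is the vessel/background MFI ratio", {
  expect_equal(movingThreshold(600, 100), 6)
  expect_equal(movingThreshold(123, 123), 1)
  expect_equal(movingThreshold(250, 125), 2)
  expect_error(movingThreshold(100, 0), "positive")
})

test_that("line profiles sample where the geometry says", {
  geo <- vesselGeometry(center = c(20, 120), normal = c(0, -1), r = 30,
                        scale = 2)
  fr <- matrix(5, 200, 40)
  prof <- sampleLineProfile(fr, geo)
  expect_length(prof$samples, round(3 * 30) + 1)
  expect_true(all(prof$samples == 5))
  # axis-aligned line on the integer grid returns raw pixel values
  fr2 <- matrix(seq_len(200), 200, 40)        # value = row index
  prof2 <- sampleLineProfile(fr2, geo)
  expect_equal(prof2$samples, as.numeric(60:150))
  expect_equal(unname(prof2$positions[1, "y"]), 120 - 60)  # bg ROI centre
  # line leaving the frame is invalid geometry
  geoBad <- vesselGeometry(center = c(20, 60), normal = c(0, -1), r = 30,
                           scale = 2)
  expect_error(sampleLineProfile(fr, geoBad), "exits")
})

test_that("an oblique profile reproduces the rendered cross-section", {
  ph <- phantomWithGeometry(d0 = 60, depth = 0, duration = 4, ncol = 200)
  fr <- ph$movie$stack[, , 1]
  geo45 <- vesselGeometry(center = c(100, 308), normal = c(1, -1) / sqrt(2),
                          r = 60, scale = 2)
  prof <- sampleLineProfile(fr, geo45)
  # background plateau, rise, lumen, fall: compare against the rendered
  # column (the frame is constant along x, so the y coordinate determines
  # the value up to bilinear interpolation error)
  expected <- vapply(seq_len(nrow(prof$positions)), function(j) {
    y <- prof$positions[j, "y"]
    y0 <- floor(y); fy <- y - y0
    (1 - fy) * fr[y0, 1] + fy * fr[y0 + 1, 1]
  }, numeric(1))
  expect_equal(prof$samples, expected, tolerance = 1e-9)
  expect_gt(max(prof$samples), 5 * min(prof$samples))  # lumen well above bg
})

test_that("profile counting converts to micrometres", {
  prof <- rep(1, 31); prof[12:21] <- 10      # normalized lumen above T
  res <- profileToDiameter(prof, threshold = 5, scale = 1.6)
  expect_identical(res$pixelCount, 10L)
  expect_equal(res$diameter, 16)
  # all sub-threshold: zero diameter, flagged by the count
  res0 <- profileToDiameter(rep(1, 31), 5, 1.6)
  expect_identical(res0$pixelCount, 0L)
  expect_error(profileToDiameter(rep(1, 5), 2, 1), "at least 10")
  expect_error(profileToDiameter(rep(-1, 31), 2, 1), "positive")
  # contiguous mode ignores detached islands
  prof2 <- rep(1, 31); prof2[12:21] <- 10; prof2[3] <- 10
  expect_identical(profileToDiameter(prof2, 5, 1)$pixelCount, 11L)
  expect_identical(profileToDiameter(prof2, 5, 1, contiguous = TRUE)$pixelCount,
                   10L)
})

test_that("static noiseless phantoms track within one pixel", {
  for (psf in c(0.5, 1)) {
    for (Dpx in c(10, 30, 60)) {
      scale <- 2
      opt <- phantomOptics(nrow = 448, ncol = 48, axisRow = 308,
                           scale = scale, psfSigma = psf, frameRate = 2.5,
                           duration = 4)
      fr <- renderFrame(Dpx * scale, opt)
      geo <- vesselGeometry(center = c(24, 308), normal = c(0, -1),
                            r = 2 * Dpx, scale = scale)
      stack <- array(fr, dim = c(dim(fr), 10))
      trk <- trackDiameter(stack, geo, 2.5)
      expect_true(all(abs(trk$table$pixel_count - Dpx) <= 1),
                  label = sprintf("D=%d psf=%g", Dpx, psf))
    }
  }
})

test_that("a contracting phantom is tracked faithfully", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0.3, duration = 60, seed = 7)
  trk <- trackDiameter(ph$movie$stack, ph$geometry, 2.5)
  expect_identical(nrow(trk$table), 150L)
  expect_length(trk$failures, 0)
  r <- pearsonCorrelation(trk$table$diameter_um,
                          ph$movie$truth$true_diameter_um)
  expect_gt(r, 0.99)
  expect_lt(max(abs(trk$table$diameter_um - ph$movie$truth$true_diameter_um)),
            2 * ph$geometry@scale)   # within 2 px everywhere, noiseless
})

test_that("tracked diameters stay within the geometric range", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0.3, duration = 20,
                            noiseSigma = 40, seed = 9)
  trk <- trackDiameter(ph$movie$stack, ph$geometry, 2.5)
  expect_true(all(trk$table$diameter_um >= 0))
  expect_true(all(trk$table$diameter_um <=
                    3 * ph$geometry@r * ph$geometry@scale))
})

test_that("pixel counts are invariant to intensity scaling", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0.3, duration = 20,
                            noiseSigma = 30, seed = 13)
  trk1 <- trackDiameter(ph$movie$stack, ph$geometry, 2.5)
  trk2 <- trackDiameter(ph$movie$stack * 3.7, ph$geometry, 2.5)
  expect_identical(trk1$table$pixel_count, trk2$table$pixel_count)
})

test_that("uniform offsets act only through the documented ratios", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0, duration = 4, seed = 2)
  stack <- array(ph$movie$stack[, , 1], dim = c(448, 48, 10))
  base <- trackDiameter(stack, ph$geometry, 2.5)$table[1, ]
  shifted <- trackDiameter(stack + 50, ph$geometry, 2.5)$table[1, ]
  # the threshold ratio compresses toward 1 with a uniform offset...
  expect_lt(shifted$threshold, base$threshold)
  # ...and so does the normalized profile, leaving the count nearly unchanged
  expect_lte(abs(shifted$pixel_count - base$pixel_count), 1)
})

test_that("MFI extraction reflects lumen volume", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0.3, duration = 60, seed = 5)
  ax <- 308; rpx <- 80
  mfi <- extractMFITrace(ph$movie$stack, c(24, ax), rpx, 2.5,
                         background = list(center = c(24, ax - 4 * rpx / 2),
                                           radius = rpx / 2))
  expect_s4_class(mfi, "Trace")
  # background-subtracted MFI proportional to D^2 within 2% relative error
  rel <- traceValues(mfi) / ph$movie$truth$true_diameter_um^2
  expect_lt((max(rel) - min(rel)) / mean(rel), 0.02)
  # uniform stack: constant trace
  flat <- extractMFITrace(array(9, c(40, 20, 12)), c(10, 20), 5, 2.5)
  expect_true(all(traceValues(flat) == 9))
})

test_that("two disjoint ROIs on one vessel agree", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0.3, duration = 60,
                            noiseSigma = 20, seed = 19, ncol = 64)
  m1 <- extractMFITrace(ph$movie$stack, c(16, 308), 30, 2.5)
  m2 <- extractMFITrace(ph$movie$stack, c(48, 308), 30, 2.5)
  expect_gt(pearsonCorrelation(m1, m2), 0.95)
})

test_that("frames with unusable normalizers are marked, many abort", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0, duration = 8, seed = 4)
  stack <- ph$movie$stack
  stack[, , 3] <- -1                       # background mean <= 0
  trk <- trackDiameter(stack, ph$geometry, 2.5)
  expect_identical(trk$failures, 3L)
  expect_true(is.na(trk$table$diameter_um[3]))
  expect_null(trk$trace)
  stack[, , 1:10] <- -1
  expect_error(trackDiameter(stack, ph$geometry, 2.5), "failed")
})

test_that("geometry suggestion lands on the vessel axis", {
  ph <- phantomWithGeometry(d0 = 80, depth = 0, duration = 4, seed = 6)
  geo <- suggestGeometry(ph$movie$stack[, , 1], scale = 2)
  expect_s4_class(geo, "VesselGeometry")
  expect_lt(abs(geo@center[2] - 308), 3)
})
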