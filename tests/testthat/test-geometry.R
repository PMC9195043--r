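test_that("pixel pitch and iso-plane conversions follow the detector geometry", {
  spec <- DetectorSpec()
  expect_equal(pixelPitch(spec), 397 / 1024, tolerance = 1e-12)
  expect_equal(pixelPitch(spec), 0.3877, tolerance = 1e-4)
  # square-pixel assumption: row pitch within 1% of column pitch
  expect_lt(abs(298 / 768 - pixelPitch(spec)) / pixelPitch(spec), 0.01)
  expect_equal(pixelPitch(DetectorSpec(100L, 75L, 100, 75)), 1.0)

  expect_equal(unname(detectorShiftToIso(c(0, 0), spec)), c(0, 0))
  expect_equal(unname(detectorShiftToIso(c(1, 0), spec)),
               c(0.3877 * 1000 / 1500, 0), tolerance = 1e-4)
})

test_that("iso-plane and detector-pixel conversions are exact inverses", {
  spec <- DetectorSpec()
  set.seed(11)
  for (i in 1:25) {
    p <- runif(2, -50, 50)
    expect_equal(unname(isoToDetectorPx(detectorShiftToIso(p, spec), spec)),
                 p, tolerance = 1e-12)
    expect_equal(unname(detectorShiftToIso(isoToDetectorPx(p, spec), spec)),
                 p, tolerance = 1e-12)
  }
})

test_that("the isocenter projects to the detector center at every gantry angle", {
  spec <- DetectorSpec()
  ctr <- detectorCenter(spec)
  for (g in seq(0, 359, by = 1)) {
    p <- projectPoint(c(0, 0, 0), g, spec)
    expect_equal(unname(p), unname(ctr), tolerance = 1e-9)
  }
})

test_that("transverse offsets at iso depth magnify by sid/sad on the detector", {
  spec <- DetectorSpec()
  ctr <- detectorCenter(spec)
  # brute-force expectation built from explicit trigonometry per angle
  set.seed(7)
  for (g in runif(10, 0, 360)) {
    rad <- g * pi / 180
    colAxis <- c(cos(rad), -sin(rad), 0)
    s <- runif(1, -20, 20)
    p <- projectPoint(s * colAxis, g, spec)
    expect_equal(unname(p["col"] - ctr["col"]),
                 s * 1500 / 1000 / pixelPitch(spec), tolerance = 1e-9)
    expect_equal(unname(p["row"]), unname(ctr["row"]), tolerance = 1e-9)
    # a 10 mm longitudinal offset maps to rows, undistorted by gantry angle
    q <- projectPoint(c(0, 0, 10), g, spec)
    expect_equal(unname(q["row"] - ctr["row"]),
                 10 * 1.5 / pixelPitch(spec), tolerance = 1e-9)
  }
  # a point displaced along the source-detector axis stays on the center
  g <- 123
  rad <- g * pi / 180
  beamAxis <- -c(sin(rad), cos(rad), 0)
  expect_equal(unname(projectPoint(10 * beamAxis, g, spec)), unname(ctr),
               tolerance = 1e-9)
  expect_error(projectPoint(-1001 * beamAxis, g, spec), "behind")
})

test_that("ROI forward projection produces the expected detector footprint", {
  spec <- DetectorSpec()
  ctr <- detectorCenter(spec)

  # single voxel at the isocenter: a small blob at the detector center
  m1 <- array(FALSE, c(11, 11, 11)); m1[6, 6, 6] <- TRUE
  roi1 <- projectROI(m1, 2, c(-10, -10, -10), 90, spec)
  hits <- which(roi1@mask, arr.ind = TRUE)
  expect_lt(max(abs(hits[, 1] - 1 - ctr["row"])), 3)
  expect_lt(max(abs(hits[, 2] - 1 - ctr["col"])), 3)

  # 2 cm cube at iso: iso-plane estimate 20 mm x 1.5 / pitch = 77 px;
  # exact cone-beam arithmetic (near face 10 mm closer to the source
  # magnifies by 1500/990) puts the voxel-center footprint at
  # round(ctr +/- 10 * 1500/990 / pitch), an 80 px bounding box
  n <- 11 # 11 voxels at 2 mm spacing = 20 mm between outermost centers
  cube <- array(TRUE, c(n, n, n))
  roi2 <- projectROI(cube, 2, c(-10, -10, -10), 180, spec)
  hits2 <- which(roi2@mask, arr.ind = TRUE)
  bbox <- c(diff(range(hits2[, 2])), diff(range(hits2[, 1]))) + 1
  half <- 10 * 1500 / 990 / pixelPitch(spec)
  expected <- round(ctr["col"] + half) - round(ctr["col"] - half) + 1
  expect_equal(unname(bbox), rep(unname(expected), 2))
  expect_true(all(abs(bbox - 20 * 1.5 / pixelPitch(spec)) <= 4))

  # opposing gantry angles see a mirrored footprint of an ROI symmetric
  # about the beam axis (here: vertically symmetric, laterally offset)
  off <- array(FALSE, c(11, 11, 11))
  off[3, c(4, 8), 6] <- TRUE
  a <- projectROI(off, 2, c(-10, -10, -10), 0, spec)@mask
  b <- projectROI(off, 2, c(-10, -10, -10), 180, spec)@mask
  expect_equal(a[, rev(seq_len(ncol(a)))], b)

  expect_error(projectROI(array(FALSE, c(3, 3, 3)), 2, c(0, 0, 0), 0, spec),
               "empty")
})

test_that("reference pairing picks the circularly closest angle within tolerance", {
  # clinical trajectory: ~895 projections -> every frame pairs within 0.202 deg
  angles <- (0:894) * angularSpacing(895)
  refs <- stubRefs(angles)
  for (imr in c(180, 160.3, 99.97, 0.15)) {
    pr <- pairReference(imr, refs)
    expect_false(is.null(pr))
    expect_lt(pr$distance, angularSpacing(895) / 2 + 1e-9)
    expect_lt(pr$distance, 0.202)
  }

  # wraparound: an IMR at 0.0 pairs with a reference at 359.9
  refs2 <- stubRefs(c(10, 180, 359.9))
  pr2 <- pairReference(0, refs2)
  expect_equal(pr2$angle, 359.9)
  expect_equal(pr2$distance, 0.1, tolerance = 1e-9)

  # nothing within tolerance -> NULL
  expect_null(pairReference(90, stubRefs(seq(180, 270, by = 5))))

  # exhaustive-search property: returned distance is the set minimum
  set.seed(21)
  for (i in 1:20) {
    a <- sort(runif(30, 0, 360))
    a <- a[!duplicated(round(a, 6))]
    refs3 <- stubRefs(a)
    q <- runif(1, 0, 360)
    pr3 <- pairReference(q, refs3, tolerance = 360)
    dAll <- pmin(abs(a - q), 360 - abs(a - q))
    expect_equal(pr3$distance, min(dAll), tolerance = 1e-9)
  }
})

test_that("angular spacing and gap diagnostics describe the trajectory", {
  expect_equal(angularSpacing(895), 360 / 895)
  expect_equal(angularSpacing(895), 0.402, tolerance = 1e-3)
  expect_equal(angularSpacing(360), 1)
  expect_equal(angularSpacing(4), 90)
  refs <- stubRefs(c(0, 10, 200, 355))
  expect_equal(sum(referenceGaps(refs)), 360)
})
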