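test_that("beam's-eye-view translation resamples the image as specified", {
  spec <- tinySpec()
  img <- smoothImage(48, 64, seed = 5) * 100

  expect_identical(translateImage(img, c(0, 0), spec), img)

  # 2 mm at iso = 3 px on this detector: exact pixel relabeling
  sh <- translateImage(img, c(2, 0), spec)
  expect_equal(sh[, 4:64], img[, 1:61], tolerance = 1e-14)

  # +d then -d round trip on the interior
  d <- c(1.3, -0.7)
  rt <- translateImage(translateImage(img, d, spec), -d, spec)
  dr <- max(img) - min(img)
  interior <- rt[5:44, 5:60] - img[5:44, 5:60]
  expect_lt(max(abs(interior)) / dr, 0.01)
})

test_that("the NCC objective matches a double-loop oracle and stays in [0,1]", {
  spec <- tinySpec(16L, 12L)
  set.seed(9)
  ref <- matrix(runif(16 * 12, 1, 100), 12, 16)
  live <- matrix(runif(16 * 12, 1, 100), 12, 16)
  mask <- matrix(FALSE, 12, 16); mask[3:10, 4:13] <- TRUE
  for (shift in list(c(0, 0), c(1.5, -0.8), c(-2.25, 0.4))) {
    px <- shift * 1.5  # iso mm -> detector px at pitch 1, magnification 1.5
    expect_equal(nccObjective(ref, live, mask, shift, spec),
                 bruteNCCOracle(ref, live, mask, px[1], px[2]),
                 tolerance = 1e-12)
  }

  # self-correlation is exactly 1; any nonnegative pair stays inside [0,1]
  expect_equal(nccObjective(ref, ref, mask, c(0, 0), spec), 1,
               tolerance = 1e-14)
  for (i in 1:20) {
    a <- matrix(runif(16 * 12, 0, 10^runif(1, 0, 4)), 12, 16)
    b <- matrix(runif(16 * 12, 0, 10^runif(1, 0, 4)), 12, 16)
    v <- nccObjective(a, b, mask, runif(2, -3, 3), spec)
    expect_gte(v, 0); expect_lte(v, 1)
  }

  expect_error(nccObjective(ref, live, matrix(FALSE, 12, 16), c(0, 0), spec),
               "empty")
})

test_that("candidates beyond the capture range score the worst NCC value", {
  spec <- tinySpec(16L, 12L)
  cfg <- RegistrationConfig()
  set.seed(10)
  ref <- matrix(runif(16 * 12, 1, 100), 12, 16)
  mask <- matrix(TRUE, 12, 16)
  expect_equal(penalizedObjective(ref, ref, mask, c(25, 0), cfg, spec), 0)
  expect_equal(penalizedObjective(ref, ref, mask, c(0, -20.01), cfg, spec), 0)
  # the boundary itself is inside the range
  b <- penalizedObjective(ref, ref, mask, c(20, 20), cfg, spec)
  expect_equal(b, nccObjective(ref, ref, mask, c(20, 20), spec))
  expect_equal(penalizedObjective(ref, ref, mask, c(0, 0), cfg, spec), 1,
               tolerance = 1e-14)
})

test_that("the downhill simplex finds closed-form optima and honors rebuilds", {
  # paraboloid with known maximum; default budget (20 iterations, 4
  # rebuilds at the 2 mm initial step) resolves the optimum to a few
  # thousandths of a mm
  f <- function(p) -((p[1] - 3.2)^2 + (p[2] + 1.7)^2)
  r <- downhillSimplex2D(f, c(0, 0))
  expect_lt(sqrt(sum((r$par - c(3.2, -1.7))^2)), 1e-2)

  # with a single long-running simplex it resolves below 1e-3 mm
  r2 <- downhillSimplex2D(f, c(0, 0),
                          RegistrationConfig(maxIter = 200L, maxRebuilds = 0L))
  expect_lt(sqrt(sum((r2$par - c(3.2, -1.7))^2)), 1e-3)

  # a constant objective converges at the first spread check at the start
  rc <- downhillSimplex2D(function(p) 0.5, c(1, 2))
  expect_equal(rc$par, c(1, 2))
  expect_true(rc$converged)
  expect_equal(rc$rebuilds, 0L)
})

test_that("self-registration returns a zero shift with objective 1", {
  bench <- tinyBench()
  i <- which(bench$refs@angles == 180)
  ref <- bench$refs@images[[i]]
  live <- ProjectionImage(ref@pixels, 180, "IMR", beamOn = TRUE)
  roi <- VerteTrack:::roiForAngle(bench$rois, 180)
  res <- registerFrame(ref, live, roi, spec = bench$spec)
  expect_lt(max(abs(res@shift)), 1e-3)
  expect_equal(res@objective, 1, tolerance = 1e-9)
  expect_true(res@converged)
})

test_that("a synthetic in-plane translation is recovered within 0.1 mm", {
  bench <- tinyBench()
  i <- which(bench$refs@angles == 180)
  ref <- bench$refs@images[[i]]
  roi <- VerteTrack:::roiForAngle(bench$rois, 180)
  truth <- c(3.0, -2.0)
  live <- ProjectionImage(translateImage(ref, truth, bench$spec), 180, "IMR",
                          beamOn = TRUE)
  res <- registerFrame(ref, live, roi, spec = bench$spec)
  expect_lt(max(abs(res@shift - truth)), 0.1)
  # monotone improvement over the cold start
  expect_gte(res@objective,
             nccObjective(ref, live, roi, c(0, 0), bench$spec))
})

test_that("registration is deterministic and warm starts reproduce exactly", {
  bench <- tinyBench()
  i <- which(bench$refs@angles == 160)
  ref <- bench$refs@images[[i]]
  roi <- VerteTrack:::roiForAngle(bench$rois, 160)
  live <- ProjectionImage(translateImage(ref, c(1.1, 0.6), bench$spec), 160,
                          "IMR", beamOn = TRUE)
  r1 <- registerFrame(ref, live, roi, spec = bench$spec)
  r2 <- registerFrame(ref, live, roi, spec = bench$spec)
  expect_identical(r1@shift, r2@shift)
  expect_identical(r1@objective, r2@objective)

  # a static frame sequence with warm-start chaining: identical results,
  # per-triplet standard deviation exactly zero
  warm <- NULL
  shifts <- matrix(NA_real_, 3, 2)
  for (k in 1:3) {
    rk <- registerFrame(ref, live, roi, spec = bench$spec, warmStart = warm)
    shifts[k, ] <- rk@shift
    warm <- unname(rk@shift)
  }
  expect_identical(sd(shifts[, 1]), 0)
  expect_identical(sd(shifts[, 2]), 0)
})

test_that("the simplex matches the exhaustive-grid oracle on random instances", {
  spec <- tinySpec()
  set.seed(77)
  for (i in 1:20) {
    img <- blobImage(48, 64, seed = 100 + i)
    truth <- runif(2, -3, 3)
    live <- translateImage(img, truth, spec)
    mask <- matrix(FALSE, 48, 64); mask[9:40, 13:52] <- TRUE
    ref <- ProjectionImage(img, 0, "CBCT")
    liveIm <- ProjectionImage(pmax(live, 0), 0, "IMR", beamOn = TRUE)
    bf <- bruteForceRegister(ref, liveIm, mask, spec, step = 1, range = 5)
    sx <- registerFrame(ref, liveIm, mask, spec = spec)
    expect_gte(sx@objective, bf$value - 1e-6)
    expect_lt(max(abs(sx@shift - bf$shift)), 1 + 1e-9)
  }

  # trivial oracle cases
  img <- smoothImage(48, 64, seed = 1) * 50
  ref <- ProjectionImage(img, 0, "CBCT")
  bf0 <- bruteForceRegister(ref, ref, matrix(TRUE, 48, 64), spec,
                            step = 1, range = 3)
  expect_equal(unname(bf0$shift), c(0, 0))
  # a 3 px = 2 mm integer-pixel shift is recovered exactly on a 1 mm grid
  liv <- ProjectionImage(translateImage(img, c(2, 0), spec), 0, "IMR",
                         beamOn = TRUE)
  bf1 <- bruteForceRegister(ref, liv, matrix(TRUE, 48, 64), spec,
                            step = 1, range = 4)
  expect_equal(unname(bf1$shift), c(2, 0))
})

test_that("reported shifts never exceed the capture range", {
  spec <- tinySpec()
  cfg <- RegistrationConfig(captureRange = 4)
  img <- smoothImage(48, 64, seed = 50) * 50 + 5
  # true displacement far outside the 4 mm capture range
  live <- translateImage(img, c(12, 0), spec)
  ref <- ProjectionImage(img, 0, "CBCT")
  liveIm <- ProjectionImage(pmax(live, 0), 0, "IMR", beamOn = TRUE)
  res <- registerFrame(ref, liveIm, matrix(TRUE, 48, 64), cfg, spec)
  expect_true(all(abs(res@shift) <= cfg@captureRange + 1e-12))
})
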