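sessionFixture <- function() {
  bench <- tinyBench()
  TrackingSession(bench$spec, bench$rois, tolerance = 2)
}

test_that("only the clinical mode sequence is allowed", {
  s <- sessionFixture()
  expect_error(setMode(s, "TRACKING"), "illegal|reference")
  expect_error(setMode(s, "EDIT_ROI"), "illegal")
  s <- setMode(s, "CBCT")
  expect_error(setMode(s, "CBCT"), "illegal")
  # TRACKING needs references even though CBCT -> TRACKING is a legal edge
  expect_error(setMode(s, "TRACKING"), "reference")

  # fuzz random transition sequences: the session never reaches a state
  # its transition graph forbids
  legal <- list(IDLE = c("IDLE", "CBCT"),
                CBCT = c("IDLE", "EDIT_ROI", "TRACKING"),
                EDIT_ROI = c("IDLE", "TRACKING"),
                TRACKING = "IDLE")
  set.seed(13)
  modes <- c("IDLE", "CBCT", "EDIT_ROI", "TRACKING")
  s <- sessionFixture()
  for (i in 1:200) {
    target <- sample(modes, 1)
    ok <- target %in% legal[[s@mode]] &&
      !(target == "TRACKING" && length(s@refImages) == 0)
    if (ok) {
      s <- setMode(s, target)
      expect_equal(s@mode, target)
    } else {
      expect_error(setMode(s, target))
    }
  }
})

test_that("frames are routed by mode and tracking uses warm starts", {
  bench <- tinyBench()
  s <- TrackingSession(bench$spec, bench$rois, tolerance = 2)
  s <- setMode(s, "CBCT")
  for (im in bench$refs@images) s <- ingestFrame(s, im)
  expect_equal(length(s@refImages), length(bench$refs@images))

  s <- setMode(s, "EDIT_ROI")
  s <- setMode(s, "TRACKING")

  pose <- Pose6D(tLat = 1.5, tLong = -1.0)
  dark <- uniformFrame(1, nr = bench$spec@nRows, nc = bench$spec@nCols,
                       gantry = 180)
  mkFrame <- function(angle, idx)
    simulateIMR(bench$phantom, pose, angle, bench$spec, index = idx)

  # unqualified frames (beam off / dark) leave no record
  off <- mkFrame(180, 1L); off@beamOn <- FALSE
  s <- ingestFrame(s, off)
  expect_equal(nrow(sessionLog(s)), 0)

  for (k in 1:3) {
    s <- ingestFrame(s, dark)                      # re-arm between pulses
    s <- ingestFrame(s, mkFrame(180, k))
  }
  log <- sessionLog(s)
  expect_equal(nrow(log), 3)
  expect_lt(max(abs(log$ref_angle_deg - 180)), 0.75)
  # static pose + warm start: identical results, std exactly 0
  expect_identical(sd(log$x_mm), 0)
  expect_identical(sd(log$y_mm), 0)
  expect_false(any(log$alert))
  # reported shift tracks the beam's-eye-view truth
  gt <- bevGroundTruth(c(1.5, 0, -1.0), 180)
  expect_lt(max(abs(c(log$x_mm[1], log$y_mm[1]) - gt)), 0.3)
})

test_that("replaying the same frame stream yields an identical log", {
  bench <- tinyBench()
  run <- function() {
    s <- TrackingSession(bench$spec, bench$rois, tolerance = 2)
    s <- setMode(s, "CBCT")
    for (im in bench$refs@images) s <- ingestFrame(s, im)
    s <- setMode(s, "TRACKING")
    dark <- uniformFrame(1, nr = bench$spec@nRows, nc = bench$spec@nCols,
                         gantry = 160)
    for (k in 1:2) {
      s <- ingestFrame(s, dark)
      s <- ingestFrame(s, simulateIMR(bench$phantom, Pose6D(tLong = 2), 160,
                                      bench$spec, index = k))
    }
    sessionLog(s)
  }
  expect_identical(run(), run())
})

test_that("tolerance alerts fire on strict per-axis exceedance", {
  res <- new("TrackingResult", shift = c(x = 0.2, y = 0.1), objective = 0.9,
             converged = TRUE, rebuilds = 0L)
  expect_false(checkTolerance(res, 2))
  res@shift <- c(x = 0, y = 2.5)
  expect_true(checkTolerance(res, 2))
  res@shift <- c(x = 2, y = 2)       # exactly at tolerance: no alert
  expect_false(checkTolerance(res, 2))
  expect_error(checkTolerance(res, 0))
})

test_that("ROI edits are pixel-set operations that preserve non-emptiness", {
  roi <- fullROI(8, 8)
  expect_identical(editROI(roi)@mask, roi@mask)

  rm <- matrix(FALSE, 8, 8); rm[1:4, ] <- TRUE
  edited <- editROI(roi, remove = rm)
  expect_equal(sum(edited@mask), 32)
  # add back the removed pixels: inverse operation restores the template
  restored <- editROI(edited, add = rm)
  expect_identical(restored@mask, roi@mask)

  expect_error(editROI(roi, remove = matrix(TRUE, 8, 8)), "empty")

  # session-level editing is gated on EDIT_ROI mode and persists
  bench <- tinyBench()
  s <- TrackingSession(bench$spec, bench$rois)
  expect_error(editSessionROI(s, 1, remove = rm), "EDIT_ROI")
})

test_that("the session log round-trips through CSV", {
  bench <- tinyBench()
  s <- TrackingSession(bench$spec, bench$rois)
  s@log <- data.frame(frame_index = 1L, gantry_deg = 180, ref_angle_deg = 180,
                      x_mm = 0.5, y_mm = -0.25, ncc = 0.99, converged = TRUE,
                      alert = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSessionLog(s, path)
  back <- read.csv(path)
  expect_equal(back, s@log)
})
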