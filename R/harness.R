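#' Expand a schedule into scheduled IMR acquisitions
#'
#' @param schedule an [IMRTSchedule-class] or [VMATSchedule-class]
#' @return data.frame with columns `beam`, `angle`, `image` (image index
#'   within the beam/arc)
#' @export
scheduleAngles <- function(schedule) {
  if (is(schedule, "IMRTSchedule")) {
    k <- schedule@imagesPerBeam
    return(data.frame(
      beam = rep(seq_along(schedule@angles), each = k),
      angle = normalizeAngle(rep(schedule@angles, each = k)),
      image = rep(seq_len(k), length(schedule@angles))))
  }
  stopifnot(is(schedule, "VMATSchedule"))
  rows <- lapply(seq_along(schedule@arcs), function(i) {
    arc <- schedule@arcs[[i]]
    travel <- abs(arc[2] - arc[1])
    k <- floor(travel / schedule@triggerInterval)
    ang <- arc[1] + sign(arc[2] - arc[1]) *
      schedule@triggerInterval * (0:k)
    data.frame(beam = i, angle = normalizeAngle(ang),
               image = seq_along(ang))
  })
  do.call(rbind, rows)
}

#' Build the standard tracking test bench
#'
#' Convenience constructor for the synthetic evaluation protocol: the
#' default spine phantom, a reduced-scale detector, the noiseless
#' reference scan, and per-angle ROI templates for a schedule's angles.
#'
#' @param spec a [DetectorSpec-class]; the default is the clinical
#'   geometry sampled on a 256 x 192 grid
#' @param nProjections reference projections over 360 degrees
#' @param phantom optional prebuilt [PhantomVolume-class]
#' @param angles gantry angles needing ROI templates (defaults to the
#'   IMRT beam angles)
#' @param noise optional [NoiseModel-class] for the reference scan
#' @return list with `phantom`, `spec`, `refs` ([ReferenceSet-class]),
#'   `rois` (list of [ROITemplate-class]), `roiMask` (3D planning mask)
#' @export
trackingTestBench <- function(spec = DetectorSpec(256L, 192L, 397, 298,
                                                  1500, 1000),
                              nProjections = 90, phantom = NULL,
                              angles = IMRTSchedule()@angles,
                              noise = NULL) {
  if (is.null(phantom)) phantom <- buildSpinePhantom()
  refs <- simulateCBCT(phantom, spec, nProjections, noise = noise)
  roiMask <- trackedVertebraMask(phantom)
  rois <- lapply(normalizeAngle(angles), function(a)
    projectROI(roiMask, phantom@spacing, phantom@origin, a, spec))
  list(phantom = phantom, spec = spec, refs = refs, rois = rois,
       roiMask = roiMask)
}

registerScheduled <- function(bench, pose, sched, truthPose = pose,
                              cfg = RegistrationConfig(), noise = NULL,
                              pairingTolerance = 0.75) {
  warm <- NULL
  out <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    a <- sched$angle[i]
    ni <- noise
    if (!is.null(ni)) ni@seed <- ni@seed + i
    live <- simulateIMR(bench$phantom, pose, a, bench$spec, beamOn = TRUE,
                        noise = ni, index = i)
    pair <- pairReference(a, bench$refs, pairingTolerance)
    if (is.null(pair)) stop("no reference within the pairing window")
    roi <- roiForAngle(bench$rois, a)
    res <- registerFrame(pair$image, live, roi, cfg, bench$spec,
                         warmStart = warm)
    warm <- unname(res@shift)
    gt <- bevGroundTruth(c(truthPose@tLat, truthPose@tVert, truthPose@tLong), a)
    out[[i]] <- data.frame(
      beam = sched$beam[i], angle = a, image = sched$image[i],
      axis = c("x", "y"),
      truth = unname(gt), reported = unname(res@shift),
      error = unname(res@shift - gt), ncc = res@objective,
      converged = res@converged, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Run a translation test series
#'
#' For each 3D couch shift: the reference set is rendered at identity
#' pose (once, in the bench), IMR frames are rendered at the shifted pose
#' per the schedule and registered with warm-start chaining, and the
#' per-axis error is the reported shift minus the beam's-eye-view
#' projection of the applied 3D shift at that gantry angle.
#'
#' @param shifts numeric matrix (cases x 3: lateral, vertical,
#'   longitudinal, mm), or a vector of magnitudes applied to all three
#'   axes at once
#' @param schedule an [IMRTSchedule-class] or [VMATSchedule-class]
#' @param bench a [trackingTestBench()] result
#' @param cfg a [RegistrationConfig-class]
#' @param noise optional [NoiseModel-class] for the IMR frames
#' @return data.frame with columns `case`, `beam`, `angle`, `image`,
#'   `axis`, `truth`, `reported`, `error`, `ncc`, `converged`
#' @export
runTranslationSeries <- function(shifts, schedule = IMRTSchedule(),
                                 bench = trackingTestBench(),
                                 cfg = RegistrationConfig(), noise = NULL) {
  if (is.null(dim(shifts))) shifts <- cbind(shifts, shifts, shifts)
  sched <- scheduleAngles(schedule)
  out <- lapply(seq_len(nrow(shifts)), function(i) {
    pose <- Pose6D(tLat = shifts[i, 1], tVert = shifts[i, 2],
                   tLong = shifts[i, 3])
    ni <- noise
    if (!is.null(ni)) ni@seed <- ni@seed + 1000L * i
    cbind(case = i, registerScheduled(bench, pose, sched, cfg = cfg,
                                      noise = ni))
  })
  do.call(rbind, out)
}

#' Run a rotation/pitch/roll tolerance series
#'
#' Adds an unmodeled rigid rotation to a base translational shift and
#' registers the scheduled frames; errors are computed against the
#' pure-translation ground truth (as if no rotation were applied), which
#' quantifies how much an in-plane-only tracker is perturbed by rotation.
#'
#' @param degrees numeric vector of rotation magnitudes (degrees); signed
#'   values are allowed (negating the rotation mirrors the error pattern)
#' @param axis one of "rotation" (yaw), "pitch", "roll"
#' @param baseShift numeric (lateral, vertical, longitudinal) mm
#' @inheritParams runTranslationSeries
#' @return data.frame as in [runTranslationSeries()], plus a `degrees`
#'   column
#' @export
runRotationSeries <- function(degrees, axis = c("rotation", "pitch", "roll"),
                              baseShift = c(5, 5, 5),
                              schedule = IMRTSchedule(),
                              bench = trackingTestBench(),
                              cfg = RegistrationConfig(), noise = NULL) {
  axis <- match.arg(axis)
  sched <- scheduleAngles(schedule)
  truthPose <- Pose6D(tLat = baseShift[1], tVert = baseShift[2],
                      tLong = baseShift[3])
  out <- lapply(seq_along(degrees), function(i) {
    args <- list(tLat = baseShift[1], tVert = baseShift[2],
                 tLong = baseShift[3])
    args[[switch(axis, rotation = "rotation", pitch = "pitch",
                 roll = "roll")]] <- degrees[i]
    pose <- do.call(Pose6D, args)
    ni <- noise
    if (!is.null(ni)) ni@seed <- ni@seed + 1000L * i
    cbind(degrees = degrees[i],
          registerScheduled(bench, pose, sched, truthPose = truthPose,
                            cfg = cfg, noise = ni))
  })
  do.call(rbind, out)
}

#' Per-triplet and summary error statistics
#'
#' Per (case, beam, axis) triplet: the sample (n-1) standard deviation of
#' the repeated registrations of a static pose. Per axis and pooled: the
#' maximum and the nearest-rank 95th percentile of the absolute errors.
#'
#' @param errors data.frame with columns `case` (optional), `beam`,
#'   `axis`, `image`, `error`
#' @return list with `tripletStd` (data.frame case/beam/axis/std) and
#'   `summary` (data.frame axis/max/p95, including a pooled "both" row)
#' @export
computeErrorStats <- function(errors) {
  stopifnot(nrow(errors) > 0)
  if (is.null(errors$case)) errors$case <- 1L
  key <- interaction(errors$case, errors$beam, errors$axis, drop = TRUE)
  std <- tapply(errors$error, key, stats::sd)
  ids <- do.call(rbind, strsplit(names(std), ".", fixed = TRUE))
  tripletStd <- data.frame(case = ids[, 1], beam = ids[, 2],
                           axis = ids[, 3], std = as.numeric(std))
  nearestRank <- function(v, p) {
    s <- sort(abs(v))
    s[max(1L, ceiling(p * length(s)))]
  }
  one <- function(v) c(max = max(abs(v)), p95 = nearestRank(v, 0.95))
  byAxis <- tapply(errors$error, errors$axis, one)
  summary <- data.frame(
    axis = c(names(byAxis), "both"),
    max = c(vapply(byAxis, `[[`, numeric(1), "max"), max(abs(errors$error))),
    p95 = c(vapply(byAxis, `[[`, numeric(1), "p95"),
            nearestRank(errors$error, 0.95)))
  rownames(summary) <- NULL
  list(tripletStd = tripletStd, summary = summary)
}

#' The 50-test repeatability suite layout
#'
#' The full intrafraction repeatability protocol: five translational cases
#' (no shift and 5 mm along each single axis and all axes) crossed with no
#' rotation plus 1, 2, 3 degrees of each of rotation, pitch, and roll —
#' 50 tests, each imaged per the schedule.
#'
#' @return data.frame with one row per test: `test`, `shiftCase`,
#'   `rotAxis` ("none", "rotation", "pitch", "roll"), `rotDeg`, and the
#'   shift components `tLat`, `tVert`, `tLong`
#' @export
repeatabilitySuiteLayout <- function() {
  shifts <- rbind(c(0, 0, 0), c(0, 0, 5), c(0, 5, 0), c(5, 0, 0), c(5, 5, 5))
  shiftNames <- c("none", "long5", "vert5", "lat5", "all5")
  rot <- rbind(data.frame(rotAxis = "none", rotDeg = 0),
               expand.grid(rotAxis = c("rotation", "pitch", "roll"),
                           rotDeg = c(1, 2, 3), stringsAsFactors = FALSE))
  grid <- expand.grid(shiftCase = seq_len(5), rotCase = seq_len(nrow(rot)))
  data.frame(test = seq_len(nrow(grid)),
             shiftCase = shiftNames[grid$shiftCase],
             rotAxis = rot$rotAxis[grid$rotCase],
             rotDeg = rot$rotDeg[grid$rotCase],
             tLat = shifts[grid$shiftCase, 1],
             tVert = shifts[grid$shiftCase, 2],
             tLong = shifts[grid$shiftCase, 3])
}

#' Run the repeatability suite
#'
#' Executes the 50-test layout against a schedule and returns the error
#' table ready for [computeErrorStats()]. With the default IMRT schedule
#' (nine beams, three images each) the per-triplet standard deviations
#' number tests x beams x axes = 50 x 9 x 2 = 900.
#'
#' For bookkeeping or statistics work the registrations can be replaced
#' by an injected `registerFn(test, angle, image, truth)` returning the
#' reported (x, y) shift, which skips all rendering.
#'
#' @param schedule an [IMRTSchedule-class] or [VMATSchedule-class]
#' @param bench a [trackingTestBench()] result (not needed with
#'   `registerFn`)
#' @param cfg a [RegistrationConfig-class]
#' @param noise optional [NoiseModel-class]
#' @param registerFn optional mock registration function
#' @param layout test layout, defaulting to [repeatabilitySuiteLayout()]
#' @return data.frame with columns `case`, `beam`, `angle`, `image`,
#'   `axis`, `truth`, `reported`, `error`
#' @export
runRepeatabilitySuite <- function(schedule = IMRTSchedule(), bench = NULL,
                                  cfg = RegistrationConfig(), noise = NULL,
                                  registerFn = NULL,
                                  layout = repeatabilitySuiteLayout()) {
  sched <- scheduleAngles(schedule)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    row <- layout[i, ]
    if (!is.null(registerFn)) {
      recs <- lapply(seq_len(nrow(sched)), function(j) {
        truth <- bevGroundTruth(c(row$tLat, row$tVert, row$tLong),
                                sched$angle[j])
        rep2 <- registerFn(row$test, sched$angle[j], sched$image[j], truth)
        data.frame(beam = sched$beam[j], angle = sched$angle[j],
                   image = sched$image[j], axis = c("x", "y"),
                   truth = unname(truth), reported = unname(rep2),
                   error = unname(rep2 - truth), row.names = NULL)
      })
      return(cbind(case = row$test, do.call(rbind, recs)))
    }
    args <- list(tLat = row$tLat, tVert = row$tVert, tLong = row$tLong)
    if (row$rotAxis != "none") args[[row$rotAxis]] <- row$rotDeg
    pose <- do.call(Pose6D, args)
    truthPose <- Pose6D(tLat = row$tLat, tVert = row$tVert, tLong = row$tLong)
    ni <- noise
    if (!is.null(ni)) ni@seed <- ni@seed + 1000L * i
    cbind(case = row$test,
          registerScheduled(bench, pose, sched, truthPose = truthPose,
                            cfg = cfg, noise = ni))
  })
  do.call(rbind, out)
}
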