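#' @import methods
NULL

#' Flat-panel detector and cone-beam imaging geometry
#'
#' Describes the on-board kV imager: pixel array, active area, and the
#' source-to-imager (SID) and source-to-axis (SAD) distances. The defaults
#' match a 1024 x 768 panel with a 39.7 x 29.8 cm active area operated at
#' 150 cm SID and 100 cm SAD, so the geometric magnification of the
#' isocenter plane is SID/SAD = 1.5.
#'
#' @slot nCols,nRows integer, detector pixel array size
#' @slot activeWidth,activeHeight numeric, active area in mm
#' @slot sid,sad numeric, source-to-imager and source-to-axis distances (mm)
#' @export
setClass("DetectorSpec",
  representation(nCols = "integer", nRows = "integer",
                 activeWidth = "numeric", activeHeight = "numeric",
                 sid = "numeric", sad = "numeric"),
  prototype(nCols = 1024L, nRows = 768L, activeWidth = 397, activeHeight = 298,
            sid = 1500, sad = 1000))

setValidity("DetectorSpec", function(object) {
  v <- c(object@nCols, object@nRows, object@activeWidth, object@activeHeight,
         object@sid, object@sad)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all detector dimensions and distances must be finite and positive")
  colPitch <- object@activeWidth / object@nCols
  rowPitch <- object@activeHeight / object@nRows
  if (abs(colPitch - rowPitch) / colPitch > 0.01)
    return("pixels must be square within 1% (column pitch vs row pitch)")
  if (object@sid <= object@sad)
    return("sid must exceed sad (detector beyond the isocenter)")
  TRUE
})

#' Construct a DetectorSpec
#'
#' @param nCols,nRows detector pixel array size
#' @param activeWidth,activeHeight active imaging area (mm)
#' @param sid,sad source-to-imager / source-to-axis distances (mm)
#' @return a [DetectorSpec-class] object
#' @examples
#' spec <- DetectorSpec()
#' pixelPitch(spec)
#' @export
DetectorSpec <- function(nCols = 1024L, nRows = 768L,
                         activeWidth = 397, activeHeight = 298,
                         sid = 1500, sad = 1000) {
  new("DetectorSpec", nCols = as.integer(nCols), nRows = as.integer(nRows),
      activeWidth = activeWidth, activeHeight = activeHeight,
      sid = sid, sad = sad)
}

#' A single 2D projection image with acquisition metadata
#'
#' Plays both roles in the tracking objective: the reference projection
#' (one frame of the setup CBCT scan) and the live intrafraction motion
#' review (IMR) image.
#'
#' @slot pixels numeric matrix (nRows x nCols), nonnegative intensities
#' @slot gantry numeric, gantry angle in degrees, normalized to [0, 360)
#' @slot kind `"CBCT"` (reference projection) or `"IMR"` (live frame)
#' @slot beamOn logical, treatment beam state when the frame was grabbed
#' @slot index integer acquisition sequence number
#' @export
setClass("ProjectionImage",
  representation(pixels = "matrix", gantry = "numeric", kind = "character",
                 beamOn = "logical", index = "integer"),
  prototype(gantry = 0, kind = "CBCT", beamOn = FALSE, index = 0L))

setValidity("ProjectionImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (any(!is.finite(object@pixels))) return("pixel intensities must be finite")
  if (any(object@pixels < 0)) return("pixel intensities must be >= 0")
  if (!object@kind %in% c("CBCT", "IMR")) return("kind must be 'CBCT' or 'IMR'")
  if (object@gantry < 0 || object@gantry >= 360)
    return("gantry angle must be normalized to [0, 360)")
  TRUE
})

#' Construct a ProjectionImage
#'
#' @param pixels numeric matrix of nonnegative intensities (rows x cols)
#' @param gantry gantry angle in degrees (normalized modulo 360)
#' @param kind `"CBCT"` or `"IMR"`
#' @param beamOn logical beam-on flag
#' @param index acquisition sequence number
#' @return a [ProjectionImage-class]
#' @export
ProjectionImage <- function(pixels, gantry = 0, kind = c("CBCT", "IMR"),
                            beamOn = FALSE, index = 0L) {
  kind <- match.arg(kind)
  new("ProjectionImage", pixels = pixels, gantry = normalizeAngle(gantry),
      kind = kind, beamOn = beamOn, index = as.integer(index))
}

#' Per-gantry-angle binary tracking mask on the detector grid
#'
#' The region of interest restricting the registration objective to the
#' vertebrae being monitored, stored on the detector pixel grid for one
#' reference gantry angle.
#'
#' @slot mask logical matrix (nRows x nCols)
#' @slot angle numeric gantry angle in degrees
#' @export
setClass("ROITemplate",
  representation(mask = "matrix", angle = "numeric"),
  prototype(angle = 0))

setValidity("ROITemplate", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("ROI mask must be non-empty")
  TRUE
})

#' Construct an ROITemplate
#' @param mask logical matrix on the detector grid; must contain TRUE pixels
#' @param angle gantry angle (degrees) the mask was projected for
#' @return an [ROITemplate-class]
#' @export
ROITemplate <- function(mask, angle = 0) {
  new("ROITemplate", mask = mask, angle = normalizeAngle(angle))
}

#' An angle-indexed set of reference projections
#'
#' The reference projections of one full-trajectory CBCT scan, ordered by
#' gantry angle over a single revolution. Serves as the template library
#' that live IMR frames are paired against.
#'
#' @slot angles numeric vector of gantry angles, strictly increasing in
#'   [0, 360)
#' @slot images list of [ProjectionImage-class], parallel to `angles`
#' @export
setClass("ReferenceSet",
  representation(angles = "numeric", images = "list"))

setValidity("ReferenceSet", function(object) {
  if (length(object@angles) != length(object@images))
    return("angles and images must have equal length")
  if (length(object@angles) == 0) return("reference set must be non-empty")
  if (any(object@angles < 0 | object@angles >= 360))
    return("angles must be normalized to [0, 360)")
  if (is.unsorted(object@angles, strictly = TRUE))
    return("angles must be strictly increasing")
  TRUE
})

#' Construct a ReferenceSet
#' @param images list of [ProjectionImage-class] reference projections
#' @return a [ReferenceSet-class] with images sorted by gantry angle
#' @export
ReferenceSet <- function(images) {
  ang <- vapply(images, function(im) im@gantry, numeric(1))
  o <- order(ang)
  new("ReferenceSet", angles = ang[o], images = images[o])
}

#' Voxelized attenuation phantom
#'
#' A 3D grid of linear attenuation coefficients in its own (phantom) frame;
#' a rigid 6-DoF pose places it in the isocenter-centered world frame at
#' render time. The source of all synthetic projections.
#'
#' @slot mu 3D numeric array of linear attenuation coefficients (1/mm),
#'   indexed \[x, y, z\] = \[lateral, vertical, longitudinal\]
#' @slot spacing voxel size (mm, isotropic)
#' @slot origin phantom-frame position (mm) of the center of voxel
#'   \[1, 1, 1\] relative to the isocenter at identity pose
#' @export
setClass("PhantomVolume",
  representation(mu = "array", spacing = "numeric", origin = "numeric"))

setValidity("PhantomVolume", function(object) {
  if (length(dim(object@mu)) != 3) return("mu must be a 3D array")
  if (any(!is.finite(object@mu)) || any(object@mu < 0))
    return("mu must be finite and >= 0 everywhere")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive value")
  if (length(object@origin) != 3) return("origin must have 3 components")
  TRUE
})

#' Rigid 6-DoF pose of the phantom
#'
#' Couch-style rigid motion: rotations about the isocenter applied in the
#' order rotation (yaw, about the vertical axis), then pitch (about the
#' lateral axis), then roll (about the longitudinal axis), followed by the
#' translation. The identity pose is all zeros.
#'
#' @slot tLat,tLong,tVert translations (mm) along the lateral,
#'   longitudinal (superior-inferior) and vertical axes
#' @slot rotation,pitch,roll rotations (degrees) about the vertical,
#'   lateral and longitudinal axes
#' @export
setClass("Pose6D",
  representation(tLat = "numeric", tLong = "numeric", tVert = "numeric",
                 rotation = "numeric", pitch = "numeric", roll = "numeric"),
  prototype(tLat = 0, tLong = 0, tVert = 0, rotation = 0, pitch = 0, roll = 0))

setValidity("Pose6D", function(object) {
  v <- c(object@tLat, object@tLong, object@tVert,
         object@rotation, object@pitch, object@roll)
  if (length(v) != 6 || any(!is.finite(v))) return("pose components must be finite scalars")
  TRUE
})

#' Construct a Pose6D
#' @param tLat,tLong,tVert translations in mm
#' @param rotation,pitch,roll rotations in degrees (yaw / pitch / roll)
#' @return a [Pose6D-class]
#' @export
Pose6D <- function(tLat = 0, tLong = 0, tVert = 0,
                   rotation = 0, pitch = 0, roll = 0) {
  new("Pose6D", tLat = tLat, tLong = tLong, tVert = tVert,
      rotation = rotation, pitch = pitch, roll = roll)
}

#' Poisson photon-counting noise model
#'
#' @slot photonsAtAir expected photon count through air per pixel
#' @slot seed integer RNG seed; identical seeds give identical images
#' @export
setClass("NoiseModel",
  representation(photonsAtAir = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (object@photonsAtAir <= 0) return("photonsAtAir must be > 0")
  if (length(object@seed) != 1 || is.na(object@seed)) return("seed is required")
  TRUE
})

#' Construct a NoiseModel
#' @param photonsAtAir expected photons per pixel through air
#' @param seed integer seed (required, for reproducibility)
#' @return a [NoiseModel-class]
#' @export
NoiseModel <- function(photonsAtAir = 1e5, seed) {
  new("NoiseModel", photonsAtAir = photonsAtAir, seed = as.integer(seed))
}

#' Optimizer constants for the 2D registration
#'
#' @slot stepInit initial simplex step size (mm; the Delta-s of the method)
#' @slot tol dimensionless relative-spread stopping tolerance (sigma)
#' @slot maxIter iterations per simplex before a rebuild (N)
#' @slot maxRebuilds maximum number of simplex rebuilds (n)
#' @slot captureRange maximum reportable per-axis shift (mm); vertices
#'   outside it score the worst objective value (0)
#' @slot interpolation resampling scheme id (only "bilinear" implemented)
#' @slot zeroMean if TRUE the objective subtracts ROI means before
#'   correlating; default FALSE (plain normalized cross-correlation)
#' @export
setClass("RegistrationConfig",
  representation(stepInit = "numeric", tol = "numeric", maxIter = "integer",
                 maxRebuilds = "integer", captureRange = "numeric",
                 interpolation = "character", zeroMean = "logical"),
  prototype(stepInit = 2, tol = 1e-6, maxIter = 20L, maxRebuilds = 4L,
            captureRange = 20, interpolation = "bilinear", zeroMean = FALSE))

setValidity("RegistrationConfig", function(object) {
  if (object@stepInit <= 0) return("stepInit must be > 0")
  if (object@tol <= 0 || object@tol >= 1) return("tol must be in (0, 1)")
  if (object@maxIter < 1) return("maxIter must be >= 1")
  if (object@maxRebuilds < 0) return("maxRebuilds must be >= 0")
  if (object@captureRange <= 0) return("captureRange must be > 0")
  if (!object@interpolation %in% "bilinear")
    return("only bilinear interpolation is implemented")
  TRUE
})

#' Construct a RegistrationConfig
#' @param stepInit initial simplex step (mm)
#' @param tol relative-spread stopping tolerance
#' @param maxIter iterations per simplex before a rebuild
#' @param maxRebuilds maximum simplex rebuilds
#' @param captureRange maximum per-axis shift (mm)
#' @param interpolation resampling scheme ("bilinear")
#' @param zeroMean use zero-mean correlation instead of the plain form
#' @return a [RegistrationConfig-class]
#' @export
RegistrationConfig <- function(stepInit = 2, tol = 1e-6, maxIter = 20L,
                               maxRebuilds = 4L, captureRange = 20,
                               interpolation = "bilinear", zeroMean = FALSE) {
  new("RegistrationConfig", stepInit = stepInit, tol = tol,
      maxIter = as.integer(maxIter), maxRebuilds = as.integer(maxRebuilds),
      captureRange = captureRange, interpolation = interpolation,
      zeroMean = zeroMean)
}

#' Frame-qualification thresholds
#'
#' Decides which grabbed frames become reference projections (mean ROI
#' intensity strictly above `cbctMinMean`) or tracked IMR frames (beam on,
#' mean inside `[imrMinMean, imrMaxMean]`, and mean strictly greater than
#' `imrPrevRatio` times the previous grabbed frame's mean).
#'
#' @slot cbctMinMean minimum mean ROI intensity for a reference frame
#' @slot imrMinMean,imrMaxMean inclusive mean-intensity window for IMR frames
#' @slot imrPrevRatio required ratio over the previous frame's mean
#' @export
setClass("FilterConfig",
  representation(cbctMinMean = "numeric", imrMinMean = "numeric",
                 imrMaxMean = "numeric", imrPrevRatio = "numeric"),
  prototype(cbctMinMean = 40, imrMinMean = 1500, imrMaxMean = 2e5,
            imrPrevRatio = 2))

setValidity("FilterConfig", function(object) {
  if (object@cbctMinMean < 0) return("cbctMinMean must be >= 0")
  if (object@imrMinMean >= object@imrMaxMean)
    return("imrMinMean must be < imrMaxMean")
  if (object@imrPrevRatio <= 1) return("imrPrevRatio must be > 1")
  TRUE
})

#' Construct a FilterConfig
#' @param cbctMinMean reference-frame mean threshold (strict)
#' @param imrMinMean,imrMaxMean IMR mean window (inclusive)
#' @param imrPrevRatio required multiple of the previous frame's mean (strict)
#' @return a [FilterConfig-class]
#' @export
FilterConfig <- function(cbctMinMean = 40, imrMinMean = 1500,
                         imrMaxMean = 2e5, imrPrevRatio = 2) {
  new("FilterConfig", cbctMinMean = cbctMinMean, imrMinMean = imrMinMean,
      imrMaxMean = imrMaxMean, imrPrevRatio = imrPrevRatio)
}

#' Result of one 2D/2D registration
#'
#' @slot shift named numeric (x, y): the reported 2D shift in mm, in the
#'   beam's-eye view at the isocenter plane
#' @slot objective normalized cross-correlation value at the optimum, in
#'   \[0, 1\]
#' @slot converged logical, whether the relative-spread criterion was met
#' @slot rebuilds number of simplex rebuilds used
#' @slot refAngle gantry angle of the paired reference projection (degrees)
#' @slot imrIndex acquisition index of the registered IMR frame
#' @export
setClass("TrackingResult",
  representation(shift = "numeric", objective = "numeric",
                 converged = "logical", rebuilds = "integer",
                 refAngle = "numeric", imrIndex = "integer"),
  prototype(refAngle = NA_real_, imrIndex = NA_integer_))

setValidity("TrackingResult", function(object) {
  if (length(object@shift) != 2 || any(!is.finite(object@shift)))
    return("shift must be two finite values")
  if (object@objective < 0 || object@objective > 1 + 1e-12)
    return("objective must lie in [0, 1]")
  TRUE
})

#' Fixed-gantry (IMRT) imaging schedule
#'
#' @slot angles gantry angles of the posterior beams (degrees)
#' @slot imagesPerBeam IMR frames acquired during each beam
#' @export
setClass("IMRTSchedule",
  representation(angles = "numeric", imagesPerBeam = "integer"),
  prototype(angles = c(180, 160, 140, 120, 100, 260, 240, 220, 200),
            imagesPerBeam = 3L))

setValidity("IMRTSchedule", function(object) {
  if (object@imagesPerBeam < 1) return("imagesPerBeam must be >= 1")
  if (length(object@angles) < 1) return("at least one beam angle required")
  TRUE
})

#' Construct an IMRTSchedule
#' @param angles gantry angles in degrees
#' @param imagesPerBeam IMR frames per beam
#' @return an [IMRTSchedule-class]
#' @export
IMRTSchedule <- function(angles = c(180, 160, 140, 120, 100, 260, 240, 220, 200),
                         imagesPerBeam = 3L) {
  new("IMRTSchedule", angles = angles, imagesPerBeam = as.integer(imagesPerBeam))
}

#' Arc (VMAT) imaging schedule
#'
#' Each arc is a (start, stop) gantry pair; IMR frames are triggered every
#' `triggerInterval` degrees of gantry travel starting at the arc's first
#' angle.
#'
#' @slot arcs list of numeric (start, stop) gantry pairs (degrees)
#' @slot triggerInterval trigger spacing in degrees of gantry travel
#' @export
setClass("VMATSchedule",
  representation(arcs = "list", triggerInterval = "numeric"),
  prototype(triggerInterval = 15))

setValidity("VMATSchedule", function(object) {
  if (length(object@arcs) < 1) return("at least one arc required")
  ok <- vapply(object@arcs, function(a) length(a) == 2 && all(is.finite(a)),
               logical(1))
  if (!all(ok)) return("each arc must be a finite (start, stop) pair")
  if (object@triggerInterval <= 0) return("triggerInterval must be > 0")
  TRUE
})

#' Construct a VMATSchedule
#'
#' The default ships four partial posterior arcs (110 to 179, 179 to 110,
#' 181 to 250, 250 to 181 degrees) with a 15-degree trigger interval,
#' yielding 20 IMR frames per treatment.
#'
#' @param arcs list of (start, stop) gantry pairs (degrees)
#' @param triggerInterval trigger spacing (degrees of travel)
#' @return a [VMATSchedule-class]
#' @export
VMATSchedule <- function(arcs = list(c(110, 179), c(179, 110),
                                     c(181, 250), c(250, 181)),
                         triggerInterval = 15) {
  new("VMATSchedule", arcs = arcs, triggerInterval = triggerInterval)
}
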