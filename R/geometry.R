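#' Normalize a gantry angle to [0, 360)
#' @param degrees angle(s) in degrees
#' @return angle(s) reduced modulo 360
#' @export
normalizeAngle <- function(degrees) degrees %% 360

#' Circular distance between gantry angles
#' @param a,b angles in degrees
#' @return the shorter angular distance, in \[0, 180\]
#' @export
circularDistance <- function(a, b) {
  d <- abs(normalizeAngle(a) - normalizeAngle(b))
  pmin(d, 360 - d)
}

#' Detector pixel pitch
#'
#' Square pixels are assumed; the column pitch (active width over number of
#' columns) is used everywhere. For the default panel this is
#' 397/1024 = 0.3877 mm per pixel.
#'
#' @param spec a [DetectorSpec-class]
#' @return pixel pitch in mm per pixel
#' @export
pixelPitch <- function(spec) spec@activeWidth / spec@nCols

#' Geometric magnification of the isocenter plane
#' @param spec a [DetectorSpec-class]
#' @return sid/sad (1.5 for the default geometry)
#' @export
magnification <- function(spec) spec@sid / spec@sad

#' Detector center in pixel coordinates
#'
#' Pixel coordinates are 0-based with the pixel-center convention, so the
#' isocenter projects to ((nCols-1)/2, (nRows-1)/2).
#'
#' @param spec a [DetectorSpec-class]
#' @return named numeric (col, row)
#' @export
detectorCenter <- function(spec) {
  c(col = (spec@nCols - 1) / 2, row = (spec@nRows - 1) / 2)
}

#' Convert a detector-plane pixel shift to isocenter-plane mm
#'
#' A displacement measured on the imager demagnifies by sad/sid when
#' expressed in the beam's-eye view at the isocenter plane.
#'
#' @param shiftPx numeric (x, y) shift in detector pixels
#' @param spec a [DetectorSpec-class]
#' @return numeric (x, y) shift in mm at the isocenter plane
#' @seealso [isoToDetectorPx()] for the exact inverse
#' @export
detectorShiftToIso <- function(shiftPx, spec) {
  out <- shiftPx * pixelPitch(spec) * spec@sad / spec@sid
  names(out) <- c("x", "y")[seq_along(out)]
  out
}

#' Convert an isocenter-plane mm shift to detector pixels
#' @param shiftMm numeric (x, y) shift in mm at the isocenter plane
#' @param spec a [DetectorSpec-class]
#' @return numeric (x, y) shift in detector pixels
#' @export
isoToDetectorPx <- function(shiftMm, spec) {
  out <- shiftMm / pixelPitch(spec) * spec@sid / spec@sad
  names(out) <- c("x", "y")[seq_along(out)]
  out
}

# Unit vectors of the rotating cone-beam frame at a gantry angle.
# World axes: x = lateral, y = vertical (up), z = longitudinal (superior).
# Gantry 0 puts the source above the isocenter; 90 on the patient's left;
# 180 below (posterior beam for a head-first supine patient).
gantryFrame <- function(gantry) {
  g <- gantry * pi / 180
  srcDir <- c(sin(g), cos(g), 0)            # isocenter -> source
  list(srcDir = srcDir,
       beamDir = -srcDir,                    # source -> detector
       colAxis = c(cos(g), -sin(g), 0),      # detector column (BEV lateral)
       rowAxis = c(0, 0, 1))                 # detector row (longitudinal)
}

#' Perspective-project a 3D point onto the detector
#'
#' Cone-beam projection: the source sits at distance sad from the isocenter
#' and the detector plane at distance sid from the source, both rotated by
#' the gantry angle about the longitudinal axis. The isocenter maps to the
#' detector center at every angle.
#'
#' @param point numeric (x, y, z) mm in isocenter-centered coordinates
#'   (lateral, vertical, longitudinal)
#' @param gantry gantry angle in degrees
#' @param spec a [DetectorSpec-class]
#' @return named numeric (col, row): 0-based detector pixel coordinates
#' @export
projectPoint <- function(point, gantry, spec) {
  fr <- gantryFrame(gantry)
  src <- fr$srcDir * spec@sad
  v <- point - src
  depth <- sum(v * fr$beamDir)
  if (depth <= 0)
    stop("point lies at or behind the source")
  colMm <- sum(v * fr$colAxis) * spec@sid / depth
  rowMm <- sum(v * fr$rowAxis) * spec@sid / depth
  ctr <- detectorCenter(spec)
  c(col = unname(ctr["col"]) + colMm / pixelPitch(spec),
    row = unname(ctr["row"]) + rowMm / pixelPitch(spec))
}

#' Beam's-eye-view projection of a 3D couch shift
#'
#' The 2D ground truth a tracker limited to in-plane translation should
#' report for a rigid 3D shift: the components of the shift along the
#' detector column axis (lateral in the beam's-eye view) and the
#' longitudinal axis, at the isocenter depth. The component along the
#' beam axis is invisible to a 2D tracker.
#'
#' @param shift3d numeric (lateral, vertical, longitudinal) mm
#' @param gantry gantry angle in degrees
#' @return named numeric (x, y) mm in the beam's-eye view
#' @export
bevGroundTruth <- function(shift3d, gantry) {
  fr <- gantryFrame(gantry)
  c(x = sum(shift3d * fr$colAxis), y = sum(shift3d * fr$rowAxis))
}

#' Isotropically expand a 3D binary mask
#'
#' Morphological dilation with a cubic structuring element whose half-width
#' is the margin in voxels (rounded to the nearest voxel). Used to apply
#' the 2 cm planning margin around the tracked vertebrae. The cubic
#' dilation is separable, so it runs as three axis-wise shift-or passes.
#'
#' @param mask logical 3D array
#' @param marginMm margin in mm
#' @param spacing voxel size in mm
#' @return logical 3D array
#' @export
expandMask <- function(mask, marginMm, spacing) {
  r <- as.integer(round(marginMm / spacing))
  if (r < 1) return(mask)
  dilate1d <- function(m, axis) {
    out <- m
    n <- dim(m)[axis]
    for (s in seq_len(r)) {
      lo <- seq_len(n - s); hi <- lo + s
      if (axis == 1) { out[hi, , ] <- out[hi, , ] | m[lo, , ]
                       out[lo, , ] <- out[lo, , ] | m[hi, , ] }
      if (axis == 2) { out[, hi, ] <- out[, hi, ] | m[, lo, ]
                       out[, lo, ] <- out[, lo, ] | m[, hi, ] }
      if (axis == 3) { out[, , hi] <- out[, , hi] | m[, , lo]
                       out[, , lo] <- out[, , lo] | m[, , hi] }
    }
    out
  }
  m <- dilate1d(mask, 1)
  m <- dilate1d(m, 2)
  dilate1d(m, 3)
}

#' Forward-project a 3D ROI mask onto the detector
#'
#' Projects the center of every masked voxel through the cone-beam geometry
#' at the given gantry angle, marks the hit pixels, and closes the result
#' with a 3x3 structuring element to remove sampling holes.
#'
#' @param mask logical 3D array on the planning grid (already including any
#'   planning margin; see [expandMask()])
#' @param spacing voxel size in mm
#' @param origin mm position of the center of voxel \[1,1,1\] relative to
#'   the isocenter
#' @param gantry gantry angle in degrees
#' @param spec a [DetectorSpec-class]
#' @return an [ROITemplate-class] for this angle
#' @export
projectROI <- function(mask, spacing, origin, gantry, spec) {
  if (!any(mask)) stop("ROI mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep((idx - 1) * spacing, 2, origin, "+")
  fr <- gantryFrame(gantry)
  src <- fr$srcDir * spec@sad
  v <- sweep(pts, 2, src, "-")
  depth <- as.vector(v %*% fr$beamDir)
  if (any(depth <= 0)) stop("ROI voxel at or behind the source")
  colMm <- as.vector(v %*% fr$colAxis) * spec@sid / depth
  rowMm <- as.vector(v %*% fr$rowAxis) * spec@sid / depth
  ctr <- detectorCenter(spec)
  cc <- round(ctr["col"] + colMm / pixelPitch(spec)) + 1
  rr <- round(ctr["row"] + rowMm / pixelPitch(spec)) + 1
  keep <- cc >= 1 & cc <= spec@nCols & rr >= 1 & rr <= spec@nRows
  m <- matrix(FALSE, spec@nRows, spec@nCols)
  m[cbind(rr[keep], cc[keep])] <- TRUE
  if (!any(m)) stop("projected ROI falls entirely outside the detector")
  m <- EBImage::closing(m * 1, matrix(1, 3, 3)) > 0
  storage.mode(m) <- "logical"
  ROITemplate(m, gantry)
}

#' Pair a live frame with the closest reference projection
#'
#' Returns the reference whose gantry angle has the minimal circular
#' distance to the query, provided that distance is strictly within the
#' pairing tolerance (default 0.75 degrees); ties are broken toward the
#' smaller angle. An unpairable frame yields NULL.
#'
#' @param imrAngle gantry angle of the live frame (degrees)
#' @param refs a [ReferenceSet-class]
#' @param tolerance pairing window in degrees
#' @return NULL, or a list with elements `image` ([ProjectionImage-class]),
#'   `angle` and `distance` (degrees)
#' @export
pairReference <- function(imrAngle, refs, tolerance = 0.75) {
  d <- circularDistance(refs@angles, imrAngle)
  best <- min(d)
  if (best >= tolerance) return(NULL)
  i <- which(d == best)
  i <- i[which.min(refs@angles[i])]
  list(image = refs@images[[i]], angle = refs@angles[i], distance = best)
}

#' Angular spacing of an equally spaced full trajectory
#'
#' A full-trajectory scan of about 895 projections yields a spacing of
#' about 0.4 degrees, which guarantees pairing within 0.2 degrees.
#'
#' @param nProjections number of projections over 360 degrees
#' @return spacing in degrees
#' @export
angularSpacing <- function(nProjections) {
  stopifnot(nProjections >= 1)
  360 / nProjections
}

#' Angular gaps of a reference set
#'
#' Diagnostic for trajectory coverage: the gap between consecutive
#' reference angles, including the wrap-around gap.
#'
#' @param refs a [ReferenceSet-class]
#' @return numeric vector of gaps in degrees (sums to 360)
#' @export
referenceGaps <- function(refs) {
  a <- refs@angles
  diff(c(a, a[1] + 360))
}
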