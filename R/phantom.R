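#' Build a synthetic thorax/spine phantom
#'
#' An elliptic-cylinder soft-tissue body containing a longitudinal column
#' of vertebra-like blocks with simple posterior-process flanges, separated
#' by low-attenuation disc gaps. One vertebra is centered on the isocenter,
#' emulating a target at a mid-thoracic vertebral body. Outside the body
#' the attenuation is zero (air).
#'
#' @param nVertebrae number of vertebral blocks (0 gives a uniform body)
#' @param vertebraMu,tissueMu linear attenuation (1/mm) of bone and soft
#'   tissue; bone must exceed tissue
#' @param bodyRadius numeric (lateral, vertical) semi-axes of the body (mm)
#' @param vertebraSize longitudinal extent of each vertebral body (mm)
#' @param discGap longitudinal gap between vertebrae (mm, filled by tissue)
#' @param spacing voxel size (mm)
#' @param bodyLength longitudinal extent of the body (mm); defaults to the
#'   spine extent plus a 30 mm margin
#' @return a [PhantomVolume-class]
#' @examples
#' ph <- buildSpinePhantom(spacing = 4)
#' range(ph@mu)
#' @export
buildSpinePhantom <- function(nVertebrae = 5L, vertebraMu = 0.06,
                              tissueMu = 0.02, bodyRadius = c(90, 70),
                              vertebraSize = 25, discGap = 5, spacing = 2,
                              bodyLength = NULL) {
  stopifnot(vertebraMu > tissueMu, tissueMu >= 0, all(bodyRadius > 0),
            vertebraSize > 0, discGap >= 0, spacing > 0, nVertebrae >= 0)
  period <- vertebraSize + discGap
  spineLen <- if (nVertebrae > 0) nVertebrae * period - discGap else 0
  if (is.null(bodyLength)) bodyLength <- spineLen + 30
  if (bodyLength < spineLen)
    stop("spine does not fit inside the body length")

  halfX <- bodyRadius[1] + spacing
  halfY <- bodyRadius[2] + spacing
  halfZ <- bodyLength / 2 + spacing
  nx <- ceiling(2 * halfX / spacing) + 1
  ny <- ceiling(2 * halfY / spacing) + 1
  nz <- ceiling(2 * halfZ / spacing) + 1
  # voxel-center coordinates, grid centered on the isocenter
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing
  z <- (seq_len(nz) - (nz + 1) / 2) * spacing

  mu <- array(0, dim = c(nx, ny, nz))
  body2d <- outer(x^2 / bodyRadius[1]^2, y^2 / bodyRadius[2]^2, "+") <= 1
  inBody <- abs(z) <= bodyLength / 2
  mu[] <- tissueMu * as.numeric(body2d)[rep(seq_len(nx * ny), nz)] *
    rep(as.numeric(inBody), each = nx * ny)

  if (nVertebrae > 0) {
    centers <- (seq_len(nVertebrae) - (nVertebrae + 1) / 2) * period
    bodyHalf <- vertebraSize / 2
    vx <- abs(x) <= 15            # vertebral body: 30 mm lateral extent
    vy <- abs(y) <= bodyHalf      # centered vertically on the isocenter
    fx <- abs(x) <= 5             # posterior process flange
    fy <- y >= -bodyHalf - 15 & y <= -bodyHalf
    blk <- outer(vx, vy, "&")
    fl <- outer(fx, fy, "&")
    for (zc in centers) {
      vz <- which(abs(z - zc) <= bodyHalf)
      if (!length(vz)) stop("vertebra falls outside the grid")
      for (zi in vz) mu[, , zi][blk] <- vertebraMu
      for (zi in which(abs(z - zc) <= 5)) mu[, , zi][fl] <- vertebraMu
    }
  }
  new("PhantomVolume", mu = mu, spacing = spacing,
      origin = c(x[1], y[1], z[1]))
}

#' 3D mask of the tracked vertebra with planning margin
#'
#' A box covering the isocenter vertebral body (and its posterior process)
#' expanded isotropically by the planning margin, on the phantom grid.
#' Forward-project it with [projectROI()] to obtain per-angle detector
#' templates.
#'
#' @param phantom a [PhantomVolume-class] from [buildSpinePhantom()]
#' @param vertebraSize longitudinal extent used when the phantom was built
#' @param marginMm isotropic expansion in mm (default 20, the 2 cm margin)
#' @return logical 3D array on the phantom grid
#' @export
trackedVertebraMask <- function(phantom, vertebraSize = 25, marginMm = 20) {
  d <- dim(phantom@mu)
  x <- phantom@origin[1] + (seq_len(d[1]) - 1) * phantom@spacing
  y <- phantom@origin[2] + (seq_len(d[2]) - 1) * phantom@spacing
  z <- phantom@origin[3] + (seq_len(d[3]) - 1) * phantom@spacing
  half <- vertebraSize / 2
  mask <- outer(outer(abs(x) <= 15, abs(y) <= half, "&"), abs(z) <= half, "&")
  expandMask(mask, marginMm, phantom@spacing)
}

# Rotation matrices about the world axes (degrees).
rotAboutX <- function(deg) {  # pitch (lateral axis)
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rotAboutY <- function(deg) {  # rotation/yaw (vertical axis)
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rotAboutZ <- function(deg) {  # roll (longitudinal axis)
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rigid transform of a pose
#'
#' World coordinates of a phantom point p are R p + t, with rotations
#' applied about the isocenter in the order rotation (yaw), pitch, roll,
#' followed by the translation.
#'
#' @param pose a [Pose6D-class]
#' @return list with `R` (3x3 rotation) and `t` (length-3 translation, mm,
#'   ordered lateral/vertical/longitudinal)
#' @export
poseTransform <- function(pose) {
  R <- rotAboutZ(pose@roll) %*% rotAboutX(pose@pitch) %*% rotAboutY(pose@rotation)
  list(R = R, t = c(pose@tLat, pose@tVert, pose@tLong))
}

#' Render a digitally reconstructed radiograph
#'
#' Casts one ray per detector pixel from the source through the pixel
#' center, accumulates the attenuation path integral through the posed
#' phantom with a fixed-step trapezoid rule, and applies the Beer-Lambert
#' law: intensity = photonsAtAir * exp(-integral). The pose is applied by
#' inverse-transforming ray sample points; the volume is never resampled.
#' With a [NoiseModel-class], Poisson counting noise is drawn under the
#' model's seed (same seed, same image, bit for bit).
#'
#' @param phantom a [PhantomVolume-class]
#' @param pose a [Pose6D-class] (identity by default)
#' @param gantry gantry angle in degrees
#' @param spec a [DetectorSpec-class]
#' @param noise a [NoiseModel-class] or NULL for noiseless rendering
#' @param photonsAtAir air-level intensity used when `noise` is NULL
#' @param step ray sampling step (mm); default half the voxel spacing
#' @param kind,beamOn,index metadata for the returned frame
#' @return a [ProjectionImage-class]
#' @export
renderDRR <- function(phantom, pose = Pose6D(), gantry, spec,
                      noise = NULL, photonsAtAir = 1e5,
                      step = phantom@spacing / 2,
                      kind = "CBCT", beamOn = FALSE, index = 0L) {
  fr <- gantryFrame(gantry)
  src <- fr$srcDir * spec@sad
  ctr <- detectorCenter(spec)
  pitch <- pixelPitch(spec)
  detCtr <- -fr$srcDir * (spec@sid - spec@sad)
  du <- fr$colAxis * pitch
  dv <- fr$rowAxis * pitch
  det00 <- detCtr - ctr["col"] * du - ctr["row"] * dv
  tr <- poseTransform(pose)
  L <- drr_line_integrals(phantom@mu, phantom@spacing, phantom@origin,
                          tr$R, tr$t, src, det00, du, dv,
                          spec@nCols, spec@nRows, step)
  I0 <- if (is.null(noise)) photonsAtAir else noise@photonsAtAir
  img <- I0 * exp(-L)
  if (!is.null(noise)) {
    img <- withPreservedRNG(noise@seed, {
      matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
    })
    img <- img * 1.0
  }
  ProjectionImage(img, gantry = gantry, kind = kind, beamOn = beamOn,
                  index = index)
}

# Evaluate expr under a given seed without disturbing the caller's RNG.
withPreservedRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a full-trajectory CBCT reference scan
#'
#' Renders projections at equally spaced angles covering 360 degrees at
#' the identity pose. About 895 projections gives the clinical spacing of
#' about 0.4 degrees.
#'
#' @param phantom a [PhantomVolume-class]
#' @param spec a [DetectorSpec-class]
#' @param nProjections number of projections (default 895)
#' @param noise optional [NoiseModel-class]; each projection uses
#'   seed + index so frames are independent but reproducible
#' @param ... further arguments passed to [renderDRR()]
#' @return a [ReferenceSet-class]
#' @export
simulateCBCT <- function(phantom, spec, nProjections = 895, noise = NULL,
                         ...) {
  stopifnot(nProjections >= 1)
  angles <- (seq_len(nProjections) - 1) * angularSpacing(nProjections)
  images <- lapply(seq_along(angles), function(i) {
    ni <- noise
    if (!is.null(ni)) ni@seed <- ni@seed + i
    renderDRR(phantom, Pose6D(), angles[i], spec, noise = ni,
              kind = "CBCT", index = i, ...)
  })
  ReferenceSet(images)
}

#' Simulate one intrafraction motion-review frame
#'
#' A single DRR of the phantom at the given pose and gantry angle, tagged
#' as an IMR frame with beam-on metadata. The default air-level intensity
#' keeps the in-ROI mean inside the standard IMR qualification window.
#'
#' @param phantom a [PhantomVolume-class]
#' @param pose a [Pose6D-class]
#' @param gantry gantry angle in degrees
#' @param spec a [DetectorSpec-class]
#' @param beamOn beam-on flag (TRUE for a genuine pulse)
#' @param noise optional [NoiseModel-class]
#' @param index acquisition index
#' @param ... further arguments passed to [renderDRR()]
#' @return a [ProjectionImage-class] of kind "IMR"
#' @export
simulateIMR <- function(phantom, pose, gantry, spec, beamOn = TRUE,
                        noise = NULL, index = 0L, ...) {
  renderDRR(phantom, pose, gantry, spec, noise = noise, kind = "IMR",
            beamOn = beamOn, index = index, ...)
}
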