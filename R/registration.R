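#' Translate an image inside the beam's-eye view
#'
#' Resamples the image at positions displaced by the detector-plane
#' equivalent of an isocenter-plane shift (see [isoToDetectorPx()]), so the
#' image content moves by +shift. Bilinear interpolation; out-of-bounds
#' samples take the nearest-edge value. Integer-pixel shifts are exact
#' pixel relabelings.
#'
#' @param image numeric matrix or [ProjectionImage-class]
#' @param shift numeric (x, y) shift in mm at the isocenter plane
#' @param spec a [DetectorSpec-class]
#' @return a pixel matrix of the same dimensions
#' @export
translateImage <- function(image, shift, spec) {
  px <- if (is(image, "ProjectionImage")) image@pixels else image
  stopifnot(all(is.finite(shift)), length(shift) == 2)
  d <- isoToDetectorPx(shift, spec)
  bilinear_translate(px, d[1], d[2])
}

roiPixels <- function(roi) {
  if (is(roi, "ROITemplate")) roi@mask else roi
}

#' Normalized cross-correlation objective
#'
#' The tracking objective: the reference projection is translated by the
#' candidate shift inside the beam's-eye view and correlated with the live
#' frame over the ROI pixels only,
#' \deqn{Obj(x, y) = \frac{\sum_{ROI} T_{2D}(x,y)[P_r] \cdot P_i}
#'                        {\|T_{2D}(x,y)[P_r]\| \, \|P_i\|}.}
#' For nonnegative images the value lies in \[0, 1\], with 1 an exact
#' match (Cauchy-Schwarz). A zero denominator (blank ROI content) scores 0.
#' With `cfg@zeroMean`, ROI means are subtracted first and the value is
#' clamped to \[0, 1\].
#'
#' @param ref reference [ProjectionImage-class] (or matrix)
#' @param live live [ProjectionImage-class] (or matrix)
#' @param roi [ROITemplate-class] (or logical matrix) on the live-frame grid
#' @param shift numeric (x, y) candidate shift in mm at the isocenter plane
#' @param spec a [DetectorSpec-class]
#' @param zeroMean subtract ROI means before correlating
#' @return objective value in \[0, 1\]
#' @export
nccObjective <- function(ref, live, roi, shift = c(0, 0), spec,
                         zeroMean = FALSE) {
  mask <- roiPixels(roi)
  if (!any(mask)) stop("ROI mask is empty")
  tref <- translateImage(ref, shift, spec)
  lv <- if (is(live, "ProjectionImage")) live@pixels else live
  a <- tref[mask]
  b <- lv[mask]
  if (zeroMean) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  den <- sqrt(sum(a * a)) * sqrt(sum(b * b))
  if (den < .Machine$double.xmin) return(0)
  val <- sum(a * b) / den
  if (zeroMean) val <- min(max(val, 0), 1)
  min(val, 1)
}

#' Capture-range-penalized objective
#'
#' Identical to [nccObjective()] inside the capture range; any candidate
#' whose |x| or |y| exceeds the capture range scores the worst possible
#' correlation value, 0, which confines the search. The boundary itself is
#' inside the range.
#'
#' @inheritParams nccObjective
#' @param cfg a [RegistrationConfig-class]
#' @return objective value in \[0, 1\]
#' @export
penalizedObjective <- function(ref, live, roi, shift, cfg, spec) {
  if (any(abs(shift) > cfg@captureRange)) return(0)
  nccObjective(ref, live, roi, shift, spec, zeroMean = cfg@zeroMean)
}

#' 2D downhill simplex maximization with rebuilds
#'
#' Classical Nelder-Mead (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5) on the sign-flipped objective. The initial simplex is
#' \{start, start + (step, 0), start + (0, step)\}. After each full
#' iteration the relative spread of the three objective values,
#' 2|ObjH - ObjL| / (ObjH + ObjL), is tested against `cfg@tol`; when the
#' spread falls below it the best vertex is returned. If `cfg@maxIter`
#' iterations pass without convergence the simplex is rebuilt at its
#' current best vertex with the initial step, at most `cfg@maxRebuilds`
#' times; exhausting the rebuilds returns the best vertex with
#' `converged = FALSE`.
#'
#' @param objective function of a length-2 numeric, returning the value to
#'   maximize (finite on the search region)
#' @param start numeric (x, y) starting vertex
#' @param cfg a [RegistrationConfig-class]
#' @return list with `par` (best vertex), `value` (objective there),
#'   `converged`, `rebuilds`, `evaluations`
#' @export
downhillSimplex2D <- function(objective, start, cfg = RegistrationConfig()) {
  nev <- 0L
  f <- function(p) {
    nev <<- nev + 1L
    -objective(p)
  }
  verts <- rbind(start, start + c(cfg@stepInit, 0), start + c(0, cfg@stepInit))
  dimnames(verts) <- NULL
  vals <- apply(verts, 1, f)
  rebuilds <- 0L
  converged <- FALSE

  spreadOK <- function(vals) {
    obj <- -vals                       # spread tested on the positive values
    hi <- max(obj); lo <- min(obj)
    if (abs(hi + lo) < 1e-12) return(TRUE)
    2 * abs(hi - lo) / abs(hi + lo) < cfg@tol
  }

  repeat {
    iter <- 0L
    while (iter < cfg@maxIter) {
      o <- order(vals)                 # ties keep vertex order
      verts <- verts[o, , drop = FALSE]
      vals <- vals[o]
      ctr <- colMeans(verts[1:2, , drop = FALSE])
      xr <- ctr + (ctr - verts[3, ])
      fr <- f(xr)
      if (fr < vals[1]) {
        xe <- ctr + 2 * (ctr - verts[3, ])
        fe <- f(xe)
        if (fe < fr) { verts[3, ] <- xe; vals[3] <- fe }
        else { verts[3, ] <- xr; vals[3] <- fr }
      } else if (fr < vals[2]) {
        verts[3, ] <- xr; vals[3] <- fr
      } else {
        if (fr < vals[3]) {            # outside contraction
          xc <- ctr + 0.5 * (ctr - verts[3, ])
          fc <- f(xc)
          if (fc <= fr) { verts[3, ] <- xc; vals[3] <- fc }
          else { verts[3, ] <- xr; vals[3] <- fr }
        } else {                       # inside contraction
          xc <- ctr - 0.5 * (ctr - verts[3, ])
          fc <- f(xc)
          if (fc < vals[3]) { verts[3, ] <- xc; vals[3] <- fc }
          else {                       # shrink toward the best vertex
            for (i in 2:3) {
              verts[i, ] <- verts[1, ] + 0.5 * (verts[i, ] - verts[1, ])
              vals[i] <- f(verts[i, ])
            }
          }
        }
      }
      iter <- iter + 1L
      if (spreadOK(vals)) { converged <- TRUE; break }
    }
    if (converged || rebuilds >= cfg@maxRebuilds) break
    best <- verts[which.min(vals), ]
    verts <- rbind(best, best + c(cfg@stepInit, 0), best + c(0, cfg@stepInit))
    dimnames(verts) <- NULL
    vals <- apply(verts, 1, f)
    rebuilds <- rebuilds + 1L
    if (spreadOK(vals)) { converged <- TRUE; break }
  }
  i <- which.min(vals)
  list(par = unname(verts[i, ]), value = -vals[i], converged = converged,
       rebuilds = rebuilds, evaluations = nev)
}

#' Register a live frame against its reference projection
#'
#' Runs the capture-range-penalized NCC objective through the 2D downhill
#' simplex. The start is (0, 0) for the first frame of a sequence and the
#' previous optimum for subsequent frames (warm start).
#'
#' @param ref reference [ProjectionImage-class]
#' @param live live [ProjectionImage-class]
#' @param roi [ROITemplate-class] on the live-frame grid
#' @param cfg a [RegistrationConfig-class]
#' @param spec a [DetectorSpec-class]
#' @param warmStart numeric (x, y) mm, or NULL for a cold (0, 0) start
#' @return a [TrackingResult-class] with the shift in isocenter-plane mm
#' @examples
#' spec <- DetectorSpec(64L, 48L, 64, 48, 1500, 1000)
#' set.seed(1)
#' px <- matrix(stats::runif(64 * 48, 10, 100), 48, 64)
#' ref <- ProjectionImage(px, 90, "CBCT")
#' roi <- ROITemplate(matrix(TRUE, 48, 64), 90)
#' live <- ProjectionImage(px, 90, "IMR", beamOn = TRUE)
#' registerFrame(ref, live, roi, spec = spec)@shift
#' @export
registerFrame <- function(ref, live, roi, cfg = RegistrationConfig(), spec,
                          warmStart = NULL) {
  if (!any(roiPixels(roi))) stop("ROI mask is empty")
  start <- if (is.null(warmStart)) c(0, 0) else as.numeric(warmStart)
  obj <- function(p) penalizedObjective(ref, live, roi, p, cfg, spec)
  res <- downhillSimplex2D(obj, start, cfg)
  shift <- pmin(pmax(res$par, -cfg@captureRange), cfg@captureRange)
  new("TrackingResult", shift = c(x = shift[1], y = shift[2]),
      objective = res$value, converged = res$converged,
      rebuilds = res$rebuilds,
      refAngle = if (is(ref, "ProjectionImage")) ref@gantry else NA_real_,
      imrIndex = if (is(live, "ProjectionImage")) live@index else NA_integer_)
}

#' Exhaustive-grid registration oracle
#'
#' Evaluates the plain NCC objective on a regular grid of candidate shifts
#' and returns the argmax. Slow by construction; intended as an independent
#' cross-check of the simplex search.
#'
#' @inheritParams registerFrame
#' @param step grid step in mm
#' @param range half-width of the search square in mm
#' @return list with `shift` (x, y mm) and `value`
#' @export
bruteForceRegister <- function(ref, live, roi, spec, step = 1, range = 5) {
  stopifnot(step > 0)
  g <- seq(-range, range, by = step)
  best <- c(0, 0); bestVal <- -Inf
  for (y in g) for (x in g) {
    v <- nccObjective(ref, live, roi, c(x, y), spec)
    if (v > bestVal) { bestVal <- v; best <- c(x, y) }
  }
  list(shift = c(x = best[1], y = best[2]), value = bestVal)
}
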