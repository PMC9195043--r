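#' Mean intensity inside the tracking ROI
#'
#' @param frame a [ProjectionImage-class] (or pixel matrix)
#' @param roi an [ROITemplate-class] (or logical matrix) on the same grid
#' @return arithmetic mean of the pixels where the mask is set
#' @export
meanROIIntensity <- function(frame, roi) {
  mask <- roiPixels(roi)
  if (!any(mask)) stop("ROI mask is empty")
  px <- if (is(frame, "ProjectionImage")) frame@pixels else frame
  stopifnot(all(dim(px) == dim(mask)))
  mean(px[mask])
}

#' Qualify a grabbed frame as a CBCT reference projection
#'
#' Minimal filtering: the frame is saved as a reference when its mean ROI
#' intensity is strictly larger than the threshold (default 40). This
#' rejects blank frames while keeping every genuine projection.
#'
#' @param frame a [ProjectionImage-class] of kind "CBCT"
#' @param roi an [ROITemplate-class]
#' @param cfg a [FilterConfig-class]
#' @return TRUE to accept, FALSE to reject
#' @export
qualifyCBCT <- function(frame, roi, cfg = FilterConfig()) {
  if (is(frame, "ProjectionImage") && frame@kind != "CBCT")
    stop("qualifyCBCT expects a CBCT-reference frame")
  meanROIIntensity(frame, roi) > cfg@cbctMinMean
}

#' Qualify a grabbed frame as a trackable IMR image
#'
#' A frame is queued for registration only when the beam is on, its mean
#' ROI intensity lies inside the configured window (inclusive), and the
#' mean is strictly more than `imrPrevRatio` times that of the previous
#' grabbed frame (whatever that frame's own verdict was). The first frame
#' of a stream has no predecessor and skips the ratio test. The `latched`
#' flag implements the one-frame-per-pulse contract: once a frame has been
#' accepted for a kV pulse, subsequent frames are rejected until the mean
#' falls back below the lower window bound (see [qualifyStream()]).
#'
#' @param frame a [ProjectionImage-class] of kind "IMR"
#' @param roi an [ROITemplate-class]
#' @param prevMean mean ROI intensity of the previous grabbed frame, or
#'   NULL at the start of a stream
#' @param cfg a [FilterConfig-class]
#' @param latched TRUE while an accepted pulse has not yet decayed
#' @return TRUE to accept, FALSE to reject
#' @export
qualifyIMR <- function(frame, roi, prevMean = NULL, cfg = FilterConfig(),
                       latched = FALSE) {
  if (is(frame, "ProjectionImage") && frame@kind != "IMR")
    stop("qualifyIMR expects an IMR frame")
  beamOn <- if (is(frame, "ProjectionImage")) frame@beamOn else TRUE
  m <- meanROIIntensity(frame, roi)
  if (latched) return(FALSE)
  beamOn &&
    m >= cfg@imrMinMean && m <= cfg@imrMaxMean &&
    (is.null(prevMean) || m > cfg@imrPrevRatio * prevMean)
}

#' Qualify a raw IMR frame stream
#'
#' Applies [qualifyIMR()] along a grabbed-frame sequence, carrying the
#' previous frame's mean and the one-frame-per-pulse latch: after an
#' acceptance, frames are rejected until the mean ROI intensity falls
#' below the lower window bound (the dark interval between kV pulses),
#' which re-arms the filter.
#'
#' @param frames list of [ProjectionImage-class] of kind "IMR"
#' @param roi an [ROITemplate-class]
#' @param cfg a [FilterConfig-class]
#' @return data.frame with columns `index`, `mean`, `accepted`
#' @export
qualifyStream <- function(frames, roi, cfg = FilterConfig()) {
  prevMean <- NULL
  latched <- FALSE
  out <- data.frame(index = seq_along(frames), mean = NA_real_,
                    accepted = FALSE)
  for (i in seq_along(frames)) {
    m <- meanROIIntensity(frames[[i]], roi)
    acc <- qualifyIMR(frames[[i]], roi, prevMean, cfg, latched)
    if (acc) latched <- TRUE
    if (latched && m < cfg@imrMinMean) latched <- FALSE
    out$mean[i] <- m
    out$accepted[i] <- acc
    prevMean <- m
  }
  out
}
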