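#' Headless tracking session
#'
#' A functional state machine mirroring the clinical workflow: IDLE ->
#' CBCT (reference acquisition) -> EDIT_ROI (optional mask touch-up) ->
#' TRACKING (live registration with warm starts). Frames are routed by the
#' current mode; accepted IMR frames append one record each to the
#' append-only session log. All mutating verbs return an updated session.
#'
#' @slot mode one of "IDLE", "CBCT", "EDIT_ROI", "TRACKING"
#' @slot spec the [DetectorSpec-class] in force
#' @slot filter the [FilterConfig-class]
#' @slot regConfig the [RegistrationConfig-class]
#' @slot rois list of [ROITemplate-class]; the template nearest in angle
#'   to each frame is used
#' @slot refImages accumulated reference projections (list)
#' @slot tolerance per-axis clinical tolerance in mm
#' @slot log data.frame of tracking records
#' @slot prevMean,latched IMR filter chain state
#' @slot warmStart previous optimum (numeric (x, y)) or NULL-equivalent
#'   (length 0) for a cold start
#' @export
setClass("TrackingSession",
  representation(mode = "character", spec = "DetectorSpec",
                 filter = "FilterConfig", regConfig = "RegistrationConfig",
                 rois = "list", refImages = "list", tolerance = "numeric",
                 log = "data.frame", prevMean = "numeric",
                 latched = "logical", warmStart = "numeric"),
  prototype(mode = "IDLE", tolerance = 2, latched = FALSE,
            prevMean = numeric(0), warmStart = numeric(0)))

setValidity("TrackingSession", function(object) {
  if (!object@mode %in% c("IDLE", "CBCT", "EDIT_ROI", "TRACKING"))
    return("unknown session mode")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  TRUE
})

emptySessionLog <- function() {
  data.frame(frame_index = integer(0), gantry_deg = numeric(0),
             ref_angle_deg = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
             ncc = numeric(0), converged = logical(0), alert = logical(0))
}

#' Open a tracking session
#'
#' @param spec a [DetectorSpec-class]
#' @param rois list of [ROITemplate-class] (one per reference angle, or a
#'   coarser set; the nearest in angle is used per frame)
#' @param filter a [FilterConfig-class]
#' @param regConfig a [RegistrationConfig-class]
#' @param tolerance per-axis clinical tolerance in mm (site policy; no
#'   universal default exists, 2 mm is a common paraspinal choice)
#' @return a [TrackingSession-class] in IDLE mode
#' @export
TrackingSession <- function(spec, rois, filter = FilterConfig(),
                            regConfig = RegistrationConfig(),
                            tolerance = 2) {
  new("TrackingSession", mode = "IDLE", spec = spec, filter = filter,
      regConfig = regConfig, rois = rois, refImages = list(),
      tolerance = tolerance, log = emptySessionLog())
}

legalTransitions <- list(
  IDLE = c("IDLE", "CBCT"),
  CBCT = c("IDLE", "EDIT_ROI", "TRACKING"),
  EDIT_ROI = c("IDLE", "TRACKING"),
  TRACKING = c("IDLE"))

#' Change the session mode
#'
#' Only the clinical sequence IDLE -> CBCT -> EDIT_ROI -> TRACKING is
#' allowed (EDIT_ROI may be skipped), plus a reset to IDLE from any mode.
#' Entering TRACKING requires at least one saved reference projection.
#' A reset clears the references, the filter chain, and the warm start,
#' but keeps the log.
#'
#' @param session a [TrackingSession-class]
#' @param mode target mode
#' @return the updated session
#' @export
setMode <- function(session, mode) {
  if (!mode %in% legalTransitions[[session@mode]])
    stop(sprintf("illegal mode transition %s -> %s", session@mode, mode))
  if (mode == "TRACKING" && length(session@refImages) == 0)
    stop("cannot enter TRACKING without reference projections")
  if (mode == "IDLE") {
    session@refImages <- list()
    session@prevMean <- numeric(0)
    session@latched <- FALSE
    session@warmStart <- numeric(0)
  }
  session@mode <- mode
  session
}

roiForAngle <- function(rois, angle) {
  d <- vapply(rois, function(r) circularDistance(r@angle, angle), numeric(1))
  rois[[which.min(d)]]
}

#' Route a grabbed frame through the session
#'
#' In CBCT mode, frames passing [qualifyCBCT()] are appended to the
#' reference set. In TRACKING mode, frames passing [qualifyIMR()] (with
#' the one-frame-per-pulse latch) are paired with the closest reference
#' within the pairing window and registered, warm-started at the previous
#' optimum; one log record is appended per accepted frame, with the
#' tolerance alert flag. IDLE and EDIT_ROI ignore frames.
#'
#' @param session a [TrackingSession-class]
#' @param frame a [ProjectionImage-class]
#' @param pairingTolerance reference pairing window in degrees
#' @return the updated session
#' @export
ingestFrame <- function(session, frame, pairingTolerance = 0.75) {
  roi <- roiForAngle(session@rois, frame@gantry)
  if (session@mode == "CBCT") {
    if (frame@kind == "CBCT" && qualifyCBCT(frame, roi, session@filter))
      session@refImages <- c(session@refImages, frame)
    return(session)
  }
  if (session@mode != "TRACKING") return(session)

  m <- meanROIIntensity(frame, roi)
  prev <- if (length(session@prevMean)) session@prevMean else NULL
  acc <- frame@kind == "IMR" &&
    qualifyIMR(frame, roi, prev, session@filter, session@latched)
  if (acc) session@latched <- TRUE
  if (session@latched && m < session@filter@imrMinMean)
    session@latched <- FALSE
  session@prevMean <- m
  if (!acc) return(session)

  refs <- ReferenceSet(session@refImages)
  pair <- pairReference(frame@gantry, refs, pairingTolerance)
  if (is.null(pair)) return(session)
  ws <- if (length(session@warmStart)) session@warmStart else NULL
  res <- registerFrame(pair$image, frame, roi, session@regConfig,
                       session@spec, warmStart = ws)
  session@warmStart <- unname(res@shift)
  alert <- checkTolerance(res, session@tolerance)
  session@log <- rbind(session@log, data.frame(
    frame_index = frame@index, gantry_deg = frame@gantry,
    ref_angle_deg = pair$angle, x_mm = unname(res@shift[1]),
    y_mm = unname(res@shift[2]), ncc = res@objective,
    converged = res@converged, alert = alert))
  session
}

#' Tolerance alert for a tracking result
#'
#' Alerts when either axis strictly exceeds the per-axis clinical
#' tolerance; a shift exactly at the tolerance does not alert.
#'
#' @param result a [TrackingResult-class]
#' @param tolerance per-axis tolerance in mm (> 0)
#' @return TRUE if out of tolerance
#' @export
checkTolerance <- function(result, tolerance) {
  stopifnot(tolerance > 0)
  any(abs(result@shift) > tolerance)
}

#' Edit an ROI template by pixel-set operations
#'
#' The headless counterpart of interactive brush editing: add or remove
#' explicit pixel sets. The edited mask must stay non-empty.
#'
#' @param template an [ROITemplate-class]
#' @param add,remove logical matrices on the detector grid (or NULL)
#' @return the edited [ROITemplate-class]
#' @export
editROI <- function(template, add = NULL, remove = NULL) {
  m <- template@mask
  if (!is.null(add)) m <- m | add
  if (!is.null(remove)) m <- m & !remove
  if (!any(m)) stop("edit would empty the ROI")
  ROITemplate(m, template@angle)
}

#' Edit a session's ROI template (EDIT_ROI mode only)
#'
#' @param session a [TrackingSession-class] in EDIT_ROI mode
#' @param which index of the template to edit
#' @param add,remove pixel sets, as in [editROI()]
#' @return the updated session; the edit persists into later modes
#' @export
editSessionROI <- function(session, which = 1L, add = NULL, remove = NULL) {
  if (session@mode != "EDIT_ROI")
    stop("ROI editing is only allowed in EDIT_ROI mode")
  session@rois[[which]] <- editROI(session@rois[[which]], add, remove)
  session
}

#' Session log accessor
#' @param session a [TrackingSession-class]
#' @return data.frame with one record per accepted IMR frame
#' @export
sessionLog <- function(session) session@log

#' Write the session log as CSV
#' @param session a [TrackingSession-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeSessionLog <- function(session, path) {
  utils::write.csv(session@log, path, row.names = FALSE)
  invisible(path)
}
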