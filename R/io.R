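#' Write a reference set to disk
#'
#' One 16-bit TIFF per projection plus a CSV manifest (index, angle,
#' filename, intensity scale, mean ROI intensity and qualification verdict
#' when an ROI is supplied). Intensities are stored as
#' round(intensity / scale * 65535) with a common scale recorded in the
#' manifest, so the round trip preserves relative intensities to 16-bit
#' precision.
#'
#' @param refs a [ReferenceSet-class]
#' @param dir output directory (created if needed)
#' @param roi optional [ROITemplate-class] used to record qualification
#' @param cfg a [FilterConfig-class] used with `roi`
#' @return invisibly, the manifest path
#' @export
writeReferenceSet <- function(refs, dir, roi = NULL, cfg = FilterConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(vapply(refs@images, function(im) max(im@pixels), numeric(1)), 1)
  rows <- lapply(seq_along(refs@angles), function(i) {
    im <- refs@images[[i]]
    fn <- sprintf("proj_%04d.tif", i)
    tiff::writeTIFF(pmin(im@pixels / scale, 1), file.path(dir, fn),
                    bits.per.sample = 16L)
    m <- if (is.null(roi)) NA_real_ else meanROIIntensity(im, roi)
    q <- if (is.null(roi)) NA else m > cfg@cbctMinMean
    data.frame(index = i, angle_deg = refs@angles[i], file = fn,
               scale = scale, mean_roi_intensity = m, qualified = q)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a reference set written by [writeReferenceSet()]
#'
#' @param dir directory containing the TIFFs and manifest.csv
#' @return a [ReferenceSet-class]
#' @export
readReferenceSet <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(seq_len(nrow(man)), function(i) {
    px <- tiff::readTIFF(file.path(dir, man$file[i])) * man$scale[i]
    ProjectionImage(px, gantry = man$angle_deg[i], kind = "CBCT",
                    index = man$index[i])
  })
  ReferenceSet(images)
}

#' Write a frame stream to disk
#'
#' Like [writeReferenceSet()] but for an ordered IMR frame stream, which
#' may repeat gantry angles (several frames per beam); the acquisition
#' order is preserved instead of angle-sorting.
#'
#' @param frames list of [ProjectionImage-class]
#' @param dir output directory
#' @return invisibly, the manifest path
#' @export
writeProjectionStream <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(vapply(frames, function(im) max(im@pixels), numeric(1)), 1)
  rows <- lapply(seq_along(frames), function(i) {
    im <- frames[[i]]
    fn <- sprintf("frame_%04d.tif", i)
    tiff::writeTIFF(pmin(im@pixels / scale, 1), file.path(dir, fn),
                    bits.per.sample = 16L)
    data.frame(index = i, angle_deg = im@gantry, file = fn, scale = scale,
               kind = im@kind, beam_on = im@beamOn)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a frame stream written by [writeProjectionStream()]
#'
#' @param dir directory containing the TIFFs and manifest.csv
#' @return list of [ProjectionImage-class] in acquisition order
#' @export
readProjectionStream <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i) {
    px <- tiff::readTIFF(file.path(dir, man$file[i])) * man$scale[i]
    kind <- if ("kind" %in% names(man)) man$kind[i] else "CBCT"
    on <- if ("beam_on" %in% names(man)) man$beam_on[i] else FALSE
    ProjectionImage(px, gantry = man$angle_deg[i], kind = kind,
                    beamOn = on, index = man$index[i])
  })
}

#' Write an ROI template as PNG + JSON sidecar
#'
#' The mask is a 1-bit-content PNG; the sidecar records the gantry angle,
#' the detector geometry and an optional plan id.
#'
#' @param roi an [ROITemplate-class]
#' @param path PNG path (the sidecar replaces the extension with .json)
#' @param spec a [DetectorSpec-class]
#' @param planId optional plan identifier string
#' @return invisibly, the PNG path
#' @export
writeROITemplate <- function(roi, path, spec, planId = "") {
  png::writePNG(roi@mask * 1, path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(
    angle_deg = roi@angle, plan_id = planId,
    detector = list(n_cols = spec@nCols, n_rows = spec@nRows,
                    active_width_mm = spec@activeWidth,
                    active_height_mm = spec@activeHeight,
                    sid_mm = spec@sid, sad_mm = spec@sad)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI template written by [writeROITemplate()]
#'
#' @param path PNG path (with its .json sidecar next to it)
#' @return list with `roi` ([ROITemplate-class]) and `spec`
#'   ([DetectorSpec-class])
#' @export
readROITemplate <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- jsonlite::read_json(sub("\\.png$", ".json", path),
                              simplifyVector = TRUE)
  d <- side$detector
  list(roi = ROITemplate(m > 0.5, side$angle_deg),
       spec = DetectorSpec(d$n_cols, d$n_rows, d$active_width_mm,
                           d$active_height_mm, d$sid_mm, d$sad_mm))
}
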