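setMethod("show", "DetectorSpec", function(object) {
  cat(sprintf("DetectorSpec: %d x %d px, %.1f x %.1f mm (%.4f mm/px), SID %.0f / SAD %.0f mm\n",
              object@nCols, object@nRows, object@activeWidth,
              object@activeHeight, pixelPitch(object), object@sid, object@sad))
})

setMethod("show", "ProjectionImage", function(object) {
  cat(sprintf("ProjectionImage [%s] %d x %d px, gantry %.2f deg, beam %s, index %d\n",
              object@kind, ncol(object@pixels), nrow(object@pixels),
              object@gantry, if (object@beamOn) "on" else "off", object@index))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ROITemplate", function(object) {
  cat(sprintf("ROITemplate at gantry %.2f deg: %d of %d px set\n",
              object@angle, sum(object@mask), length(object@mask)))
})

setMethod("show", "ReferenceSet", function(object) {
  g <- referenceGaps(object)
  cat(sprintf("ReferenceSet: %d projections, %.2f-%.2f deg, max gap %.3f deg\n",
              length(object@angles), min(object@angles), max(object@angles),
              max(g)))
})

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@mu)
  cat(sprintf("PhantomVolume: %d x %d x %d voxels @ %.2f mm, mu in [%.4f, %.4f] /mm\n",
              d[1], d[2], d[3], object@spacing, min(object@mu), max(object@mu)))
})

setMethod("show", "Pose6D", function(object) {
  cat(sprintf("Pose6D: t = (%.2f, %.2f, %.2f) mm; rotation %.2f, pitch %.2f, roll %.2f deg\n",
              object@tLat, object@tVert, object@tLong,
              object@rotation, object@pitch, object@roll))
})

setMethod("show", "TrackingResult", function(object) {
  cat(sprintf("TrackingResult: shift (%.3f, %.3f) mm, NCC %.6f, %s, %d rebuild(s)\n",
              object@shift[1], object@shift[2], object@objective,
              if (object@converged) "converged" else "not converged",
              object@rebuilds))
})

setMethod("show", "TrackingSession", function(object) {
  cat(sprintf("TrackingSession in %s mode: %d reference frame(s), %d log record(s)\n",
              object@mode, length(object@refImages), nrow(object@log)))
})
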