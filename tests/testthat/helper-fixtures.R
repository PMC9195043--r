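# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoized for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

# Small detector with 1 mm pixel pitch: conversions are easy to reason about
# (1 mm at iso = 1.5 px on the detector).
tinySpec <- function(nCols = 64L, nRows = 48L) {
  DetectorSpec(nCols, nRows, nCols, nRows, sid = 1500, sad = 1000)
}

# Reduced-scale clinical panel: same active area and SID/SAD as the 1024x768
# imager, sampled on a 256x192 grid.
reducedSpec <- function() DetectorSpec(256L, 192L, 397, 298, 1500, 1000)

# Smooth strictly positive test image built from a few random cosine modes.
smoothImage <- function(nRows, nCols, seed = 1) {
  set.seed(seed)
  x <- seq(0, 1, length.out = nCols)
  y <- seq(0, 1, length.out = nRows)
  img <- matrix(0, nRows, nCols)
  for (k in 1:4) {
    img <- img + runif(1, 0.5, 2) *
      outer(sin(2 * pi * (k * runif(1, 0.5, 1.5) * y + runif(1))),
            cos(2 * pi * (k * runif(1, 0.5, 1.5) * x + runif(1))))
  }
  img - min(img) + 1
}

# Smooth image with one dominant localized feature (a Gaussian blob on a
# low-frequency background): the NCC surface over a few mm is unimodal, the
# landscape the tracker is designed for.
blobImage <- function(nRows, nCols, seed = 1) {
  set.seed(seed)
  cx <- runif(1, 0.35, 0.65) * nCols
  cy <- runif(1, 0.35, 0.65) * nRows
  sig <- runif(1, 5, 9)
  blob <- outer(seq_len(nRows), seq_len(nCols), function(r, c)
    exp(-((r - cy)^2 + (c - cx)^2) / (2 * sig^2)))
  bg <- outer(sin(seq(0, pi, length.out = nRows) + runif(1)),
              cos(seq(0, pi, length.out = nCols) + runif(1)))
  100 * blob + 10 * bg + 20
}

# Hand-coded double-loop NCC oracle: its own bilinear sampling (edge clamp),
# independent of the package's compiled path. Shifts are in detector pixels.
bruteNCCOracle <- function(refPx, livePx, mask, dxPx, dyPx) {
  nr <- nrow(refPx); nc <- ncol(refPx)
  num <- 0; na <- 0; nb <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    sr <- min(max(r - dyPx, 1), nr)
    sc <- min(max(c - dxPx, 1), nc)
    r0 <- min(max(floor(sr), 1), nr - 1)
    c0 <- min(max(floor(sc), 1), nc - 1)
    wr <- sr - r0; wc <- sc - c0
    a <- (1 - wr) * ((1 - wc) * refPx[r0, c0] + wc * refPx[r0, c0 + 1]) +
      wr * ((1 - wc) * refPx[r0 + 1, c0] + wc * refPx[r0 + 1, c0 + 1])
    b <- livePx[r, c]
    num <- num + a * b; na <- na + a * a; nb <- nb + b * b
  }
  num / (sqrt(na) * sqrt(nb))
}

# Small phantom + coarse detector bench for fast module-level tests.
tinyBench <- function() {
  if (is.null(.fixtures$tiny)) {
    phantom <- buildSpinePhantom(nVertebrae = 3L, bodyRadius = c(60, 50),
                                 spacing = 3)
    spec <- DetectorSpec(128L, 96L, 397, 298, 1500, 1000)
    .fixtures$tiny <- trackingTestBench(spec = spec, nProjections = 36,
                                        phantom = phantom)
  }
  .fixtures$tiny
}

# Full-protocol bench at the reduced clinical scale (90-projection
# reference scan of the default phantom); built once, shared by the
# acceptance-level tests.
protocolBench <- function() {
  if (is.null(.fixtures$protocol))
    .fixtures$protocol <- trackingTestBench(spec = reducedSpec(),
                                            nProjections = 90)
  .fixtures$protocol
}

# A reference set of tiny stub images at given angles (for pairing logic).
stubRefs <- function(angles) {
  ReferenceSet(lapply(seq_along(angles), function(i)
    ProjectionImage(matrix(1, 2, 2), gantry = angles[i], kind = "CBCT",
                    index = i)))
}

# Uniform frame on the tiny detector grid with a given mean.
uniformFrame <- function(value, kind = "IMR", beamOn = TRUE, nr = 8, nc = 8,
                         gantry = 0, index = 0L) {
  ProjectionImage(matrix(value, nr, nc), gantry = gantry, kind = kind,
                  beamOn = beamOn, index = index)
}

fullROI <- function(nr = 8, nc = 8, angle = 0) {
  ROITemplate(matrix(TRUE, nr, nc), angle)
}
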