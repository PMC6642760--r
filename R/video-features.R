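#' @include AllClasses.R biosignal.R
NULL

#' Optical-flow parameters
#'
#' Tunables of the silhouette motion descriptor: the Horn-Schunck
#' smoothness weight and iteration count, the motion-binarization threshold
#' `T` (constant for all subjects and activities), the median-filter
#' neighbourhood, how the two flow masks are combined into the moving
#' silhouette, and whether direction histograms weight each contour vector
#' by its magnitude or count it once.
#'
#' @param alpha Horn-Schunck smoothness weight (> 0, default 1).
#' @param nIter number of Jacobi iterations (default 100).
#' @param T binarization threshold on the flow magnitude, px/frame
#'   (default 0.5).
#' @param medianSize median-filter window (default 5, i.e. 5 x 5).
#' @param combine `"union"` (default) or `"intersection"` of the two masks.
#' @param weighting `"magnitude"` (default) or `"count"` histogram
#'   aggregation.
#' @return A list with class `"FlowParams"`.
#' @examples
#' flowParams()
#' @export
flowParams <- function(alpha = 1.0, nIter = 100, T = 0.5, medianSize = 5,
                       combine = c("union", "intersection"),
                       weighting = c("magnitude", "count")) {
  if (alpha <= 0) stop("'alpha' must be positive")
  if (nIter < 1) stop("'nIter' must be at least 1")
  if (T <= 0) stop("threshold 'T' must be positive")
  structure(list(alpha = alpha, nIter = as.integer(nIter), T = T,
                 medianSize = as.integer(medianSize),
                 combine = match.arg(combine),
                 weighting = match.arg(weighting)),
            class = "FlowParams")
}

#' @export
print.FlowParams <- function(x, ...) {
  cat(sprintf(
    "FlowParams: alpha = %g, %d iterations, T = %g px/frame, %dx%d median, %s masks, %s-weighted bins\n",
    x$alpha, x$nIter, x$T, x$medianSize, x$medianSize, x$combine,
    x$weighting))
  invisible(x)
}

#' Convert a frame to grayscale
#'
#' Single-channel frames pass through unchanged; 3-channel frames are
#' reduced to luminance with the ITU-R BT.601 weights
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param frame a matrix (already grayscale) or an `h x w x 3` array.
#' @return An intensity matrix.
#' @examples
#' toGrayscale(array(1, dim = c(2, 2, 3)))
#' @export
toGrayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3L] == 1L)
    return(frame[, , 1L])
  if (is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3L] == 3L)
    return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
           0.114 * frame[, , 3L])
  stop("unsupported channel count: expected 1 or 3 channels")
}

#' Horn-Schunck optical flow between two frames
#'
#' Estimates the dense motion field from frame `frameA` to `frameB` by the
#' classical Horn-Schunck method: the flow minimizing the
#' brightness-constancy error plus `alpha^2` times a smoothness penalty,
#' solved by the Jacobi fixed-point iteration from zero initial flow.
#' Identical or textureless frame pairs give exactly zero flow.
#'
#' Frames are intensities in `[0, 1]`; internally they are scaled to the
#' 8-bit 0..255 range on which the conventional smoothness weight
#' `alpha = 1` has its classical meaning (`alpha` trades off against the
#' squared image gradient, so it is tied to the intensity scale).
#'
#' @param frameA,frameB same-shape grayscale matrices.
#' @param params a [flowParams()].
#' @param trace if `TRUE`, also return the brightness-constancy residual
#'   after every iteration.
#' @return A list with matrices `u` (flow along image x, columns, rightward
#'   positive) and `v` (flow along image y, rows, downward positive), in
#'   pixels/frame, and optionally `residuals`.
#' @examples
#' f <- matrix(runif(64), 8, 8)
#' flow <- hornSchunck(f, f)
#' max(abs(flow$u))  # identical frames: zero flow
#' @export
hornSchunck <- function(frameA, frameB, params = flowParams(),
                        trace = FALSE) {
  frameA <- toGrayscale(frameA)
  frameB <- toGrayscale(frameB)
  if (!identical(dim(frameA), dim(frameB)))
    stop("'frameA' and 'frameB' must have the same shape")
  .hornSchunckCpp(frameA * 255, frameB * 255, params$alpha, params$nIter,
                  trace)
}

#' Median-filter the flow components
#'
#' Applies an n-by-n median filter (default 5 x 5) to `u` and `v`
#' independently, removing salt-and-pepper flow outliers. Border windows
#' shrink to the pixels available.
#'
#' @param flow a list with matrices `u`, `v`.
#' @param size window side length (default 5).
#' @return The filtered flow.
#' @export
medianFilterFlow <- function(flow, size = 5) {
  list(u = .medianFilter2dCpp(flow$u, as.integer(size)),
       v = .medianFilter2dCpp(flow$v, as.integer(size)))
}

#' Binarize the flow magnitude
#'
#' A pixel is moving iff its flow magnitude `sqrt(u^2 + v^2)` strictly
#' exceeds the threshold `T`.
#'
#' @param flow a list with matrices `u`, `v`.
#' @param T positive threshold in pixels/frame.
#' @return A logical matrix.
#' @export
motionMask <- function(flow, T) {
  if (T <= 0) stop("threshold 'T' must be positive")
  sqrt(flow$u^2 + flow$v^2) > T
}

#' Moving-silhouette mask from two flow masks
#'
#' Combines the motion masks of the flows into frame `n - 1` and out of it
#' (union by default, intersection by option) and fills enclosed holes:
#' background components not connected to the image border become
#' foreground.
#'
#' @param maskPrev motion mask of the flow between frames `n - 2` and
#'   `n - 1`.
#' @param maskNext motion mask of the flow between frames `n - 1` and `n`.
#' @param combine `"union"` (default) or `"intersection"`.
#' @return A logical silhouette mask.
#' @export
movingSilhouette <- function(maskPrev, maskNext,
                             combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!identical(dim(maskPrev), dim(maskNext)))
    stop("masks must have the same shape")
  m <- if (combine == "union") maskPrev | maskNext else maskPrev & maskNext
  EBImage::fillHull(m * 1L) > 0
}

#' Inner contour band of a silhouette
#'
#' Thickens the silhouette contour inward to approximately `width` pixels:
#' the band is the mask minus its erosion by a
#' `(2 * width + 1)`-pixel square, i.e. the inner boundary ring. Masks
#' thinner than twice the width erode away entirely and the band equals the
#' mask.
#'
#' @param mask a logical silhouette mask.
#' @param width band width in pixels (default 4).
#' @return A logical contour-band matrix, a subset of `mask`.
#' @export
thickenContour <- function(mask, width = 4) {
  storage.mode(mask) <- "integer"
  if (!any(mask)) return(mask > 0)
  eroded <- EBImage::erode(mask, EBImage::makeBrush(2L * width + 1L, "box"))
  mask > 0 & !(eroded > 0)
}

#' Eight-direction histogram of contour flow vectors
#'
#' Aggregates the flow vectors on the contour band into 8 direction bins of
#' 45 degrees. Angles are measured in display space (image x rightward,
#' y upward on screen, counter-clockwise); bin B1 is centered on 0 degrees
#' (covering 337.5..22.5), B2 on 45 degrees, and so on counter-clockwise.
#' Aggregation is magnitude-weighted by default, and the histogram is
#' normalized to sum to 1. If the band carries no motion at all, the
#' all-zero sentinel histogram is returned.
#'
#' @param flow a list with matrices `u`, `v`.
#' @param band logical contour-band matrix of the same shape.
#' @param weighting `"magnitude"` (default) or `"count"`.
#' @return Numeric length-8 vector `B1..B8`, summing to 1 (or all zero).
#' @examples
#' flow <- list(u = matrix(1, 4, 4), v = matrix(0, 4, 4))
#' directionHistogram(flow, matrix(TRUE, 4, 4))  # all mass in B1
#' @export
directionHistogram <- function(flow, band,
                               weighting = c("magnitude", "count")) {
  weighting <- match.arg(weighting)
  if (!identical(dim(flow$u), dim(band)))
    stop("'band' must match the flow shape")
  u <- flow$u[band]
  v <- flow$v[band]
  mag <- sqrt(u^2 + v^2)
  keep <- mag > 0
  h <- numeric(8L)
  names(h) <- paste0("B", 1:8)
  if (!any(keep)) return(h)
  ang <- (atan2(-v[keep], u[keep]) * 180 / pi) %% 360
  bin <- floor(((ang + 22.5) %% 360) / 45) + 1L
  w <- if (weighting == "magnitude") mag[keep] else rep(1, sum(keep))
  for (b in seq_len(8L)) h[b] <- sum(w[bin == b])
  h / sum(h)
}

#' Build the video feature vector of a clip
#'
#' Runs the full silhouette motion descriptor over an `N`-frame clip. For
#' every interior frame with both neighbouring flow fields (frames
#' `2 .. N - 1`): compute Horn-Schunck flow into and out of the frame,
#' median-filter the components, binarize both magnitudes with threshold
#' `T`, combine the masks into the moving silhouette, fill its holes,
#' thicken the contour inward to ~4 px, and aggregate the outgoing flow
#' vectors on that band into an 8-direction histogram. Histograms are
#' concatenated in time order, giving `(N - 2) * 8` values (304 for a
#' 40-frame clip), then the amplitude is normalized to the unit interval.
#' A clip without any detected motion raises a degenerate-vector error.
#'
#' @param frameClip `height x width x N` array (N >= 3) of grayscale
#'   frames.
#' @param params a [flowParams()].
#' @param contourWidth contour band width in pixels (default 4).
#' @return Numeric feature vector of length `(N - 2) * 8`.
#' @export
buildVideoFeature <- function(frameClip, params = flowParams(),
                              contourWidth = 4) {
  d <- dim(frameClip)
  if (length(d) != 3L || d[3L] < 3L)
    stop("'frameClip' must hold at least 3 frames")
  nF <- d[3L]
  flows <- vector("list", nF - 1L)
  masks <- vector("list", nF - 1L)
  for (k in seq_len(nF - 1L)) {
    fl <- hornSchunck(frameClip[, , k], frameClip[, , k + 1L], params)
    fl <- medianFilterFlow(fl, params$medianSize)
    flows[[k]] <- fl
    masks[[k]] <- motionMask(fl, params$T)
  }
  hists <- vector("list", nF - 2L)
  for (n in seq.int(2L, nF - 1L)) {
    sil <- movingSilhouette(masks[[n - 1L]], masks[[n]], params$combine)
    if (!any(sil)) {
      hists[[n - 1L]] <- numeric(8L)
      next
    }
    band <- thickenContour(sil, contourWidth)
    hists[[n - 1L]] <- directionHistogram(flows[[n]], band,
                                          params$weighting)
  }
  unitIntervalNormalize(unlist(hists, use.names = FALSE))
}
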