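# ---- low-level image operators -------------------------------------------
#
# Images are plain numeric matrices indexed [row, col] with a top-left
# origin; pixel coordinates reported to the user are 0-based (x = col - 1,
# y = row - 1).  All operators treat the image boundary by mirror
# reflection so that flat fields stay flat under filtering.

#' Reflect-pad a matrix
#'
#' Pads `img` by `pr` rows and `pc` columns on each side using mirror
#' reflection (edge pixel not duplicated where possible), the boundary
#' convention shared by all filters in this package.
#'
#' @param img numeric matrix.
#' @param pr,pc non-negative integers, padding in rows and columns.
#' @return a `(nrow + 2 pr) x (ncol + 2 pc)` matrix.
#' @keywords internal
reflect_pad <- function(img, pr, pc) {
  mirror <- function(k, n) {      # reflect about the edge pixel centers
    while (any(bad <- k < 1L | k > n)) {
      k[k < 1L] <- 2L - k[k < 1L]
      k[k > n] <- 2L * n - k[k > n]
    }
    k
  }
  ridx <- mirror((1L - pr):(nrow(img) + pr), nrow(img))
  cidx <- mirror((1L - pc):(ncol(img) + pc), ncol(img))
  img[ridx, cidx, drop = FALSE]
}

#' Linear convolution with reflective boundary
#'
#' Correlates `image` with `kernel` (both orientations coincide for the
#' symmetric kernels used throughout).  The kernel is applied as given; use
#' [normalize_kernel()] for smoothing kernels that must preserve the mean.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix of the same dimensions as `image`.
#' @examples
#' smooth_convolve(matrix(1:9, 3), matrix(1/9, 3, 3))
#' @export
smooth_convolve <- function(image, kernel) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L == 0L || kc %% 2L == 0L)
    stop("kernel dimensions must be odd")
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  pad <- reflect_pad(image, hr, hc)
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  # shift-and-add: one vectorized pass per kernel entry
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

#' Normalized 2-D Gaussian kernel
#'
#' @param sigma_px standard deviation in pixels.
#' @param half_width half-width in pixels; defaults to `ceiling(4 * sigma)`.
#' @return square matrix with odd side summing to 1.
#' @export
gaussian_kernel <- function(sigma_px, half_width = ceiling(4 * sigma_px)) {
  stopifnot(sigma_px > 0)
  x <- seq(-half_width, half_width)
  g <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Normalize a kernel to unit sum
#' @param kernel numeric matrix with nonzero sum.
#' @export
normalize_kernel <- function(kernel) {
  s <- sum(kernel)
  if (s == 0) stop("kernel sums to zero; cannot normalize")
  kernel / s
}

# separable Gaussian smoothing, much faster than the generic path
gaussian_smooth <- function(image, sigma_px) {
  hw <- ceiling(4 * sigma_px)
  g <- exp(-seq(-hw, hw)^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  nr <- nrow(image); nc <- ncol(image)
  pad <- reflect_pad(image, hw, 0L)
  tmp <- matrix(0, nr, nc)
  for (i in seq_along(g))
    tmp <- tmp + g[i] * pad[(i - 1L) + seq_len(nr), , drop = FALSE]
  pad <- reflect_pad(tmp, 0L, hw)
  out <- matrix(0, nr, nc)
  for (j in seq_along(g))
    out <- out + g[j] * pad[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

#' Spot-enhancing (Laplacian-of-Gaussian) filter
#'
#' Gaussian smoothing at scale `sigma_um` followed by the discrete 4-
#' neighbour Laplacian, scale-normalized by `sigma_px^2` and sign-flipped so
#' that bright blobs of radius about `sigma * sqrt(2)` produce positive
#' peaks.  This is the standard blob (spot) enhancement used ahead of
#' auto-thresholding in nuclear segmentation.
#'
#' @param image numeric matrix of intensities.
#' @param sigma_um filter scale in micrometres; for nuclei of radius r a
#'   matched scale is `r / sqrt(2)`.
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @return numeric matrix, same size as `image`; values are in intensity
#'   units (a.u.), approximately zero over flat background.
#' @export
spot_enhance <- function(image, sigma_um, pixel_size_um) {
  if (!is.numeric(sigma_um) || length(sigma_um) != 1L || sigma_um <= 0)
    stop("`sigma_um` must be a positive number")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  sigma_px <- sigma_um / pixel_size_um
  if (sigma_px < 0.5)
    stop("filter scale below 0.5 px; image is undersampled for this sigma")
  sm <- gaussian_smooth(image, sigma_px)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  -sigma_px^2 * smooth_convolve(sm, lap)
}

# ---- histograms, mode, triangle threshold --------------------------------

#' Intensity histogram
#'
#' Integer images get exact per-value counts; non-integer images are binned
#' into 256 equal-width bins over the observed range.
#'
#' @param image numeric matrix.
#' @param n_bins number of bins for non-integer data.
#' @return list with `bin_edges` (length `n + 1`), `counts` (length `n`) and
#'   `mids`, of class `"intensity_histogram"`.
#' @export
intensity_histogram <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  if (length(v) == 0L) stop("empty image")
  if (all(v == round(v))) {
    lo <- min(v); hi <- max(v)
    edges <- seq(lo - 0.5, hi + 0.5, by = 1)
    counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  } else {
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(bin_edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-length(edges)]) / 2),
            class = "intensity_histogram")
}

#' Most frequent integer pixel value
#'
#' Pixels are rounded to integers before counting; ties resolve to the
#' smallest value.  Used as the background estimate subtracted from the
#' Hoechst, Lysotracker and propidium-iodide channels.
#'
#' @param image numeric matrix.
#' @return integer scalar.
#' @export
histogram_mode <- function(image) {
  v <- round(as.vector(image))
  if (length(v) == 0L) stop("empty image")
  lo <- min(v)
  counts <- tabulate(v - lo + 1L)
  as.integer(lo + which.max(counts) - 1L)   # which.max takes first = smallest
}

#' Triangle auto-threshold
#'
#' Draws a line from the histogram peak to the farthest nonzero bin on the
#' longer-tail side and returns the intensity of the bin whose (height,
#' position) point lies at maximal perpendicular distance below that line.
#' Tie rules: among equally distant bins the middle one of the tied run
#' wins (so two equal spikes flanking an empty valley threshold at the
#' valley midpoint); when the two tails have equal length the right tail
#' is used.
#'
#' @param hist an `intensity_histogram`, or any list with `counts` and
#'   either `mids` or `bin_edges`.
#' @return threshold intensity (a bin midpoint); pixels strictly above it
#'   are foreground.
#' @export
triangle_threshold <- function(hist) {
  counts <- as.numeric(hist$counts)
  mids <- if (!is.null(hist$mids)) hist$mids
          else (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  nz <- which(counts > 0)
  if (length(nz) < 2L) stop("degenerate histogram: fewer than 2 nonzero bins")
  peak <- which.max(counts)
  left <- peak - nz[1L]
  right <- nz[length(nz)] - peak
  tail_bin <- if (right >= left) nz[length(nz)] else nz[1L]
  if (tail_bin == peak) stop("degenerate histogram: peak at the only tail")
  span <- if (tail_bin > peak) peak:tail_bin else tail_bin:peak
  # distance from (i, counts[i]) to the peak--tail line, in bin-index units
  x1 <- peak; y1 <- counts[peak]; x2 <- tail_bin; y2 <- counts[tail_bin]
  d <- abs((y2 - y1) * (span - x1) - (x2 - x1) * (counts[span] - y1)) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  best <- max(d)
  cand <- span[d >= best - 1e-12]
  thr_bin <- cand[ceiling(length(cand) / 2)]   # middle of the tied run
  mids[thr_bin]
}
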