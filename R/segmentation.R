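# ---- nuclear segmentation and ROI construction ---------------------------

#' Segment nuclei from a Hoechst image
#'
#' Enhancement (spot-enhancing LoG filter or plain Gaussian smoothing,
#' selectable per assay variant), triangle auto-threshold on the enhanced
#' image's 256-bin histogram, hole filling, and connected-component
#' labelling.  No size or shape filtering happens here; merged or spurious
#' objects are expected to be removed later by the outlier rulesets.
#'
#' @param hoechst_image numeric matrix (raw Hoechst counts).
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @param params list: `mode` one of `"spot"` or `"smooth"`; `sigma_um`
#'   filter scale (default 2, which keeps the positive LoG response of a
#'   ~5 um nucleus compact enough that densely plated neighbours stay
#'   separate).
#' @return list with `labels` (integer matrix, 0 = background) and `nuclei`,
#'   a data frame with one row per label: `label`, `centroid_x_px`,
#'   `centroid_y_px` (0-based), `pixel_count`, `area_um2`, `max_feret_um`,
#'   `circularity`.
#' @export
segment_nuclei <- function(hoechst_image, pixel_size_um,
                           params = list(mode = "spot", sigma_um = 2)) {
  mode <- match.arg(params$mode %||% "spot", c("spot", "smooth"))
  sigma_um <- params$sigma_um %||% 2
  enhanced <- if (mode == "spot") {
    spot_enhance(hoechst_image, sigma_um, pixel_size_um)
  } else {
    gaussian_smooth(hoechst_image, sigma_um / pixel_size_um)
  }
  h <- tryCatch(intensity_histogram(enhanced),
                error = function(e) NULL)
  thr <- if (is.null(h)) NULL else
    tryCatch(triangle_threshold(h), error = function(e) NULL)
  if (is.null(thr)) {
    warning("blank or degenerate image: no nuclei segmented")
    return(list(labels = matrix(0L, nrow(hoechst_image), ncol(hoechst_image)),
                nuclei = empty_nucleus_table()))
  }
  mask <- enhanced > thr
  mask <- EBImage::fillHull(mask * 1)
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  list(labels = labels,
       nuclei = nucleus_table(labels, pixel_size_um))
}

empty_nucleus_table <- function() {
  data.frame(label = integer(), centroid_x_px = numeric(),
             centroid_y_px = numeric(), pixel_count = integer(),
             area_um2 = numeric(), max_feret_um = numeric(),
             circularity = numeric())
}

# shape table for every label in a label map
nucleus_table <- function(labels, pixel_size_um) {
  n <- max(labels)
  if (n == 0L) return(empty_nucleus_table())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels)       # 0-based y
  cols <- (idx - 1L) %/% nrow(labels)      # 0-based x
  cnt <- tabulate(lab, nbins = n)
  cx <- rowsum_vec(cols, lab, n) / cnt
  cy <- rowsum_vec(rows, lab, n) / cnt
  sm <- vapply(seq_len(n), function(l) {
    sel <- lab == l
    m <- mask_from_pixels(rows[sel], cols[sel])
    unlist(shape_metrics(m, pixel_size_um))
  }, numeric(3))
  data.frame(label = seq_len(n), centroid_x_px = cx, centroid_y_px = cy,
             pixel_count = cnt, area_um2 = sm["area_um2", ],
             max_feret_um = sm["max_feret_um", ],
             circularity = sm["circularity", ])
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# build a tight logical mask from 0-based pixel coordinates
mask_from_pixels <- function(rows0, cols0) {
  r <- rows0 - min(rows0) + 1L
  c <- cols0 - min(cols0) + 1L
  m <- matrix(FALSE, max(r), max(c))
  m[cbind(r, c)] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shape metrics of a connected pixel mask
#'
#' * area: `pixel_count * pixel_size_um^2`;
#' * maximum Feret diameter: largest center-to-center distance between any
#'   two boundary pixels (the "nuclear diameter");
#' * circularity: `4 * pi * area / perimeter^2`, with the perimeter from a
#'   weighted boundary-step estimator (0.948 per axial step, 1.340 per
#'   diagonal step along the traced outer boundary), which is close to
#'   unbiased for large smooth shapes; may exceed 1 on small discrete masks.
#'
#' @param mask logical or 0/1 matrix, nonempty.
#' @param pixel_size_um physical pixel size.
#' @return list with `area_um2`, `max_feret_um`, `circularity`.
#' @export
shape_metrics <- function(mask, pixel_size_um) {
  mask <- mask != 0
  npix <- sum(mask)
  if (npix == 0L) stop("empty mask")
  area <- npix * pixel_size_um^2
  bp <- boundary_pixels(mask)
  # max Feret via convex hull of boundary centers (exact: the diameter of a
  # point set is attained on its hull)
  pts <- bp * pixel_size_um
  if (nrow(pts) == 1L) {
    feret <- pixel_size_um       # single pixel: nominal one-pixel diameter
  } else {
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    feret <- sqrt(max(outer(hp[, 1], hp[, 1], "-")^2 +
                      outer(hp[, 2], hp[, 2], "-")^2))
  }
  per <- perimeter_um(mask, pixel_size_um)
  list(area_um2 = area, max_feret_um = feret,
       circularity = 4 * pi * area / per^2)
}

# boundary pixels: foreground with at least one 4-neighbour outside the mask
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  nb <- pad[1:nr, 2:(nc + 1L), drop = FALSE] &
        pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] &
        pad[2:(nr + 1L), 1:nc, drop = FALSE] &
        pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  which(core & !nb, arr.ind = TRUE) - 1L    # 0-based (row, col)
}

# Perimeter by Moore boundary tracing of the outer contour, with weighted
# step lengths (0.948 per axial step, 1.340 per diagonal step) so that large
# rasterized disks measure close to their true circumference.
perimeter_um <- function(mask, pixel_size_um) {
  npix <- sum(mask)
  if (npix == 1L) return(2 * sqrt(pi) * pixel_size_um)  # circle-equivalent
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pad, arr.ind = TRUE)           # column-major: first col, then row
  start <- as.integer(fg[1L, ])
  # Moore neighbourhood, clockwise: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # direction index lookup for an offset (dr, dc)
  dir_of <- matrix(0L, 3L, 3L)
  for (d in 1:8) dir_of[dr[d] + 2L, dc[d] + 2L] <- d
  P <- start
  bdir <- 1L   # backtrack direction: W neighbour of start is background
  n_ax <- 0L; n_di <- 0L
  max_steps <- 8L * npix + 8L
  # The trace is a deterministic walk on (pixel, backtrack) states; once a
  # state recurs, the steps taken between its two visits form the closed
  # contour.  First-visit counters make the cycle extraction exact.
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(P[1L], P[2L], bdir), c(0L, 0L), envir = seen)
  repeat {
    found <- 0L
    for (k in 1:8) {                         # scan clockwise after backtrack
      d <- (bdir - 1L + k) %% 8L + 1L
      r2 <- P[1L] + dr[d]; c2 <- P[2L] + dc[d]
      if (pad[r2, c2]) { found <- d; break }
    }
    if (found == 0L) break                   # no 8-neighbour: lone pixel
    if (dr[found] == 0L || dc[found] == 0L) n_ax <- n_ax + 1L
    else n_di <- n_di + 1L
    dprev <- (bdir - 1L + k - 1L) %% 8L + 1L # background cell just before hit
    bcell <- c(P[1L] + dr[dprev], P[2L] + dc[dprev])
    P <- c(P[1L] + dr[found], P[2L] + dc[found])
    off <- bcell - P
    bdir <- dir_of[off[1L] + 2L, off[2L] + 2L]
    key <- paste(P[1L], P[2L], bdir)
    prev <- get0(key, envir = seen, ifnotfound = NULL)
    if (!is.null(prev)) {
      n_ax <- n_ax - prev[1L]; n_di <- n_di - prev[2L]
      break
    }
    assign(key, c(n_ax, n_di), envir = seen)
    if (n_ax + n_di > max_steps) break       # safety
  }
  steps <- 0.948 * n_ax + 1.340 * n_di
  if (steps == 0) return(2 * sqrt(pi * npix) * pixel_size_um)
  steps * pixel_size_um
}

#' Build annular cytosolic ROIs around segmented nuclei
#'
#' For each nucleus the cytosolic ROI is the annulus of non-nuclear pixels
#' whose Euclidean center-to-center distance to that nucleus's pixels is at
#' most `band_um` (default 3, the ring from the nuclear border to 3 microns
#' beyond it).  Pixels within the band of two or more nuclei go to the
#' nearest nucleus, ties to the lower label; annuli are clipped at field
#' edges.  The result is membrane-agnostic: a pixel geometrically closer to
#' a neighbouring nucleus belongs to that neighbour's annulus.
#'
#' @param label_map integer matrix of nucleus labels (0 = background).
#' @param pixel_size_um physical pixel size.
#' @param band_um annulus width in micrometres.
#' @return list with `cytosol_labels` (integer matrix; 0 = no ROI) and
#'   `nuclear_labels` (the input map).  The two maps are disjoint by
#'   construction.
#' @export
build_cytosol_rois <- function(label_map, pixel_size_um, band_um = 3) {
  if (band_um <= 0) stop("`band_um` must be positive")
  nr <- nrow(label_map); nc <- ncol(label_map)
  n <- max(label_map)
  band_px <- band_um / pixel_size_um
  pad <- as.integer(ceiling(band_px)) + 1L
  best_d <- matrix(Inf, nr, nc)
  best_l <- matrix(0L, nr, nc)
  if (n > 0L) {
    idx_all <- which(label_map > 0L)
    lab_all <- label_map[idx_all]
    rows_all <- (idx_all - 1L) %% nr + 1L
    cols_all <- (idx_all - 1L) %/% nr + 1L
    for (l in seq_len(n)) {
      sel <- lab_all == l
      if (!any(sel)) next
      r0 <- max(1L, min(rows_all[sel]) - pad); r1 <- min(nr, max(rows_all[sel]) + pad)
      c0 <- max(1L, min(cols_all[sel]) - pad); c1 <- min(nc, max(cols_all[sel]) + pad)
      win <- matrix(1, r1 - r0 + 1L, c1 - c0 + 1L)
      win[cbind(rows_all[sel] - r0 + 1L, cols_all[sel] - c0 + 1L)] <- 0
      d <- EBImage::distmap(win)     # distance to this nucleus's pixels
      d <- matrix(as.numeric(d), nrow(win), ncol(win))
      cand <- which(d > 0 & d <= band_px + 1e-9)
      if (length(cand) == 0L) next
      wr <- (cand - 1L) %% nrow(win) + r0
      wc <- (cand - 1L) %/% nrow(win) + c0
      gi <- (wc - 1L) * nr + wr
      upd <- d[cand] < best_d[gi]    # strict: ties keep the lower label
      gi <- gi[upd]
      best_d[gi] <- d[cand][upd]
      best_l[gi] <- l
    }
    best_l[label_map > 0L] <- 0L     # annulus excludes every nucleus pixel
  }
  list(cytosol_labels = best_l, nuclear_labels = label_map)
}
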