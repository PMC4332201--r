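# Independent brute-force oracles used across the suite.  Each reimplements
# the documented rule from scratch (loops, exhaustive enumeration), never
# calling the code path it checks.

# exhaustive point-to-line triangle threshold over all bins
oracle_triangle <- function(counts, mids) {
  nz <- which(counts > 0)
  peak <- which.max(counts)
  left <- peak - nz[1]
  right <- nz[length(nz)] - peak
  tail_bin <- if (right >= left) nz[length(nz)] else nz[1]
  span <- if (tail_bin > peak) peak:tail_bin else tail_bin:peak
  p1 <- c(peak, counts[peak]); p2 <- c(tail_bin, counts[tail_bin])
  v <- p2 - p1; vn <- sqrt(sum(v^2))
  dist <- vapply(span, function(i) {
    w <- c(i, counts[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / vn     # cross-product distance
  }, numeric(1))
  best <- span[dist >= max(dist) - 1e-12]
  mids[best[ceiling(length(best) / 2)]]
}

# all-pairs boundary-distance maximum Feret (no convex hull)
oracle_feret <- function(mask, pixel_size_um) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nbrs <- c(if (i > 1) mask[i - 1, j] else FALSE,
              if (i < nr) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE,
              if (j < nc) mask[i, j + 1] else FALSE)
    if (!all(nbrs)) pts <- rbind(pts, c(i - 1, j - 1))
  }
  if (is.null(pts) || nrow(pts) == 1L) return(pixel_size_um)
  best <- 0
  for (a in seq_len(nrow(pts) - 1L)) for (b in (a + 1L):nrow(pts)) {
    d <- sqrt(sum((pts[a, ] - pts[b, ])^2))
    if (d > best) best <- d
  }
  best * pixel_size_um
}

# direct nested-loop convolution with reflection boundary
oracle_convolve <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1) %/% 2; hc <- (kc - 1) %/% 2
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      ii <- reflect(i + a - 1L - hr, nr)
      jj <- reflect(j + b - 1L - hc, nc)
      acc <- acc + kernel[a, b] * image[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# per-record, per-rule brute-force re-evaluation of an exclusion ruleset
oracle_exclusions <- function(records, ruleset) {
  pop_mean <- function(col) mean(records[[col]], na.rm = TRUE)
  flags <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- character(0)
    for (j in seq_len(nrow(ruleset))) {
      r <- ruleset[j, ]
      col <- if (r$statistic == "area") "area_um2"
             else if (r$statistic == "circularity") "circularity"
             else if (r$statistic == "sd")
               paste(r$channel, r$roi, "sd", sep = "_")
             else {
               b <- paste(r$channel, r$roi, "mean", sep = "_")
               if (paste0(b, "_corr") %in% names(records))
                 paste0(b, "_corr") else b
             }
      v <- records[[col]][i]
      bound <- if (r$bound_type == "abs") r$bound else r$bound * pop_mean(col)
      viol <- if (r$relation == "gt") isTRUE(v > bound) else isTRUE(v < bound)
      if (viol) hit <- c(hit, r$rule_id)
    }
    flags[i] <- paste(hit, collapse = ",")
  }
  flags
}

# one-line linear scan death-call oracle
oracle_death <- function(pi_trace, threshold) {
  for (f in seq_along(pi_trace)) if (pi_trace[f] > threshold) return(f)
  NA_integer_
}

# randomized cell records with the columns the rulesets read
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    label = seq_len(n),
    area_um2 = stats::runif(n, 10, 500),
    circularity = stats::runif(n, 0, 1.2),
    anion_cytosol_sd = stats::rlnorm(n, 3, 1.5),
    lysotracker_cytosol_sd = stats::rlnorm(n, 3, 1.2),
    lysotracker_nuclear_mean = stats::rlnorm(n, 5, 0.8),
    hoechst_nuclear_sd = stats::rlnorm(n, 4, 0.8),
    pi_nuclear_mean = stats::runif(n, 0, 400),
    anion_cytosol_mean = stats::rlnorm(n, 6, 0.3),
    hoechst_nuclear_mean = stats::rlnorm(n, 6.5, 0.2),
    lysotracker_cytosol_mean = stats::rlnorm(n, 5.5, 0.3))
}

# Monte-Carlo expectation of tertile death fractions under the logistic
# per-frame hazard, from the closed-form survival function (independent of
# the generator's per-frame sampling path)
oracle_tertile_death <- function(cfg, n_mc = 200000L, seed = 12345L) {
  set.seed(seed)
  f <- stats::rlnorm(n_mc, cfg$fba_lognormal_mu, cfg$fba_lognormal_sigma)
  p <- stats::plogis(cfg$death_base_logodds +
                       cfg$death_coupling_beta * (log(f) - cfg$fba_lognormal_mu))
  p_death <- 1 - (1 - p)^(cfg$n_frames - 1L)
  q <- stats::quantile(f, c(1 / 3, 2 / 3))
  list(low = mean(p_death[f <= q[1]]),
       mid = mean(p_death[f > q[1] & f <= q[2]]),
       high = mean(p_death[f > q[2]]),
       whole = mean(p_death))
}

# standard fixtures -------------------------------------------------------

clean_standard_config <- function(seed = 1L) {
  simulation_config(dead_fraction = 0, debris_rate_per_mm2 = 0,
                    rng_seed = seed)
}

isolated_clean_config <- function(seed = 5L) {
  simulation_config(field_width_px = 500L, field_height_px = 500L,
                    cell_density_per_mm2 = 400, dead_fraction = 0,
                    debris_rate_per_mm2 = 0, noise_poisson = FALSE,
                    noise_read_sd = 0, min_sep_extra_um = 12,
                    rng_seed = seed)
}

small_field_config <- function(seed = 11L, ...) {
  simulation_config(field_width_px = 300L, field_height_px = 300L,
                    rng_seed = seed, ...)
}

# match segmented nuclei to ground-truth cells by centroid distance
match_to_truth <- function(nuclei, truth, pixel_size_um) {
  tr <- truth[truth$is_cell, ]
  rad_px <- sqrt(tr$true_nucleus_area_um2 / pi) / pixel_size_um
  d <- sqrt(outer(nuclei$centroid_x_px, tr$centroid_x_px, "-")^2 +
              outer(nuclei$centroid_y_px, tr$centroid_y_px, "-")^2)
  list(recall = mean(apply(d, 2, min) < rad_px),
       precision = mean(apply(d, 1, min) < mean(rad_px)),
       nearest_truth = apply(d, 1, which.min),
       nearest_dist_px = apply(d, 1, min),
       truth_cells = tr)
}
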