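test_that("generation is bit-identical under a fixed seed and validates
           its configuration", {
  cfg <- small_field_config(seed = 77L)
  a <- generate_field(cfg)
  b <- generate_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  # rendered pixels are nonnegative 16-bit integers
  for (ch in a$field$channels) {
    expect_true(all(ch == round(ch)))
    expect_gte(min(ch), 0); expect_lte(max(ch), 65535)
  }
  expect_error(simulation_config(field_width_px = 0), "positive")
  expect_error(simulation_config(pixel_size_um = -1), "positive")
  expect_error(simulation_config(dead_fraction = 1.5), "dead_fraction")
})

test_that("cell count follows plating density and FBA heterogeneity follows
           the configured lognormal CV", {
  # 1200 cells/mm^2 on a 0.25 mm^2 field: expect ~300 +- Poisson error
  cfg <- clean_standard_config(seed = 2L)
  g <- generate_field(cfg)
  n <- sum(g$truth$is_cell)
  area_mm2 <- cfg$field_width_px * cfg$field_height_px *
    (cfg$pixel_size_um / 1000)^2
  lambda <- cfg$cell_density_per_mm2 * area_mm2
  expect_gt(n, lambda - 4 * sqrt(lambda))
  expect_lt(n, lambda + 4 * sqrt(lambda))
  # sigma chosen for CV 15%: sample CV of true intensities within 10%
  # relative of 100 * sqrt(exp(sigma^2) - 1)
  sigma <- cfg$fba_lognormal_sigma
  cv_expected <- 100 * sqrt(exp(sigma^2) - 1)
  fba <- unlist(lapply(1:4, function(s) {
    gg <- generate_field(clean_standard_config(seed = s))
    gg$truth$true_fba[gg$truth$is_cell]
  }))
  expect_gt(length(fba), 1000)
  cv <- coefficient_of_variation(fba)
  expect_lt(abs(cv - cv_expected) / cv_expected, 0.10)
})

test_that("ideal ground-truth masks recover the rendered cytosol
           intensities within noise", {
  cfg <- small_field_config(seed = 31L, dead_fraction = 0,
                            debris_rate_per_mm2 = 0)
  g <- generate_field(cfg)
  tr <- g$truth
  px <- cfg$pixel_size_um
  img <- g$field$channels$anion
  nr <- nrow(img); nc <- ncol(img)
  radii <- sqrt(tr$true_nucleus_area_um2 / pi)
  # signed border distance of every pixel to every cell; the ideal ROI of a
  # cell is its 3-um ring restricted to pixels it owns (nearest border)
  ys <- rep(0:(nr - 1), times = nc); xs <- rep(0:(nc - 1), each = nr)
  dmat <- vapply(seq_len(nrow(tr)), function(i)
    sqrt((ys - tr$centroid_y_px[i])^2 + (xs - tr$centroid_x_px[i])^2) * px -
      radii[i], numeric(nr * nc))
  owner <- max.col(-dmat, ties.method = "first")
  own_d <- dmat[cbind(seq_len(nr * nc), owner)]
  zs <- vapply(seq_len(nrow(tr)), function(i) {
    ring <- owner == i & own_d > 0 & own_d <= 3
    v <- img[ring] - cfg$background_level
    se <- stats::sd(v) / sqrt(sum(ring))
    (mean(v) - tr$true_fba[i]) / se
  }, numeric(1))
  expect_gt(mean(abs(zs) <= 3), 0.98)
})

test_that("a 181-frame, 10-min time-lapse spans 30 h and death converges to
           the marginal hazard probability", {
  cfg <- simulation_config(field_width_px = 1200L, field_height_px = 1200L,
                           dead_fraction = 0, debris_rate_per_mm2 = 0,
                           rng_seed = 8L)
  tl <- generate_timelapse(cfg, render = FALSE)
  tr1 <- tl$traces[[1]]
  expect_identical(length(tr1$time_min), 181L)
  expect_equal(max(tr1$time_min), 30 * 60)   # 30 h in minutes
  # marginal death probability: binomial CI around the closed form
  dead <- !is.na(tl$truth$death_frame[tl$truth$is_cell])
  p <- death_hazard <- oracle_tertile_death(cfg)$whole
  n <- sum(tl$truth$is_cell)
  expect_lt(abs(mean(dead) - p), 3 * sqrt(p * (1 - p) / n))
  # death frames never exceed n_frames
  df <- tl$truth$death_frame
  expect_true(all(is.na(df) | df <= cfg$n_frames))
})

test_that("death couples to FBA when beta > 0 and decouples at beta = 0", {
  cfg0 <- simulation_config(field_width_px = 1300L, field_height_px = 1300L,
                            dead_fraction = 0, debris_rate_per_mm2 = 0,
                            death_coupling_beta = 0, rng_seed = 13L)
  tl0 <- generate_timelapse(cfg0, render = FALSE)
  t0 <- tl0$truth[tl0$truth$is_cell, ]
  dead0 <- !is.na(t0$death_frame)
  r0 <- correlate_per_cell(log(t0$true_fba), as.numeric(dead0))
  expect_lt(abs(r0$r), 3 / sqrt(r0$n))
  cfg1 <- simulation_config(field_width_px = 1300L, field_height_px = 1300L,
                            dead_fraction = 0, debris_rate_per_mm2 = 0,
                            rng_seed = 13L)
  tl1 <- generate_timelapse(cfg1, render = FALSE)
  t1 <- tl1$truth[tl1$truth$is_cell, ]
  dead1 <- !is.na(t1$death_frame)
  r1 <- correlate_per_cell(log(t1$true_fba), as.numeric(dead1))
  expect_gt(r1$r, 2 / sqrt(r1$n))
  # direct Monte-Carlo of the same hazard outside the generator gives the
  # same correlation within sampling error
  set.seed(99)
  f_mc <- rlnorm(200000, cfg1$fba_lognormal_mu, cfg1$fba_lognormal_sigma)
  p_mc <- plogis(cfg1$death_base_logodds +
                   cfg1$death_coupling_beta * (log(f_mc) - cfg1$fba_lognormal_mu))
  d_mc <- runif(200000) < 1 - (1 - p_mc)^(cfg1$n_frames - 1)
  r_mc <- cor(log(f_mc), as.numeric(d_mc))
  expect_lt(abs(r1$r - r_mc), 3 / sqrt(r1$n))
})

test_that("rendered dead cells carry the nonviable phenotype and debris is
           flagged as non-cell", {
  cfg <- small_field_config(seed = 17L, dead_fraction = 0.15,
                            debris_rate_per_mm2 = 100)
  g <- generate_field(cfg)
  expect_gt(sum(!g$truth$is_cell), 0)
  seg <- segment_nuclei(g$field$channels$hoechst, cfg$pixel_size_um)
  rois <- build_cytosol_rois(seg$labels, cfg$pixel_size_um)
  rec <- measure_cells(g$field, rois, seg$nuclei)
  rec <- subtract_backgrounds(rec, g$field, control_mean_anion = 0)
  mt <- match_to_truth(rec, g$truth, cfg$pixel_size_um)
  near <- mt$truth_cells[mt$nearest_truth, ]
  is_dead_cell <- !near$viable_at_t0 & mt$nearest_dist_px < 8
  sc <- score_viability(rec, cfg$pixel_size_um)
  # no rendered dead cell is ever scored viable
  expect_identical(sum(sc$records$viable & is_dead_cell), 0L)
  # live-cell viability scoring matches the generator's live count closely
  n_live_true <- sum(g$truth$is_cell & g$truth$viable_at_t0)
  expect_gt(sc$n_viable, 0.85 * n_live_true)
  expect_lte(sc$n_viable, n_live_true)
})
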