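# a tiny two-cell field with hand-built ROIs for arithmetic checks
tiny_field <- function() {
  img <- function(v) matrix(v, 10, 10)
  nuc <- matrix(0L, 10, 10); nuc[2:4, 2:4] <- 1L; nuc[7:9, 7:9] <- 2L
  cyt <- matrix(0L, 10, 10); cyt[2:4, 5:6] <- 1L; cyt[7:9, 4:5] <- 2L
  anion <- img(0); anion[cyt == 1L] <- 100; anion[cyt == 2L] <- 200
  hoechst <- img(40); hoechst[nuc == 1L] <- 200; hoechst[nuc == 2L] <- 300
  field <- image_field(list(hoechst = hoechst, anion = anion,
                            lysotracker = img(50), pi = img(10)),
                       pixel_size_um = 1)
  list(field = field, rois = list(nuclear_labels = nuc, cytosol_labels = cyt))
}

test_that("measurement returns exact means, sds and the integrated
           identity", {
  tf <- tiny_field()
  rec <- measure_cells(tf$field, tf$rois)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$anion_cytosol_mean, c(100, 200))
  expect_equal(rec$anion_cytosol_sd, c(0, 0))
  expect_equal(rec$hoechst_nuclear_mean, c(200, 300))
  # integrated = mean * pixel_count for every channel/ROI
  for (ch in c("hoechst", "anion", "lysotracker", "pi"))
    for (roi in c("nuclear", "cytosol")) {
      expect_equal(rec[[paste(ch, roi, "integrated", sep = "_")]],
                   rec[[paste(ch, roi, "mean", sep = "_")]] *
                     rec[[paste(ch, roi, "pixel_count", sep = "_")]])
    }
})

test_that("background subtraction uses the vehicle control for anion and
           the image mode elsewhere", {
  tf <- tiny_field()
  rec <- measure_cells(tf$field, tf$rois)
  out <- subtract_backgrounds(rec, tf$field, control_mean_anion = 120)
  expect_equal(out$anion_cytosol_mean_corr, c(100, 200) - 120)  # keeps sign
  expect_equal(out$hoechst_nuclear_mean_corr, c(200, 300) - 40)
  expect_equal(out$pi_nuclear_mean_corr, c(0, 0))
  expect_error(subtract_backgrounds(rec, tf$field), "vehicle")
  # a vehicle field processed as its own control centers on zero
  expect_equal(mean(subtract_backgrounds(
    rec, tf$field, mean(rec$anion_cytosol_mean))$anion_cytosol_mean_corr), 0)
})

test_that("exclusion flags reproduce the documented thresholds", {
  rec <- random_records(6, seed = 1)
  rec$area_um2 <- c(40, 100, 100, 100, 100, 400)
  rec$circularity <- c(0.9, 0.55, 0.9, 0.9, 0.9, 0.9)
  rs <- exclusion_ruleset("accumulation_assay")
  out <- apply_exclusions(rec, rs, 0.65)
  expect_match(out$flags[1], "area_small")      # 40 < 47 um^2
  expect_match(out$flags[2], "circ_low")        # circularity 0.55 < 0.6
  expect_match(out$flags[6], "area_large")      # 400 > 360 um^2
  # timelapse variant uses the looser day-0 bounds
  out2 <- apply_exclusions(rec, exclusion_ruleset("timelapse_assay"), 0.65)
  expect_false(grepl("area_small", out2$flags[1]))  # 40 > 36
  expect_match(out2$flags[6], "area_large")         # 400 > 252
  expect_error(apply_exclusions(rec[0, ], rs, 0.65), "empty")
})

test_that("exclusion flagging equals brute-force rule evaluation, is
           idempotent and order-independent", {
  rec <- random_records(300, seed = 42)
  for (name in c("accumulation_assay", "viability_assay", "timelapse_assay")) {
    rs <- exclusion_ruleset(name)
    out <- apply_exclusions(rec, rs, 0.65)
    expect_identical(out$flags, oracle_exclusions(rec, rs))
    # idempotent: reapplying does not change flags
    out2 <- apply_exclusions(out, rs, 0.65)
    expect_identical(out2$flags, out$flags)
    # order-independent: a permutation flags the same records
    set.seed(7); perm <- sample(nrow(rec))
    outp <- apply_exclusions(rec[perm, ], rs, 0.65)
    expect_identical(outp$flags[order(perm)], out$flags)
  }
})

test_that("viability scoring applies the PI, area, Hoechst-SD and
           circularity rules and is monotone", {
  rec <- random_records(20, seed = 3)
  rec$area_um2 <- rep(100, 20)
  rec$circularity <- rep(0.9, 20)
  rec$hoechst_nuclear_sd <- rep(50, 20)
  rec$pi_nuclear_mean <- rep(50, 20)
  rec$pi_nuclear_mean[1] <- 250          # PI-positive: nonviable
  rec$area_um2[2] <- 30                  # too small: not counted
  sc <- score_viability(rec, 0.65)
  expect_false(sc$records$viable[1])
  expect_false(sc$records$viable[2])
  expect_identical(sc$n_viable, 18L)
  # adding a PI-positive cell never increases the viable count
  extra <- rec[1, ]; extra$pi_nuclear_mean <- 300
  sc2 <- score_viability(rbind(rec, extra), 0.65)
  expect_lte(sc2$n_viable, sc$n_viable)
  expect_error(score_viability(rec[, setdiff(names(rec), "pi_nuclear_mean")],
                               0.65), "PI")
})

test_that("death detection matches a linear-scan oracle and is invariant to
           appended post-death frames", {
  # direct rule: background 40 already subtracted
  tr <- timelapse_trace(1, c(0, 10, 20), c(40, 90, 110), c(1, 1, 1))
  expect_identical(detect_death(tr), 3L)
  expect_identical(detect_death(timelapse_trace(1, 0:4 * 10, rep(0, 5),
                                                rep(1, 5))), NA_integer_)
  set.seed(5)
  for (i in 1:200) {
    p <- rnorm(20, 60, 40)
    tr <- timelapse_trace(i, seq(0, 190, 10), p, rep(1, 20))
    expect_identical(detect_death(tr), oracle_death(p, 100))
    # appending frames after a detected death never changes the call
    if (!is.na(detect_death(tr))) {
      tr2 <- timelapse_trace(i, seq(0, 290, 10), c(p, rnorm(10, 60, 40)),
                             rep(1, 30))
      expect_identical(detect_death(tr2), detect_death(tr))
    }
  }
})

test_that("traces from frozen frame-1 ROIs are flat without death and cross
           the threshold at the rendered death frame", {
  cfg <- simulation_config(field_width_px = 220L, field_height_px = 220L,
                           n_frames = 10L, dead_fraction = 0,
                           debris_rate_per_mm2 = 0,
                           death_base_logodds = -30,  # no spontaneous death
                           rng_seed = 23L)
  tl <- generate_timelapse(cfg, render = TRUE)
  sf <- segment_nuclei(tl$fields[[1]]$channels$hoechst, cfg$pixel_size_um)
  rois <- build_cytosol_rois(sf$labels, cfg$pixel_size_um)
  traces <- link_and_trace(tl$fields, rois)
  # static fixture: flat PI traces, no deaths
  expect_true(all(vapply(traces, function(t) is.na(t$death_frame),
                         logical(1))))
  rngs <- vapply(traces, function(t) diff(range(t$pi)), numeric(1))
  expect_lt(max(rngs), 50)
  # now with forced deaths: PI exceeds the threshold from the true frame on
  cfg2 <- simulation_config(field_width_px = 220L, field_height_px = 220L,
                            n_frames = 10L, dead_fraction = 0,
                            debris_rate_per_mm2 = 0,
                            death_base_logodds = 0, death_coupling_beta = 0,
                            rng_seed = 24L)
  tl2 <- generate_timelapse(cfg2, render = TRUE)
  sf2 <- segment_nuclei(tl2$fields[[1]]$channels$hoechst, cfg2$pixel_size_um)
  rois2 <- build_cytosol_rois(sf2$labels, cfg2$pixel_size_um)
  traces2 <- link_and_trace(tl2$fields, rois2)
  mt <- match_to_truth(sf2$nuclei, tl2$truth, cfg2$pixel_size_um)
  tru <- tl2$truth[tl2$truth$is_cell, ]
  for (i in seq_along(traces2)) {
    if (mt$nearest_dist_px[i] > 3) next
    want <- tru$death_frame[mt$nearest_truth[i]]
    got <- traces2[[i]]$death_frame
    if (!is.na(want) && want > 1)
      expect_lte(abs(got - want), 1)
  }
  # fba_over_hoechst: simple ratio, undefined on nonpositive Hoechst
  t0 <- attr(traces2, "t0")
  expect_true(all(is.finite(t0$fba_over_hoechst) |
                    t0$hoechst_nuclear_mean <=
                      histogram_mode(tl2$fields[[1]]$channels$hoechst)))
  expect_error(link_and_trace(tl2$fields[1], rois2), "2 frames")
})
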