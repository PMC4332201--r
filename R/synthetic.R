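# ---- synthetic hepatocyte field generator --------------------------------
#
# Renders multi-channel fields that mimic the statistical structure the
# analysis assumes: nuclei as smooth Hoechst blobs at plating density,
# a uniform cytoplasmic fluorescent-bile-acid (FBA) signal whose per-cell
# amplitude follows a lognormal law, a Lysotracker vital-dye channel, a
# propidium-iodide (PI) channel that lights up in dead cells, debris that
# trips the exclusion rules, additive background, and optional Poisson shot
# noise plus Gaussian read noise.  Every run is reproducible from
# `rng_seed` and accompanied by a ground-truth table.

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_field()] /
#' [generate_timelapse()].  Defaults describe the standard assay: a
#' 770 x 770 px field at 0.65 um/px (0.25 mm^2), hepatocytes plated at
#' 1200 cells/mm^2 (about 300 per field), nuclear radius 5.0 +/- 0.3 um,
#' lognormal cell-to-cell FBA heterogeneity with sigma = 0.15 (CV about
#' 15%), and a 10-min-interval, 181-frame (30 h) time-lapse in which the
#' per-frame log-odds of death increase by `death_coupling_beta` per unit
#' log-FBA.
#'
#' @param field_width_px,field_height_px field size in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param cell_density_per_mm2 expected plating density.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd nuclear radius law
#'   (normal, truncated at 3 sd).
#' @param fba_lognormal_mu,fba_lognormal_sigma log-scale location and sd of
#'   the per-cell true cytosolic FBA intensity (a.u. above background).
#' @param hoechst_mean,hoechst_sd per-cell nuclear Hoechst amplitude law.
#' @param lyso_mean,lyso_sd per-cell cytoplasmic Lysotracker amplitude law.
#' @param marker_rho log-scale correlation between the Lysotracker-channel
#'   amplitude and FBA (used by the immunofluorescence-correlation assay,
#'   where the Lysotracker slot carries the antibody marker).
#' @param dead_fraction fraction of cells dead at plating (t0).
#' @param death_base_logodds per-frame log-odds of death for a cell at the
#'   median FBA (time-lapse mode).
#' @param death_coupling_beta increase in per-frame log-odds of death per
#'   unit log-FBA; 0 decouples death from accumulation.
#' @param frame_interval_min,n_frames time-lapse sampling (10 min x 181
#'   frames spans 30 h).
#' @param noise_read_sd Gaussian read noise sd (counts).
#' @param noise_poisson logical, apply Poisson shot noise.
#' @param debris_rate_per_mm2 expected density of sub-cellular debris.
#' @param background_level additive background (counts).
#' @param cyto_extent_um cytoplasm extent beyond the nuclear border; must
#'   exceed the 3-um measurement annulus so segmentation jitter cannot push
#'   the annulus off the rendered cytoplasm.
#' @param pi_live_level,pi_dead_level PI amplitude over background for live
#'   and dead cells.
#' @param fba_dead_decay per-frame multiplicative FBA decay after death.
#' @param min_sep_extra_um extra center-to-center clearance added to the sum
#'   of nuclear radii during rejection sampling; set negative (touching
#'   mode) to stress-test segmentation with merging nuclei.
#' @param rng_seed integer seed; identical seed + config gives bit-identical
#'   fields.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(field_width_px = 770L,
                              field_height_px = 770L,
                              pixel_size_um = 0.65,
                              cell_density_per_mm2 = 1200,
                              nucleus_radius_um_mean = 5.0,
                              nucleus_radius_um_sd = 0.3,
                              fba_lognormal_mu = log(500),
                              fba_lognormal_sigma = 0.15,
                              hoechst_mean = 800,
                              hoechst_sd = 60,
                              lyso_mean = 300,
                              lyso_sd = 25,
                              marker_rho = 0,
                              dead_fraction = 0.05,
                              death_base_logodds = -5.5,
                              death_coupling_beta = 2.2,
                              frame_interval_min = 10,
                              n_frames = 181L,
                              noise_read_sd = 2,
                              noise_poisson = TRUE,
                              debris_rate_per_mm2 = 50,
                              background_level = 100,
                              cyto_extent_um = 5,
                              pi_live_level = 10,
                              pi_dead_level = 400,
                              fba_dead_decay = 0.97,
                              min_sep_extra_um = 1,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("field_width_px", "field_height_px", "pixel_size_um",
              "cell_density_per_mm2", "nucleus_radius_um_mean",
              "frame_interval_min", "n_frames"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("invalid config: `%s` must be a positive number", f))
  if (cfg$dead_fraction < 0 || cfg$dead_fraction > 1)
    stop("invalid config: `dead_fraction` must be in [0, 1]")
  if (cfg$noise_read_sd < 0) stop("invalid config: `noise_read_sd` negative")
  if (cfg$debris_rate_per_mm2 < 0) stop("invalid config: negative debris rate")
  if (cfg$cyto_extent_um <= 0) stop("invalid config: `cyto_extent_um`")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  class(cfg) <- "simulation_config"
  cfg
}

# run `expr` under the config seed without disturbing the caller's RNG
with_config_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rnorm_trunc <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  pmin(pmax(stats::rnorm(n, mean, sd), mean - k * sd), mean + k * sd)
}

# sample non-overlapping centers by rejection; coordinates are 0-based px
sample_positions <- function(n, cfg, radii_um) {
  w <- cfg$field_width_px; h <- cfg$field_height_px
  px <- cfg$pixel_size_um
  margin_px <- (radii_um + 1) / px
  xs <- numeric(0); ys <- numeric(0); keep <- logical(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      x <- stats::runif(1, margin_px[i], w - 1 - margin_px[i])
      y <- stats::runif(1, margin_px[i], h - 1 - margin_px[i])
      if (length(xs)) {
        d_um <- sqrt((xs - x)^2 + (ys - y)^2) * px
        min_d <- radii_um[seq_along(xs)] + radii_um[i] + cfg$min_sep_extra_um
        if (any(d_um < min_d)) next
      }
      xs <- c(xs, x); ys <- c(ys, y); keep <- c(keep, TRUE)
      placed <- TRUE
      break
    }
    if (!placed) keep <- keep  # drop cell silently; density stays Poisson-ish
  }
  cbind(x = xs, y = ys)
}

# sample all per-cell properties for one field (no rendering)
sample_cells <- function(cfg) {
  area_mm2 <- cfg$field_width_px * cfg$field_height_px *
    (cfg$pixel_size_um / 1000)^2
  n <- stats::rpois(1L, cfg$cell_density_per_mm2 * area_mm2)
  if (n < 1L) stop("field too small to hold a cell at this density")
  radii <- rnorm_trunc(n, cfg$nucleus_radius_um_mean, cfg$nucleus_radius_um_sd)
  pos <- sample_positions(n, cfg, radii)
  n <- nrow(pos)
  radii <- radii[seq_len(n)]
  z <- stats::rnorm(n)
  fba <- exp(cfg$fba_lognormal_mu + cfg$fba_lognormal_sigma * z)
  # marker (Lysotracker slot) log-correlated with FBA by marker_rho
  lsd <- cfg$lyso_sd / cfg$lyso_mean          # approximate log-scale sd
  zm <- cfg$marker_rho * z + sqrt(max(0, 1 - cfg$marker_rho^2)) * stats::rnorm(n)
  lyso <- if (cfg$marker_rho != 0) {
    exp(log(cfg$lyso_mean) + lsd * zm)
  } else {
    rnorm_trunc(n, cfg$lyso_mean, cfg$lyso_sd)
  }
  hoechst <- rnorm_trunc(n, cfg$hoechst_mean, cfg$hoechst_sd)
  dead <- stats::runif(n) < cfg$dead_fraction
  data.frame(cell_id = seq_len(n),
             centroid_x_px = pos[, "x"], centroid_y_px = pos[, "y"],
             radius_um = radii,
             true_nucleus_area_um2 = pi * radii^2,
             true_hoechst = hoechst, true_fba = fba, true_lyso = lyso,
             viable_at_t0 = !dead)
}

sample_debris <- function(cfg) {
  area_mm2 <- cfg$field_width_px * cfg$field_height_px *
    (cfg$pixel_size_um / 1000)^2
  nd <- stats::rpois(1L, cfg$debris_rate_per_mm2 * area_mm2)
  if (nd == 0L)
    return(data.frame(x = numeric(), y = numeric(), r_um = numeric(),
                      amp = numeric()))
  data.frame(x = stats::runif(nd, 4, cfg$field_width_px - 5),
             y = stats::runif(nd, 4, cfg$field_height_px - 5),
             r_um = stats::runif(nd, 0.7, 1.6),      # area well below 36 um^2
             amp = stats::runif(nd, 0.5, 1.5) * cfg$hoechst_mean)
}

# soft-edged radial profile: 1 for d <= -e, 0 for d >= e, linear ramp between
edge_profile <- function(d_um, e = 0.5) {
  pmin(pmax((e - d_um) / (2 * e), 0), 1)
}

# Rasterizer state: per-pixel owner cell and signed distance to the owner's
# nuclear border (negative inside the nucleus), limited to cyto extent.
build_ownership <- function(cells, cfg) {
  w <- cfg$field_width_px; h <- cfg$field_height_px; px <- cfg$pixel_size_um
  owner <- matrix(0L, h, w)
  dborder <- matrix(Inf, h, w)
  ext_px <- ceiling((max(cells$radius_um) + cfg$cyto_extent_um) / px) + 2L
  for (i in seq_len(nrow(cells))) {
    cx <- cells$centroid_x_px[i]; cy <- cells$centroid_y_px[i]
    r0 <- max(1L, floor(cy) - ext_px + 1L); r1 <- min(h, ceiling(cy) + ext_px + 1L)
    c0 <- max(1L, floor(cx) - ext_px + 1L); c1 <- min(w, ceiling(cx) + ext_px + 1L)
    yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
    d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+")) * px - cells$radius_um[i]
    sub_d <- dborder[r0:r1, c0:c1]
    upd <- d < sub_d & d <= cfg$cyto_extent_um + 0.5
    sub_o <- owner[r0:r1, c0:c1]
    sub_d[upd] <- d[upd]; sub_o[upd] <- i
    dborder[r0:r1, c0:c1] <- sub_d
    owner[r0:r1, c0:c1] <- sub_o
  }
  list(owner = owner, dborder = dborder)
}

# draw fragmented (dead) nuclei: several overlapping lobes + speckle
render_dead_nucleus <- function(img, cell, cfg) {
  px <- cfg$pixel_size_um
  r <- cell$radius_um
  n_lobes <- 4L
  ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_lobes + 1L)[-1]
  off <- 0.55 * r      # lobes overlap: one connected, lumpy condensed nucleus
  lob_r <- 0.5 * r
  ext <- ceiling((off + lob_r + 1) / px) + 2L
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, floor(cell$centroid_y_px) - ext); r1 <- min(h, ceiling(cell$centroid_y_px) + ext)
  c0 <- max(1L, floor(cell$centroid_x_px) - ext); c1 <- min(w, ceiling(cell$centroid_x_px) + ext)
  yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
  prof <- matrix(0, length(yy), length(xx))
  for (k in seq_len(n_lobes)) {
    lx <- cell$centroid_x_px + off * cos(ang[k]) / px
    ly <- cell$centroid_y_px + off * sin(ang[k]) / px
    d <- sqrt(outer((yy - ly)^2, (xx - lx)^2, "+")) * px - lob_r
    prof <- pmax(prof, edge_profile(d, 0.4))
  }
  # speckle tuned so the measured nuclear Hoechst SD roughly doubles the
  # live-cell value without dominating the population mean of SDs
  speckle <- exp(stats::rnorm(length(prof), 0, 0.18))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + cell$true_hoechst * prof * speckle
  img
}

apply_camera <- function(signal, cfg) {
  v <- signal + cfg$background_level
  if (cfg$noise_poisson) {
    v[] <- stats::rpois(length(v), pmax(v, 0))
  }
  if (cfg$noise_read_sd > 0) {
    v <- v + stats::rnorm(length(v), 0, cfg$noise_read_sd)
  }
  v[] <- pmin(pmax(round(v), 0), 65535)
  storage.mode(v) <- "integer"
  v
}

# render the four channels for one frame given cell state at that frame
render_frame <- function(cells, own, debris, cfg,
                         dead_now = !cells$viable_at_t0,
                         fba_scale = rep(1, nrow(cells))) {
  h <- cfg$field_height_px; w <- cfg$field_width_px
  owner <- own$owner; dbrd <- own$dborder
  inside <- owner > 0L
  # cytoplasmic channels: uniform over the whole owned footprint so the
  # measured annulus is unbiased wherever exactly it lands
  foot <- matrix(0, h, w)
  foot[inside] <- edge_profile(dbrd[inside] - cfg$cyto_extent_um, 0.5)
  fba_img <- matrix(0, h, w)
  fba_img[inside] <- (cells$true_fba[owner[inside]] *
                        fba_scale[owner[inside]]) * foot[inside]
  lyso_img <- matrix(0, h, w)
  lyso_img[inside] <- cells$true_lyso[owner[inside]] * foot[inside]
  pi_amp <- ifelse(dead_now, cfg$pi_dead_level, cfg$pi_live_level)
  pi_img <- matrix(0, h, w)
  pi_img[inside] <- pi_amp[owner[inside]] * foot[inside]
  # Hoechst: live nuclei as smooth disks; dead nuclei fragmented + speckled
  hoechst_img <- matrix(0, h, w)
  nuc <- which(inside & dbrd <= 0.5)
  nuc <- nuc[!dead_now[owner[nuc]]]
  hoechst_img[nuc] <- cells$true_hoechst[owner[nuc]] *
    edge_profile(dbrd[nuc], 0.5)
  for (i in which(dead_now)) {
    hoechst_img <- render_dead_nucleus(hoechst_img, cells[i, ], cfg)
  }
  # debris: bright specks in Hoechst and anion channels
  if (nrow(debris)) {
    for (k in seq_len(nrow(debris))) {
      ext <- ceiling((debris$r_um[k] + 1) / cfg$pixel_size_um) + 2L
      r0 <- max(1L, floor(debris$y[k]) - ext); r1 <- min(h, ceiling(debris$y[k]) + ext)
      c0 <- max(1L, floor(debris$x[k]) - ext); c1 <- min(w, ceiling(debris$x[k]) + ext)
      yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
      d <- sqrt(outer((yy - debris$y[k])^2, (xx - debris$x[k])^2, "+")) *
        cfg$pixel_size_um - debris$r_um[k]
      prof <- edge_profile(d, 0.3)
      spk <- exp(stats::rnorm(length(prof), 0, 0.5))
      hoechst_img[r0:r1, c0:c1] <- hoechst_img[r0:r1, c0:c1] +
        debris$amp[k] * prof * spk
      fba_img[r0:r1, c0:c1] <- fba_img[r0:r1, c0:c1] +
        3 * debris$amp[k] * prof * spk
    }
  }
  list(hoechst = apply_camera(hoechst_img, cfg),
       anion = apply_camera(fba_img, cfg),
       lysotracker = apply_camera(lyso_img, cfg),
       pi = apply_camera(pi_img, cfg))
}

truth_table <- function(cells, debris, cfg, death_frame = NULL) {
  n <- nrow(cells)
  tt <- data.frame(cell_id = cells$cell_id,
                   is_cell = TRUE,
                   centroid_x_px = cells$centroid_x_px,
                   centroid_y_px = cells$centroid_y_px,
                   true_nucleus_area_um2 = cells$true_nucleus_area_um2,
                   true_hoechst = cells$true_hoechst,
                   true_fba = cells$true_fba,
                   true_lyso = cells$true_lyso,
                   viable_at_t0 = cells$viable_at_t0,
                   death_frame = if (is.null(death_frame)) NA_integer_
                                 else death_frame,
                   tertile_true = NA_character_,
                   stringsAsFactors = FALSE)
  viable <- which(tt$viable_at_t0)
  if (length(viable) >= 3L) {
    tt$tertile_true[viable] <-
      as.character(stratify_by_fba(tt$true_fba[viable]))
  }
  if (nrow(debris)) {
    dd <- data.frame(cell_id = n + seq_len(nrow(debris)),
                     is_cell = FALSE,
                     centroid_x_px = debris$x, centroid_y_px = debris$y,
                     true_nucleus_area_um2 = pi * debris$r_um^2,
                     true_hoechst = debris$amp, true_fba = NA_real_,
                     true_lyso = NA_real_, viable_at_t0 = FALSE,
                     death_frame = NA_integer_,
                     tertile_true = NA_character_,
                     stringsAsFactors = FALSE)
    tt <- rbind(tt, dd)
  }
  tt
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `field` (an `image_field`: named channel matrices
#'   `hoechst`, `anion`, `lysotracker`, `pi`, plus `pixel_size_um` and
#'   `metadata`) and `truth`, the ground-truth table (one row per rendered
#'   object, debris flagged `is_cell = FALSE`).
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_config_seed(config$rng_seed, {
    cells <- sample_cells(config)
    debris <- sample_debris(config)
    own <- build_ownership(cells, config)
    ch <- render_frame(cells, own, debris, config)
    field <- image_field(ch, config$pixel_size_um,
                         metadata = list(field_id = "sim1", condition = "sim",
                                         time_h = 0, frame = 1L))
    list(field = field, truth = truth_table(cells, debris, config))
  })
}

# closed-form per-frame death probability given true FBA
death_hazard_p <- function(fba, cfg) {
  stats::plogis(cfg$death_base_logodds +
                  cfg$death_coupling_beta * (log(fba) - cfg$fba_lognormal_mu))
}

# sample per-cell death frames (first frame at risk is frame 2)
sample_death_frames <- function(cells, cfg) {
  n <- nrow(cells)
  p <- death_hazard_p(cells$true_fba, cfg)
  # geometric first-success; frame = 1 + number of survived frames + 1
  u <- stats::runif(n)
  surv_frames <- cfg$n_frames - 1L
  # P(no death in k frames) = (1-p)^k ; death frame f in 2..n_frames
  k <- ceiling(log(u) / log1p(-p))          # first failing frame index >= 1
  k[p <= 0] <- Inf
  df <- ifelse(k <= surv_frames, k + 1L, NA_integer_)
  df[!cells$viable_at_t0] <- 1L             # already dead at t0
  as.integer(df)
}

#' Generate a synthetic time-lapse with FBA-coupled death
#'
#' Cells alive at frame 1 die with a per-frame hazard
#' `plogis(death_base_logodds + death_coupling_beta * (log FBA - mu))`;
#' from the death frame onward the cell's PI fluorescence is rendered far
#' above background and its FBA decays.  With `render = TRUE` every frame
#' is rasterized as a full four-channel field; with `render = FALSE` the
#' same stochastic model produces per-cell intensity traces directly (the
#' form used for population-scale studies where rasterizing hundreds of
#' frames adds nothing but runtime).
#'
#' @param config a [simulation_config()] with `n_frames >= 2`.
#' @param render logical; rasterize frames (TRUE) or return traces.
#' @return list with `truth` plus either `fields` (list of `image_field`)
#'   or `traces` (list of per-cell traces: `cell_id`, `time_min`, `pi`,
#'   `fba`, background-subtracted PI in `pi`).
#' @export
generate_timelapse <- function(config, render = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_frames < 2L) stop("`n_frames` must be at least 2")
  with_config_seed(config$rng_seed, {
    cells <- sample_cells(config)
    debris <- sample_debris(config)
    df <- sample_death_frames(cells, config)
    truth <- truth_table(cells, debris, config, death_frame = df)
    n <- nrow(cells)
    times <- (seq_len(config$n_frames) - 1L) * config$frame_interval_min
    if (render) {
      own <- build_ownership(cells, config)
      fields <- vector("list", config$n_frames)
      for (f in seq_len(config$n_frames)) {
        dead_now <- !is.na(df) & df <= f
        since <- ifelse(dead_now, f - df, 0)
        fba_scale <- config$fba_dead_decay^since
        ch <- render_frame(cells, own, debris, config,
                           dead_now = dead_now, fba_scale = fba_scale)
        fields[[f]] <- image_field(ch, config$pixel_size_um,
                                   metadata = list(field_id = "sim1",
                                                   condition = "sim",
                                                   time_h = 0, frame = f))
      }
      list(fields = fields, truth = truth)
    } else {
      traces <- vector("list", n)
      for (i in seq_len(n)) {
        dead_now <- !is.na(df[i]) & seq_len(config$n_frames) >= df[i]
        since <- ifelse(dead_now, seq_len(config$n_frames) - df[i], 0)
        pi_mu <- ifelse(dead_now, config$pi_dead_level, config$pi_live_level)
        noise_sd <- sqrt(pmax(pi_mu + config$background_level, 1) *
                           config$noise_poisson + config$noise_read_sd^2)
        pi_tr <- pi_mu + stats::rnorm(config$n_frames, 0, noise_sd /
                                        sqrt(annulus_npx(config)))
        fba_mu <- cells$true_fba[i] * config$fba_dead_decay^since
        fba_tr <- fba_mu + stats::rnorm(config$n_frames, 0, noise_sd /
                                          sqrt(annulus_npx(config)))
        traces[[i]] <- timelapse_trace(cells$cell_id[i], times, pi_tr, fba_tr)
      }
      list(traces = traces, truth = truth)
    }
  })
}

# typical annulus pixel count for the configured nucleus size
annulus_npx <- function(cfg) {
  r <- cfg$nucleus_radius_um_mean
  max(1, round(pi * ((r + 3)^2 - r^2) / cfg$pixel_size_um^2))
}
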