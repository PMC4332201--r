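# ---- per-cell measurement, exclusion rules, viability, death -------------

roi_stat_cols <- function(channels = CHANNELS,
                          rois = c("nuclear", "cytosol"),
                          stats = c("mean", "sd", "integrated", "pixel_count")) {
  as.vector(outer(outer(channels, rois, paste, sep = "_"),
                  stats, paste, sep = "_"))
}

#' Measure per-cell per-channel intensity statistics
#'
#' For every label present in the ROI maps and every available channel,
#' computes the mean, sample standard deviation, integrated intensity
#' (`mean * pixel_count`) and pixel count over the nuclear mask and over
#' the cytosolic annulus.  No filtering happens here.
#'
#' @param field an `image_field`.
#' @param rois ROI maps from [build_cytosol_rois()].
#' @param nuclei optional nucleus shape table from [segment_nuclei()];
#'   its columns are carried through into the records.
#' @return data frame with one row per label: `label`, shape columns when
#'   `nuclei` is given, and `{channel}_{roi}_{stat}` columns.
#' @export
measure_cells <- function(field, rois, nuclei = NULL) {
  nuc_map <- rois$nuclear_labels
  cyt_map <- rois$cytosol_labels
  d <- dim(field$channels[[1]])
  if (!identical(dim(nuc_map), d))
    stop("ROI maps and field have different dimensions")
  n <- max(nuc_map, cyt_map)
  if (n == 0L) stop("no labelled cells to measure")
  out <- data.frame(label = seq_len(n))
  for (roi in c("nuclear", "cytosol")) {
    map <- if (roi == "nuclear") nuc_map else cyt_map
    idx <- which(map > 0L)
    lab <- map[idx]
    cnt <- tabulate(lab, nbins = n)
    for (ch in names(field$channels)) {
      v <- as.numeric(field$channels[[ch]][idx])
      s1 <- rowsum_vec(v, lab, n)
      s2 <- rowsum_vec(v^2, lab, n)
      mu <- ifelse(cnt > 0, s1 / cnt, NA_real_)
      sdv <- ifelse(cnt > 1, sqrt(pmax(s2 - cnt * mu^2, 0) / (cnt - 1)),
                    ifelse(cnt == 1, 0, NA_real_))
      out[[paste(ch, roi, "mean", sep = "_")]] <- mu
      out[[paste(ch, roi, "sd", sep = "_")]] <- sdv
      out[[paste(ch, roi, "integrated", sep = "_")]] <- s1
      out[[paste(ch, roi, "pixel_count", sep = "_")]] <- cnt
    }
  }
  if (!is.null(nuclei)) out <- merge(nuclei, out, by = "label", sort = TRUE)
  out
}

#' Subtract channel backgrounds from measured records
#'
#' Anion (FBA) intensities are corrected by subtracting the mean cytosolic
#' intensity measured in a vehicle control lacking fluorescent anion; the
#' Hoechst, Lysotracker and PI channels are corrected by subtracting the
#' field's modal pixel value (image mode).  Corrected means keep their
#' sign: negative values are retained, not clamped.  Adds
#' `{channel}_{roi}_mean_corr` columns.
#'
#' @param records output of [measure_cells()].
#' @param field the `image_field` the records were measured on.
#' @param control_mean_anion mean vehicle-control anion cytosol intensity;
#'   required whenever the anion channel was measured.
#' @export
subtract_backgrounds <- function(records, field, control_mean_anion = NULL) {
  for (ch in names(field$channels)) {
    bg <- if (ch == "anion") {
      if (is.null(control_mean_anion))
        stop("configuration error: `control_mean_anion` is required to ",
             "correct the anion channel (vehicle control)")
      control_mean_anion
    } else {
      histogram_mode(field$channels[[ch]])
    }
    for (roi in c("nuclear", "cytosol")) {
      mc <- paste(ch, roi, "mean", sep = "_")
      if (mc %in% names(records))
        records[[paste0(mc, "_corr")]] <- records[[mc]] - bg
    }
  }
  records
}

#' Exclusion rulesets
#'
#' The three named rulesets used across the assay variants.  Each rule is a
#' row: `statistic` (`sd`, `mean`, `area`, `circularity`), the `roi` and
#' `channel` it reads, a `relation` (`gt`/`lt`), a `bound_type` (`rel` for
#' population-relative multipliers of the population mean of that
#' statistic, `abs` for absolute values in a.u. or um^2), and the `bound`.
#'
#' * `accumulation_assay`: pixel-SD outliers (anion cytosol SD > 15x or
#'   < 1/15 of the population mean SD; Lysotracker cytosol SD > 10x or
#'   < 1/5; Hoechst nuclear SD > 2.5x or < 1/5), nuclear Lysotracker mean
#'   > 1.5x, nuclear area outside (47, 360) um^2, circularity < 0.6.
#' * `viability_assay`: nuclear area outside (36, 468) um^2, nuclear PI
#'   mean >= 200 a.u., Hoechst nuclear SD > 2x or < 1/2 of the population
#'   mean SD, circularity < 0.6.
#' * `timelapse_assay`: nuclear area outside (36, 252) um^2, circularity
#'   < 0.05.
#'
#' @param name one of `"accumulation_assay"`, `"viability_assay"`,
#'   `"timelapse_assay"`.
#' @return data frame of rules of class `"exclusion_ruleset"`.
#' @export
exclusion_ruleset <- function(name = c("accumulation_assay",
                                       "viability_assay",
                                       "timelapse_assay")) {
  name <- match.arg(name)
  r <- function(rule_id, statistic, roi, channel, relation, bound_type, bound)
    data.frame(rule_id = rule_id, statistic = statistic, roi = roi,
               channel = channel, relation = relation,
               bound_type = bound_type, bound = bound,
               stringsAsFactors = FALSE)
  rules <- switch(name,
    accumulation_assay = rbind(
      r("anion_sd_high",  "sd", "cytosol", "anion",       "gt", "rel", 15),
      r("anion_sd_low",   "sd", "cytosol", "anion",       "lt", "rel", 1 / 15),
      r("lyso_sd_high",   "sd", "cytosol", "lysotracker", "gt", "rel", 10),
      r("lyso_sd_low",    "sd", "cytosol", "lysotracker", "lt", "rel", 1 / 5),
      r("hoechst_sd_high","sd", "nuclear", "hoechst",     "gt", "rel", 2.5),
      r("hoechst_sd_low", "sd", "nuclear", "hoechst",     "lt", "rel", 1 / 5),
      r("lyso_nuc_high",  "mean", "nuclear", "lysotracker", "gt", "rel", 1.5),
      r("area_small",     "area", "nuclear", NA,          "lt", "abs", 47),
      r("area_large",     "area", "nuclear", NA,          "gt", "abs", 360),
      r("circ_low",       "circularity", "nuclear", NA,   "lt", "abs", 0.6)),
    viability_assay = rbind(
      r("area_small",     "area", "nuclear", NA,          "lt", "abs", 36),
      r("area_large",     "area", "nuclear", NA,          "gt", "abs", 468),
      r("pi_high",        "mean", "nuclear", "pi",        "gt", "abs", 200),
      r("hoechst_sd_high","sd", "nuclear", "hoechst",     "gt", "rel", 2),
      r("hoechst_sd_low", "sd", "nuclear", "hoechst",     "lt", "rel", 1 / 2),
      r("circ_low",       "circularity", "nuclear", NA,   "lt", "abs", 0.6)),
    timelapse_assay = rbind(
      r("area_small",     "area", "nuclear", NA,          "lt", "abs", 36),
      r("area_large",     "area", "nuclear", NA,          "gt", "abs", 252),
      r("circ_low",       "circularity", "nuclear", NA,   "lt", "abs", 0.05)))
  structure(rules, name = name, class = c("exclusion_ruleset", "data.frame"))
}

# fetch the column a rule reads; mean rules prefer background-corrected
rule_values <- function(records, rule) {
  col <- switch(rule$statistic,
    area = "area_um2",
    circularity = "circularity",
    sd = paste(rule$channel, rule$roi, "sd", sep = "_"),
    mean = {
      base <- paste(rule$channel, rule$roi, "mean", sep = "_")
      if (paste0(base, "_corr") %in% names(records)) paste0(base, "_corr")
      else base
    })
  if (!col %in% names(records))
    stop("records lack the column required by rule '", rule$rule_id,
         "': ", col)
  records[[col]]
}

#' Apply an exclusion ruleset, flagging outlier records
#'
#' Population-relative bounds (`rel`) compare each cell's statistic to
#' `bound * mean(statistic)` where the mean is taken once over all
#' candidate records supplied (all fields of the same condition/time
#' point), so flagging is deterministic and order-free.  With
#' `reference = "self"` the multiplier instead applies to the same cell's
#' own mean intensity in that ROI/channel (the alternative reading for SD
#' rules).  Every violated rule id is appended to `flags`; a record is
#' retained iff `flags` is empty.
#'
#' @param records measured (and optionally background-corrected) records.
#' @param ruleset an [exclusion_ruleset()].
#' @param pixel_size_um physical pixel size (areas are already in um^2;
#'   kept in the signature for interface symmetry and validation).
#' @param reference `"population"` (default) or `"self"`.
#' @return `records` with `flags` (comma-separated rule ids) and `retained`
#'   columns.
#' @export
apply_exclusions <- function(records, ruleset, pixel_size_um,
                             reference = c("population", "self")) {
  reference <- match.arg(reference)
  if (nrow(records) == 0L) stop("empty record list")
  has_rel <- any(ruleset$bound_type == "rel")
  if (has_rel && reference == "population" && nrow(records) < 2L)
    stop("population-relative rules need at least 2 candidate records")
  flags <- rep("", nrow(records))
  for (i in seq_len(nrow(ruleset))) {
    rule <- ruleset[i, ]
    v <- rule_values(records, rule)
    bound <- if (rule$bound_type == "abs") {
      rep(rule$bound, nrow(records))
    } else if (reference == "population") {
      rule$bound * mean(v, na.rm = TRUE)
    } else {
      base <- paste(rule$channel, rule$roi, "mean", sep = "_")
      rule$bound * records[[base]]
    }
    hit <- if (rule$relation == "gt") v > bound else v < bound
    hit[is.na(hit)] <- FALSE
    flags[hit] <- ifelse(flags[hit] == "", rule$rule_id,
                         paste(flags[hit], rule$rule_id, sep = ","))
  }
  records$flags <- flags
  records$retained <- flags == ""
  records
}

#' Score per-field viability
#'
#' Viable cells are qualifying nuclei (area strictly between 36 and
#' 468 um^2) with nuclear PI mean below 200 a.u., Hoechst nuclear SD within
#' (1/2, 2) times the population mean SD, and circularity at least 0.6.
#'
#' @param records measured records including PI and Hoechst statistics.
#' @param pixel_size_um physical pixel size.
#' @return list with `records` (a `viable` logical column added) and
#'   `n_viable`, the per-field viable count.
#' @export
score_viability <- function(records, pixel_size_um) {
  if (!"pi_nuclear_mean" %in% names(records))
    stop("PI channel measurements missing; cannot score viability")
  rs <- exclusion_ruleset("viability_assay")
  scored <- apply_exclusions(records, rs, pixel_size_um)
  records$viable <- scored$retained
  list(records = records, n_viable = sum(records$viable))
}

#' Extract per-cell time-lapse traces with frozen frame-1 ROIs
#'
#' ROIs are fixed from the first frame (no re-segmentation or tracking:
#' the fields are re-imaged in place and hepatocytes are essentially
#' non-motile over the assay).  For every frame, PI and FBA are measured
#' in the frame-1 cellular ROI and the per-frame image mode of each
#' channel is subtracted.  `fba_over_hoechst` is computed at frame 1 from
#' the corrected FBA cytosol mean and Hoechst nuclear mean; cells with
#' non-positive Hoechst are given `NA` (undefined ratio, excluded
#' downstream).  Death is called on each finished trace with
#' [detect_death()].
#'
#' @param fields time-ordered list of `image_field`s with identical
#'   dimensions.
#' @param rois frame-1 ROI maps from [build_cytosol_rois()].
#' @param death_threshold_au death-call threshold, a.u. above background.
#' @param pi_roi which ROI carries "cell fluorescence" for the death call:
#'   `"cytosol"` (the cellular ROI, default), `"nuclear"`, or `"union"`.
#' @param frame_interval_min sampling interval in minutes.
#' @return list of `timelapse_trace` objects; attribute `t0` holds the
#'   frame-1 record table (with `fba_over_hoechst`).
#' @export
link_and_trace <- function(fields, rois, death_threshold_au = 100,
                           pi_roi = c("cytosol", "nuclear", "union"),
                           frame_interval_min = 10) {
  pi_roi <- match.arg(pi_roi)
  if (length(fields) < 2L) stop("need at least 2 frames")
  d1 <- dim(fields[[1]]$channels[[1]])
  for (f in fields)
    if (!identical(dim(f$channels[[1]]), d1))
      stop("frame dimension mismatch")
  nuc_map <- rois$nuclear_labels
  roi_map <- switch(pi_roi,
    cytosol = rois$cytosol_labels,
    nuclear = rois$nuclear_labels,
    union = { m <- rois$cytosol_labels
              m[nuc_map > 0L] <- nuc_map[nuc_map > 0L]; m })
  n <- max(nuc_map, roi_map)
  idx <- which(roi_map > 0L)
  lab <- roi_map[idx]
  cnt <- tabulate(lab, nbins = n)
  nf <- length(fields)
  pi_tr <- matrix(NA_real_, n, nf)
  fba_tr <- matrix(NA_real_, n, nf)
  for (f in seq_len(nf)) {
    pi_img <- fields[[f]]$channels$pi
    fba_img <- fields[[f]]$channels$anion
    if (is.null(pi_img) || is.null(fba_img))
      stop("time-lapse fields need both `pi` and `anion` channels")
    pi_bg <- histogram_mode(pi_img)
    fba_bg <- histogram_mode(fba_img)
    pi_tr[, f] <- rowsum_vec(as.numeric(pi_img[idx]), lab, n) / cnt - pi_bg
    fba_tr[, f] <- rowsum_vec(as.numeric(fba_img[idx]), lab, n) / cnt - fba_bg
  }
  # frame-1 records for stratification
  t0 <- measure_cells(fields[[1]], rois)
  hoechst_bg <- histogram_mode(fields[[1]]$channels$hoechst)
  h0 <- t0$hoechst_nuclear_mean - hoechst_bg
  f0 <- fba_tr[, 1L]
  t0$fba_over_hoechst <- ifelse(h0 > 0, f0 / h0, NA_real_)
  t0$fba_initial <- f0
  times <- (seq_len(nf) - 1L) * frame_interval_min
  traces <- lapply(seq_len(n), function(i) {
    tr <- timelapse_trace(i, times, pi_tr[i, ], fba_tr[i, ])
    tr$death_frame <- detect_death(tr, death_threshold_au)
    tr
  })
  attr(traces, "t0") <- t0
  traces
}

#' Call cell death from a background-subtracted PI trace
#'
#' The death frame is the first frame at which PI cell fluorescence
#' exceeds `threshold_au` units above background; `NA` if it never does.
#'
#' @param trace a `timelapse_trace` (background-subtracted `pi`).
#' @param threshold_au threshold in a.u. above background.
#' @return integer frame index or `NA`.
#' @export
detect_death <- function(trace, threshold_au = 100) {
  p <- trace$pi
  if (length(p) == 0L) stop("empty trace")
  hit <- which(p > threshold_au)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
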