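# ---- population statistics: tertiles, death fractions, CV, fits ---------

#' Tertile stratification by initial FBA accumulation
#'
#' Sorts values ascending and splits them into three contiguous groups of
#' (as near as possible) equal size: remainders go to the low, then the mid
#' group, so group sizes differ by at most one.  Ties keep their original
#' (stable) order, so permuting equal values never moves a (value, index)
#' pair between groups.
#'
#' @param fba_values numeric vector of initial (frame-1) FBA values for the
#'   retained, t0-viable cells; length at least 3.
#' @return factor of levels `low`, `mid`, `high` in the input order.
#' @export
stratify_by_fba <- function(fba_values) {
  n <- length(fba_values)
  if (n < 3L) stop("need at least 3 cells to form tertiles")
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- c(low = base + (extra >= 1L), mid = base + (extra >= 2L),
             high = base)
  ord <- order(fba_values)            # stable for ties
  g <- rep(c("low", "mid", "high"), times = sizes)
  out <- character(n)
  out[ord] <- g
  factor(out, levels = c("low", "mid", "high"))
}

#' Percentage of cells that died within a group
#'
#' @param dead logical vector (death called within the observation window).
#' @param group optional factor/logical subsetting `dead`; omitted = whole
#'   population.
#' @return percentage in `[0, 100]`.
#' @export
death_fraction <- function(dead, group = NULL) {
  if (!is.null(group)) dead <- dead[group]
  if (length(dead) == 0L) stop("empty group")
  100 * mean(dead)
}

#' Fold difference in initial FBA between dying and surviving cells
#'
#' @param fba_initial numeric vector of frame-1 FBA values.
#' @param dead logical vector of death calls.
#' @return `mean(FBA | dead) / mean(FBA | surviving)`.
#' @export
fold_fba_dying_vs_surviving <- function(fba_initial, dead) {
  if (!any(dead) || all(dead))
    stop("need at least one dying and one surviving cell")
  mean(fba_initial[dead]) / mean(fba_initial[!dead])
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, the
#' standard measure of cell-to-cell heterogeneity of accumulation.
#'
#' @param values numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for a meaningful CV")
  100 * stats::sd(values) / m
}

#' Pearson correlation between two per-cell quantities
#'
#' @param x_values,y_values equal-length numeric vectors, `n >= 3`.
#' @return list with `r` and `n`.
#' @export
correlate_per_cell <- function(x_values, y_values) {
  if (length(x_values) != length(y_values)) stop("unequal lengths")
  ok <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  list(r = stats::cor(x, y), n = length(x))
}

#' Summarize a condition x time design over replicate experiments
#'
#' The unit of replication is the experiment: per-experiment means are
#' averaged, SEM is `sd / sqrt(n_experiments)`, fold-changes are ratios of
#' condition means between a reference time point and each later one, and
#' condition contrasts at each time use the classic two-sample, two-sided,
#' equal-variance Student's t-test on experiment means.
#'
#' @param data data frame with columns `condition`, `time_h`, `experiment`,
#'   `value` (per-experiment mean of the background-corrected statistic).
#' @param reference_time_h time point the fold-changes are relative to;
#'   defaults to the earliest.
#' @return list with `summary` (condition, time_h, n, mean, sem,
#'   fold_vs_reference), and `comparisons` (pairwise condition t-tests per
#'   time point).  With a single experiment the SEM is `NA` (undefined).
#' @export
summarize_timecourse <- function(data, reference_time_h = NULL) {
  need <- c("condition", "time_h", "experiment", "value")
  if (!all(need %in% names(data)))
    stop("`data` needs columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(value ~ condition + time_h, data,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  s <- data.frame(condition = agg$condition, time_h = agg$time_h,
                  n = agg$value[, "n"], mean = agg$value[, "mean"],
                  sem = ifelse(agg$value[, "n"] > 1,
                               agg$value[, "sd"] / sqrt(agg$value[, "n"]),
                               NA_real_))
  if (is.null(reference_time_h)) reference_time_h <- min(s$time_h)
  ref <- s[s$time_h == reference_time_h, c("condition", "mean")]
  names(ref)[2] <- "ref_mean"
  s <- merge(s, ref, by = "condition", sort = FALSE)
  s$fold_vs_reference <- s$ref_mean / s$mean
  s$ref_mean <- NULL
  s <- s[order(s$condition, s$time_h), ]
  comps <- list()
  for (t in unique(s$time_h)) {
    conds <- unique(data$condition[data$time_h == t])
    if (length(conds) < 2L) next
    prs <- utils::combn(as.character(conds), 2L)
    for (j in seq_len(ncol(prs))) {
      a <- data$value[data$condition == prs[1, j] & data$time_h == t]
      b <- data$value[data$condition == prs[2, j] & data$time_h == t]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- stats::t.test(a, b, var.equal = TRUE)
      comps[[length(comps) + 1L]] <-
        data.frame(time_h = t, condition_a = prs[1, j],
                   condition_b = prs[2, j], p_value = tt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  list(summary = s,
       comparisons = if (length(comps)) do.call(rbind, comps)
                     else data.frame(time_h = numeric(),
                                     condition_a = character(),
                                     condition_b = character(),
                                     p_value = numeric()))
}

#' Fit the power law y = a x^b
#'
#' Ordinary least squares on the linearized model
#' `log y = log a + b log x`; `rss` is reported on the log scale.  With
#' `refine = TRUE` the log-fit seeds a nonlinear least-squares refinement
#' on the raw scale.
#'
#' @param x_values,y_values strictly positive numeric vectors, `n >= 2`.
#' @param refine logical; refine on the raw scale with [stats::nls()].
#' @return list of class `"power_law_fit"` with `a`, `b`, `rss`.
#' @export
fit_power_law <- function(x_values, y_values, refine = FALSE) {
  if (length(x_values) != length(y_values)) stop("unequal lengths")
  if (length(x_values) < 2L) stop("need at least 2 points")
  if (any(x_values <= 0) || any(y_values <= 0))
    stop("power-law fit requires strictly positive x and y")
  fit <- stats::lm(log(y_values) ~ log(x_values))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (refine) {
    nl <- tryCatch(
      stats::nls(y_values ~ a * x_values^b, start = list(a = a, b = b)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      a <- unname(cf["a"]); b <- unname(cf["b"])
      rss <- sum(log(y_values / (a * x_values^b))^2)
    }
  }
  structure(list(a = a, b = b, rss = rss), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law  y = a x^b :  a = %.6g, b = %.6g (log-scale RSS %.3g)\n",
              x$a, x$b, x$rss))
  invisible(x)
}

#' Group summary table for tertile-stratified death analysis
#'
#' @param fba_initial frame-1 FBA per cell (retained, t0-viable cells).
#' @param dead logical death calls for the same cells.
#' @return data frame with rows `low`, `mid`, `high`, `whole`: `n`,
#'   `death_pct`, `mean_fba`, `sem_fba`, `cv_pct`, and both the absolute
#'   (percentage-point) and relative difference of each group's death
#'   against the whole population.
#' @export
tertile_death_summary <- function(fba_initial, dead) {
  g <- stratify_by_fba(fba_initial)
  rows <- lapply(c("low", "mid", "high"), function(lev) {
    sel <- g == lev
    data.frame(group = lev, n = sum(sel),
               death_pct = death_fraction(dead, sel),
               mean_fba = mean(fba_initial[sel]),
               sem_fba = stats::sd(fba_initial[sel]) / sqrt(sum(sel)),
               cv_pct = coefficient_of_variation(fba_initial[sel]))
  })
  whole <- data.frame(group = "whole", n = length(dead),
                      death_pct = death_fraction(dead),
                      mean_fba = mean(fba_initial),
                      sem_fba = stats::sd(fba_initial) / sqrt(length(dead)),
                      cv_pct = coefficient_of_variation(fba_initial))
  out <- rbind(do.call(rbind, rows), whole)
  out$death_diff_vs_whole_pts <- out$death_pct - whole$death_pct
  out$death_diff_vs_whole_rel <- if (whole$death_pct > 0) {
    (out$death_pct - whole$death_pct) / whole$death_pct
  } else NA_real_
  out
}
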