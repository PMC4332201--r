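test_that("tertile stratification splits sorted values with the remainder
           rule and is a stable partition", {
  g <- stratify_by_fba(1:9)
  expect_identical(as.character(g), rep(c("low", "mid", "high"), each = 3))
  # n = 10: sizes (4, 3, 3), extras to low first
  expect_identical(as.vector(table(stratify_by_fba(1:10))), c(4L, 3L, 3L))
  expect_identical(as.vector(table(stratify_by_fba(1:11))), c(4L, 4L, 3L))
  set.seed(10)
  for (i in 1:20) {
    v <- rlnorm(sample(10:200, 1))
    g <- stratify_by_fba(v)
    expect_gte(min(v[g == "high"]), max(v[g == "low"]))   # sort oracle
    expect_lte(diff(range(table(g))), 1)
    # permutation never moves a (value, index) pair between groups
    perm <- sample(length(v))
    expect_identical(as.character(stratify_by_fba(v[perm])[order(perm)]),
                     as.character(g))
  }
  expect_error(stratify_by_fba(c(1, 2)), "at least 3")
})

test_that("death fractions and the dying-vs-surviving fold behave
           arithmetically", {
  dead <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(death_fraction(dead), 25)
  # whole-population fraction is the size-weighted mean of group fractions
  set.seed(1)
  d <- runif(100) < 0.3
  g <- stratify_by_fba(rlnorm(100))
  per <- vapply(levels(g), function(l) death_fraction(d, g == l), numeric(1))
  expect_equal(sum(per * table(g)) / 100, death_fraction(d))
  expect_equal(fold_fba_dying_vs_surviving(c(200, 220, 100, 110),
                                           c(TRUE, TRUE, FALSE, FALSE)), 2)
  expect_error(death_fraction(logical(0)), "empty")
  expect_error(fold_fba_dying_vs_surviving(1:3, c(TRUE, TRUE, TRUE)),
               "surviving")
})

test_that("CV matches hand arithmetic, the lognormal closed form, and is
           scale-invariant", {
  expect_equal(coefficient_of_variation(c(8, 12)), 28.28, tolerance = 1e-3)
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  set.seed(33)
  sigma <- 0.25
  v <- rlnorm(20000, 5, sigma)
  expect_equal(coefficient_of_variation(v), 100 * sqrt(exp(sigma^2) - 1),
               tolerance = 0.03)
  expect_equal(coefficient_of_variation(v * 17),
               coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-5, 1)), "positive")
})

test_that("per-cell correlation is exact on degenerate lines and
           scale-invariant", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate_per_cell(x, x)$r, 1)
  expect_equal(correlate_per_cell(x, -x)$r, -1)
  expect_identical(correlate_per_cell(x, x)$n, 5L)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(correlate_per_cell(a * 3, b * 9)$r,
               correlate_per_cell(a, b)$r)
  expect_error(correlate_per_cell(a, rep(1, 50)), "zero variance")
  expect_error(correlate_per_cell(a, b[1:10]), "unequal")
})

test_that("timecourse summaries average experiment means with SEM and
           classic t-tests", {
  d <- data.frame(condition = rep(c("c2d", "c3d"), each = 6),
                  time_h = rep(c(7, 7, 7, 32, 32, 32), 2),
                  experiment = rep(1:3, 4),
                  value = c(100, 110, 120, 50, 55, 60,
                            100, 110, 120, 90, 100, 110))
  s <- summarize_timecourse(d)
  r1 <- s$summary[s$summary$condition == "c2d" & s$summary$time_h == 7, ]
  expect_equal(r1$mean, 110)
  expect_equal(r1$sem, sd(c(100, 110, 120)) / sqrt(3))
  expect_equal(r1$sem, 5.7735, tolerance = 1e-4)
  # fold-change vs the 7 h reference
  r2 <- s$summary[s$summary$condition == "c2d" & s$summary$time_h == 32, ]
  expect_equal(r2$fold_vs_reference, 110 / 55)
  # identical conditions give fold-change 1 and p = 1
  expect_equal(s$summary$fold_vs_reference[s$summary$time_h == 7], c(1, 1))
  p <- s$comparisons$p_value[s$comparisons$time_h == 7]
  expect_equal(p, 1)
  # matches stats::t.test with equal variances at 32 h
  want <- t.test(c(50, 55, 60), c(90, 100, 110), var.equal = TRUE)$p.value
  expect_equal(s$comparisons$p_value[s$comparisons$time_h == 32], want)
  # single experiment: SEM undefined
  s1 <- summarize_timecourse(d[d$experiment == 1, ])
  expect_true(all(is.na(s1$summary$sem)))
})

test_that("power-law fitting is exact on noiseless data and the flat-data
           closed form", {
  f <- fit_power_law(c(1, 4, 9), c(2, 4, 6))
  expect_equal(f$a, 2, tolerance = 1e-10)
  expect_equal(f$b, 0.5, tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-12)
  # flat data (b = 0): a is the geometric mean of y
  y <- c(2, 8, 4)
  f0 <- fit_power_law(c(1, 2, 4, 8), rep(3, 4))
  expect_equal(f0$a, 3, tolerance = 1e-12)
  expect_equal(f0$b, 0, tolerance = 1e-12)
  f1 <- fit_power_law(c(1, 2, 4), y)
  expect_equal(f1$a * exp(f1$b * mean(log(c(1, 2, 4)))),
               exp(mean(log(y))), tolerance = 1e-10)
  expect_error(fit_power_law(c(-1, 2), c(1, 2)), "positive")
  # raw-scale refinement reproduces the exact fit on clean data
  fr <- fit_power_law(c(1, 4, 9), c(2, 4, 6), refine = TRUE)
  expect_equal(fr$a, 2, tolerance = 1e-6)
  expect_equal(fr$b, 0.5, tolerance = 1e-6)
})

test_that("monotone hazard gives high >= whole >= low expected death and
           the tertile summary reports both difference scales", {
  set.seed(44)
  for (i in 1:10) {
    f <- rlnorm(900, 6, 0.3)
    p <- plogis(-1 + 1.5 * (log(f) - 6))
    dead <- runif(900) < p
    ts <- tertile_death_summary(f, dead)
    expect_gte(ts$death_pct[ts$group == "high"],
               ts$death_pct[ts$group == "whole"] - 1e-9)
    expect_gte(ts$death_pct[ts$group == "whole"],
               ts$death_pct[ts$group == "low"] - 1e-9)
  }
  ts <- tertile_death_summary(c(1:9), c(rep(FALSE, 6), TRUE, TRUE, TRUE))
  expect_equal(ts$death_pct, c(0, 0, 100, 100 / 3), tolerance = 1e-9)
  w <- ts$death_pct[ts$group == "whole"]
  expect_equal(ts$death_diff_vs_whole_pts[ts$group == "high"], 100 - w)
  expect_equal(ts$death_diff_vs_whole_rel[ts$group == "high"],
               (100 - w) / w)
})
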