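# Oracle note: expected z-scores below are brute-force recomputations of
# (y - mean(y)) / population-sd(y) frozen from direct arithmetic.

test_that("isolated spike is flagged: z, neighbour ratio and guard all hold", {
  s <- stat_series(2000:2019, yield = c(rep(1, 10), 6, rep(1, 9)))
  res <- flag_outliers(s)
  expect_identical(which(res$flag == 1L), 11L)
  expect_equal(res$z_score[11], (6 - 1.25) / sqrt(23.75 / 20),
               tolerance = 1e-12)  # = 4.3589 under population sd
  expect_equal(sum(res$flag == 1L, na.rm = TRUE), 1L)
})

test_that("high z without the 250% neighbour condition is not flagged", {
  y <- c(rep(1, 9), 2, 4.8, 2, rep(1, 8))
  s <- stat_series(2000:2019, yield = y)
  res <- flag_outliers(s)
  expect_gt(res$z_score[11], 3)       # z of 4.8 is about 4.09
  expect_equal(res$ratio_prev[11], 2.4)
  expect_equal(res$ratio_next[11], 2.4)
  expect_identical(sum(res$flag == 1L, na.rm = TRUE), 0L)
})

test_that("low-yield guard and constant series produce no outlier flags", {
  low <- stat_series(2000:2009,
                     yield = c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  expect_identical(sum(flag_outliers(low)$flag == 1L, na.rm = TRUE), 0L)
  const <- stat_series(2000:2009, yield = rep(2, 10))
  expect_identical(sum(flag_outliers(const)$flag == 1L, na.rm = TRUE), 0L)
})

test_that("neighbour comparison skips missing years and works at endpoints", {
  # spike at the first year: only the following neighbour exists
  s1 <- stat_series(2000:2014, yield = c(6, rep(1, 14)))
  expect_identical(which(flag_outliers(s1)$flag == 1L), 1L)
  # missing year between spike and its nearest observed neighbour
  s2 <- stat_series(2000:2019,
                    yield = c(rep(1, 9), NA, 6, rep(1, 9)))
  res <- flag_outliers(s2)
  expect_identical(which(res$flag == 1L), 11L)
  expect_equal(res$ratio_prev[11], 6)  # ratio against year 2008, not the gap
})

test_that("second-difference rule flags the spanned window", {
  s <- stat_series(2001:2007, yield = c(2, 2, 2, 2, 2, 2.6, 2.2))
  res <- flag_low_variance(s)
  # d = [0, 0, 0, 0.6, -1.0]; threshold 1.5% of median 2 = 0.03
  expect_identical(which(res$flag == 2L), 1:5)
  expect_equal(res$second_diff[2:6], c(0, 0, 0, 0.6, -1.0))
})

test_that("linear series is fully flagged; alternating series is not", {
  lin <- stat_series(2000:2009, yield = 1 + 0.1 * (0:9))
  expect_identical(which(flag_low_variance(lin)$flag == 2L), 1:10)
  alt <- stat_series(2000:2004, yield = c(1, 2, 1, 2, 1))
  expect_identical(sum(flag_low_variance(alt)$flag == 2L, na.rm = TRUE), 0L)
})

test_that("missing years break second-difference runs", {
  # two short observed runs of 4 years each: no run of 3 second differences
  y <- c(2, 2, 2, 2, NA, 2, 2, 2, 2)
  s <- stat_series(2000:2008, yield = y)
  expect_identical(sum(flag_low_variance(s)$flag == 2L, na.rm = TRUE), 0L)
})

test_that("overlapping low-variance windows merge", {
  s <- stat_series(2000:2009, yield = rep(3, 10))
  expect_identical(which(flag_low_variance(s)$flag == 2L), 1:10)
})

test_that("flags are invariant under positive rescaling (guard permitting)", {
  set.seed(31)
  for (k in 1:10) {
    y <- exp(rnorm(15, log(2), 0.3))
    y[8] <- y[8] * 6
    y[2:5] <- y[2]
    s1 <- stat_series(2000:2014, yield = y)
    s2 <- stat_series(2000:2014, yield = y * 3.7)
    f1 <- qc_flag_series(s1)
    f2 <- qc_flag_series(s2)
    expect_identical(f1$flag, f2$flag)
  }
})

test_that("outlier code wins when both rules hit the same year", {
  # constant run whose last year spikes: craft via params so both fire
  y <- c(1, 1, 1, 1, 1, 6, 1, 1, 1, 1)
  s <- stat_series(2000:2009, yield = y)
  res <- qc_flag_series(s, qc_params(second_diff_frac = 0.015))
  out_years <- which(flag_outliers(s)$flag == 1L)
  lv_years <- which(flag_low_variance(s)$flag == 2L)
  both <- intersect(out_years, lv_years)
  if (length(both) > 0) expect_true(all(res$flag[both] == 1L))
  expect_true(all(res$flag[setdiff(lv_years, out_years)] == 2L))
})

test_that("apply_qc is idempotent, recomputes rather than ORs, and never
           mutates statistics", {
  sc <- make_scenario(scenario_config(seed = 8))
  rec <- sc$series$records
  rec$qc_flag <- sample(0:2, nrow(rec), replace = TRUE)  # stale flags
  once <- apply_qc(rec)
  twice <- apply_qc(once)
  expect_identical(once$qc_flag, twice$qc_flag)
  expect_identical(once$production, rec$production)
  expect_identical(once$area, rec$area)
  expect_identical(once$yield, rec$yield)
})

test_that("injected anomalies are recovered exactly on the synthetic fixture", {
  sc <- make_scenario(scenario_config(seed = 11))
  flagged <- apply_qc(sc$series$records)
  truth <- sc$series$truth_flags
  j <- dplyr::inner_join(
    flagged, truth,
    by = c("fnid", "product", "season_name", "crop_production_system",
           "harvest_year"))
  expect_identical(nrow(j), nrow(flagged))
  expect_identical(j$qc_flag, j$true_flag)   # precision = recall = 1, both codes
  expect_identical(sum(j$true_flag == 1L), 5L)
  expect_identical(sum(j$true_flag == 2L), 25L)
})

test_that("all-clean fixture gets qc_flag 0 everywhere", {
  sc <- make_scenario(scenario_config(seed = 2, n_outliers = 0, n_runs = 0))
  flagged <- apply_qc(sc$series$records)
  expect_true(all(flagged$qc_flag == 0L))
})
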