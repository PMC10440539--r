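test_that("KS normality screen matches a brute-force supremum", {
  x <- c(-2, -1, 0, 1, 2)
  z <- (x - mean(x)) / sd(x)
  n <- length(x)
  Fe <- pnorm(sort(z))
  D <- max(pmax(abs(seq_len(n) / n - Fe), abs((seq_len(n) - 1) / n - Fe)))
  expect_equal(ks_normality(x)$statistic, D, tolerance = 1e-12)
  # a sample on the normal quantile grid sits at the discretisation floor
  q <- qnorm((seq_len(50) - 0.5) / 50)
  ks <- ks_normality(q)
  expect_lte(ks$statistic, 1 / (2 * 50) + 0.005)
  expect_true(ks$statistic >= 0 && ks$statistic <= 1)
  expect_true(ks$p_value >= 0 && ks$p_value <= 1)
  expect_error(ks_normality(rep(1, 10)), "zero-variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("the paired t test reduces to its closed form", {
  single <- c(10, 20, 30)
  multi <- single + c(1, 2, 3)
  pc <- paired_t(multi, single)
  expect_equal(pc$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(pc$df, 2L)
  expect_equal(pc$p_value, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE))
  # swapping the samples negates t and keeps p
  sw <- paired_t(single, multi)
  expect_equal(sw$t, -pc$t)
  expect_equal(sw$p_value, pc$p_value)
  expect_error(paired_t(single, single), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("reference tables reproduce their printed summary rows", {
  combos <- expand.grid(region = c("plaque", "cap", "outwall"),
                        measure = c("stress", "strain"),
                        stringsAsFactors = FALSE)
  printed <- list(
    plaque_stress = list(mean = c(385.13, 270.91, 129.59, 93.27),
                         sd = c(110.09, 95.86, 32.77, 18.20),
                         diff = c(42.16, 38.93), dtol = 0.01),
    plaque_strain = list(mean = c(0.264, 0.237, 0.133, 0.112),
                         sd = c(0.066, 0.069, 0.019, 0.015),
                         diff = c(11.57, 19.02), dtol = 0.25),
    cap_stress = list(mean = c(340.42, 249.61, 119.86, 93.16),
                      sd = c(148.92, 108.09, 45.46, 26.74),
                      diff = c(36.38, 28.66), dtol = 0.01),
    cap_strain = list(mean = c(0.246, 0.225, 0.118, 0.105),
                      sd = c(0.077, 0.074, 0.028, 0.022),
                      diff = c(9.63, 12.93), dtol = 0.25),
    outwall_stress = list(mean = c(34.76, 77.38, 14.62, 51.47),
                          sd = c(10.77, 12.00, 4.54, 7.73),
                          diff = c(-55.07, -71.58), dtol = 0.01),
    outwall_strain = list(mean = c(0.161, 0.078, 0.079, 0.054),
                          sd = c(0.030, 0.015, 0.018, 0.002),
                          diff = c(106.40, 46.95), dtol = 0.25))
  for (i in seq_len(nrow(combos))) {
    key <- paste(combos$region[i], combos$measure[i], sep = "_")
    tab <- reference_comparison_table(combos$region[i], combos$measure[i])
    s <- summarize_comparison_table(tab)
    want <- printed[[key]]
    expect_lt(max(abs(unname(s$mean) - want$mean)), 0.011)
    expect_lt(max(abs(unname(s$sd) - want$sd)), 0.011)
    expect_lt(abs(s$diff_max_pct - want$diff[1]), want$dtol + 1e-9)
    expect_lt(abs(s$diff_mean_pct - want$diff[2]), want$dtol + 1e-9)
  }
})

test_that("printed per-patient difference cells are arithmetic", {
  # each stress-table Difference cell is the single-layer-base percent
  # difference of its own printed cells; printed rounding propagates to
  # about +/- 0.02 on a percentage
  for (region in c("plaque", "cap")) {
    tab <- reference_comparison_table(region, "stress")
    expect_lt(max(abs(relative_difference(tab$multi_max, tab$single_max) -
                        tab$diff_max_pct)), 0.02)
    expect_lt(max(abs(relative_difference(tab$multi_mean, tab$single_mean) -
                        tab$diff_mean_pct)), 0.02)
  }
})

test_that("all reference table column pairs differ significantly", {
  for (region in c("plaque", "cap", "outwall")) {
    for (measure in c("stress", "strain")) {
      tab <- reference_comparison_table(region, measure)
      expect_lt(paired_t(tab$multi_max, tab$single_max)$p_value, 0.001)
      expect_lt(paired_t(tab$multi_mean, tab$single_mean)$p_value, 0.001)
    }
  }
})

test_that("degenerate pairings are reported, not crashed, in study tables", {
  df <- data.frame(patient = sprintf("P%02d", 1:6),
                   multi_max = c(5, 6, 7, 8, 9, 10),
                   single_max = c(5, 6, 7, 8, 9, 10),
                   diff_max_pct = 0,
                   multi_mean = 1:6, single_mean = 1:6,
                   diff_mean_pct = 0)
  tt <- vesselfem:::table_tests(df)
  expect_true(is.na(tt$max$p_value))
  expect_match(tt$max$degenerate, "zero-variance")
})

test_that("study output files are deterministic for a fixed study", {
  spec <- cohort_spec(n_patients = 2, slices_per_patient = 1, seed = 9)
  coh <- generate_cohort(spec)
  st <- run_comparison_study(coh, config = list(n_rays = 32,
                                                n_radial_per_layer = 1))
  d1 <- file.path(tempdir(), "study1"); d2 <- file.path(tempdir(), "study2")
  vesselfem:::write_study(st, d1)
  vesselfem:::write_study(st, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_equal(nrow(st$tables$plaque_stress), 2)
  # the solver and extraction pipeline is deterministic slice-for-slice
  mats <- default_materials()
  cfg <- st$config
  v1 <- vesselfem:::solve_slice_pair(coh[[1]]$slices[[1]], mats,
                                     mmHg_to_kPa(coh[[1]]$pressure_mmHg),
                                     cfg)
  v2 <- vesselfem:::solve_slice_pair(coh[[1]]$slices[[1]], mats,
                                     mmHg_to_kPa(coh[[1]]$pressure_mmHg),
                                     cfg)
  expect_identical(v1$multi$plaque_stress, v2$multi$plaque_stress)
})
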