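test_that("the log-logistic curve hits its midpoint, limits and a hand-computed value", {
  expect_equal(loglogistic_mortality(1, lc50 = 1, slope = 2), 0.5)
  expect_equal(loglogistic_mortality(0.3, lc50 = 0.3, slope = 5,
                                     floor = 0.1, ceiling = 0.9), 0.5)
  expect_equal(loglogistic_mortality(1e9, lc50 = 1, slope = 2), 1,
               tolerance = 1e-12)
  expect_equal(loglogistic_mortality(1e-9, lc50 = 1, slope = 2), 0,
               tolerance = 1e-12)
  # direct arithmetic: 1 / (1 + (1/10)^2) = 100/101
  expect_equal(loglogistic_mortality(10, lc50 = 1, slope = 2), 100 / 101)
  expect_error(loglogistic_mortality(0, 1, 2), "positive")
  expect_error(loglogistic_mortality(1, 1, 2, floor = 0.5, ceiling = 0.4),
               "floor")
})

test_that("genotype curve generation enforces the resistance ordering and saturates", {
  params <- dose_response_params(c("SS", "SR", "RR"),
                                 lc50 = c(0.01, 0.1, 1), slope = 3)
  axis <- 10^seq(-4, 2, length.out = 13)
  cur <- generate_genotype_curves(params, axis)
  expect_s3_class(cur, "mortality_curve")
  # far above every LC50 all genotypes die: the window is shut up there
  top <- cur$mortality[cur$axis == 100]
  expect_true(all(top > 0.999))

  bad <- dose_response_params(c("SS", "SR", "RR"),
                              lc50 = c(1, 0.1, 0.01), slope = 3)
  expect_error(generate_genotype_curves(bad, axis), "ordering")
  expect_error(generate_strain_curves(
    dose_response_params(c("R", "S"), lc50 = c(0.01, 0.1), slope = 2),
    axis), "ordering")
})

test_that("exponential decay halves on schedule", {
  expect_equal(concentration_decay(0, c0 = 8, half_life = 3), 8)
  expect_equal(concentration_decay(3, c0 = 8, half_life = 3), 4)
  expect_equal(concentration_decay(9, c0 = 8, half_life = 3), 1)
  t <- seq(0, 24, by = 0.5)
  expect_true(all(diff(concentration_decay(t, 1, 6)) < 0))
  expect_error(concentration_decay(-1, 1, 1), "non-negative")
})

test_that("bioassay sampling is seeded, unbiased and leaves the RNG alone", {
  a <- sample_bioassay(0.3, 100, seed = 7)
  b <- sample_bioassay(0.3, 100, seed = 7)
  expect_identical(a, b)
  expect_equal(sample_bioassay(0, 50, seed = 1)$dead, 0)
  expect_equal(sample_bioassay(1, 50, seed = 1)$dead, 50)

  big <- sample_bioassay(0.3, 100000, seed = 3)
  se <- sqrt(0.3 * 0.7 / 100000)
  expect_lt(abs(big$mortality - 0.3), 3 * se)

  withr::with_seed(123, {
    before <- stats::runif(1)
    set.seed(123)
    invisible(sample_bioassay(0.5, 10, seed = 99))
    expect_identical(stats::runif(1), before)
  })
})

test_that("simulated bioassay tables are deterministic and read back as curves", {
  cur <- idealized_scenario(axis = 10^seq(-3, 1, length.out = 9))
  tab1 <- simulate_bioassay(cur, n_exposed = 100, replicates = 3, seed = 42)
  tab2 <- simulate_bioassay(cur, n_exposed = 100, replicates = 3, seed = 42)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 9 * 3 * 3)
  expect_true(all(tab1$dead <= tab1$exposed))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab1, path)
  back <- read_bioassay_table(path)
  expect_s3_class(back, "mortality_curve")
  expect_equal(curve_axis(back), curve_axis(cur))
})

test_that("dose-response fits recover the generating parameters from counts", {
  conc <- 10^seq(-2.5, 0.5, length.out = 10)
  truth <- loglogistic_mortality(conc, lc50 = 0.05, slope = 2)
  counts <- tidyr::expand_grid(conc = conc, rep = 1:20)
  counts$truth <- loglogistic_mortality(counts$conc, 0.05, 2)
  samp <- sample_bioassay(counts$truth, 100, seed = 8)
  counts$dead <- samp$dead
  counts$exposed <- samp$exposed
  fit <- fit_dose_response(counts)
  expect_true(fit$converged)
  expect_lt(abs(fit$lc50 / 0.05 - 1), 0.1)
  expect_lt(abs(fit$slope / 2 - 1), 0.15)
})

test_that("a time-axis curve maps its window back onto the concentration window", {
  params <- dose_response_params(c("SS", "SR", "RR"),
                                 lc50 = c(0.01, 0.1, 1), slope = 3)
  conc_axis <- 10^seq(-4, 1, length.out = 26)
  c0 <- 10
  half_life <- 2
  # time grid chosen to decay exactly onto the concentration grid
  times <- half_life * log2(c0 / rev(conc_axis))
  cw <- detect_selection_window(generate_genotype_curves(params, conc_axis),
                                delta = 0.01, smooth = FALSE)
  tw <- detect_selection_window(
    generate_time_curves(params, times, c0 = c0, half_life = half_life),
    delta = 0.01, smooth = FALSE)
  # map the time boundaries back to concentrations
  expect_within_grid_step(concentration_decay(tw$open_at, c0, half_life),
                          cw$open_at, conc_axis)
  expect_within_grid_step(concentration_decay(tw$close_at, c0, half_life),
                          cw$close_at, conc_axis)
})

test_that("scenario heterozygotes pin dominance at its extremes over a shared envelope", {
  best <- scenario_curves("best")
  worst <- scenario_curves("worst")
  mid <- scenario_curves("intermediate")
  expect_error(scenario_curves("awful"), "arg")

  h_best <- dominance_profile(best)
  expect_true(all(h_best$dominance[h_best$defined] == 0))
  h_worst <- dominance_profile(worst)
  expect_true(all(h_worst$dominance[h_worst$defined] == 1))

  for (arm in c("SS", "RR")) {
    expect_equal(best$mortality[best$arm == arm],
                 worst$mortality[worst$arm == arm])
    expect_equal(best$mortality[best$arm == arm],
                 mid$mortality[mid$arm == arm])
  }
})

test_that("generated mortalities respect the floor/ceiling envelope", {
  for (i in 1:20) {
    params <- withr::with_seed(1000 + i, random_genotype_params())
    cur <- generate_genotype_curves(params, 10^seq(-4, 2, length.out = 15))
    for (j in seq_len(nrow(params))) {
      m <- cur$mortality[cur$arm == params$arm[j]]
      expect_true(all(m >= params$floor[j] - 1e-12 &
                        m <= params$ceiling[j] + 1e-12))
    }
  }
})
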