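test_that("fitness conversion inverts mortality and averages reciprocal heterozygotes", {
  w <- fitness_from_mortality(
    tibble::tibble(m_ss = 1.0, m_sr = 0.88, m_rr = 0.0))
  expect_equal(c(w$w_ss, w$w_sr, w$w_rr), c(0.0, 0.12, 1.0))

  none <- fitness_from_mortality(
    tibble::tibble(m_ss = 0, m_sr = 0, m_rr = 0))
  expect_equal(c(none$w_ss, none$w_sr, none$w_rr), c(1, 1, 1))

  recip <- fitness_from_mortality(
    tibble::tibble(m_ss = 1, m_sr = 0.6, m_rs = 0.4, m_rr = 0))
  expect_equal(recip$w_sr, 0.5)

  expect_error(
    fitness_from_mortality(tibble::tibble(m_ss = 1.2, m_sr = 0, m_rr = 0)),
    "\\[0, 1\\]")
  expect_error(fitness_from_mortality(tibble::tibble(m_ss = 1, m_rr = 0)),
               "m_sr")
})

test_that("recursion matches the six-mass enumeration oracle and conserves frequency", {
  expect_equal(next_allele_frequency(0.5, 1, w_ss = 0, w_sr = 1, w_rr = 1),
               2 / 3, tolerance = 1e-14)

  draws <- random_draws(2000)
  got <- next_allele_frequency(draws$p, draws$x,
                               draws$w_ss, draws$w_sr, draws$w_rr)
  want <- purrr::pmap_dbl(draws, oracle_next_p)
  expect_lt(max(abs(got - want)), 1e-12)
  expect_true(all(got > 0 & got < 1))

  # neutral fitness and zero exposure leave the frequency untouched
  expect_equal(next_allele_frequency(0.3, 0.7, 1, 1, 1), 0.3)
  expect_equal(next_allele_frequency(draws$p, 0, draws$w_ss,
                                     draws$w_sr, draws$w_rr),
               draws$p, tolerance = 1e-14)
})

test_that("full exposure reduces to the textbook diploid selection formula", {
  draws <- random_draws(500, seed = 7)
  ok <- draws$w_ss + draws$w_sr + draws$w_rr > 0
  draws <- draws[ok, ]
  got <- next_allele_frequency(draws$p, 1, draws$w_ss, draws$w_sr,
                               draws$w_rr)
  want <- oracle_textbook_p(draws$p, draws$w_ss, draws$w_sr, draws$w_rr)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("total kill of an entirely exposed population is a degenerate-population error", {
  expect_error(next_allele_frequency(0.5, 1, 0, 0, 0), "degenerate")
  expect_error(selective_advantage(0.5, 1, 0, 0, 0), "degenerate")
  # partial exposure leaves unexposed survivors, so no error
  expect_silent(next_allele_frequency(0.5, 0.9, 0, 0, 0))
})

test_that("selective advantage is zero exactly when selection is absent", {
  grid <- tidyr::expand_grid(p = c(1e-4, 0.01, 0.5, 0.99),
                             x = c(0, 0.3, 1))
  expect_equal(selective_advantage(grid$p, grid$x, 1, 1, 1),
               rep(0, nrow(grid)))
  expect_equal(selective_advantage(grid$p, grid$x, 0.4, 0.4, 0.4),
               rep(0, nrow(grid)))
  expect_equal(selective_advantage(0.5, 1, 0, 1, 1), 1 / 3,
               tolerance = 1e-14)
})

test_that("model inputs round-trip mortalities when dominance is defined", {
  triples <- withr::with_seed(99, {
    m_ss <- stats::runif(200, 0.05, 1)
    m_rr <- stats::runif(200, 0, 1) * m_ss * 0.95
    h <- stats::runif(200)
    tibble::tibble(m_ss = m_ss, m_rr = m_rr,
                   m_sr = m_ss - h * (m_ss - m_rr))
  })
  inputs <- model_inputs_from_mortalities(triples)
  back <- mortalities_from_model_inputs(inputs)
  expect_equal(back$m_ss, triples$m_ss, tolerance = 1e-12)
  expect_equal(back$m_sr, triples$m_sr, tolerance = 1e-12)
  expect_equal(back$m_rr, triples$m_rr, tolerance = 1e-12)
  expect_true(all(inputs$defined) && !any(inputs$clamped))
})

test_that("dominance endpoints, clamping and the undefined regime behave as stated", {
  got <- model_inputs_from_mortalities(
    tibble::tibble(m_ss = 1.0, m_sr = 0.88, m_rr = 0))
  expect_equal(got$effectiveness, 1)
  expect_equal(got$restoration, 1)
  expect_equal(got$dominance, 0.12)

  recessive <- model_inputs_from_mortalities(
    tibble::tibble(m_ss = 0.8, m_sr = 0.8, m_rr = 0.1))
  expect_equal(recessive$dominance, 0)
  dominant <- model_inputs_from_mortalities(
    tibble::tibble(m_ss = 0.8, m_sr = 0.1, m_rr = 0.1))
  expect_equal(dominant$dominance, 1)

  # heterozygote outside the [m_rr, m_ss] envelope: clamped with a warning
  expect_warning(
    clamped <- model_inputs_from_mortalities(
      tibble::tibble(m_ss = 0.8, m_sr = 0.9, m_rr = 0.1)),
    "clamped")
  expect_equal(clamped$dominance, 0)
  expect_true(clamped$clamped)

  expect_error(model_inputs_from_mortalities(
    tibble::tibble(m_ss = 0.2, m_sr = 0.2, m_rr = 0.5)),
    "dominance undefined")
  lax <- model_inputs_from_mortalities(
    tibble::tibble(m_ss = 0.2, m_sr = 0.2, m_rr = 0.5), strict = FALSE)
  expect_false(lax$defined)
  expect_true(is.na(lax$dominance))
})

test_that("selection strengthens with exposure and with dominance", {
  inputs <- tibble::tibble(effectiveness = 0.9, restoration = 0.9,
                           dominance = 0.5)
  m <- mortalities_from_model_inputs(inputs)
  xs <- seq(0.05, 1, by = 0.05)
  z <- selective_advantage(0.01, xs, 1 - m$m_ss, 1 - m$m_sr, 1 - m$m_rr)
  expect_true(all(diff(z) > -1e-12))
  gens_x <- vapply(xs, function(x) {
    g <- time_to_resistance(inputs, p0 = 0.01, x = x)$generations
    if (is.na(g)) Inf else g
  }, numeric(1))
  expect_true(all(diff(gens_x) <= 0))

  hs <- seq(0, 1, by = 0.1)
  gens_h <- vapply(hs, function(h) {
    g <- time_to_resistance(
      tibble::tibble(effectiveness = 0.9, restoration = 0.9, dominance = h),
      p0 = 1e-4, x = 0.3)$generations
    if (is.na(g)) Inf else g
  }, numeric(1))
  expect_true(all(diff(gens_h) <= 0))
})

test_that("dominance boosts the advantage most at low allele frequency", {
  z_at <- function(h, p) {
    m <- mortalities_from_model_inputs(
      tibble::tibble(effectiveness = 0.9, restoration = 0.9, dominance = h))
    selective_advantage(p, 0.3, 1 - m$m_ss, 1 - m$m_sr, 1 - m$m_rr)
  }
  expect_gt(z_at(1, 1e-4), z_at(0, 1e-4))
  # the relative gain from dominance is larger at the rarer frequency,
  # where nearly all R alleles sit in heterozygotes
  gain_rare <- z_at(1, 1e-4) / z_at(0, 1e-4)
  gain_common <- z_at(1, 0.01) / z_at(0, 0.01)
  expect_gt(gain_rare, gain_common)
})
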