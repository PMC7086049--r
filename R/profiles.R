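#' Dominance of resistance at each point along the deployment axis
#'
#' Computes the dominance coefficient `h` at every axis point of a genotype
#' mortality curve (the row of numbers the field prints along the top of a
#' window-of-selection plot). Dominance is the position of heterozygote
#' mortality between the homozygotes, from
#' [model_inputs_from_mortalities()]; points where `m_ss <= m_rr` (window
#' of selection shut, or fitness-cost regime) are flagged undefined rather
#' than numeric, and heterozygote mortalities outside the `[m_rr, m_ss]`
#' envelope are clamped and flagged.
#'
#' @param curve A [mortality_curve()] with genotype arms `SS`, `RR` and at
#'   least one of `SR`/`RS` (reciprocal heterozygotes are averaged).
#' @return A `dominance_profile` tibble: `axis`, `dominance`, `defined`,
#'   `clamped`.
#' @export
dominance_profile <- function(curve) {
  m <- genotype_mortalities(curve)
  complete <- !is.na(m$m_ss) & !is.na(m$m_sr) & !is.na(m$m_rr)
  out <- tibble(axis = m$axis, dominance = NA_real_,
                defined = NA, clamped = NA)
  if (any(complete)) {
    inputs <- model_inputs_from_mortalities(
      tibble(m_ss = m$m_ss[complete], m_sr = m$m_sr[complete],
             m_rr = m$m_rr[complete]),
      strict = FALSE)
    out$dominance[complete] <- inputs$dominance
    out$defined[complete] <- inputs$defined
    out$clamped[complete] <- inputs$clamped
  }
  new_profile(out, "dominance_profile", curve)
}

#' Selective advantage along the deployment axis
#'
#' Evaluates the per-generation selective advantage `z` of the resistance
#' allele at each axis point of a genotype mortality curve, for each
#' starting allele frequency. Unlike dominance, `z` needs only the genotype
#' fitnesses, so it is computed even at points where dominance is
#' undefined.
#'
#' @inheritParams dominance_profile
#' @param x Proportion of the population exposed (default 0.3).
#' @param p0 Starting resistance allele frequencies (default
#'   `c(0.01, 1e-4)`).
#' @return A `selection_profile` tibble: `axis`, `p0`, `z`.
#' @export
selection_profile <- function(curve, x = 0.3, p0 = c(0.01, 1e-4)) {
  m <- genotype_mortalities(curve)
  grid <- tidyr::expand_grid(m, p0 = p0)
  complete <- !is.na(grid$m_ss) & !is.na(grid$m_sr) & !is.na(grid$m_rr)
  z <- rep(NA_real_, nrow(grid))
  if (any(complete)) {
    g <- grid[complete, ]
    z[complete] <- selective_advantage(
      p = g$p0, x = x,
      w_ss = 1 - g$m_ss, w_sr = 1 - g$m_sr, w_rr = 1 - g$m_rr)
  }
  out <- tibble(axis = grid$axis, p0 = grid$p0, z = z)
  out <- new_profile(out, "selection_profile", curve)
  attr(out, "x") <- x
  out
}

#' Time to resistance along the deployment axis
#'
#' Runs an independent generations-to-threshold simulation at every axis
#' point of a genotype mortality curve, holding that point's mortalities
#' constant across generations, for each starting frequency. Runs that do
#' not reach the threshold within `max_generations` are censored
#' (`generations = NA`, `censored = TRUE`, label `">500"`-style).
#'
#' @inheritParams selection_profile
#' @param threshold Resistance allele-frequency target (default 0.5).
#' @param max_generations Generation cap per simulation (default 500).
#' @return A `resistance_profile` tibble: `axis`, `p0`, `generations`,
#'   `censored`, `label`.
#' @export
resistance_time_profile <- function(curve, x = 0.3, p0 = c(0.01, 1e-4),
                                    threshold = 0.5, max_generations = 500) {
  m <- genotype_mortalities(curve)
  grid <- tidyr::expand_grid(m, p0 = p0)
  res <- purrr::pmap(grid, function(axis, m_ss, m_sr, m_rr, p0) {
    if (is.na(m_ss) || is.na(m_sr) || is.na(m_rr)) {
      return(tibble(generations = NA_integer_, censored = NA,
                    label = NA_character_))
    }
    sim <- simulate_resistance(
      w_ss = 1 - m_ss, w_sr = 1 - m_sr, w_rr = 1 - m_rr,
      x = x, p0 = p0, threshold = threshold,
      max_generations = max_generations)
    tibble(generations = sim$generations, censored = sim$censored,
           label = format_generations(sim))
  })
  out <- dplyr::bind_cols(grid[c("axis", "p0")], dplyr::bind_rows(res))
  out <- new_profile(out, "resistance_profile", curve)
  attr(out, "x") <- x
  attr(out, "threshold") <- threshold
  attr(out, "max_generations") <- max_generations
  out
}

new_profile <- function(data, subclass, curve) {
  structure(as_tibble(data),
            axis_kind = curve_axis_kind(curve),
            class = c(subclass, "selwin_profile", class(tibble())))
}
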