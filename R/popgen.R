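#' Convert genotype mortalities to exposure fitnesses
#'
#' Fitness under exposure is the proportion of a genotype surviving the
#' insecticide, `w = 1 - mortality`. When both reciprocal heterozygote
#' mortalities are supplied (`m_sr` from SS fathers x RR mothers, `m_rs` from
#' the reverse cross) the heterozygote fitness uses their unweighted
#' arithmetic mean.
#'
#' @param data A data frame with columns `m_ss`, `m_sr`, `m_rr` (mortality
#'   proportions in `[0, 1]`) and optionally `m_rs` (reciprocal
#'   heterozygote). One row per exposure condition.
#' @return The input as a tibble with fitness columns `w_ss`, `w_sr`, `w_rr`
#'   appended.
#' @examples
#' fitness_from_mortality(tibble::tibble(m_ss = 1, m_sr = 0.88, m_rr = 0))
#' @export
fitness_from_mortality <- function(data) {
  data <- as_tibble(data)
  need <- setdiff(c("m_ss", "m_sr", "m_rr"), names(data))
  if (length(need) > 0) {
    abort(paste0("`data` is missing mortality column(s): ",
                 paste(need, collapse = ", ")))
  }
  m_het <- heterozygote_mortality(data$m_sr, data[["m_rs"]])
  check_proportion(data$m_ss, "m_ss")
  check_proportion(data$m_rr, "m_rr")
  check_proportion(m_het, "heterozygote mortality")
  data$w_ss <- 1 - data$m_ss
  data$w_sr <- 1 - m_het
  data$w_rr <- 1 - data$m_rr
  data
}

# Unweighted mean of reciprocal heterozygotes; m_rs may be NULL or NA.
heterozygote_mortality <- function(m_sr, m_rs = NULL) {
  check_proportion(m_sr, "m_sr")
  if (is.null(m_rs)) {
    return(m_sr)
  }
  check_proportion(m_rs, "m_rs", allow_na = TRUE)
  ifelse(is.na(m_rs), m_sr, (m_sr + m_rs) / 2)
}

check_proportion <- function(x, what, allow_na = FALSE) {
  bad <- if (allow_na) {
    !is.na(x) & (x < 0 | x > 1)
  } else {
    is.na(x) | x < 0 | x > 1
  }
  if (any(bad)) {
    abort(paste0("`", what, "` must lie in [0, 1]; offending value(s): ",
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

#' One generation of diploid selection under partial exposure
#'
#' Advances the resistance-allele frequency by one discrete generation.
#' Genotypes start at Hardy-Weinberg proportions `p^2`, `2pq`, `q^2`; a
#' fraction `x` of the population is exposed to the insecticide and survives
#' with genotype fitnesses `w_rr`, `w_sr`, `w_ss`, while the unexposed
#' fraction `1 - x` survives regardless of genotype (no fitness costs).
#' The updated frequency is
#' \deqn{p' = \frac{x (p^2 w_{rr} + pq\, w_{sr}) + (1-x)(p^2 + pq)}{\bar W}}
#' with \eqn{\bar W} the total surviving mass (the sum of the `p'` and `q'`
#' numerators), so `p' + q' = 1` by construction.
#'
#' @param p Resistance allele frequency, in `(0, 1)`. Vectorized.
#' @param x Proportion of the population exposed, in `[0, 1]`.
#' @param w_ss,w_sr,w_rr Genotype fitnesses (survival proportions) under
#'   exposure, each in `[0, 1]`.
#' @return The next-generation frequency `p'`, same length as the recycled
#'   inputs.
#' @examples
#' next_allele_frequency(p = 0.5, x = 1, w_ss = 0, w_sr = 1, w_rr = 1) # 2/3
#' @export
next_allele_frequency <- function(p, x, w_ss, w_sr, w_rr) {
  n <- max(length(p), length(x), length(w_ss), length(w_sr), length(w_rr))
  p <- rep_len(p, n); x <- rep_len(x, n)
  w_ss <- rep_len(w_ss, n); w_sr <- rep_len(w_sr, n); w_rr <- rep_len(w_rr, n)
  if (any(is.na(p) | p <= 0 | p >= 1)) {
    abort("`p` must lie strictly within (0, 1)")
  }
  if (any(is.na(x) | x < 0 | x > 1)) {
    abort("`x` must lie in [0, 1]")
  }
  check_proportion(w_ss, "w_ss")
  check_proportion(w_sr, "w_sr")
  check_proportion(w_rr, "w_rr")
  q <- 1 - p
  num_p <- x * (p^2 * w_rr + 2 * p * q * 0.5 * w_sr) +
    (1 - x) * (p^2 + 2 * p * q * 0.5)
  num_q <- x * (2 * p * q * 0.5 * w_sr + q^2 * w_ss) +
    (1 - x) * (2 * p * q * 0.5 + q^2)
  w_bar <- num_p + num_q
  if (any(w_bar == 0)) {
    abort(paste0("degenerate population: every genotype is killed ",
                 "(mean fitness is 0), allele frequencies are undefined"))
  }
  num_p / w_bar
}

#' Per-generation selective advantage of the resistance allele
#'
#' The selective advantage `z = p'/p - 1` is the proportional change in
#' resistance-allele frequency over a single generation of exposure. It is 0
#' exactly when selection is absent (equal fitnesses, or no exposure) and
#' depends on the current allele frequency `p` because `p` sets the share of
#' R alleles carried by heterozygotes.
#'
#' @inheritParams next_allele_frequency
#' @return Dimensionless per-generation advantage `z`, vectorized.
#' @examples
#' selective_advantage(p = 0.5, x = 1, w_ss = 0, w_sr = 1, w_rr = 1) # 1/3
#' @export
selective_advantage <- function(p, x, w_ss, w_sr, w_rr) {
  next_allele_frequency(p, x, w_ss, w_sr, w_rr) / p - 1
}

#' Convert genotype mortalities to simulation model inputs
#'
#' Re-expresses per-genotype mortalities as the three standard inputs of
#' single-locus resistance simulations:
#' * effectiveness — mortality of the SS genotype under exposure;
#' * restoration — the proportion of SS mortality prevented in the RR
#'   genotype, `(m_ss - m_rr) / m_ss` (0 when `m_ss = 0`: no mortality to
#'   prevent);
#' * dominance `h` — the position of heterozygote mortality between the two
#'   homozygotes, `(m_ss - m_sr) / (m_ss - m_rr)`; 0 means resistance is
#'   fully recessive, 1 fully dominant.
#'
#' Dominance is only defined when `m_ss > m_rr` (the window of selection is
#' open). With `strict = TRUE` (the default) a violation is an error; with
#' `strict = FALSE` such rows get `dominance = NA` and `defined = FALSE`,
#' which is what per-point profile computations need on noisy data.
#' Heterozygote mortality outside the `[m_rr, m_ss]` envelope (measurement
#' noise) is clamped into `[0, 1]` dominance and flagged via `clamped`.
#'
#' @inheritParams fitness_from_mortality
#' @param x Proportion of the population exposed each generation, carried
#'   through unchanged (default 0.3).
#' @param strict If `TRUE`, rows with `m_ss <= m_rr` raise an
#'   undefined-dominance error naming the offending rows; if `FALSE`, they
#'   are flagged instead.
#' @return A tibble with columns `effectiveness`, `restoration`,
#'   `dominance`, `exposure`, `defined` and `clamped`.
#' @examples
#' model_inputs_from_mortalities(
#'   tibble::tibble(m_ss = 1, m_sr = 0.88, m_rr = 0))
#' @export
model_inputs_from_mortalities <- function(data, x = 0.3, strict = TRUE) {
  data <- as_tibble(data)
  need <- setdiff(c("m_ss", "m_sr", "m_rr"), names(data))
  if (length(need) > 0) {
    abort(paste0("`data` is missing mortality column(s): ",
                 paste(need, collapse = ", ")))
  }
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort("`x` must be a single value in [0, 1]")
  }
  m_ss <- check_proportion(data$m_ss, "m_ss")
  m_sr <- heterozygote_mortality(data$m_sr, data[["m_rs"]])
  m_rr <- check_proportion(data$m_rr, "m_rr")
  undefined <- m_ss <= m_rr
  if (strict && any(undefined)) {
    abort(paste0(
      "dominance undefined: m_ss <= m_rr in row(s) ",
      paste(which(undefined), collapse = ", "),
      " (no selection for resistance at these points, or a fitness-cost ",
      "regime where resistant mortality exceeds susceptible)"))
  }
  restoration <- ifelse(m_ss == 0, 0, (m_ss - m_rr) / m_ss)
  h_raw <- ifelse(undefined, NA_real_, (m_ss - m_sr) / (m_ss - m_rr))
  clamped <- !undefined & (h_raw < 0 | h_raw > 1)
  if (any(clamped)) {
    warn(paste0("heterozygote mortality outside the [m_rr, m_ss] envelope ",
                "in row(s) ", paste(which(clamped), collapse = ", "),
                "; dominance clamped to [0, 1]"))
  }
  tibble(
    effectiveness = m_ss,
    restoration = ifelse(undefined, NA_real_, restoration),
    dominance = pmin(pmax(h_raw, 0), 1),
    exposure = x,
    defined = !undefined,
    clamped = clamped
  )
}

#' Recover genotype mortalities from model inputs
#'
#' Inverse of [model_inputs_from_mortalities()]:
#' `m_ss = effectiveness`, `m_rr = effectiveness * (1 - restoration)`,
#' `m_sr = m_ss - dominance * (m_ss - m_rr)`. Round-trips exactly whenever
#' `m_ss > m_rr` and the heterozygote lay inside the envelope.
#'
#' @param inputs A data frame with columns `effectiveness`, `restoration`,
#'   `dominance` (each in `[0, 1]`).
#' @return A tibble with columns `m_ss`, `m_sr`, `m_rr`.
#' @export
mortalities_from_model_inputs <- function(inputs) {
  inputs <- as_tibble(inputs)
  need <- setdiff(c("effectiveness", "restoration", "dominance"),
                  names(inputs))
  if (length(need) > 0) {
    abort(paste0("`inputs` is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  check_proportion(inputs$effectiveness, "effectiveness")
  check_proportion(inputs$restoration, "restoration")
  check_proportion(inputs$dominance, "dominance")
  m_ss <- inputs$effectiveness
  m_rr <- m_ss * (1 - inputs$restoration)
  tibble(
    m_ss = m_ss,
    m_sr = m_ss - inputs$dominance * (m_ss - m_rr),
    m_rr = m_rr
  )
}
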