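# Shared fixtures built in code.

# random fitness/exposure/frequency draws for property-style tests
random_draws <- function(n, seed = 424242) {
  withr::with_seed(seed, tibble::tibble(
    p = stats::runif(n, 1e-6, 1 - 1e-6),
    x = stats::runif(n),
    w_ss = stats::runif(n),
    w_sr = stats::runif(n),
    w_rr = stats::runif(n)
  ))
}

# genotype dose-response parameters with the resistance ordering
random_genotype_params <- function() {
  lc_ss <- 10^stats::runif(1, -3, -1)
  lc_sr <- lc_ss * 10^stats::runif(1, 0.3, 1)
  lc_rr <- lc_sr * 10^stats::runif(1, 0.3, 1)
  dose_response_params(
    arm = c("SS", "SR", "RR"),
    lc50 = c(lc_ss, lc_sr, lc_rr),
    slope = stats::runif(3, 1.5, 4),
    floor = stats::runif(1, 0, 0.05),
    ceiling = stats::runif(1, 0.95, 1)
  )
}

# the two discussion-example genotype mortality triples for
# permethrin-resistant Culex: a mild-kill situation (only 24% of SS die)
# versus an intense-kill one (88% of SR and all SS die)
culex_triples <- function() {
  tibble::tibble(
    situation = c("mild_kill", "intense_kill"),
    m_rr = c(0, 0),
    m_sr = c(0, 0.88),
    m_ss = c(0.24, 1.0)
  )
}
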