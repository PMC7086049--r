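# Independent oracles: deliberately brute-force, sharing no code with the
# package internals they check.

# Enumerate the six population masses (exposed / unexposed x three
# genotypes), apply survival, and count R alleles among survivors.
oracle_next_p <- function(p, x, w_ss, w_sr, w_rr) {
  q <- 1 - p
  mass <- c(
    exp_rr = x * p^2 * w_rr,
    exp_sr = x * 2 * p * q * w_sr,
    exp_ss = x * q^2 * w_ss,
    une_rr = (1 - x) * p^2,
    une_sr = (1 - x) * 2 * p * q,
    une_ss = (1 - x) * q^2
  )
  r_alleles <- 2 * (mass[["exp_rr"]] + mass[["une_rr"]]) +
    (mass[["exp_sr"]] + mass[["une_sr"]])
  total_alleles <- 2 * sum(mass)
  r_alleles / total_alleles
}

# Textbook diploid selection formula (full exposure).
oracle_textbook_p <- function(p, w_ss, w_sr, w_rr) {
  q <- 1 - p
  (p^2 * w_rr + p * q * w_sr) /
    (p^2 * w_rr + 2 * p * q * w_sr + q^2 * w_ss)
}

# Hand-iterated recursion: count generations to the threshold using only
# the enumeration oracle.
oracle_generations <- function(w_ss, w_sr, w_rr, x, p0, threshold = 0.5,
                               max_generations = 500) {
  p <- p0
  for (g in seq_len(max_generations)) {
    p <- oracle_next_p(p, x, w_ss, w_sr, w_rr)
    if (p >= threshold) return(g)
  }
  NA_integer_
}

# Dense-grid brute-force window scan of the *generating* log-logistic
# functions (not the package's curve code): returns the outer open
# boundaries on a 1000-point log10 grid spanning the observation axis.
oracle_dense_window <- function(params, axis, delta = 0,
                                pair = c(susceptible = "S",
                                         resistant = "R"),
                                n_dense = 1000) {
  grid <- 10^seq(log10(min(axis)), log10(max(axis)), length.out = n_dense)
  mort <- function(arm, conc) {
    p <- params[params$arm == arm, ]
    p$floor + (p$ceiling - p$floor) / (1 + (p$lc50 / conc)^p$slope)
  }
  gap <- mort(pair[["susceptible"]], grid) -
    mort(pair[["resistant"]], grid) - delta
  open <- gap > 0
  if (!any(open)) {
    return(list(no_window = TRUE))
  }
  list(no_window = FALSE,
       low = grid[which(open)[1]],
       high = grid[max(which(open))],
       low_open_ended = open[1],
       high_open_ended = open[n_dense])
}

# One observation-grid step on the log10 axis.
log_step <- function(axis) {
  max(abs(diff(log10(sort(axis)))))
}

expect_within_grid_step <- function(found, truth, axis) {
  expect_lt(abs(log10(found) - log10(truth)), log_step(axis) + 1e-9)
}
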