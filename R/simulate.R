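#' Simulate generations until a resistance-frequency threshold
#'
#' Iterates the one-generation selection recursion
#' ([next_allele_frequency()]) from a starting resistance-allele frequency
#' `p0`, holding the genotype mortalities (expressed as model inputs)
#' constant across generations, and reports the first generation at which
#' the frequency reaches `threshold`. Runs that do not reach the threshold
#' within `max_generations` are censored: `generations` is `NA` and the
#' result prints as e.g. `">500"` rather than a number.
#'
#' @param inputs A one-row data frame (or named list) with
#'   `effectiveness`, `restoration`, `dominance` and optionally `exposure`
#'   — as produced by [model_inputs_from_mortalities()].
#' @param p0 Starting resistance allele frequency, in `(0, threshold)`.
#' @param threshold Allele-frequency target (default 0.5).
#' @param max_generations Generation cap (default 500).
#' @param x Exposure proportion; overrides `inputs$exposure` when given.
#' @return A `resistance_sim` object: a list with `generations` (integer or
#'   `NA`), `censored`, `trajectory` (tibble of `generation`, `p` starting
#'   at generation 0 = `p0`), `threshold`, `max_generations`, `p0` and the
#'   fitnesses used. [tidy()] returns the trajectory, [glance()] a one-row
#'   summary.
#' @examples
#' time_to_resistance(
#'   tibble::tibble(effectiveness = 1, restoration = 1, dominance = 0.12),
#'   p0 = 0.01, x = 0.3)
#' @export
time_to_resistance <- function(inputs, p0 = 1e-4, threshold = 0.5,
                               max_generations = 500, x = NULL) {
  inputs <- as_tibble(as.list(inputs)[c(
    intersect(c("effectiveness", "restoration", "dominance", "exposure"),
              names(inputs)))])
  if (nrow(inputs) != 1) {
    abort("`inputs` must describe exactly one exposure condition (one row)")
  }
  x <- x %||% inputs[["exposure"]] %||% 0.3
  m <- mortalities_from_model_inputs(inputs)
  w <- fitness_from_mortality(m)
  simulate_resistance(w$w_ss, w$w_sr, w$w_rr, x = x, p0 = p0,
                      threshold = threshold,
                      max_generations = max_generations)
}

# Core loop on fitnesses; time_to_resistance() is the model-input wrapper.
simulate_resistance <- function(w_ss, w_sr, w_rr, x, p0,
                                threshold = 0.5, max_generations = 500) {
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1) {
    abort("`p0` must be a single frequency in (0, 1)")
  }
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= p0 || threshold >= 1) {
    abort("`threshold` must lie strictly between `p0` and 1")
  }
  if (length(max_generations) != 1 || max_generations < 1) {
    abort("`max_generations` must be a positive integer")
  }
  max_generations <- as.integer(max_generations)
  traj <- numeric(max_generations + 1)
  traj[1] <- p0
  p <- p0
  generations <- NA_integer_
  for (g in seq_len(max_generations)) {
    p <- next_allele_frequency(p, x, w_ss, w_sr, w_rr)
    traj[g + 1] <- p
    if (p >= threshold) {
      generations <- g
      break
    }
  }
  n_kept <- if (is.na(generations)) max_generations else generations
  structure(
    list(
      generations = generations,
      censored = is.na(generations),
      trajectory = tibble(generation = 0:n_kept, p = traj[1:(n_kept + 1)]),
      threshold = threshold,
      max_generations = max_generations,
      p0 = p0,
      x = x,
      w = c(w_ss = w_ss, w_sr = w_sr, w_rr = w_rr)
    ),
    class = "resistance_sim"
  )
}

#' @export
print.resistance_sim <- function(x, ...) {
  cat("<resistance_sim>\n")
  cat(sprintf("  p0 = %g, threshold = %g, exposure = %g\n",
              x$p0, x$threshold, x$x))
  cat(sprintf("  generations to threshold: %s\n", format_generations(x)))
  invisible(x)
}

# ">500"-style label for censored runs; bare number otherwise.
format_generations <- function(sim) {
  if (sim$censored) paste0(">", sim$max_generations)
  else as.character(sim$generations)
}

#' @exportS3Method generics::tidy
tidy.resistance_sim <- function(x, ...) {
  x$trajectory
}

#' @exportS3Method generics::glance
glance.resistance_sim <- function(x, ...) {
  tibble(
    generations = x$generations,
    censored = x$censored,
    label = format_generations(x),
    p0 = x$p0,
    threshold = x$threshold,
    max_generations = x$max_generations,
    exposure = x$x,
    p_final = tail(x$trajectory$p, 1)
  )
}
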