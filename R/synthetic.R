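#' Log-logistic (Hill) dose-response mortality
#'
#' The standard bioassay dose-response model on a log concentration scale:
#' \deqn{m(c) = floor + \frac{ceiling - floor}{1 + (lc50 / c)^{slope}}}
#' Mortality rises strictly with concentration, equals the floor/ceiling
#' midpoint at `c = lc50`, and tends to `floor` as `c -> 0` and `ceiling`
#' as `c -> Inf`.
#'
#' @param conc Concentration(s), strictly positive (assay units are opaque
#'   and carried through unchanged).
#' @param lc50 Concentration killing half the exposed (between floor and
#'   ceiling), > 0.
#' @param slope Hill slope (steepness on the log-concentration scale), > 0.
#' @param floor Minimum mortality, in `[0, 1)` (default 0).
#' @param ceiling Maximum mortality, in `(floor, 1]` (default 1).
#' @return Mortality proportion(s), same length as `conc`.
#' @examples
#' loglogistic_mortality(1, lc50 = 1, slope = 2) # 0.5
#' @export
loglogistic_mortality <- function(conc, lc50, slope, floor = 0, ceiling = 1) {
  if (any(is.na(conc) | conc <= 0)) {
    abort("`conc` must be strictly positive")
  }
  if (any(lc50 <= 0) || any(slope <= 0)) {
    abort("`lc50` and `slope` must be strictly positive")
  }
  if (any(floor < 0) || any(floor >= 1) || any(ceiling <= floor) ||
      any(ceiling > 1)) {
    abort("need 0 <= floor < ceiling <= 1")
  }
  floor + (ceiling - floor) / (1 + (lc50 / conc)^slope)
}

#' Dose-response parameter table for a set of arms
#'
#' Convenience constructor for the per-arm parameter tables consumed by the
#' curve generators.
#'
#' @param arm Arm labels (genotypes `SS`/`SR`/`RR` or strains `R`/`S`).
#' @param lc50,slope,floor,ceiling Per-arm log-logistic parameters,
#'   recycled to the number of arms.
#' @return A tibble with columns `arm`, `lc50`, `slope`, `floor`,
#'   `ceiling`.
#' @export
dose_response_params <- function(arm, lc50, slope = 3, floor = 0,
                                 ceiling = 1) {
  tibble(arm = arm, lc50 = lc50, slope = slope,
         floor = floor, ceiling = ceiling)
}

#' Generate noise-free genotype mortality curves
#'
#' Evaluates per-genotype log-logistic dose-response curves on a
#' concentration grid. With equal slopes and LC50s ordered
#' `RR > SR > SS` (resistance raises the tolerated concentration) the
#' induced dominance rises from about 0 at high concentration towards 1 as
#' concentration declines, which is the geometry that opens a window of
#' dominance inside the window of selection.
#'
#' @param params A [dose_response_params()] table with arms `SS`, `SR`,
#'   `RR`; their LC50s must satisfy `lc50_RR > lc50_SR > lc50_SS`.
#' @param axis Concentration grid (strictly positive).
#' @param metadata Optional metadata list for the curve.
#' @return A [mortality_curve()] on a concentration axis.
#' @export
generate_genotype_curves <- function(params, axis, metadata = list()) {
  params <- as_tibble(params)
  need <- setdiff(c("SS", "SR", "RR"), params$arm)
  if (length(need) > 0) {
    abort(paste0("`params` is missing genotype arm(s): ",
                 paste(need, collapse = ", ")))
  }
  lc <- setNames(params$lc50, params$arm)
  if (!(lc[["RR"]] > lc[["SR"]] && lc[["SR"]] > lc[["SS"]])) {
    abort("resistance ordering violated: need lc50 RR > SR > SS")
  }
  generate_curves(params, axis, metadata = metadata)
}

#' Generate noise-free resistant/susceptible strain curves
#'
#' @param params A [dose_response_params()] table with arms `R` and `S`;
#'   `lc50_R > lc50_S`.
#' @inheritParams generate_genotype_curves
#' @return A [mortality_curve()] with arms `R` and `S`.
#' @export
generate_strain_curves <- function(params, axis, metadata = list()) {
  params <- as_tibble(params)
  need <- setdiff(c("R", "S"), params$arm)
  if (length(need) > 0) {
    abort(paste0("`params` is missing strain arm(s): ",
                 paste(need, collapse = ", ")))
  }
  lc <- setNames(params$lc50, params$arm)
  if (!(lc[["R"]] > lc[["S"]])) {
    abort("resistance ordering violated: need lc50 R > S")
  }
  generate_curves(params, axis, metadata = metadata)
}

generate_curves <- function(params, axis, axis_kind = "concentration",
                            axis_values = NULL, metadata = list()) {
  conc <- axis_values %||% axis
  rows <- purrr::pmap(params, function(arm, lc50, slope, floor, ceiling) {
    tibble(axis = axis, arm = arm,
           mortality = loglogistic_mortality(conc, lc50, slope,
                                             floor, ceiling))
  })
  mortality_curve(dplyr::bind_rows(rows), axis_kind = axis_kind,
                  metadata = metadata)
}

#' Residual insecticide concentration after deployment
#'
#' First-order (exponential) decay of the deployed concentration:
#' `c(t) = c0 * 2^(-t / half_life)`. This maps a time-after-deployment
#' axis onto the concentration axis, so windows measured in concentration
#' units can be re-expressed in units of time.
#'
#' @param t Time since deployment, >= 0 (any unit; `half_life` must match).
#' @param c0 Initial deployed concentration, > 0.
#' @param half_life Time for the concentration to halve, > 0.
#' @return Concentration(s) at time `t`.
#' @examples
#' concentration_decay(c(0, 3, 9), c0 = 8, half_life = 3) # 8, 4, 1
#' @export
concentration_decay <- function(t, c0, half_life) {
  if (any(is.na(t) | t < 0)) abort("`t` must be non-negative")
  if (any(c0 <= 0) || any(half_life <= 0)) {
    abort("`c0` and `half_life` must be strictly positive")
  }
  c0 * 2^(-t / half_life)
}

#' Generate genotype curves on a time axis via concentration decay
#'
#' Composes [generate_genotype_curves()] with [concentration_decay()]: the
#' mortality at each time point is the dose-response mortality at the
#' decayed concentration.
#'
#' @inheritParams generate_genotype_curves
#' @param times Time grid since deployment (>= 0, strictly increasing).
#' @param c0,half_life Decay parameters, see [concentration_decay()].
#' @return A [mortality_curve()] on a time axis.
#' @export
generate_time_curves <- function(params, times, c0, half_life,
                                 metadata = list()) {
  conc <- concentration_decay(times, c0, half_life)
  generate_curves(as_tibble(params), axis = times, axis_kind = "time",
                  axis_values = conc, metadata = metadata)
}

#' Sample bioassay counts from true mortalities
#'
#' Draws binomial dead counts at the given true mortalities, emulating
#' cone-bioassay replicates. The same seed always yields identical counts;
#' the sampler leaves the session's random-number state untouched.
#'
#' @param true_mortality True mortality proportion(s) in `[0, 1]`.
#' @param n_exposed Insects exposed per observation (recycled), >= 1.
#' @param seed Integer seed.
#' @return A tibble with `dead`, `exposed` and the observed `mortality`.
#' @export
sample_bioassay <- function(true_mortality, n_exposed, seed) {
  check_proportion(true_mortality, "true_mortality")
  if (any(n_exposed < 1)) abort("`n_exposed` must be >= 1")
  n <- length(true_mortality)
  n_exposed <- rep_len(as.integer(n_exposed), n)
  dead <- withr::with_seed(seed, rbinom(n, n_exposed, true_mortality))
  tibble(dead = dead, exposed = n_exposed, mortality = dead / n_exposed)
}

#' Simulate a replicated bioassay experiment over a curve
#'
#' Samples binomial counts for every (axis point, arm) of a noise-free
#' mortality curve, with the stated number of replicates, producing a tidy
#' bioassay count table in the same schema that [read_bioassay_table()]
#' accepts.
#'
#' @param curve A noise-free [mortality_curve()] (no `NA` mortalities).
#' @param n_exposed Insects exposed per replicate (default 100).
#' @param replicates Replicates per (axis point, arm) (default 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble: `axis_kind`, `axis_value`, `arm`, `replicate`,
#'   `exposed`, `dead`.
#' @export
simulate_bioassay <- function(curve, n_exposed = 100, replicates = 1,
                              seed = 1) {
  stopifnot(inherits(curve, "mortality_curve"))
  df <- as_tibble(curve)
  if (any(is.na(df$mortality))) {
    abort("curve has missing mortalities; complete it before sampling")
  }
  grid <- tidyr::expand_grid(df[c("axis", "arm", "mortality")],
                             replicate = seq_len(replicates))
  counts <- sample_bioassay(grid$mortality, n_exposed, seed = seed)
  tibble(axis_kind = curve_axis_kind(curve), axis_value = grid$axis,
         arm = grid$arm, replicate = grid$replicate,
         exposed = counts$exposed, dead = counts$dead)
}

#' Fit a log-logistic dose-response to bioassay counts
#'
#' Maximum-likelihood fit of the floor-0 / ceiling-1 log-logistic model to
#' binomial dead/exposed counts. On the natural-log concentration scale
#' this model is exactly a logistic regression,
#' `logit(m) = slope * (ln c - ln lc50)`, so the fit uses a binomial GLM
#' and back-transforms its coefficients.
#'
#' @param counts A data frame with columns `conc` (or `axis_value`),
#'   `dead`, `exposed`.
#' @return A one-row tibble: `lc50`, `slope`, `converged`.
#' @export
fit_dose_response <- function(counts) {
  counts <- as_tibble(counts)
  if (!"conc" %in% names(counts) && "axis_value" %in% names(counts)) {
    counts$conc <- counts$axis_value
  }
  need <- setdiff(c("conc", "dead", "exposed"), names(counts))
  if (length(need) > 0) {
    abort(paste0("`counts` is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  fit <- glm(cbind(dead, exposed - dead) ~ log(conc),
             family = binomial(), data = counts)
  b <- coef(fit)
  tibble(lc50 = exp(-b[[1]] / b[[2]]), slope = b[[2]],
         converged = fit$converged)
}

#' Default concentration grid for idealized scenarios
#'
#' Log-spaced grid spanning seven decades (1e-5 to 1e2 assay units),
#' wide enough that both homozygote dose-response curves saturate at each
#' end and the windows of selection and dominance sit in the interior.
#'
#' @param n Number of grid points (default 29, four per decade).
#' @return Ascending concentration grid.
#' @export
scenario_axis <- function(n = 29) {
  10^seq(-5, 2, length.out = n)
}

#' Idealized best / intermediate / worst dominance scenarios
#'
#' Three genotype-curve scenarios sharing the same SS and RR dose-response
#' envelopes (LC50 0.01 and 1.0 assay units, Hill slope 3, floor 0,
#' ceiling 1) and differing only in the heterozygote:
#' * `best` — dominance constant 0: SR mortality tracks SS everywhere, so
#'   there is no window of dominance;
#' * `worst` — dominance constant 1: SR tracks RR, the window of dominance
#'   spans the whole window of selection;
#' * `intermediate` — SR has its own LC50 (0.1) between the homozygotes,
#'   so dominance transitions from about 0 at high concentration to about
#'   1 as concentration declines.
#'
#' The constants are package fixtures chosen to give a selection window of
#' roughly two decades with the dominance window inside it.
#'
#' @param kind `"best"`, `"intermediate"` (alias `"idealized"`) or
#'   `"worst"`.
#' @param axis Concentration grid (default [scenario_axis()]).
#' @return A genotype [mortality_curve()].
#' @export
scenario_curves <- function(kind = c("intermediate", "best", "worst",
                                     "idealized"),
                            axis = scenario_axis()) {
  kind <- match.arg(kind)
  if (kind == "idealized") kind <- "intermediate"
  env <- scenario_envelope()
  sr <- switch(kind,
    best = dplyr::mutate(env[env$arm == "SS", ], arm = "SR"),
    worst = dplyr::mutate(env[env$arm == "RR", ], arm = "SR"),
    intermediate = dose_response_params("SR", lc50 = 0.1))
  params <- dplyr::bind_rows(env, sr)
  generate_curves(params, axis,
                  metadata = list(scenario = kind, synthetic = TRUE))
}

# Shared SS / RR envelope of the three scenarios.
scenario_envelope <- function() {
  dose_response_params(c("SS", "RR"), lc50 = c(0.01, 1), slope = 3)
}

#' @rdname scenario_curves
#' @export
idealized_scenario <- function(axis = scenario_axis()) {
  scenario_curves("intermediate", axis = axis)
}
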