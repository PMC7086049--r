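#' Construct a window report
#'
#' A window report records where a window of selection (differential
#' mortality of resistant vs susceptible arms) or a window of dominance
#' (heterozygote mortality below susceptible, within the selection window)
#' is open along a concentration or time axis. Reports are usually produced
#' by [detect_selection_window()] / [detect_dominance_window()], but can be
#' built directly from known boundaries (e.g. boundaries reported in the
#' literature) to compute their [window_metrics()].
#'
#' Boundaries are stated in deployment order: a concentration window opens
#' at its high-concentration boundary and closes at its low-concentration
#' boundary (concentrations decay after deployment); a time window opens
#' early and closes late.
#'
#' @param kind `"selection"` or `"dominance"`.
#' @param axis_kind `"concentration"` or `"time"`.
#' @param open_at,close_at Window boundaries in deployment order, or `NA`
#'   for an empty report.
#' @param open_ended_open,open_ended_close Whether the window was already
#'   open at the first observed point / still open at the last, so the
#'   corresponding boundary is an observed bound rather than a crossing.
#' @param flags Optional tibble of per-grid-point `axis` and logical `open`.
#' @param fragmented Whether several disjoint open runs were merged into
#'   the reported maximal spanning window.
#' @param delta Minimum mortality difference used for detection.
#' @param smoothed Whether detection ran on loess-smoothed series.
#' @return A `window_report` object. [tidy()] returns the per-point flags,
#'   [glance()] the one-row summary of [window_metrics()].
#' @examples
#' w <- window_report("selection", "concentration",
#'                    open_at = 0.8, close_at = 0.0025)
#' window_metrics(w)
#' @export
window_report <- function(kind = c("selection", "dominance"),
                          axis_kind = c("concentration", "time"),
                          open_at = NA_real_, close_at = NA_real_,
                          open_ended_open = FALSE, open_ended_close = FALSE,
                          flags = NULL, fragmented = FALSE,
                          delta = 0, smoothed = FALSE) {
  kind <- match.arg(kind)
  axis_kind <- match.arg(axis_kind)
  if (is.null(flags)) {
    flags <- tibble(axis = numeric(), open = logical())
  }
  no_window <- is.na(open_at) && is.na(close_at)
  if (!no_window && (is.na(open_at) || is.na(close_at))) {
    abort("supply both `open_at` and `close_at`, or neither")
  }
  if (!no_window && axis_kind == "time" && close_at < open_at) {
    abort("a time window must close at or after it opens")
  }
  structure(
    list(kind = kind, axis_kind = axis_kind,
         open_at = open_at, close_at = close_at,
         open_ended_open = open_ended_open,
         open_ended_close = open_ended_close,
         flags = as_tibble(flags), fragmented = fragmented,
         no_window = no_window, delta = delta, smoothed = smoothed),
    class = "window_report")
}

#' @export
print.window_report <- function(x, ...) {
  cat(sprintf("<window_report: %s window on %s axis>\n", x$kind, x$axis_kind))
  if (x$no_window) {
    cat("  no window: the arms never differ by more than delta\n")
  } else {
    cat(sprintf("  opens at %g%s, closes at %g%s\n",
                x$open_at, if (x$open_ended_open) " (open-ended)" else "",
                x$close_at, if (x$open_ended_close) " (open-ended)" else ""))
    m <- window_metrics(x)
    cat(sprintf("  %s: %g%s\n", m$measure, m$value,
                if (x$fragmented) " (fragmented open region)" else ""))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.window_report <- function(x, ...) x$flags

#' @exportS3Method generics::glance
glance.window_report <- function(x, ...) window_metrics(x)

#' Measure a window: fold-range or duration
#'
#' On a concentration axis the window's size is its fold-range, the larger
#' boundary concentration divided by the smaller (always >= 1, invariant
#' under which boundary is called "opening"). On a time axis it is the
#' duration `close_at - open_at`; open-ended windows report the observed
#' span flagged as open-ended. An empty report yields a defined
#' `no_window` row rather than an error.
#'
#' @param report A [window_report()].
#' @return A one-row tibble: `kind`, `axis_kind`, `open_at`, `close_at`,
#'   `measure` (`"fold_range"`, `"duration"` or `"none"`), `value`,
#'   `open_ended`, `fragmented`, `no_window`.
#' @examples
#' window_metrics(window_report("selection", "concentration", 0.8, 0.0025))
#' @export
window_metrics <- function(report) {
  stopifnot(inherits(report, "window_report"))
  if (report$no_window) {
    return(tibble(kind = report$kind, axis_kind = report$axis_kind,
                  open_at = NA_real_, close_at = NA_real_,
                  measure = "none", value = NA_real_,
                  open_ended = FALSE, fragmented = report$fragmented,
                  no_window = TRUE))
  }
  value <- if (report$axis_kind == "concentration") {
    max(report$open_at, report$close_at) /
      min(report$open_at, report$close_at)
  } else {
    report$close_at - report$open_at
  }
  tibble(kind = report$kind, axis_kind = report$axis_kind,
         open_at = report$open_at, close_at = report$close_at,
         measure = if (report$axis_kind == "concentration") "fold_range"
                   else "duration",
         value = value,
         open_ended = report$open_ended_open || report$open_ended_close,
         fragmented = report$fragmented, no_window = FALSE)
}

# Build a window_report from a per-point signed gap (difference minus
# delta). Open points have gap > 0 strictly; boundaries are located by
# linear interpolation of the gap on the transformed axis. Disjoint open
# runs are merged to the maximal spanning window with fragmented = TRUE.
window_from_gap <- function(axis, gap, axis_kind, kind,
                            delta = 0, smoothed = FALSE) {
  keep <- !is.na(gap)
  axis <- axis[keep]
  gap <- gap[keep]
  open <- gap > 0
  flags <- tibble(axis = axis, open = open)
  if (!any(open)) {
    return(window_report(kind, axis_kind, flags = flags,
                         delta = delta, smoothed = smoothed))
  }
  tf <- axis_transform(axis_kind)
  inv <- axis_inverse(axis_kind)
  t <- tf(axis)
  first <- which(open)[1]
  last <- tail(which(open), 1)
  runs <- rle(open)
  fragmented <- sum(runs$values) > 1
  # boundary on the low-axis side of the spanning open region
  if (first == 1) {
    low <- axis[1]
    low_open_ended <- TRUE
  } else {
    i <- first - 1
    t_star <- t[i] + (0 - gap[i]) * (t[i + 1] - t[i]) / (gap[i + 1] - gap[i])
    low <- inv(t_star)
    low_open_ended <- FALSE
  }
  n <- length(axis)
  if (last == n) {
    high <- axis[n]
    high_open_ended <- TRUE
  } else {
    i <- last
    t_star <- t[i] + (0 - gap[i]) * (t[i + 1] - t[i]) / (gap[i + 1] - gap[i])
    high <- inv(t_star)
    high_open_ended <- FALSE
  }
  # deployment order: concentration decays high -> low; time runs early -> late
  if (axis_kind == "concentration") {
    window_report(kind, axis_kind, open_at = high, close_at = low,
                  open_ended_open = high_open_ended,
                  open_ended_close = low_open_ended,
                  flags = flags, fragmented = fragmented,
                  delta = delta, smoothed = smoothed)
  } else {
    window_report(kind, axis_kind, open_at = low, close_at = high,
                  open_ended_open = low_open_ended,
                  open_ended_close = high_open_ended,
                  flags = flags, fragmented = fragmented,
                  delta = delta, smoothed = smoothed)
  }
}

# Pick the resistant / susceptible arm pair present on a curve.
strain_pair <- function(curve) {
  arms <- curve_arms(curve)
  if (all(c("R", "S") %in% arms)) {
    c(resistant = "R", susceptible = "S")
  } else if (all(c("RR", "SS") %in% arms)) {
    c(resistant = "RR", susceptible = "SS")
  } else {
    abort(paste0("need a resistant/susceptible arm pair (R and S, or RR ",
                 "and SS); curve has: ", paste(arms, collapse = ", ")))
  }
}

arm_series <- function(curve, arm) {
  df <- as_tibble(curve)
  df <- df[df$arm == arm, ]
  df$mortality[order(df$axis)]
}

#' Detect the window of selection on a mortality curve
#'
#' The window of selection is open wherever the susceptible arm's mortality
#' exceeds the resistant arm's by more than `delta` (default 0, strict
#' inequality). Detection runs by default on loess-smoothed series, since
#' raw bioassay replicates cross erratically; set `smooth = FALSE` for
#' raw-series detection. Boundaries are located by linear interpolation of
#' the mortality difference between adjacent grid points, on the log10 axis
#' for concentration curves; windows open at the first or last grid point
#' are marked open-ended.
#'
#' @param curve A [mortality_curve()] with strain arms `R`/`S` or genotype
#'   arms `RR`/`SS`.
#' @param delta Minimum mortality difference (proportion) for the window to
#'   count as open; default 0.
#' @param smooth Detect on loess-smoothed series (default `TRUE`).
#' @param span Loess span when `smooth = TRUE`.
#' @return A [window_report()] of kind `"selection"`.
#' @export
detect_selection_window <- function(curve, delta = 0, smooth = TRUE,
                                    span = 0.75) {
  stopifnot(inherits(curve, "mortality_curve"))
  if (delta < 0) abort("`delta` must be >= 0")
  pair <- strain_pair(curve)
  if (smooth) curve <- smooth_mortality(curve, span = span)
  gap <- arm_series(curve, pair["susceptible"]) -
    arm_series(curve, pair["resistant"]) - delta
  window_from_gap(curve_axis(curve), gap, curve_axis_kind(curve),
                  kind = "selection", delta = delta, smoothed = smooth)
}

#' Detect the window of dominance on a genotype mortality curve
#'
#' The window of dominance is the sub-region of the window of selection
#' where dominance is greater than zero: heterozygote mortality falls below
#' the SS mortality by more than `delta` while the SS-vs-RR selection
#' window is itself open. Its open region is by construction a subset of
#' the selection window's. Reciprocal heterozygote arms (`SR`, `RS`) are
#' averaged first.
#'
#' @inheritParams detect_selection_window
#' @param curve A [mortality_curve()] with genotype arms `SS`, `RR` and at
#'   least one of `SR`/`RS`.
#' @return A [window_report()] of kind `"dominance"`.
#' @export
detect_dominance_window <- function(curve, delta = 0, smooth = TRUE,
                                    span = 0.75) {
  stopifnot(inherits(curve, "mortality_curve"))
  if (delta < 0) abort("`delta` must be >= 0")
  if (smooth) curve <- smooth_mortality(curve, span = span)
  m <- genotype_mortalities(curve)
  # open where both the selection gap (SS vs RR) and the heterozygote gap
  # (SS vs SR) exceed delta; the min gap interpolates the binding boundary
  gap <- pmin(m$m_ss - m$m_rr, m$m_ss - m$m_sr) - delta
  window_from_gap(m$axis, gap, curve_axis_kind(curve),
                  kind = "dominance", delta = delta, smoothed = smooth)
}

# Wide per-point genotype mortalities with reciprocal heterozygotes
# averaged; errors naming any missing genotype arm.
genotype_mortalities <- function(curve) {
  arms <- curve_arms(curve)
  missing_arms <- setdiff(c("SS", "RR"), arms)
  if (!any(c("SR", "RS") %in% arms)) {
    missing_arms <- c(missing_arms, "SR (or RS)")
  }
  if (length(missing_arms) > 0) {
    abort(paste0("curve is missing genotype arm(s): ",
                 paste(missing_arms, collapse = ", ")))
  }
  axis <- curve_axis(curve)
  m_sr <- if ("SR" %in% arms) arm_series(curve, "SR") else NULL
  m_rs <- if ("RS" %in% arms) arm_series(curve, "RS") else NULL
  het <- if (is.null(m_sr)) {
    m_rs
  } else if (is.null(m_rs)) {
    m_sr
  } else {
    ifelse(is.na(m_rs), m_sr, ifelse(is.na(m_sr), m_rs, (m_sr + m_rs) / 2))
  }
  tibble(axis = axis,
         m_ss = arm_series(curve, "SS"),
         m_sr = het,
         m_rr = arm_series(curve, "RR"))
}
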