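#' Build a mortality curve
#'
#' A mortality curve holds per-arm mortality proportions along a strictly
#' monotone concentration or time axis, in long (tidy) form: one row per
#' (axis point, arm). Arms are strain labels (`"R"`, `"S"`) or genotype
#' labels (`"SS"`, `"SR"`, `"RS"`, `"RR"`). Every arm covers every axis
#' point; missing observations are stored as `NA` mortality (fill them with
#' [complete_curve()]). Rows are stored in canonical ascending-axis order;
#' deployment order (high-to-low concentration, early-to-late time) is a
#' presentation concern handled by the window reports and plots.
#'
#' @param data A data frame with columns `axis` (positive numeric), `arm`
#'   (character) and `mortality` (proportion in `[0, 1]` or `NA`), and
#'   optionally `dead`/`exposed` counts.
#' @param axis_kind `"concentration"` or `"time"`.
#' @param metadata Optional named list (species, insecticide, substrate,
#'   ...) carried as an attribute.
#' @return A `mortality_curve`: a tibble with attributes `axis_kind` and
#'   `metadata`.
#' @export
mortality_curve <- function(data, axis_kind = c("concentration", "time"),
                            metadata = list()) {
  axis_kind <- match.arg(axis_kind)
  data <- as_tibble(data)
  need <- setdiff(c("axis", "arm", "mortality"), names(data))
  if (length(need) > 0) {
    abort(paste0("curve data is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  if (any(is.na(data$axis)) || !is.numeric(data$axis)) {
    abort("`axis` must be numeric with no missing values")
  }
  if (axis_kind == "concentration" && any(data$axis <= 0)) {
    abort("concentration axis values must be strictly positive")
  }
  if (axis_kind == "time" && any(data$axis < 0)) {
    abort("time axis values must be non-negative")
  }
  check_proportion(data$mortality, "mortality", allow_na = TRUE)
  if (all(c("dead", "exposed") %in% names(data))) {
    ok <- is.na(data$dead) | is.na(data$exposed) |
      (data$dead >= 0 & data$exposed >= 1 & data$dead <= data$exposed)
    if (!all(ok)) {
      abort(paste0("count columns invalid (need 0 <= dead <= exposed) in ",
                   "row(s) ", paste(which(!ok), collapse = ", ")))
    }
  }
  # complete the (arm x axis) grid so all arms share the axis
  data <- tidyr::complete(data, .data$arm,
                          axis = sort(unique(data$axis)))
  if (anyDuplicated(data[c("arm", "axis")]) > 0) {
    abort("duplicate (arm, axis) rows; pool replicates before building a curve")
  }
  data <- dplyr::arrange(data, .data$arm, .data$axis)
  data <- data[, c("axis", "arm", "mortality",
                   intersect(c("dead", "exposed"), names(data)))]
  structure(data,
            axis_kind = axis_kind,
            metadata = metadata,
            class = c("mortality_curve", class(tibble())))
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("<mortality_curve: %s axis, %d points, arms: %s>\n",
              curve_axis_kind(x), length(curve_axis(x)),
              paste(curve_arms(x), collapse = ", ")))
  NextMethod()
}

#' Axis kind, axis grid, and arm labels of a curve
#'
#' @param curve A [mortality_curve()].
#' @return `curve_axis_kind()`: `"concentration"` or `"time"`;
#'   `curve_axis()`: the sorted unique axis values; `curve_arms()`: the arm
#'   labels.
#' @export
curve_axis_kind <- function(curve) attr(curve, "axis_kind")

#' @rdname curve_axis_kind
#' @export
curve_axis <- function(curve) sort(unique(curve$axis))

#' @rdname curve_axis_kind
#' @export
curve_arms <- function(curve) sort(unique(curve$arm))

# keep attributes through dplyr-style subsetting used internally
restore_curve <- function(data, template) {
  structure(as_tibble(data),
            axis_kind = attr(template, "axis_kind"),
            metadata = attr(template, "metadata"),
            class = class(template))
}

# Smoothing and interpolation happen on log10 concentration (bioassay
# concentrations span decades) and on linear time.
axis_transform <- function(axis_kind) {
  if (axis_kind == "concentration") log10 else identity
}

axis_inverse <- function(axis_kind) {
  if (axis_kind == "concentration") function(t) 10^t else identity
}

#' Smooth a mortality curve with a locally weighted regression
#'
#' Applies a loess smoother (locally weighted linear regression, tricube
#' weights) per arm, on the log10 axis for concentration curves and the
#' linear axis for time curves, evaluated back at the original axis points
#' and clipped to `[0, 1]`. Arms with fewer than 4 observed points are
#' passed through unchanged with a warning.
#'
#' @param curve A [mortality_curve()].
#' @param span Loess span, in `(0, 1]` (default 0.75).
#' @return A smoothed `mortality_curve` (attribute `smoothed = TRUE`).
#' @export
smooth_mortality <- function(curve, span = 0.75) {
  stopifnot(inherits(curve, "mortality_curve"))
  if (length(span) != 1 || is.na(span) || span <= 0 || span > 1) {
    abort("`span` must be a single value in (0, 1]")
  }
  tf <- axis_transform(curve_axis_kind(curve))
  out <- dplyr::group_modify(
    dplyr::group_by(as_tibble(curve), .data$arm),
    function(df, key) {
      obs <- !is.na(df$mortality)
      if (sum(obs) < 4) {
        warn(paste0("arm '", key$arm, "' has fewer than 4 observed points; ",
                    "returned unsmoothed"))
        return(df)
      }
      t <- tf(df$axis)
      fit <- loess(mortality ~ t, data = df[obs, , drop = FALSE],
                   span = span, degree = 1, surface = "direct",
                   control = loess.control(statistics = "none"))
      sm <- predict(fit, newdata = data.frame(t = t[obs]))
      df$mortality[obs] <- pmin(pmax(sm, 0), 1)
      df
    })
  out <- dplyr::ungroup(out)
  out <- restore_curve(out[, names(curve)], curve)
  attr(out, "smoothed") <- TRUE
  attr(out, "span") <- span
  out
}

#' Fill missing mortalities by extrapolation rules
#'
#' Bioassay series often lack observations where the outcome is not in
#' doubt (e.g. a resistant genotype at concentrations far below its
#' tolerance). `complete_curve()` imposes stated constants (0 or 1) on
#' missing points within per-arm axis regions, never overwriting observed
#' data: a rule region that overlaps observed points is an error.
#'
#' @param curve A [mortality_curve()] with `NA` mortalities to fill.
#' @param rules A data frame with columns `arm`, `value` (0 or 1) and
#'   region bounds `min`/`max` on the original axis (closed interval;
#'   either may be omitted / infinite).
#' @return The completed `mortality_curve`.
#' @examples
#' # assume RR mortality 0 at concentrations <= 0.01
#' # complete_curve(curve, tibble::tibble(arm = "RR", value = 0, max = 0.01))
#' @export
complete_curve <- function(curve, rules) {
  stopifnot(inherits(curve, "mortality_curve"))
  rules <- as_tibble(rules)
  if (!all(c("arm", "value") %in% names(rules))) {
    abort("`rules` needs columns `arm` and `value`")
  }
  if (!all(rules$value %in% c(0, 1))) {
    abort("extrapolation `value` must be 0 or 1")
  }
  if (is.null(rules[["min"]])) rules$min <- -Inf
  if (is.null(rules[["max"]])) rules$max <- Inf
  rules$min[is.na(rules$min)] <- -Inf
  rules$max[is.na(rules$max)] <- Inf
  data <- as_tibble(curve)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    in_region <- data$arm == r$arm & data$axis >= r$min & data$axis <= r$max
    if (!any(in_region)) next
    if (any(in_region & !is.na(data$mortality))) {
      abort(paste0("extrapolation region for arm '", r$arm,
                   "' overlaps observed data; rules may only fill gaps"))
    }
    data$mortality[in_region] <- r$value
  }
  restore_curve(data, curve)
}
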