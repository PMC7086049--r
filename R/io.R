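#' Read a bioassay table into a mortality curve
#'
#' Accepts the package's single delimited dialect: comma-separated UTF-8
#' with a mandatory header and columns `axis_kind` (`concentration` or
#' `time`, one kind per file), `axis_value`, `arm`, and either counts
#' (`exposed`, `dead`) or percentages (`mortality_pct` in `[0, 100]`).
#' Replicate rows for the same (axis point, arm) are pooled: counts are
#' summed, percentages averaged. Percentages are converted to proportions
#' internally. Row order in the file does not matter.
#'
#' @param path Path to a CSV file.
#' @return A [mortality_curve()].
#' @export
read_bioassay_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("axis_kind", "axis_value", "arm"), names(raw))
  if (length(need) > 0) {
    abort(paste0("bioassay table is missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  kinds <- unique(raw$axis_kind)
  if (length(kinds) != 1) {
    abort(paste0("mixed axis kinds in one file: ",
                 paste(kinds, collapse = ", ")))
  }
  if (!kinds %in% c("concentration", "time")) {
    abort(paste0("unknown axis_kind '", kinds,
                 "' (need concentration or time)"))
  }
  has_counts <- all(c("exposed", "dead") %in% names(raw))
  has_pct <- "mortality_pct" %in% names(raw)
  if (!has_counts && !has_pct) {
    abort("need either count columns (exposed, dead) or mortality_pct")
  }
  if (has_counts) {
    bad <- which(!is.na(raw$dead) & !is.na(raw$exposed) &
                   (raw$dead < 0 | raw$exposed < 1 |
                      raw$dead > raw$exposed))
    if (length(bad) > 0) {
      abort(paste0("invalid counts (need 0 <= dead <= exposed) in data ",
                   "row(s) ", paste(bad, collapse = ", "),
                   ", columns dead/exposed"))
    }
    pooled <- dplyr::summarise(
      dplyr::group_by(raw, .data$axis_value, .data$arm),
      dead = sum(.data$dead), exposed = sum(.data$exposed),
      .groups = "drop")
    pooled$mortality <- pooled$dead / pooled$exposed
  } else {
    bad <- which(!is.na(raw$mortality_pct) &
                   (raw$mortality_pct < 0 | raw$mortality_pct > 100))
    if (length(bad) > 0) {
      abort(paste0("mortality_pct outside [0, 100] in data row(s) ",
                   paste(bad, collapse = ", "), ", column mortality_pct"))
    }
    pooled <- dplyr::summarise(
      dplyr::group_by(raw, .data$axis_value, .data$arm),
      mortality = mean(.data$mortality_pct) / 100,
      .groups = "drop")
  }
  pooled <- dplyr::rename(pooled, axis = "axis_value")
  mortality_curve(pooled, axis_kind = kinds)
}

#' Write a mortality curve as a bioassay table
#'
#' Inverse of [read_bioassay_table()]: writes the percentage schema (and
#' pooled counts when the curve carries them) at full double precision, so
#' a write-then-read round trip reproduces the curve exactly.
#'
#' @param curve A [mortality_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bioassay_table <- function(curve, path) {
  stopifnot(inherits(curve, "mortality_curve"))
  df <- as_tibble(curve)
  out <- tibble(axis_kind = curve_axis_kind(curve),
                axis_value = df$axis, arm = df$arm,
                mortality_pct = df$mortality * 100)
  if (all(c("dead", "exposed") %in% names(df))) {
    out$dead <- df$dead
    out$exposed <- df$exposed
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run configuration with the study's default parameterization
#'
#' Bundles the tunable analysis parameters with their standard values: 30%
#' of the population exposed each generation, starting resistance
#' frequencies 1% and 0.01%, a 50% allele-frequency threshold, a
#' 500-generation cap, loess span 0.75 and a zero minimum mortality
#' difference for window detection. Every value can be overridden here or
#' per call.
#'
#' @param x Exposure proportion.
#' @param p0 Starting resistance allele frequencies.
#' @param threshold Resistance allele-frequency target.
#' @param max_generations Simulation cap.
#' @param span Loess span for curve smoothing.
#' @param delta Minimum mortality difference for window detection.
#' @param seed Integer seed for synthetic sampling (`NULL` if unused).
#' @return A validated `run_config` list.
#' @export
run_config <- function(x = 0.3, p0 = c(0.01, 1e-4), threshold = 0.5,
                       max_generations = 500, span = 0.75, delta = 0,
                       seed = NULL) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort("`x` must be a single value in [0, 1]")
  }
  if (length(p0) < 1 || any(is.na(p0) | p0 <= 0 | p0 >= 1)) {
    abort("`p0` values must lie in (0, 1)")
  }
  if (length(threshold) != 1 || threshold <= max(p0) || threshold >= 1) {
    abort("`threshold` must lie strictly between max(p0) and 1")
  }
  if (max_generations < 1) abort("`max_generations` must be >= 1")
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1]")
  if (delta < 0) abort("`delta` must be >= 0")
  structure(list(x = x, p0 = p0, threshold = threshold,
                 max_generations = as.integer(max_generations),
                 span = span, delta = delta, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' The file holds any subset of the [run_config()] fields; missing fields
#' take the defaults, unknown fields are an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

# full-precision, locale-stable number formatting for reports
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write an analysis result as a structured text report
#'
#' Serializes a [window_report()], `resistance_sim` or profile tibble as a
#' self-describing text file: a key/value header, a `---` separator and a
#' per-point CSV table. Censored simulation results are written as explicit
#' `">500"`-style markers, never bare numbers; empty windows are written as
#' an explicit no-window record. Output is byte-stable for fixed inputs and
#' round-trips through [read_report()].
#'
#' @param report A `window_report`, `resistance_sim`, `dominance_profile`,
#'   `selection_profile` or `resistance_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  UseMethod("write_report")
}

write_report_lines <- function(header, table, path) {
  con <- file(path, open = "wb") # wb: byte-stable newlines across platforms
  on.exit(close(con))
  writeLines(c("# selwin report",
               paste0(names(header), ": ", unlist(header)), "---"),
             con, sep = "\n")
  cols <- names(table)
  body <- do.call(paste, c(lapply(table, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' @export
write_report.window_report <- function(report, path) {
  header <- list(
    object = "window_report",
    kind = report$kind,
    axis_kind = report$axis_kind,
    no_window = tolower(report$no_window),
    open_at = fmt_num(report$open_at),
    close_at = fmt_num(report$close_at),
    open_ended_open = tolower(report$open_ended_open),
    open_ended_close = tolower(report$open_ended_close),
    fragmented = tolower(report$fragmented),
    delta = fmt_num(report$delta),
    smoothed = tolower(report$smoothed))
  write_report_lines(header, report$flags, path)
}

#' @export
write_report.resistance_sim <- function(report, path) {
  header <- list(
    object = "resistance_sim",
    generations = format_generations(report),
    censored = tolower(report$censored),
    threshold = fmt_num(report$threshold),
    max_generations = report$max_generations,
    p0 = fmt_num(report$p0),
    x = fmt_num(report$x),
    w_ss = fmt_num(report$w[["w_ss"]]),
    w_sr = fmt_num(report$w[["w_sr"]]),
    w_rr = fmt_num(report$w[["w_rr"]]))
  write_report_lines(header, report$trajectory, path)
}

#' @export
write_report.selwin_profile <- function(report, path) {
  subclass <- class(report)[1]
  header <- list(object = subclass,
                 axis_kind = attr(report, "axis_kind"))
  for (a in c("x", "threshold", "max_generations")) {
    if (!is.null(attr(report, a))) header[[a]] <- fmt_num(attr(report, a))
  }
  tab <- as_tibble(report)
  if ("generations" %in% names(tab)) {
    # censored runs carry the ">cap" label; drop the redundant NA number
    tab$generations <- tab$label
    tab$label <- NULL
  }
  write_report_lines(header, tab, path)
}

#' Re-read a structured text report
#'
#' Parses a file written by [write_report()] back into the corresponding
#' object.
#'
#' @param path Report file path.
#' @return A `window_report`, `resistance_sim` or profile tibble.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "---")[1]
  if (is.na(sep)) abort("not a selwin report: missing '---' separator")
  header_lines <- grep("^#", lines[seq_len(sep - 1)], invert = TRUE,
                       value = TRUE)
  kv <- strsplit(header_lines, ": ", fixed = TRUE)
  header <- setNames(lapply(kv, function(p) paste(p[-1], collapse = ": ")),
                     vapply(kv, `[[`, "", 1))
  tab <- readr::read_csv(I(paste(lines[(sep + 1):length(lines)],
                                 collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  attr(tab, "spec") <- NULL
  attr(tab, "problems") <- NULL
  as_bool <- function(s) identical(s, "true")
  as_num <- function(s) if (identical(s, "NA")) NA_real_ else as.numeric(s)
  switch(header$object,
    window_report = window_report(
      kind = header$kind, axis_kind = header$axis_kind,
      open_at = as_num(header$open_at), close_at = as_num(header$close_at),
      open_ended_open = as_bool(header$open_ended_open),
      open_ended_close = as_bool(header$open_ended_close),
      flags = tab, fragmented = as_bool(header$fragmented),
      delta = as_num(header$delta), smoothed = as_bool(header$smoothed)),
    resistance_sim = {
      censored <- as_bool(header$censored)
      structure(
        list(
          generations = if (censored) NA_integer_
                        else as.integer(header$generations),
          censored = censored,
          trajectory = tab,
          threshold = as_num(header$threshold),
          max_generations = as.integer(header$max_generations),
          p0 = as_num(header$p0),
          x = as_num(header$x),
          w = c(w_ss = as_num(header$w_ss), w_sr = as_num(header$w_sr),
                w_rr = as_num(header$w_rr))),
        class = "resistance_sim")
    },
    dominance_profile = ,
    selection_profile = ,
    resistance_profile = {
      if ("generations" %in% names(tab)) {
        lab <- as.character(tab$generations)
        tab$label <- lab
        tab$generations <- suppressWarnings(as.integer(lab))
        tab <- tab[c("axis", "p0", "generations", "censored", "label")]
      }
      out <- structure(tab,
                       axis_kind = header$axis_kind,
                       class = c(header$object, "selwin_profile",
                                 class(tibble())))
      for (a in c("x", "threshold", "max_generations")) {
        if (!is.null(header[[a]])) attr(out, a) <- as_num(header[[a]])
      }
      out
    },
    abort(paste0("unknown report object type: ", header$object)))
}
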