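#' Validate and canonicalize a table of cumulative release curves
#'
#' A release-curve table is a long tibble with one row per observation and
#' columns `sample_id` (character label), `pH` (numeric), `time_h` (hours,
#' non-negative) and `released_pct` (cumulative release as % of encapsulated
#' drug, \eqn{M_t/M_\infty \times 100}). Each `(sample_id, pH)` pair keys one
#' curve. Optional metadata columns `temperature_C` (default 37) and `medium`
#' are carried through untouched.
#'
#' Raw experimental curves need not be monotone, but released values above
#' 110% or below 0, non-increasing time within a curve, or duplicate
#' `(sample_id, pH, time_h)` rows are rejected. Values between 100 and 110%
#' (small experimental overshoot) and a positive release at `t = 0` (burst
#' release) are kept but flagged with a warning.
#'
#' @param x A data frame with at least the four curve columns.
#' @return A tibble sorted by `(sample_id, pH, time_h)` with class
#'   `release_curves` prepended.
#' @examples
#' as_release_curves(data.frame(
#'   sample_id = "A", pH = 7.4, time_h = c(0, 1, 2), released_pct = c(0, 5, 9)
#' ))
#' @export
as_release_curves <- function(x) {
  needed <- c("sample_id", "pH", "time_h", "released_pct")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("release table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mfrelease_parse_error")
  }
  out <- as_tibble(x)
  out$sample_id <- as.character(out$sample_id)
  for (col in c("pH", "time_h", "released_pct")) {
    if (!is.numeric(out[[col]])) {
      abort(paste0("column '", col, "' must be numeric"),
            class = "mfrelease_parse_error")
    }
  }
  if (!"temperature_C" %in% names(out)) out$temperature_C <- 37
  if (anyNA(out[needed])) {
    abort("release table contains missing values in key columns",
          class = "mfrelease_parse_error")
  }
  if (any(out$time_h < 0)) {
    abort("time_h must be >= 0", class = "mfrelease_parse_error")
  }
  if (any(out$released_pct < 0 | out$released_pct > 110)) {
    abort("released_pct must lie in [0, 110]", class = "mfrelease_parse_error")
  }
  if (any(out$released_pct > 100)) {
    warn("released_pct above 100% (experimental overshoot); kept as-is")
  }
  out <- dplyr::arrange(out, .data$sample_id, .data$pH, .data$time_h)
  dup <- dplyr::summarise(
    dplyr::group_by(out, .data$sample_id, .data$pH),
    any_dup = anyDuplicated(.data$time_h) > 0, .groups = "drop"
  )
  if (any(dup$any_dup)) {
    bad <- dup[dup$any_dup, ]
    abort(paste0("duplicate time points within curve(s): ",
                 paste0(bad$sample_id, "/pH", bad$pH, collapse = ", ")),
          class = "mfrelease_parse_error")
  }
  if (any(out$time_h == 0 & out$released_pct > 0)) {
    warn("positive release at t = 0 (burst release); kept as-is")
  }
  class(out) <- unique(c("release_curves", class(out)))
  out
}

#' Read a delimited release table
#'
#' Reads a comma-delimited UTF-8 text file with mandatory header columns
#' `time_h`, `released_pct`, `sample_id`, `pH` (any order; extra columns
#' kept). Non-numeric cells and duplicate times within a curve raise a parse
#' error naming the offending line.
#'
#' @param path Path to a CSV file.
#' @return A [as_release_curves()] tibble, one curve per `(sample_id, pH)`.
#' @seealso [write_release_table()]
#' @export
read_release_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mfrelease_parse_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("time_h", "released_pct", "sample_id", "pH")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("release table '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mfrelease_parse_error")
  }
  for (col in c("time_h", "released_pct", "pH")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      # +1 for the header line
      abort(paste0("non-numeric value '", raw[[col]][bad[1]], "' in column '",
                   col, "' at line ", bad[1] + 1, " of ", path),
            class = "mfrelease_parse_error")
    }
    raw[[col]] <- vals
  }
  dup <- duplicated(raw[c("sample_id", "pH", "time_h")])
  if (any(dup)) {
    abort(paste0("duplicate time point within a curve at line ",
                 which(dup)[1] + 1, " of ", path),
          class = "mfrelease_parse_error")
  }
  if ("temperature_C" %in% names(raw)) {
    raw$temperature_C <- suppressWarnings(as.numeric(raw$temperature_C))
  }
  as_release_curves(raw)
}

#' Write release curves to a delimited text file
#'
#' Inverse of [read_release_table()]: numbers are written with 12 significant
#' digits so that a read/write round trip reproduces the curves exactly at
#' that precision, and repeated writes of the same object are byte-identical.
#'
#' @param curves A release-curve table (coerced via [as_release_curves()]
#'   unless empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_table <- function(curves, path) {
  cols <- c("sample_id", "pH", "time_h", "released_pct")
  if (is.null(curves) || nrow(curves) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  curves <- as_release_curves(curves)
  keep <- intersect(c(cols, "temperature_C", "medium"), names(curves))
  df <- as.data.frame(curves)[keep]
  for (col in keep) {
    if (is.numeric(df[[col]])) df[[col]] <- formatC(df[[col]], digits = 12, format = "g")
  }
  lines <- c(paste(keep, collapse = ","),
             do.call(paste, c(unname(df), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Split a release table into single curves
#'
#' @param curves A release-curve table.
#' @return A named list of single-curve tibbles, names `"<sample_id>/pH<pH>"`.
#' @export
split_curves <- function(curves) {
  curves <- as_release_curves(curves)
  key <- paste0(curves$sample_id, "/pH", curves$pH)
  lapply(split(seq_len(nrow(curves)), key), function(i) curves[i, ])
}

#' Plot release curves
#'
#' One panel per pH, one colour per sample: cumulative release (%) against
#' time (h).
#'
#' @param curves A release-curve table.
#' @return A ggplot object.
#' @export
plot_release_curves <- function(curves) {
  curves <- as_release_curves(curves)
  ggplot2::ggplot(curves, ggplot2::aes(.data$time_h, .data$released_pct,
                                       colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pH), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (h)", y = "cumulative release (%)",
                  colour = "sample") +
    ggplot2::theme_minimal()
}
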