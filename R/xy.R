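#' Two-column ordered series
#'
#' Shared carrier for force curves (piezo-Z nm vs deflection nm), absorption
#' spectra (wavelength nm vs optical density) and amperometric traces
#' (time s vs current pA). A tibble with strictly increasing `x`.
#'
#' @param x,y Equal-length numeric vectors; all values finite.
#' @param units Length-2 character vector of unit labels, `c(x, y)`.
#' @return A tibble of class `xy_series` with columns `x` and `y`.
#' @export
xy_series <- function(x, y, units = c("x", "y")) {
  if (length(x) != length(y)) abort_format("`x` and `y` must have equal length")
  stop_if_not_finite(x, "x")
  stop_if_not_finite(y, "y")
  if (is.unsorted(x, strictly = FALSE)) {
    o <- order(x)
    x <- x[o]
    y <- y[o]
  }
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  out <- tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "units") <- as.character(units)
  class(out) <- c("xy_series", class(out))
  out
}

#' Read a two-column delimited table as an ordered series
#'
#' Accepts comma-, tab-, semicolon- or whitespace-delimited files with an
#' optional single header line. Rows are sorted by `x`; duplicate `x` values
#' are collapsed by averaging `y`.
#'
#' @param path File path.
#' @param units Unit labels forwarded to [xy_series()].
#' @return An [xy_series()].
#' @export
read_xy <- function(path, units = c("x", "y")) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_data("empty file")
  split_row <- function(s) {
    s <- trimws(s)
    if (grepl(",", s)) strsplit(s, ",")[[1]]
    else if (grepl(";", s)) strsplit(s, ";")[[1]]
    else strsplit(s, "[[:space:]]+")[[1]]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  if (anyNA(first)) lines <- lines[-1]  # header line
  if (length(lines) < 3) abort_data("need at least 3 data rows")
  rows <- lapply(lines, function(l) suppressWarnings(as.numeric(split_row(l))))
  ncols <- lengths(rows)
  if (any(ncols < 2)) abort_format("need at least two columns per row")
  m <- t(vapply(rows, function(r) r[1:2], numeric(2)))
  if (anyNA(m) || !all(is.finite(m))) {
    abort_format("non-numeric or non-finite values in data rows")
  }
  xy_series(m[, 1], m[, 2], units = units)
}

#' Write an ordered series as a two-column CSV
#'
#' @param xy An [xy_series()] (or any data frame with columns `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(xy, path) {
  u <- attr(xy, "units") %||% c("x", "y")
  df <- tibble(x = xy$x, y = xy$y)
  names(df) <- make.names(u)
  readr::write_csv(df, path)
  invisible(path)
}
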