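#' Height-map container
#'
#' An AFM height map: a rectangular numeric matrix of surface heights in
#' nanometres with an isotropic pixel size. Row 1 is the top of the image;
#' heights are measured relative to the substrate plane (0 nm).
#'
#' @param heights Numeric matrix of heights (nm).
#' @param pixel_size Lateral size of one pixel in nm (isotropic, > 0).
#' @param name Identifier carried through result tables.
#' @return A `heightmap` object (a classed numeric matrix with `pixel_size`
#'   and `name` attributes).
#' @examples
#' hm <- heightmap(matrix(0, 16, 16), pixel_size = 10)
#' dim(hm)
#' @export
heightmap <- function(heights, pixel_size, name = "map") {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    abort_format("`heights` must be a numeric matrix")
  }
  if (nrow(heights) < 1 || ncol(heights) < 1) {
    abort_format("height map must have at least one pixel")
  }
  stop_if_not_finite(heights, "height map")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    abort_param("`pixel_size` must be a single positive number (nm per pixel)")
  }
  structure(heights,
            pixel_size = as.numeric(pixel_size),
            name = as.character(name),
            class = c("heightmap", "matrix", "array"))
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap '%s'> %d x %d px, %.4g nm/px (%.3g x %.3g um)\n",
              attr(x, "name"), nrow(x), ncol(x), attr(x, "pixel_size"),
              nrow(x) * attr(x, "pixel_size") / 1e3,
              ncol(x) * attr(x, "pixel_size") / 1e3))
  cat(sprintf("  height range [%.3g, %.3g] nm\n", min(x), max(x)))
  invisible(x)
}

pixel_size <- function(map) attr(map, "pixel_size")
map_name <- function(map) attr(map, "name") %||% "map"

# strip attributes down to a plain matrix
as_plain_matrix <- function(map) {
  m <- unclass(map)
  attr(m, "pixel_size") <- NULL
  attr(m, "name") <- NULL
  m
}

#' Read a height map from a text matrix plus sidecar metadata
#'
#' The on-disk format is a whitespace-delimited numeric matrix (one image row
#' per line, row 1 = top of image, heights in nm) with a JSON sidecar
#' `<path>.json` holding at least `pixel_size` (nm per pixel) and optionally
#' `name`.
#'
#' @param path Path to the matrix file. The sidecar is `<path>.json`.
#' @return A [heightmap()].
#' @export
read_heightmap <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort_format(sprintf("missing sidecar metadata file: %s", sidecar))
  }
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e) abort_format(
                     sprintf("garbled sidecar %s: %s", sidecar, conditionMessage(e))))
  if (is.null(meta$pixel_size)) abort_format("sidecar lacks `pixel_size`")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("empty height-map file")
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(tok) {
    suppressWarnings(as.numeric(tok))
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    abort_format("ragged rows: height-map file is not a rectangular matrix")
  }
  m <- do.call(rbind, rows)
  if (anyNA(m) || !all(is.finite(m))) {
    abort_format("height-map file contains non-numeric or non-finite cells")
  }
  heightmap(m, pixel_size = meta$pixel_size, name = meta$name %||% basename(path))
}

#' Write a height map to a text matrix plus sidecar metadata
#'
#' Values are written with full double precision so that
#' `read_heightmap(write_heightmap(...))` round-trips bit-identically.
#'
#' @param map A [heightmap()].
#' @param path Output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(map, path) {
  if (!inherits(map, "heightmap")) abort_param("`map` must be a heightmap")
  m <- as_plain_matrix(map)
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  tryCatch(writeLines(txt, path),
           error = function(e) abort(sprintf("cannot write %s: %s", path,
                                             conditionMessage(e)),
                                     class = "rbcnano_io_error"))
  jsonlite::write_json(
    list(pixel_size = pixel_size(map), name = map_name(map),
         rows = nrow(m), cols = ncol(m), units = "nm"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
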