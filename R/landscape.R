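#' Binary landscape
#'
#' Container for a rectangular grid of foreground/background cells, the unit
#' consumed by every spatial stage (MSPA segmentation, patch metrics,
#' transition estimation). Grids follow the shared coordinate convention:
#' cells are addressed `(row, col)`, row 1 is the top (north) row.
#'
#' @param grid Logical matrix (`TRUE` = foreground) or a 0/1 integer matrix.
#' @param cell_size Cell side length in meters (default 30 m, i.e. 0.09 ha
#'   per cell).
#' @return An object of class `binary_landscape` with elements `grid`
#'   (logical matrix), `n_rows`, `n_cols`, `cell_size` (m) and `cell_area`
#'   (hectares per cell).
#' @export
binary_landscape <- function(grid, cell_size = 30) {
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1))) {
      stop("numeric 'grid' must contain only 0 (background) and 1 (foreground)")
    }
    grid <- grid == 1
  }
  stopifnot(is.matrix(grid), is.logical(grid))
  if (anyNA(grid)) stop("'grid' must not contain NA; resolve nodata first")
  if (nrow(grid) < 1L || ncol(grid) < 1L) stop("'grid' must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("'cell_size' must be a positive scalar (meters)")
  }
  structure(
    list(
      grid      = grid,
      n_rows    = nrow(grid),
      n_cols    = ncol(grid),
      cell_size = cell_size,
      cell_area = cell_size^2 / 1e4  # m^2 -> ha
    ),
    class = "binary_landscape"
  )
}

#' @export
print.binary_landscape <- function(x, ...) {
  f <- mean(x$grid)
  cat(sprintf(
    "<binary_landscape> %d x %d cells, cell size %g m (%.4g ha/cell)\n",
    x$n_rows, x$n_cols, x$cell_size, x$cell_area
  ))
  cat(sprintf("  foreground: %d cells (F = %.4f)\n", sum(x$grid), f))
  invisible(x)
}

#' Foreground proportion of a binary landscape
#' @param landscape A [binary_landscape()].
#' @return Fraction of cells that are foreground, in `[0, 1]`.
#' @export
foreground_proportion <- function(landscape) {
  stopifnot(inherits(landscape, "binary_landscape"))
  mean(landscape$grid)
}

# ---------------------------------------------------------------------------
# class code scheme

#' MSPA class labels
#'
#' The fixed label set used throughout: background plus the seven
#' mutually exclusive foreground classes.
#' @return Character vector of the 8 labels in canonical order.
#' @export
mspa_classes <- function() {
  c("background", "core", "islet", "bridge", "loop",
    "perforation", "edge", "branch")
}

#' Class code scheme
#'
#' Bijection between the 8 MSPA labels and distinct integer codes used when
#' a class map is written to (or read from) a raster file. The default
#' assigns 0..7 in the order of [mspa_classes()]; background is always 0.
#'
#' @param codes Named integer vector mapping every label in
#'   [mspa_classes()] to a distinct code; background must map to 0.
#' @return Named integer vector of class `class_code_scheme`.
#' @export
class_code_scheme <- function(codes = NULL) {
  labels <- mspa_classes()
  if (is.null(codes)) {
    codes <- stats::setNames(0:7, labels)
  }
  if (!setequal(names(codes), labels)) {
    stop("'codes' must name exactly the 8 labels of mspa_classes()")
  }
  codes <- codes[labels]
  if (anyDuplicated(codes)) stop("class codes must be distinct")
  if (codes[["background"]] != 0L) stop("background code must be 0")
  structure(as.integer(codes), names = labels, class = "class_code_scheme")
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid

#' Read a single-band categorical raster
#'
#' Reads an ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header, optional `NODATA_value`) or a single-band TIFF of integer codes.
#' Row 1 of the returned matrix is the top row of the map.
#'
#' TIFF files carry no cell-size metadata that this reader interprets, so
#' `cell_size` must be supplied for them; for ASCII grids a supplied
#' `cell_size` overrides the header value with a warning when they differ.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ascii"` or `"tiff"`.
#' @param cell_size Optional cell size override in meters.
#' @return List with `grid` (integer matrix of class codes), `cell_size`,
#'   `nodata_value` (or `NA`) and `nodata_count`.
#' @export
read_landcover <- function(path, format = c("auto", "ascii", "tiff"),
                           cell_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii"
  }
  if (format == "tiff") {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) stop("unsupported input: multi-band raster")
    if (is.null(cell_size)) {
      stop("cell size metadata unavailable for TIFF input; supply 'cell_size'")
    }
    grid <- matrix(as.integer(img), nrow(img), ncol(img))
    return(list(grid = grid, cell_size = cell_size,
                nodata_value = NA_integer_, nodata_count = 0L))
  }
  read_asc(path, cell_size = cell_size)
}

# Parse an ESRI ASCII grid. Header keys are case-insensitive; data rows are
# stored top row first, matching the (row, col) convention.
read_asc <- function(path, cell_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) stop("format error: ASCII grid header lacks ", k)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(i + 1L):length(lines)]), "\\s+")
  )))
  if (anyNA(vals) || length(vals) != nr * nc) {
    stop("format error: expected ", nr * nc, " numeric cells, got ",
         length(vals))
  }
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) NA_integer_ else
    as.integer(hdr$nodata_value)
  n_nodata <- if (is.na(nodata)) 0L else sum(grid == nodata)
  cs <- hdr$cellsize
  if (!is.null(cell_size)) {
    if (abs(cell_size - cs) > 1e-9) {
      warning(sprintf(
        "cell size override %g differs from header value %g; using override",
        cell_size, cs
      ))
    }
    cs <- cell_size
  }
  list(grid = grid, cell_size = cs, nodata_value = nodata,
       nodata_count = n_nodata)
}

# Write an integer matrix as an ESRI ASCII grid.
write_asc <- function(grid, path, cell_size, nodata_value = NULL) {
  stopifnot(is.matrix(grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(cell_size, scientific = FALSE))
  ), con)
  if (!is.null(nodata_value)) {
    writeLines(paste("NODATA_value", nodata_value), con)
  }
  utils::write.table(grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# binarize

#' Binarize a categorical land-cover grid
#'
#' Marks cells whose code belongs to `foreground_codes` (e.g. the farmland
#' class) as foreground and everything else as background. Nodata cells are
#' either treated as background (default, the conservative choice for
#' fragmentation statistics: unknown cells never add habitat) or rejected.
#'
#' @param lc Either the list returned by [read_landcover()] or an integer
#'   matrix of class codes.
#' @param foreground_codes Non-empty integer vector of foreground codes.
#' @param nodata_policy `"background"` or `"error"`.
#' @param cell_size Cell size in meters; required when `lc` is a bare
#'   matrix, otherwise taken from `lc`.
#' @param nodata_value Nodata code when `lc` is a bare matrix.
#' @return A [binary_landscape()].
#' @export
binarize <- function(lc, foreground_codes,
                     nodata_policy = c("background", "error"),
                     cell_size = NULL, nodata_value = NA_integer_) {
  nodata_policy <- match.arg(nodata_policy)
  if (length(foreground_codes) < 1L) stop("'foreground_codes' must be non-empty")
  if (is.matrix(lc)) {
    lc <- list(grid = lc,
               cell_size = if (is.null(cell_size)) 30 else cell_size,
               nodata_value = nodata_value,
               nodata_count = if (is.na(nodata_value)) 0L else
                 sum(lc == nodata_value))
  }
  grid <- lc$grid
  nd <- lc$nodata_value
  if (!is.na(nd) && lc$nodata_count > 0L) {
    if (nodata_policy == "error") {
      stop("input contains ", lc$nodata_count, " nodata cells")
    }
    message(lc$nodata_count, " nodata cells treated as background")
    if (nd %in% foreground_codes) {
      stop("nodata code ", nd, " overlaps 'foreground_codes'")
    }
  }
  fg <- matrix(grid %in% foreground_codes, nrow(grid), ncol(grid))
  binary_landscape(fg, cell_size = if (is.null(cell_size)) lc$cell_size
                   else cell_size)
}

# ---------------------------------------------------------------------------
# class map IO

#' Write an MSPA class map to a raster file
#'
#' Encodes the label grid with a [class_code_scheme()] and writes it as an
#' ESRI ASCII grid or single-band TIFF. A round-trip through
#' [read_class_map()] reproduces the label grid exactly.
#'
#' @param map An `mspa_map` from [mspa_segment()].
#' @param path Output path.
#' @param scheme A [class_code_scheme()].
#' @param format `"auto"`, `"ascii"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path, scheme = class_code_scheme(),
                            format = c("auto", "ascii", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "mspa_map"))
  scheme <- class_code_scheme(stats::setNames(as.integer(scheme), names(scheme)))
  present <- unique(as.vector(map$labels))
  missing <- setdiff(mspa_classes()[present], names(scheme))
  if (length(missing)) stop("scheme lacks labels: ", paste(missing, collapse = ", "))
  codes <- matrix(scheme[map$labels], nrow(map$labels), ncol(map$labels))
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii"
  }
  if (format == "tiff") {
    # 8-bit integer payload; codes must fit a byte
    if (max(codes) > 255L) stop("TIFF output requires codes <= 255")
    tiff::writeTIFF(codes / 255, path, bits.per.sample = 8L)
  } else {
    write_asc(codes, path, cell_size = map$cell_size)
  }
  invisible(path)
}

#' Read an MSPA class map written by [write_class_map()]
#'
#' @inheritParams write_class_map
#' @param cell_size Cell size override (required for TIFF).
#' @return An `mspa_map` (without parameters, which are not stored in the
#'   raster; `params` is `NULL`).
#' @export
read_class_map <- function(path, scheme = class_code_scheme(),
                           format = c("auto", "ascii", "tiff"),
                           cell_size = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii"
  }
  if (format == "tiff") {
    img <- tiff::readTIFF(path)
    codes <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    cs <- if (is.null(cell_size)) 30 else cell_size
  } else {
    r <- read_asc(path, cell_size = cell_size)
    codes <- r$grid
    cs <- r$cell_size
  }
  lut <- match(codes, as.integer(scheme))
  if (anyNA(lut)) stop("file contains codes outside the supplied scheme")
  labels <- matrix(as.integer(lut), nrow(codes), ncol(codes))
  new_mspa_map(labels, params = NULL, cell_size = cs)
}

# Report rounding: round half away from the larger magnitude (toward zero),
# ordinary rounding otherwise; applied only at the reporting boundary.
round_report <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 - 1e-8) / s
}
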