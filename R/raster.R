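#' Gridded raster container
#'
#' A minimal single-band raster: a numeric matrix (row 1 = top of the map),
#' a cell size in metres, and the map coordinates of the upper-left corner.
#' Invalid (nodata) cells are stored as `NA` and are excluded from every
#' statistic computed by the package. The centre of pixel `(r, c)` (1-based)
#' sits at `x = origin[1] + (c - 0.5) * cell_size`,
#' `y = origin[2] - (r - 0.5) * cell_size`.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, map coordinates `(x, y)` of the
#'   upper-left corner of the grid.
#' @return An object of class `mt_raster`.
#' @export
mt_raster <- function(values, cell_size = 30, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be a length-2 numeric vector", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "mt_raster"
  )
}

#' @export
print.mt_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<mt_raster> %d x %d cells, %.6g m/cell, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  valid: %d / %d; range: [%.6g, %.6g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.mt_raster <- function(x) dim(x$values)

#' Test for the raster class
#' @param x Object.
#' @return Logical scalar.
#' @export
is_mt_raster <- function(x) inherits(x, "mt_raster")

stopifnot_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_mt_raster(x))
    stop(sprintf("`%s` must be an mt_raster", arg), call. = FALSE)
  invisible(x)
}

#' Read a raster from disk
#'
#' Supports two plain-text formats: ESRI ASCII grid (`.asc`, the standard
#' headered text grid with `ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header lines) and a headered CSV grid dialect
#' whose first line is a comment of the form
#' `# cellsize=<m> xll=<x> yll=<y> nodata=<v>` followed by comma-separated
#' rows, top row first. Nodata values are mapped to `NA`; all other values
#' are read untouched.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"asc"` or `"csv"`.
#' @param nodata Optional value to treat as nodata in addition to the one
#'   declared in the header.
#' @return An [mt_raster].
#' @export
read_raster <- function(path, format = c("auto", "asc", "csv"), nodata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("asc", "agr", "grd")) "asc" else "csv"
  }
  out <- switch(format, asc = read_asc(path), csv = read_csvgrid(path))
  if (!is.null(nodata)) out$values[out$values %in% nodata] <- NA_real_
  out
}

read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("file %s lacks a complete ASCII-grid header (ncols/nrows/cellsize)",
                 path), call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("file %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  mt_raster(m, cell_size = hdr$cellsize,
            origin = c(xll, yll + nr * hdr$cellsize))
}

read_csvgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#", lines[1]))
    stop(sprintf("file %s is not a headered CSV grid (missing '#' header line)",
                 path), call. = FALSE)
  kv <- regmatches(lines[1], gregexpr("[a-z]+=[-0-9.eE+]+|[a-z]+=NA", lines[1]))[[1]]
  hdr <- list()
  for (p in kv) {
    parts <- strsplit(p, "=")[[1]]
    hdr[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
  }
  if (is.null(hdr$cellsize))
    stop(sprintf("file %s: CSV grid header lacks cellsize", path), call. = FALSE)
  rows <- lapply(lines[-1][nzchar(lines[-1])], function(l)
    suppressWarnings(as.numeric(strsplit(l, ",")[[1]])))
  nc <- length(rows[[1]])
  if (any(vapply(rows, length, 1L) != nc))
    stop(sprintf("file %s: ragged CSV grid", path), call. = FALSE)
  m <- do.call(rbind, rows)
  if (!is.null(hdr$nodata) && !is.na(hdr$nodata)) m[m == hdr$nodata] <- NA_real_
  nr <- nrow(m)
  xll <- if (is.null(hdr$xll)) 0 else hdr$xll
  yll <- if (is.null(hdr$yll)) 0 else hdr$yll
  mt_raster(m, cell_size = hdr$cellsize,
            origin = c(xll, yll + nr * hdr$cellsize))
}

#' Write a raster to disk
#'
#' Formats as in [read_raster()]. `NA` cells are written as the `nodata`
#' sentinel value.
#'
#' @param x An [mt_raster].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"asc"` or `"csv"`.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, format = c("auto", "asc", "csv"),
                         nodata = -9999) {
  stopifnot_raster(x)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("asc", "agr", "grd")) "asc" else "csv"
  }
  m <- x$values
  nr <- nrow(m); nc <- ncol(m)
  yll <- x$origin[2] - nr * x$cell_size
  m[is.na(m)] <- nodata
  if (format == "asc") {
    hdr <- c(
      sprintf("ncols %d", nc),
      sprintf("nrows %d", nr),
      sprintf("xllcorner %.10g", x$origin[1]),
      sprintf("yllcorner %.10g", yll),
      sprintf("cellsize %.10g", x$cell_size),
      sprintf("NODATA_value %.10g", nodata)
    )
    body <- apply(m, 1L, function(r) paste(format(r, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = " "))
    writeLines(c(hdr, body), path)
  } else {
    hdr <- sprintf("# cellsize=%.10g xll=%.10g yll=%.10g nodata=%.10g",
                   x$cell_size, x$origin[1], yll, nodata)
    body <- apply(m, 1L, function(r) paste(format(r, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = ","))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Resample a raster onto another raster's grid by nearest neighbour
#'
#' Every cell of the output (which has `template`'s shape, cell size and
#' origin) takes the value of the `source` cell whose centre is nearest to
#' the output cell's centre. Output cells whose centre falls outside the
#' source extent are nodata; source nodata propagates. Used to bring
#' elevation onto the tree-cover grid before feature derivation.
#'
#' @param source Raster to resample.
#' @param template Raster defining the output grid.
#' @return An [mt_raster] on `template`'s grid carrying `source`'s values.
#' @export
align_nearest <- function(source, template) {
  stopifnot_raster(source); stopifnot_raster(template)
  sv <- source$values
  snr <- nrow(sv); snc <- ncol(sv)
  tnr <- nrow(template$values); tnc <- ncol(template$values)
  # template cell centres in map coordinates
  cx <- template$origin[1] + (seq_len(tnc) - 0.5) * template$cell_size
  cy <- template$origin[2] - (seq_len(tnr) - 0.5) * template$cell_size
  # nearest source indices (centre of source cell c at xll + (c-0.5)*cs)
  col_idx <- round((cx - source$origin[1]) / source$cell_size + 0.5)
  row_idx <- round((source$origin[2] - cy) / source$cell_size + 0.5)
  ok_col <- col_idx >= 1L & col_idx <= snc
  ok_row <- row_idx >= 1L & row_idx <= snr
  if (!any(ok_col) || !any(ok_row))
    stop("source and template extents are disjoint; cannot align",
         call. = FALSE)
  out <- matrix(NA_real_, tnr, tnc)
  rr <- which(ok_row); cc <- which(ok_col)
  out[rr, cc] <- sv[row_idx[rr], col_idx[cc], drop = FALSE]
  mt_raster(out, cell_size = template$cell_size, origin = template$origin)
}

#' Apply a validity mask to a raster
#'
#' Cells that are nodata in `mask` become nodata in the result; the output
#' nodata set is the union of both rasters' nodata sets. Used for the
#' human-impact / water-body mask.
#'
#' @param target Raster to mask.
#' @param mask Raster of identical shape; its `NA` cells are removed from
#'   `target`.
#' @return Masked [mt_raster].
#' @export
apply_mask <- function(target, mask) {
  stopifnot_raster(target); stopifnot_raster(mask)
  if (!identical(dim(target$values), dim(mask$values)))
    stop("target and mask shapes differ", call. = FALSE)
  v <- target$values
  v[is.na(mask$values)] <- NA_real_
  mt_raster(v, cell_size = target$cell_size, origin = target$origin)
}
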