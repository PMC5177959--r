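#' Grid geometry for regular rasters
#'
#' Describes a north-up regular lattice: pixel (row 0 = northernmost,
#' col 0 = westernmost) indexing is 0-based in the coordinate arithmetic,
#' cell extents are half-open `[x, x + cell)`, and map units are metres
#' unless the CRS tag says otherwise.
#'
#' @param origin_x,origin_y Map coordinates of the outer corner of the
#'   top-left cell (west edge, north edge).
#' @param cell_size Cell size in map units; length 1 (square cells) or
#'   length 2 `c(x, y)`.
#' @param n_rows,n_cols Raster dimensions (rows count southwards).
#' @param crs_tag Opaque CRS identifier. The default `"local-metric"`
#'   declares metric map units; tags containing `"4326"`, `"deg"` or
#'   `"lonlat"` are treated as non-metric and refuse area computations.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin_x = 0, origin_y = 0, cell_size = 1,
                          n_rows, n_cols, crs_tag = "local-metric") {
  if (length(cell_size) == 1L) cell_size <- c(cell_size, cell_size)
  stopifnot(length(cell_size) == 2L, all(is.finite(cell_size)))
  if (any(cell_size <= 0)) stop("cell_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (!is.character(crs_tag) || length(crs_tag) != 1L || !nzchar(crs_tag))
    stop("crs_tag must be a non-empty string")
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = n_rows, n_cols = n_cols,
                 crs_tag = crs_tag),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells of %g x %g map units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size[1], x$cell_size[2],
              x$origin_x, x$origin_y, x$crs_tag))
  invisible(x)
}

geom_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    all(abs(a$cell_size - b$cell_size) < tol) && a$crs_tag == b$crs_tag
}

is_metric_crs <- function(crs_tag) {
  !grepl("4326|deg|lonlat", crs_tag, ignore.case = TRUE)
}

#' Cell area in square kilometres
#'
#' @param geometry A [grid_geometry()]. Errors when the CRS tag declares
#'   non-metric units (degrees have no fixed cell area).
#' @return Scalar cell area in km^2.
#' @export
cell_area_km2 <- function(geometry) {
  if (!is_metric_crs(geometry$crs_tag))
    stop("cell area undefined for non-metric CRS tag '", geometry$crs_tag, "'")
  geometry$cell_size[1] * geometry$cell_size[2] / 1e6
}

#' Multiband raster stack
#'
#' The package's in-memory raster container: an ordered set of 2-D real
#' planes sharing one [grid_geometry()], plus a nodata mask. `NA`/`NaN`
#' values present in any band are folded into the mask at construction so
#' masked cells are excluded from every downstream statistic.
#'
#' @param bands A matrix (single band) or list of matrices, each
#'   `n_rows x n_cols`.
#' @param geometry A [grid_geometry()].
#' @param band_labels Unique band names; defaults to `band1`, `band2`, ...
#' @param nodata Optional logical matrix, `TRUE` where the cell is masked.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands, geometry, band_labels = NULL, nodata = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  if (!length(bands)) stop("need at least one band")
  dm <- c(geometry$n_rows, geometry$n_cols)
  for (b in bands)
    if (!is.matrix(b) || !identical(dim(b), as.integer(dm)))
      stop("all bands must be ", dm[1], " x ", dm[2], " matrices matching the geometry")
  if (is.null(band_labels)) band_labels <- paste0("band", seq_along(bands))
  if (anyDuplicated(band_labels) || length(band_labels) != length(bands))
    stop("band_labels must be unique and match the number of bands")
  if (is.null(nodata)) nodata <- matrix(FALSE, dm[1], dm[2])
  if (!is.logical(nodata) || !identical(dim(nodata), as.integer(dm)))
    stop("nodata must be a logical matrix matching the geometry")
  for (b in bands) nodata <- nodata | !is.finite(b)
  names(bands) <- band_labels
  structure(list(geometry = geometry, bands = bands,
                 band_labels = band_labels, nodata = nodata),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  cat(sprintf("<band_stack> %d band(s) [%s], %d x %d, %d masked cell(s)\n",
              length(x$bands), paste(x$band_labels, collapse = ", "),
              x$geometry$n_rows, x$geometry$n_cols, sum(x$nodata)))
  invisible(x)
}

#' Number of bands in a stack
#' @param stack A [band_stack()].
#' @export
n_bands <- function(stack) length(stack$bands)

#' Extract one band as a matrix with masked cells set to NA
#'
#' @param stack A [band_stack()].
#' @param which Band index or label.
#' @return A numeric matrix; masked cells are `NA`.
#' @export
band_values <- function(stack, which = 1L) {
  m <- stack$bands[[which]]
  m[stack$nodata] <- NA_real_
  m
}

#' Categorical class map
#'
#' Integer plane over a [grid_geometry()] with the fixed legend
#' `desertified = 1`, `vegetation = 2`, `others = 3`, `nodata = 0`.
#'
#' @param labels Integer matrix of legend codes.
#' @param geometry A [grid_geometry()].
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, geometry) {
  stopifnot(is.matrix(labels))
  if (!identical(dim(labels), c(geometry$n_rows, geometry$n_cols)))
    stop("labels must match the geometry")
  labels[is.na(labels)] <- 0L
  storage.mode(labels) <- "integer"
  if (!all(labels %in% legend_codes()))
    stop("labels outside the legend {desertified=1, vegetation=2, others=3, nodata=0}")
  structure(list(geometry = geometry, labels = labels), class = "class_map")
}

#' Class legend codes
#'
#' @return Named integer vector mapping class names to raster codes.
#' @export
legend_codes <- function() {
  c(nodata = 0L, desertified = 1L, vegetation = 2L, others = 3L)
}

#' @export
print.class_map <- function(x, ...) {
  tb <- table(factor(x$labels, levels = legend_codes(),
                     labels = names(legend_codes())))
  cat(sprintf("<class_map> %d x %d: %s\n", x$geometry$n_rows, x$geometry$n_cols,
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

## ---- raster I/O: the package cube format -----------------------------------
## Single file: a 4-byte little-endian header length, a JSON header carrying
## geometry / CRS / band labels / optional nodata value and scale factor,
## then band-major float64 planes in column-major order. Nodata cells are
## stored as the declared nodata value (default NaN). Lossless for doubles.

#' Write a raster stack to the package cube format
#'
#' @param stack A [band_stack()].
#' @param path Output file path (conventionally `.aeo`).
#' @param nodata_value Value stored in masked cells (default `NaN`).
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(stack, path, nodata_value = NaN) {
  g <- stack$geometry
  hdr <- jsonlite::toJSON(list(
    format = "aeoscan-cube", version = 1L,
    origin_x = g$origin_x, origin_y = g$origin_y,
    cell_size = g$cell_size, n_rows = g$n_rows, n_cols = g$n_cols,
    crs_tag = g$crs_tag, band_labels = stack$band_labels,
    nodata_value = if (is.nan(nodata_value)) "NaN" else nodata_value
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  raw_hdr <- charToRaw(as.character(hdr))
  writeBin(length(raw_hdr), con, size = 4L, endian = "little")
  writeBin(raw_hdr, con)
  for (b in stack$bands) {
    b[stack$nodata] <- nodata_value
    writeBin(as.numeric(b), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a raster stack from the package cube format
#'
#' Nodata values are translated to the mask; band order and labels are
#' preserved. If the header declares a `scale_factor` (MOD09-style stored
#' integers times 1e-4), it is applied to the values at read time.
#'
#' @param path File written by [write_raster()] (or by any writer of the
#'   documented cube layout).
#' @return A [band_stack()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  n_hdr <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(n_hdr) || n_hdr <= 0L || n_hdr > 1e6L)
    stop("not an aeoscan cube file: ", path)
  hdr <- tryCatch(jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = n_hdr))),
                  error = function(e) stop("corrupt cube header in ", path))
  req <- c("origin_x", "origin_y", "cell_size", "n_rows", "n_cols", "crs_tag")
  if (!all(req %in% names(hdr)))
    stop("cube header lacks geometry/CRS fields (", paste(setdiff(req, names(hdr)), collapse = ", "),
         ") in ", path, "; refusing to guess defaults")
  g <- grid_geometry(hdr$origin_x, hdr$origin_y, hdr$cell_size,
                     hdr$n_rows, hdr$n_cols, hdr$crs_tag)
  labels <- hdr$band_labels
  n_px <- g$n_rows * g$n_cols
  bands <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    v <- readBin(con, "numeric", n = n_px, size = 8L, endian = "little")
    if (length(v) != n_px) stop("truncated cube file: ", path)
    bands[[i]] <- matrix(v, g$n_rows, g$n_cols)
  }
  ndv <- hdr$nodata_value
  mask <- Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  if (!is.null(ndv) && !identical(ndv, "NaN")) {
    ndv <- as.numeric(ndv)
    mask <- mask | Reduce(`|`, lapply(bands, function(b) b == ndv))
  }
  if (!is.null(hdr$scale_factor))
    bands <- lapply(bands, function(b) b * as.numeric(hdr$scale_factor))
  for (i in seq_along(bands)) bands[[i]][mask] <- NA_real_
  band_stack(bands, g, band_labels = labels, nodata = mask)
}

#' Export a reflectance stack as a multi-plane TIFF image
#'
#' Convenience export for viewers; values are clipped to `[0, 1]` (32-bit
#' float samples) and masked cells written as 0. The cube format
#' ([write_raster()]) remains the lossless interchange format.
#'
#' @param stack A [band_stack()] with values in `[0, 1]`.
#' @param path Output `.tif` path.
#' @export
export_raster_tiff <- function(stack, path) {
  planes <- lapply(stack$bands, function(b) {
    b[stack$nodata] <- 0
    pmin(pmax(b, 0), 1)
  })
  tiff::writeTIFF(unname(planes), path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

## block sums over f x f tiles of a matrix (dims divisible by f)
block_sum <- function(m, f) {
  R <- nrow(m); C <- ncol(m)
  s1 <- colSums(array(m, dim = c(f, R %/% f, C)))       # (R/f) x C
  t(colSums(array(t(s1), dim = c(f, C %/% f, R %/% f)))) # (R/f) x (C/f)
}

resample_factor <- function(src, target) {
  rx <- target$cell_size[1] / src$cell_size[1]
  ry <- target$cell_size[2] / src$cell_size[2]
  if (abs(rx - round(rx)) > 1e-9 || abs(ry - round(ry)) > 1e-9 || rx < 1 || ry < 1)
    stop("target cell size must be an integer multiple of the source cell size")
  if (abs(rx - ry) > 1e-9)
    stop("anisotropic resampling factors are not supported")
  if (abs(src$origin_x - target$origin_x) > 1e-9 ||
      abs(src$origin_y - target$origin_y) > 1e-9)
    stop("source and target origins must coincide")
  f <- as.integer(round(rx))
  if (src$n_rows != target$n_rows * f || src$n_cols != target$n_cols * f)
    stop("target extent must tile the source grid exactly")
  f
}

#' Aggregate a stack to a coarser aligned grid by block mean
#'
#' Each target cell is the mean of the covered, unmasked source cells; a
#' target cell is masked iff every covered source cell is masked. The grand
#' mean over a fully covered, fully unmasked extent is conserved.
#'
#' @param stack Source [band_stack()].
#' @param target Coarser [grid_geometry()] whose cell size is an integer
#'   multiple of the source's and whose origin coincides with it.
#' @return A [band_stack()] on `target`.
#' @export
resample_mean <- function(stack, target) {
  f <- resample_factor(stack$geometry, target)
  valid <- !stack$nodata
  cnt <- block_sum(valid + 0, f)
  bands <- lapply(stack$bands, function(b) {
    b[stack$nodata] <- 0
    s <- block_sum(b, f)
    out <- s / cnt
    out[cnt == 0] <- NA_real_
    out
  })
  band_stack(bands, target, band_labels = stack$band_labels,
             nodata = cnt == 0)
}

#' Aggregate a stack to a coarser aligned grid by nearest neighbour
#'
#' Takes the source cell containing each target cell centre; intended for
#' categorical planes where averaging is meaningless.
#'
#' @inheritParams resample_mean
#' @return A [band_stack()] on `target`.
#' @export
resample_nearest <- function(stack, target) {
  f <- resample_factor(stack$geometry, target)
  off <- (f - 1L) %/% 2L  # block-local index of the cell holding the centre
  ri <- seq.int(1L + off, by = f, length.out = target$n_rows)
  ci <- seq.int(1L + off, by = f, length.out = target$n_cols)
  bands <- lapply(stack$bands, function(b) b[ri, ci, drop = FALSE])
  band_stack(bands, target, band_labels = stack$band_labels,
             nodata = stack$nodata[ri, ci, drop = FALSE])
}

#' Coarse grid frame linking fine classification to coarse pixels
#'
#' Builds the coarse lattice that nests an integer number of fine pixels
#' per cell, with unique cell identifiers assigned row-major starting at 1.
#' Class proportions are empty until filled by [class_proportions()].
#'
#' @param fine Fine-resolution [grid_geometry()].
#' @param coarse_cell Coarse cell size in map units; must be an integer
#'   multiple of the fine cell size, and the fine extent must tile exactly.
#' @return An object of class `grid_frame` with fields `geometry` (coarse),
#'   `cell_ids` (integer matrix), `proportions` (`NULL` until populated),
#'   `fine_geometry` and `factor`.
#' @export
build_grid_frame <- function(fine, coarse_cell) {
  if (length(coarse_cell) == 1L) coarse_cell <- c(coarse_cell, coarse_cell)
  target <- grid_geometry(fine$origin_x, fine$origin_y, coarse_cell,
                          n_rows = max(1L, (fine$n_rows * fine$cell_size[2]) %/% coarse_cell[2]),
                          n_cols = max(1L, (fine$n_cols * fine$cell_size[1]) %/% coarse_cell[1]),
                          crs_tag = fine$crs_tag)
  f <- resample_factor(fine, target)
  ids <- matrix(seq_len(target$n_rows * target$n_cols),
                target$n_rows, target$n_cols, byrow = TRUE)
  structure(list(geometry = target, cell_ids = ids, proportions = NULL,
                 fine_geometry = fine, factor = f),
            class = "grid_frame")
}

#' @export
print.grid_frame <- function(x, ...) {
  cat(sprintf("<grid_frame> %d x %d cells (factor %d over fine grid), proportions %s\n",
              x$geometry$n_rows, x$geometry$n_cols, x$factor,
              if (is.null(x$proportions)) "empty" else "populated"))
  invisible(x)
}

#' Map every fine pixel to its coarse cell id
#'
#' @param frame A `grid_frame`.
#' @return Integer matrix at fine resolution; entry = covering cell id.
#' @export
fine_cell_ids <- function(frame) {
  f <- frame$factor
  frame$cell_ids[rep(seq_len(frame$geometry$n_rows), each = f),
                 rep(seq_len(frame$geometry$n_cols), each = f)]
}

#' @export
as.data.frame.grid_frame <- function(x, ...) {
  g <- x$geometry
  rows <- rep(seq_len(g$n_rows), times = g$n_cols)
  cols <- rep(seq_len(g$n_cols), each = g$n_rows)
  ids <- x$cell_ids[cbind(rows, cols)]
  out <- data.frame(cell_id = ids, row = rows - 1L, col = cols - 1L)
  if (!is.null(x$proportions)) {
    pm <- x$proportions[match(out$cell_id, as.integer(rownames(x$proportions))), ,
                        drop = FALSE]
    colnames(pm) <- paste0("prop_", colnames(pm))
    out <- cbind(out, as.data.frame(pm, row.names = FALSE))
  }
  out[order(out$cell_id), , drop = FALSE]
}
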