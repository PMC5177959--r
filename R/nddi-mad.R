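#' Normalized Difference Desertification Index
#'
#' `NDDI = (band1 - band2) / (band1 + band2)` with band1 the red
#' (620-670 nm) and band2 the near-infrared (841-876 nm) reflectance:
#' the negative of NDVI, so sparsely vegetated desertified surfaces score
#' high while vegetated surfaces dip strongly in the growing season.
#' Cells where the band sum is non-positive, or where either band is
#' masked, are returned as `NA`.
#'
#' @param band1 Red reflectance plane (matrix), values `> 0` where valid.
#' @param band2 NIR reflectance plane, same geometry.
#' @return Matrix of NDDI values in `[-1, 1]` (NA where undefined).
#' @export
compute_nddi <- function(band1, band2) {
  if (!identical(dim(band1), dim(band2)))
    stop("band geometries differ")
  s <- band1 + band2
  out <- (band1 - band2) / s
  out[!is.finite(s) | s <= 0] <- NA_real_
  out
}

#' NDDI from a two-or-more band reflectance stack
#'
#' @param stack A [band_stack()].
#' @param red,nir Band indices or labels (default the first two bands,
#'   mirroring MODIS band1/band2).
#' @return NDDI matrix as from [compute_nddi()].
#' @export
nddi_from_stack <- function(stack, red = 1L, nir = 2L) {
  compute_nddi(band_values(stack, red), band_values(stack, nir))
}

#' Per-pixel NDDI time series cube
#'
#' @param values Numeric array `n x rows x cols` (composite index first),
#'   or a list of `n` NDDI matrices.
#' @param geometry Coarse [grid_geometry()].
#' @param n_per_year Composites per year; 46 for 8-day annual composites.
#' @return An object of class `nddi_cube`.
#' @export
nddi_cube <- function(values, geometry, n_per_year = 46L) {
  if (is.list(values)) {
    n <- length(values)
    values <- vapply(values, identity,
                     matrix(0, geometry$n_rows, geometry$n_cols))
    values <- aperm(values, c(3L, 1L, 2L))  # -> time x rows x cols
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[2] != geometry$n_rows || dim(values)[3] != geometry$n_cols)
    stop("cube spatial dimensions must match the geometry")
  structure(list(geometry = geometry, values = values,
                 n = dim(values)[1], n_per_year = as.integer(n_per_year)),
            class = "nddi_cube")
}

#' Build an NDDI cube from a reflectance time series
#'
#' @param stacks List of [band_stack()]s, one per composite, sharing a
#'   geometry.
#' @param red,nir Band selectors passed to [nddi_from_stack()].
#' @param n_per_year Composites per year (46 for the 8-day calendar).
#' @return An [nddi_cube()].
#' @export
build_nddi_cube <- function(stacks, red = 1L, nir = 2L, n_per_year = 46L) {
  g <- stacks[[1]]$geometry
  for (s in stacks)
    if (!geom_equal(s$geometry, g)) stop("all composites must share one geometry")
  nddi_cube(lapply(stacks, nddi_from_stack, red = red, nir = nir),
            g, n_per_year = n_per_year)
}

#' @export
print.nddi_cube <- function(x, ...) {
  cat(sprintf("<nddi_cube> %d composites x %d x %d pixels (%d per year)\n",
              x$n, x$geometry$n_rows, x$geometry$n_cols, x$n_per_year))
  invisible(x)
}

#' Reference NDDI trajectory of a land-cover class
#'
#' Averages the NDDI time series over the pure coarse cells of one class
#' and smooths the mean curve with a Savitzky-Golay filter, yielding the
#' class's standard annual trajectory used for per-pixel matching.
#'
#' @param cube An [nddi_cube()].
#' @param pure A pure-pixel set from [select_pure_pixels()].
#' @param frame The `grid_frame` that assigned the cell ids.
#' @param class Class name (default `"desertified"`).
#' @param window,order Savitzky-Golay parameters (defaults 5 and 2).
#' @return An object of class `reference_curve` with fields `raw`,
#'   `filtered`, `class` and `filter_params`.
#' @export
build_reference_curve <- function(cube, pure, frame, class = "desertified",
                                  window = 5L, order = 2L) {
  ids <- pure$cell_id[pure$class == class]
  if (!length(ids))
    stop("no pure cells of class '", class, "'")
  pos <- which(frame$cell_ids %in% ids)  # column-major positions in the coarse grid
  v <- cube$values
  dim(v) <- c(cube$n, length(frame$cell_ids))
  raw <- rowMeans(v[, pos, drop = FALSE], na.rm = TRUE)
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("reference curve undefined at some composites (all pure cells masked)")
  structure(list(raw = raw,
                 filtered = savitzky_golay(raw, window, order),
                 class = class,
                 filter_params = c(window = as.integer(window),
                                   order = as.integer(order))),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("<reference_curve> class '%s', n = %d, SG window %d order %d\n",
              x$class, length(x$raw), x$filter_params["window"],
              x$filter_params["order"]))
  invisible(x)
}

#' Mean Absolute Distance to a reference curve
#'
#' `MAD_ij = (1/n) * sum_k |NDDI_ijk - ref_k|` against the filtered
#' reference. Pixels with missing composites are averaged over the
#' available ones (n replaced by the available count); pixels with less
#' than `min_coverage` of the composites present are masked and counted in
#' the `flagged` attribute.
#'
#' @param cube An [nddi_cube()].
#' @param ref A [build_reference_curve()] result (or a plain numeric
#'   vector of length `cube$n`).
#' @param min_coverage Minimum fraction of composites required per pixel.
#' @return An object of class `mad_map` with fields `geometry`, `values`
#'   (matrix, `NA` where masked), `threshold`, `prior_fraction`.
#' @export
compute_mad <- function(cube, ref, min_coverage = 0.8) {
  rv <- if (inherits(ref, "reference_curve")) ref$filtered else as.numeric(ref)
  if (length(rv) != cube$n)
    stop("reference length (", length(rv), ") != cube composites (", cube$n, ")")
  n <- cube$n
  npx <- cube$geometry$n_rows * cube$geometry$n_cols
  v <- cube$values
  dim(v) <- c(n, npx)
  a <- abs(v - rv)          # ref recycles down the composite dimension
  cnt <- colSums(!is.na(a))
  s <- colSums(a, na.rm = TRUE)
  mad <- s / cnt
  low <- cnt < min_coverage * n
  mad[low | cnt == 0] <- NA_real_
  out <- structure(list(geometry = cube$geometry,
                        values = matrix(mad, cube$geometry$n_rows,
                                        cube$geometry$n_cols),
                        threshold = NULL, prior_fraction = NULL),
                   class = "mad_map")
  attr(out, "flagged") <- sum(low & cnt > 0)
  out
}

#' @export
print.mad_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<mad_map> %d x %d, MAD range [%.4g, %.4g]%s\n",
              x$geometry$n_rows, x$geometry$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (is.null(x$threshold)) "" else
                sprintf(", threshold %.4g", x$threshold)))
  invisible(x)
}

#' p-tile threshold on a MAD map
#'
#' Selects the threshold as the empirical `prior_fraction` quantile
#' (linear interpolation, type 7) of the unmasked MAD values, so that
#' approximately that prior-known fraction of the area falls at or below
#' it. Low MAD means a close match to the desertified reference curve.
#'
#' @param mad A [compute_mad()] result.
#' @param prior_fraction Prior fraction of the area assumed desertified,
#'   in `(0, 1)`; in practice official survey area divided by study area.
#' @return Scalar threshold.
#' @export
ptile_threshold <- function(mad, prior_fraction) {
  if (!is.numeric(prior_fraction) || prior_fraction <= 0 || prior_fraction >= 1)
    stop("prior_fraction must be in (0, 1)")
  v <- if (inherits(mad, "mad_map")) mad$values else as.numeric(mad)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no unmasked MAD values")
  if (max(v) == min(v)) {
    warning("degenerate MAD map (all values equal); threshold set to that value")
    return(v[1])
  }
  unname(stats::quantile(v, probs = prior_fraction, type = 7, names = FALSE))
}

#' Binary desertification map from a thresholded MAD map
#'
#' A pixel is desertified iff its MAD is at or below the threshold
#' (lower MAD = closer to the desertified reference); all other unmasked
#' pixels are labelled `others`, masked pixels stay `nodata`.
#'
#' @param mad A [compute_mad()] result.
#' @param threshold Finite scalar, e.g. from [ptile_threshold()].
#' @return A binary [class_map()] (`desertified` / `others` / `nodata`).
#' @export
classify_desertified <- function(mad, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  lg <- legend_codes()
  lab <- matrix(lg[["others"]], mad$geometry$n_rows, mad$geometry$n_cols)
  lab[mad$values <= threshold] <- lg[["desertified"]]
  lab[is.na(mad$values)] <- lg[["nodata"]]
  class_map(lab, mad$geometry)
}

#' Desertified area of a class map
#'
#' @param map A [class_map()].
#' @param class Class counted (default `"desertified"`).
#' @return Area in km^2 (cell count times metric cell area).
#' @export
area_estimate <- function(map, class = "desertified") {
  sum(map$labels == legend_codes()[[class]]) * cell_area_km2(map$geometry)
}

#' Relative error of an area estimate against survey data
#'
#' `100 * |estimated - investigated| / investigated`, rounded half-up to
#' two decimals for reporting.
#'
#' @param estimated Estimated area, km^2.
#' @param investigated Officially investigated area, km^2; must be `> 0`.
#' @return Relative error in percent (2 decimals).
#' @export
relative_error <- function(estimated, investigated) {
  if (any(investigated <= 0)) stop("investigated area must be positive")
  x <- 100 * abs(estimated - investigated) / investigated
  floor(x * 100 + 0.5) / 100  # round half-up for reporting
}

#' Annual area validation table
#'
#' @param year Integer vector of years.
#' @param estimated,investigated Areas in km^2, same length as `year`.
#' @return `data.frame` with columns `year`, `estimated_km2`,
#'   `investigated_km2`, `relative_error_pct`.
#' @export
area_record <- function(year, estimated, investigated) {
  stopifnot(length(year) == length(estimated),
            length(year) == length(investigated))
  if (any(estimated < 0)) stop("areas must be non-negative")
  data.frame(year = as.integer(year),
             estimated_km2 = estimated,
             investigated_km2 = investigated,
             relative_error_pct = relative_error(estimated, investigated))
}
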