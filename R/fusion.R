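## Pan-sharpening: PCA, multiplicative and Brovey fusion of a multispectral
## stack with a finer panchromatic band, plus the four quality metrics
## (mean, standard deviation, entropy, correlation against the raw bands)
## used to choose among them.

#' Upsample a stack to a finer aligned geometry
#'
#' @param stack A [band_stack()].
#' @param target Finer [grid_geometry()]; the source cell size must be an
#'   integer multiple of the target's, with coincident origins.
#' @param method `"nearest"` (block replication) or `"bilinear"`
#'   (separable linear interpolation between cell centres, clamped at the
#'   margins).
#' @return A [band_stack()] on `target`.
#' @export
upsample <- function(stack, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  f <- resample_factor(target, stack$geometry)  # reversed roles: source coarser
  if (f == 1L && method == "nearest") {
    return(band_stack(stack$bands, target, band_labels = stack$band_labels,
                      nodata = stack$nodata))
  }
  src_r <- stack$geometry$n_rows; src_c <- stack$geometry$n_cols
  if (method == "nearest") {
    ri <- rep(seq_len(src_r), each = f)
    ci <- rep(seq_len(src_c), each = f)
    bands <- lapply(stack$bands, function(b) b[ri, ci, drop = FALSE])
    nod <- stack$nodata[ri, ci, drop = FALSE]
  } else {
    # positions of target centres on the source-centre axis (cell units)
    tr <- ((seq_len(target$n_rows) - 0.5) / f) + 0.5
    tc <- ((seq_len(target$n_cols) - 0.5) / f) + 0.5
    interp_axis <- function(p, n) {
      i0 <- pmin(pmax(floor(p), 1L), n - 1L)
      w <- pmin(pmax(p - i0, 0), 1)
      list(i0 = i0, w = w)
    }
    ax_r <- interp_axis(tr, src_r); ax_c <- interp_axis(tc, src_c)
    bands <- lapply(stack$bands, function(b) {
      b[stack$nodata] <- NA_real_
      # rows first, then columns
      top <- b[ax_r$i0, , drop = FALSE]; bot <- b[ax_r$i0 + 1L, , drop = FALSE]
      m <- top * (1 - ax_r$w) + bot * ax_r$w
      lft <- m[, ax_c$i0, drop = FALSE]; rgt <- m[, ax_c$i0 + 1L, drop = FALSE]
      sweep(lft, 2L, 1 - ax_c$w, `*`) + sweep(rgt, 2L, ax_c$w, `*`)
    })
    nod <- Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  }
  band_stack(bands, target, band_labels = stack$band_labels, nodata = nod)
}

align_pair <- function(ms, pan, resample = "nearest") {
  if (n_bands(pan) != 1L) stop("pan must be a single-band stack")
  if (!geom_equal(ms$geometry, pan$geometry))
    ms <- upsample(ms, pan$geometry, method = resample)
  mask <- ms$nodata | pan$nodata
  list(ms = ms, pan = pan, mask = mask)
}

#' PCA pan-sharpening
#'
#' Principal-component transform of the (upsampled) multispectral bands;
#' the first component is replaced by the pan band after matching pan's
#' mean and standard deviation to the first component's, and the inverse
#' transform is returned. When pan already equals the first component the
#' output reproduces the input exactly.
#'
#' @param ms Multispectral [band_stack()] (>= 2 bands).
#' @param pan Single-band [band_stack()], same or finer geometry.
#' @param resample Upsampling method for `ms` (`"nearest"` or
#'   `"bilinear"`).
#' @return Fused [band_stack()] on the pan geometry, band count preserved.
#' @export
fuse_pca <- function(ms, pan, resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  p <- align_pair(ms, pan, resample)
  ok <- !p$mask
  X <- vapply(p$ms$bands, function(b) b[ok], numeric(sum(ok)))
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("degenerate multispectral input: zero-variance band")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1L]
  pv <- p$pan$bands[[1L]][ok]
  if (stats::sd(pv) == 0) stop("degenerate pan band: zero variance")
  # orient PC1 so it correlates positively with pan (the component sign
  # is arbitrary; substituting pan into a flipped PC1 would invert the
  # scene contrast)
  if (stats::cor(pv, s1) < 0) {
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
    pc$x[, 1L] <- -pc$x[, 1L]
    s1 <- -s1
  }
  pv <- (pv - mean(pv)) / stats::sd(pv) * stats::sd(s1) + mean(s1)
  scores <- pc$x
  scores[, 1L] <- pv
  Xf <- scores %*% t(pc$rotation)
  Xf <- sweep(Xf, 2L, pc$center, `+`)
  g <- p$pan$geometry
  bands <- lapply(seq_len(ncol(Xf)), function(i) {
    m <- matrix(NA_real_, g$n_rows, g$n_cols)
    m[ok] <- Xf[, i]
    m
  })
  band_stack(bands, g, band_labels = p$ms$band_labels, nodata = p$mask)
}

#' Multiplicative pan-sharpening
#'
#' `fused_b = ms_b * pan` per pixel. Simple, but inflates mean and
#' standard deviation by the pan magnitude, which is what disqualifies it
#' in the quality comparison.
#'
#' @inheritParams fuse_pca
#' @return Fused [band_stack()] on the pan geometry.
#' @export
fuse_multiplicative <- function(ms, pan, resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  p <- align_pair(ms, pan, resample)
  pv <- p$pan$bands[[1L]]
  bands <- lapply(p$ms$bands, function(b) b * pv)
  band_stack(bands, p$pan$geometry, band_labels = p$ms$band_labels,
             nodata = p$mask)
}

#' Brovey transform pan-sharpening
#'
#' Three-band ratio fusion: `fused_b = pan * ms_b / sum_b(ms_b)`, so the
#' fused bands sum to the pan value at every pixel. Pixels whose band sum
#' is zero are masked in the output (their count is reported in the
#' `zero_sum` attribute).
#'
#' @inheritParams fuse_pca
#' @param bands Which three multispectral bands to fuse (indices into
#'   `ms`); default bands 2-4.
#' @return Fused three-band [band_stack()] on the pan geometry.
#' @export
fuse_brovey <- function(ms, pan, bands = 2:4,
                        resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  if (length(bands) != 3L) stop("Brovey fusion takes exactly 3 bands")
  p <- align_pair(ms, pan, resample)
  bl <- p$ms$bands[bands]
  tot <- bl[[1L]] + bl[[2L]] + bl[[3L]]
  zero <- !p$mask & tot == 0
  pv <- p$pan$bands[[1L]]
  fused <- lapply(bl, function(b) {
    m <- pv * b / tot
    m[zero] <- NA_real_
    m
  })
  out <- band_stack(fused, p$pan$geometry,
                    band_labels = p$ms$band_labels[bands],
                    nodata = p$mask | zero)
  attr(out, "zero_sum") <- sum(zero)
  out
}

#' Shannon entropy of an image plane
#'
#' Values are quantised into `n_bins` equal-width bins over the observed
#' range and the entropy `-sum p log2 p` of the occupied bins is returned,
#' so the result is invariant under monotone affine rescaling. A constant
#' plane has entropy 0.
#'
#' @param plane Numeric matrix or vector; `NA`s are excluded.
#' @param n_bins Number of bins, `>= 2` (default 256, 8-bit style).
#' @return Entropy in bits.
#' @export
image_entropy <- function(plane, n_bins = 256L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  v <- plane[!is.na(plane)]
  if (!length(v)) stop("all-masked plane has no entropy")
  rg <- range(v)
  if (rg[1] == rg[2]) return(0)
  bin <- pmin(floor((v - rg[1]) / (rg[2] - rg[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Pearson correlation between two image planes
#'
#' Computed over jointly unmasked pixels; errors (rather than returning
#' `NaN`) when either plane has zero variance there.
#'
#' @param a,b Numeric matrices with identical dimensions.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
band_correlation <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("plane geometries differ")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("need >= 2 jointly unmasked pixels")
  x <- a[ok]; y <- b[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance plane: correlation undefined")
  stats::cor(x, y)
}

#' Compare pan-sharpening algorithms on one scene
#'
#' Runs PCA, multiplicative and Brovey fusion and tabulates mean,
#' standard deviation, entropy and correlation-against-raw for the raw
#' multispectral bands and each fused result. The method choice encodes a
#' two-step elimination: methods whose per-band mean or standard
#' deviation drifts more than `distortion_factor` away from the raw image
#' are rejected (this removes multiplicative fusion), and among the
#' survivors the method with the highest mean entropy + correlation wins.
#'
#' @inheritParams fuse_pca
#' @param brovey_bands Three band indices for the Brovey transform.
#' @param distortion_factor Maximum tolerated ratio between fused and raw
#'   mean / standard deviation (default 10).
#' @param quantize Round every product to integer digital numbers before
#'   computing the metrics (default `TRUE`): the comparison then scores
#'   the integer imagery a processing chain would actually write, so a
#'   method that compresses the dynamic range occupies fewer gray levels
#'   and pays for it in entropy.
#' @return An object of class `fusion_report`: a `data.frame` with
#'   columns `method`, `band`, `mean`, `sd`, `entropy`, `correlation`
#'   plus a `chosen_method` attribute.
#' @export
compare_fusions <- function(ms, pan, brovey_bands = 2:4,
                            distortion_factor = 10, quantize = TRUE,
                            resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  p <- align_pair(ms, pan, resample)
  raw <- p$ms
  fused <- list(
    PCA = function() fuse_pca(ms, pan, resample),
    multiplicative = function() fuse_multiplicative(ms, pan, resample),
    brovey = function() fuse_brovey(ms, pan, bands = brovey_bands, resample)
  )
  fused <- lapply(fused, function(f)
    tryCatch(f(), error = function(e) {
      warning("fusion method skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }))
  fused <- Filter(Negate(is.null), fused)
  if (!length(fused)) stop("every fusion method failed on this pair")
  metric_rows <- function(method, stack) {
    do.call(rbind, lapply(stack$band_labels, function(lb) {
      v <- band_values(stack, lb)
      if (quantize) v <- round(v)
      rawv <- band_values(raw, lb)
      if (quantize) rawv <- round(rawv)
      corr <- if (identical(method, "raw")) NA_real_ else
        band_correlation(v, rawv)
      data.frame(method = method, band = lb,
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v[!is.na(v)]),
                 entropy = image_entropy(v),
                 correlation = corr)
    }))
  }
  rep <- rbind(metric_rows("raw", raw),
               do.call(rbind, Map(metric_rows, names(fused), fused)))
  rownames(rep) <- NULL
  raw_rows <- rep[rep$method == "raw", ]
  ok_method <- function(m) {
    rr <- rep[rep$method == m, ]
    ref <- raw_rows[match(rr$band, raw_rows$band), ]
    ratios <- c(abs(rr$mean) / pmax(abs(ref$mean), .Machine$double.eps),
                rr$sd / pmax(ref$sd, .Machine$double.eps))
    all(ratios < distortion_factor & ratios > 1 / distortion_factor)
  }
  candidates <- names(fused)[vapply(names(fused), ok_method, logical(1))]
  if (!length(candidates)) candidates <- names(fused)
  score <- vapply(candidates, function(m) {
    rr <- rep[rep$method == m, ]
    mean(rr$entropy + rr$correlation)
  }, numeric(1))
  chosen <- candidates[which.max(score)]
  structure(rep, class = c("fusion_report", "data.frame"),
            chosen_method = chosen)
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("Fusion quality comparison (chosen method:",
      attr(x, "chosen_method"), ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Chosen method of a fusion report
#' @param report A [compare_fusions()] result.
#' @export
chosen_method <- function(report) attr(report, "chosen_method")
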