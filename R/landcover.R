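#' Labelled training samples for supervised classification
#'
#' @param samples Numeric matrix, one row per training pixel, one column
#'   per band.
#' @param labels Class labels (legend names or codes), length
#'   `nrow(samples)`; at least two classes.
#' @param provenance Optional identifiers of the field points the samples
#'   came from.
#' @return An object of class `training_set`.
#' @export
training_set <- function(samples, labels, provenance = NULL) {
  samples <- as.matrix(samples)
  if (anyNA(samples)) stop("training samples must not contain masked values")
  labels <- normalize_labels(labels)
  if (length(labels) != nrow(samples))
    stop("labels length must match the number of samples")
  if (length(unique(labels)) < 2L)
    stop("training set must contain at least two classes")
  structure(list(samples = samples, labels = labels,
                 provenance = provenance),
            class = "training_set")
}

normalize_labels <- function(labels) {
  lg <- legend_codes()
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% names(lg))) stop("unknown class label(s)")
    labels <- lg[labels]
  }
  labels <- as.integer(labels)
  if (!all(labels %in% lg) || any(labels == lg[["nodata"]]))
    stop("labels must be valid non-nodata legend codes")
  unname(labels)
}

#' @export
print.training_set <- function(x, ...) {
  tb <- table(factor(x$labels, levels = legend_codes(),
                     labels = names(legend_codes())))
  cat(sprintf("<training_set> %d samples x %d bands: %s\n",
              nrow(x$samples), ncol(x$samples),
              paste(names(tb)[tb > 0], tb[tb > 0], sep = "=", collapse = ", ")))
  invisible(x)
}

#' Train a support-vector classifier with a polynomial kernel
#'
#' Maximum-margin classification with kernel
#' `(gamma * <u, v> + coef0)^degree`; the default degree 2 separates
#' quadratic class boundaries (including XOR-type layouts). Deterministic
#' given fixed inputs and hyperparameters.
#'
#' @param train A [training_set()].
#' @param kernel_degree Polynomial degree, `>= 1` (default 2).
#' @param cost Soft-margin cost parameter.
#' @param gamma Kernel scale; defaults to `1 / n_bands`.
#' @param coef0 Kernel offset (default 1, inhomogeneous polynomial).
#' @param scale Standardise features before training (constant features
#'   are left unscaled automatically).
#' @return An object of class `aeoscan_classifier`.
#' @export
train_classifier <- function(train, kernel_degree = 2L, cost = 1,
                             gamma = NULL, coef0 = 1, scale = TRUE) {
  stopifnot(inherits(train, "training_set"))
  if (kernel_degree < 1L) stop("kernel_degree must be >= 1")
  x <- train$samples
  y <- factor(train$labels)
  if (nlevels(y) < 2L) stop("training set must contain at least two classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate features: all bands constant")
  do_scale <- if (scale) sds > 0 else rep(FALSE, ncol(x))
  fit <- e1071::svm(x, y, kernel = "polynomial", degree = kernel_degree,
                    gamma = gamma, coef0 = coef0, cost = cost,
                    scale = do_scale)
  structure(list(fit = fit, n_features = ncol(x),
                 kernel_degree = as.integer(kernel_degree)),
            class = "aeoscan_classifier")
}

#' @export
print.aeoscan_classifier <- function(x, ...) {
  cat(sprintf("<aeoscan_classifier> polynomial SVM, degree %d, %d feature(s)\n",
              x$kernel_degree, x$n_features))
  invisible(x)
}

#' Predict class labels for raw feature vectors
#'
#' @param object An `aeoscan_classifier`.
#' @param newdata Numeric matrix, columns matching the training bands.
#' @param ... Unused.
#' @return Integer legend codes.
#' @export
predict.aeoscan_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature count (", ncol(newdata), ") != training band count (",
         object$n_features, ")")
  as.integer(as.character(stats::predict(object$fit, newdata)))
}

#' Classify a reflectance stack into a land-cover map
#'
#' @param model An `aeoscan_classifier` from [train_classifier()].
#' @param stack A [band_stack()] whose band count equals the training
#'   feature count.
#' @return A [class_map()]; masked pixels become `nodata`.
#' @export
classify <- function(model, stack) {
  if (n_bands(stack) != model$n_features)
    stop("stack has ", n_bands(stack), " band(s) but the model expects ",
         model$n_features)
  g <- stack$geometry
  lab <- matrix(legend_codes()[["nodata"]], g$n_rows, g$n_cols)
  ok <- !stack$nodata
  if (any(ok)) {
    X <- vapply(stack$bands, function(b) b[ok], numeric(sum(ok)))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    lab[ok] <- predict(model, X)
  }
  class_map(lab, g)
}

#' Per-grid-cell class proportions of a fine classification map
#'
#' For every coarse frame cell, the fraction of each legend class among
#' the cell's unmasked fine pixels. Cells with no unmasked pixel get `NA`
#' proportions and are excluded downstream.
#'
#' @param map Fine-resolution [class_map()].
#' @param frame A `grid_frame` built on the map's geometry
#'   ([build_grid_frame()]).
#' @return The frame with its `proportions` field populated
#'   (matrix: one row per cell id, columns `desertified`, `vegetation`,
#'   `others`).
#' @export
class_proportions <- function(map, frame) {
  if (!geom_equal(map$geometry, frame$fine_geometry))
    stop("class map geometry does not match the frame's fine geometry")
  f <- frame$factor
  lg <- legend_codes()
  classes <- setdiff(names(lg), "nodata")
  counts <- vapply(classes, function(cl) {
    as.vector(t(block_sum((map$labels == lg[[cl]]) + 0, f)))  # row-major = id order
  }, numeric(frame$geometry$n_rows * frame$geometry$n_cols))
  tot <- rowSums(counts)
  prop <- counts / tot
  prop[tot == 0, ] <- NA_real_
  rownames(prop) <- as.character(seq_len(nrow(prop)))  # ids are row-major 1..N
  frame$proportions <- prop
  frame
}

#' Select pure coarse pixels from class proportions
#'
#' A cell is a pure pixel for the desertified class when its desertified
#' proportion strictly exceeds `t_desert` (default 0.70), and a pure
#' pixel for vegetation or others when that class's proportion strictly
#' exceeds `t_other` (default 0.90). Thresholds are strict: a proportion
#' exactly at the threshold does not qualify.
#'
#' @param frame A `grid_frame` with populated proportions.
#' @param t_desert Purity threshold for the desertified class.
#' @param t_other Purity threshold for vegetation and others (applied to
#'   each class separately).
#' @return An object of class `pure_pixel_set`: a `data.frame` with
#'   columns `cell_id`, `class`, `proportion`, plus the thresholds as
#'   attributes. May be empty.
#' @export
select_pure_pixels <- function(frame, t_desert = 0.70, t_other = 0.90) {
  if (is.null(frame$proportions))
    stop("frame proportions not populated; run class_proportions() first")
  pm <- frame$proportions
  thr <- c(desertified = t_desert, vegetation = t_other, others = t_other)
  out <- do.call(rbind, lapply(colnames(pm), function(cl) {
    sel <- which(!is.na(pm[, cl]) & pm[, cl] > thr[[cl]])
    if (!length(sel)) return(NULL)
    data.frame(cell_id = as.integer(rownames(pm))[sel], class = cl,
               proportion = pm[sel, cl])
  }))
  if (is.null(out))
    out <- data.frame(cell_id = integer(), class = character(),
                      proportion = numeric())
  rownames(out) <- NULL
  out <- out[order(out$cell_id), , drop = FALSE]
  if (anyDuplicated(out$cell_id))
    stop("internal error: cell assigned to more than one pure class")
  structure(out, class = c("pure_pixel_set", "data.frame"),
            thresholds = thr)
}

#' Rank band pairs by spectral complementarity over pure pixels
#'
#' For each band pair and each pure class, correlates the two bands' mean
#' reflectance time series over that class's pure cells; the total index
#' is the sum of the per-class correlations. Pairs are ranked ascending:
#' the lowest total correlation marks the most complementary pair, the
#' one used to build the normalized-difference index. Pairs with a
#' constant series in any class are flagged and excluded from the
#' ranking.
#'
#' @param stacks List of coarse [band_stack()]s (the composite time
#'   series), sharing a geometry with >= 2 bands.
#' @param pure A [select_pure_pixels()] result with >= 1 cell per class
#'   considered.
#' @param frame The `grid_frame` that assigned the cell ids.
#' @return `data.frame` with columns `band_a`, `band_b`, `total_r`,
#'   `rank` (`NA` rank where flagged), sorted by rank.
#' @export
band_pair_separability <- function(stacks, pure, frame) {
  g <- stacks[[1]]$geometry
  nb <- n_bands(stacks[[1]])
  if (nb < 2L) stop("need >= 2 bands")
  classes <- unique(pure$class)
  if (!length(classes)) stop("pure pixel set is empty")
  # mean reflectance per (class, band, composite)
  series <- lapply(classes, function(cl) {
    pos <- which(frame$cell_ids %in% pure$cell_id[pure$class == cl])
    vapply(seq_len(nb), function(b) {
      vapply(stacks, function(s) mean(band_values(s, b)[pos], na.rm = TRUE),
             numeric(1))
    }, numeric(length(stacks)))
  })
  names(series) <- classes
  pairs <- utils::combn(nb, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    rs <- vapply(series, function(m) {
      if (stats::sd(m[, a]) == 0 || stats::sd(m[, b]) == 0) NA_real_
      else stats::cor(m[, a], m[, b])
    }, numeric(1))
    data.frame(band_a = stacks[[1]]$band_labels[a],
               band_b = stacks[[1]]$band_labels[b],
               total_r = if (anyNA(rs)) NA_real_ else sum(rs))
  }))
  out$rank <- NA_integer_
  ok <- !is.na(out$total_r)
  out$rank[ok] <- rank(out$total_r[ok], ties.method = "first")
  out[order(out$rank, na.last = TRUE), , drop = FALSE]
}
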