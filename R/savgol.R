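#' Interior Savitzky-Golay smoothing weights
#'
#' Solves the local least-squares system for a centred window: fit a
#' polynomial of the given order to the window samples and evaluate it at
#' the centre. The returned weights are the centre row of the projection
#' matrix; for `window = 5, order = 2` they are the classic
#' `(-3, 12, 17, 12, -3) / 35`.
#'
#' @param window Odd window length, `>= 3`.
#' @param order Polynomial order, `0 <= order < window`.
#' @return Numeric vector of length `window`.
#' @export
savgol_weights <- function(window, order) {
  check_sg_params(window, order, n = window)
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  # value of the fitted polynomial at t = 0 is coefficient a0
  (solve(crossprod(A), t(A)))[1L, ]
}

check_sg_params <- function(window, order, n) {
  if (window %% 2L != 1L || window < 3L)
    stop("window must be an odd integer >= 3")
  if (window > n)
    stop("window (", window, ") exceeds series length (", n, ")")
  if (order < 0L || order >= window)
    stop("order must satisfy 0 <= order < window")
  invisible(TRUE)
}

#' Savitzky-Golay filter
#'
#' Local least-squares polynomial smoothing: each interior point is
#' replaced by the centre value of a polynomial of degree `order` fitted
#' to its `window` neighbours, so any polynomial of degree `<= order`
#' passes through unchanged. Near the boundaries the window is truncated
#' to the available samples and the polynomial (degree capped at one less
#' than the truncated window length) is refitted and evaluated at the
#' boundary point.
#'
#' @param series Numeric vector; `NA`s are not allowed.
#' @param window Odd window length, `3 <= window <= length(series)`.
#' @param order Polynomial order, `< window`.
#' @return Filtered numeric vector, same length as `series`.
#' @export
savitzky_golay <- function(series, window = 5L, order = 2L) {
  n <- length(series)
  check_sg_params(window, order, n)
  if (anyNA(series)) stop("series contains NA; fill or drop before filtering")
  h <- (window - 1L) %/% 2L
  w <- savgol_weights(window, order)
  out <- series
  if (n >= window) {
    idx <- (h + 1L):(n - h)
    # centred moving dot product with the interior weights
    sm <- vapply(idx, function(i) sum(w * series[(i - h):(i + h)]), numeric(1))
    out[idx] <- sm
  }
  # truncated-window refit at the two boundaries
  for (i in seq_len(min(h, n))) {
    out[i] <- sg_edge_value(series, lo = 1L, hi = min(n, i + h),
                            at = i, order = order)
    j <- n - i + 1L
    out[j] <- sg_edge_value(series, lo = max(1L, j - h), hi = n,
                            at = j, order = order)
  }
  out
}

sg_edge_value <- function(series, lo, hi, at, order) {
  t <- lo:hi
  deg <- min(order, length(t) - 1L)
  A <- outer(t - at, 0:deg, `^`)
  beta <- qr.solve(A, series[t])
  beta[1L]
}
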