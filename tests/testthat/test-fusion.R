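make_pair <- function(seed = 21, nr = 16, nc = 16, f = 2) {
  set.seed(seed)
  g_ms <- tiny_geom(nr, nc, 500)
  g_pan <- tiny_geom(nr * f, nc * f, 500 / f)
  ms <- band_stack(lapply(1:3, function(b) matrix(runif(nr * nc, 50, 250),
                                                  nr, nc)),
                   g_ms)
  pan <- band_stack(matrix(runif(nr * nc * f * f, 50, 250), nr * f, nc * f),
                    g_pan, band_labels = "pan")
  list(ms = ms, pan = pan)
}

test_that("PCA fusion is an identity when pan equals the first component", {
  sc <- small_scene()
  ms <- sc$fine_ms
  ok <- !ms$nodata
  X <- vapply(ms$bands, function(b) b[ok], numeric(sum(ok)))
  s1 <- stats::prcomp(X)$x[, 1]
  panm <- matrix(0, ms$geometry$n_rows, ms$geometry$n_cols)
  panm[ok] <- s1
  pan <- band_stack(panm, ms$geometry, band_labels = "pan")
  fused <- fuse_pca(ms, pan)
  for (b in seq_len(n_bands(ms)))
    expect_equal(band_values(fused, b), band_values(ms, b),
                 tolerance = 1e-6)
})

test_that("PCA fusion preserves band count and geometry", {
  p <- make_pair()
  fused <- fuse_pca(p$ms, p$pan)
  expect_equal(n_bands(fused), n_bands(p$ms))
  expect_true(aeoscan:::geom_equal(fused$geometry, p$pan$geometry))
  expect_identical(fused$band_labels, p$ms$band_labels)
  ## degenerate inputs refuse politely
  const <- band_stack(list(matrix(1, 4, 4), matrix(2, 4, 4)),
                      tiny_geom(4, 4))
  expect_error(fuse_pca(const, band_stack(matrix(rnorm(16), 4, 4),
                                          tiny_geom(4, 4),
                                          band_labels = "pan")),
               "zero-variance")
  expect_error(fuse_pca(p$ms, p$ms), "single-band")
})

test_that("multiplicative fusion is the per-pixel product", {
  g <- tiny_geom(1, 1)
  ms <- band_stack(matrix(100, 1, 1), g)
  pan <- band_stack(matrix(200, 1, 1), g, band_labels = "pan")
  expect_equal(band_values(fuse_multiplicative(ms, pan), 1)[1, 1], 20000)
  ## pan of ones is the identity
  p <- make_pair()
  ones <- band_stack(matrix(1, 32, 32), p$pan$geometry, band_labels = "pan")
  fused <- fuse_multiplicative(p$ms, ones)
  up <- upsample(p$ms, p$pan$geometry)
  expect_equal(band_values(fused, 2), band_values(up, 2))
})

test_that("Brovey fusion matches its ratio definition and sum identity", {
  g <- tiny_geom(1, 1)
  ms <- band_stack(list(matrix(10, 1, 1), matrix(50, 1, 1),
                        matrix(100, 1, 1), matrix(150, 1, 1)), g)
  pan <- band_stack(matrix(200, 1, 1), g, band_labels = "pan")
  fused <- fuse_brovey(ms, pan, bands = 2:4)
  got <- vapply(1:3, function(b) band_values(fused, b)[1, 1], numeric(1))
  expect_equal(got, c(200 * 50 / 300, 200 * 100 / 300, 200 * 150 / 300))

  ## equal bands share pan equally
  eq <- band_stack(list(matrix(2, 1, 1), matrix(7, 1, 1), matrix(7, 1, 1),
                        matrix(7, 1, 1)), g)
  f_eq <- fuse_brovey(eq, pan)
  expect_equal(band_values(f_eq, 1)[1, 1], 200 / 3)

  ## band-sum identity at machine precision on a real pair
  sc <- small_scene()
  fb <- fuse_brovey(sc$fine_ms, sc$pan)
  total <- band_values(fb, 1) + band_values(fb, 2) + band_values(fb, 3)
  panv <- sc$pan$bands[[1]]
  ok <- !is.na(total)
  expect_lt(max(abs(total[ok] - panv[ok])), 1e-9 * max(panv))

  ## zero band-sum pixels are masked and counted
  z <- band_stack(list(matrix(c(0, 1), 1, 2), matrix(c(0, 2), 1, 2),
                       matrix(c(0, 3), 1, 2), matrix(c(0, 4), 1, 2)),
                  tiny_geom(1, 2))
  pz <- band_stack(matrix(5, 1, 2), tiny_geom(1, 2), band_labels = "pan")
  fz <- fuse_brovey(z, pz)
  expect_true(fz$nodata[1, 1])
  expect_equal(attr(fz, "zero_sum"), 1L)
  expect_error(fuse_brovey(z, pz, bands = 1:2), "exactly 3")
})

test_that("image entropy counts occupied equal-width bins", {
  expect_equal(image_entropy(matrix(3, 5, 5)), 0)
  expect_equal(image_entropy(c(rep(0, 50), rep(1, 50))), 1)
  expect_equal(image_entropy(rep(0:255, each = 4)), 8)
  ## affine invariance under observed-range binning
  set.seed(22)
  v <- rnorm(4000)
  expect_equal(image_entropy(v), image_entropy(5 * v - 20))
  expect_error(image_entropy(matrix(NA_real_, 2, 2)), "all-masked")
  expect_error(image_entropy(1:10, n_bins = 1), "n_bins")
})

test_that("band correlation is Pearson over jointly unmasked pixels", {
  a <- matrix(rnorm(100), 10, 10)
  expect_equal(band_correlation(a, a), 1)
  expect_equal(band_correlation(a, -a), -1)
  set.seed(23)
  x <- matrix(rnorm(1e4), 100, 100)
  y <- matrix(rnorm(1e4), 100, 100)
  expect_lt(abs(band_correlation(x, y)), 0.05)
  expect_error(band_correlation(a, matrix(1, 10, 10)), "variance")
  expect_error(band_correlation(a, matrix(1, 2, 2)), "differ")
})

test_that("the fusion comparison reproduces the selection narrative", {
  sc <- small_scene()
  rep <- compare_fusions(sc$fine_ms, sc$pan)
  ## multiplicative is rejected for mean/std distortion; PCA beats
  ## Brovey on entropy + correlation
  expect_identical(chosen_method(rep), "PCA")
  df <- as.data.frame(rep)
  raw_mean <- df$mean[df$method == "raw" & df$band == "band2"]
  mult_mean <- df$mean[df$method == "multiplicative" & df$band == "band2"]
  expect_gt(mult_mean / raw_mean, 10)
  score <- function(m) mean(df$entropy[df$method == m] +
                            df$correlation[df$method == m])
  expect_gt(score("PCA"), score("brovey"))
})

test_that("the fusion report covers every method-band pair computed", {
  sc <- small_scene()
  rep <- compare_fusions(sc$fine_ms, sc$pan)
  expect_setequal(unique(rep$method),
                  c("raw", "PCA", "multiplicative", "brovey"))
  ## Brovey is a three-band method: band1 row absent
  expect_equal(sum(rep$method == "brovey"), 3L)
  expect_false("band1" %in% rep$band[rep$method == "brovey"])
  expect_equal(sum(rep$method == "PCA"), 4L)
  expect_true(all(rep$correlation[rep$method != "raw"] >= -1 &
                  rep$correlation[rep$method != "raw"] <= 1))
  expect_true(all(rep$entropy >= 0))
})

test_that("pan of ones leaves multiplicative metrics at the raw values", {
  p <- make_pair()
  ones <- band_stack(matrix(1, 32, 32), p$pan$geometry, band_labels = "pan")
  ## the constant pan defeats the PCA variance matching, which is
  ## dropped with a warning; the multiplicative identity still holds
  expect_warning(
    rep <- compare_fusions(p$ms, ones, brovey_bands = 1:3, quantize = FALSE),
    "skipped")
  df <- as.data.frame(rep)
  for (b in unique(df$band)) {
    raw <- df[df$method == "raw" & df$band == b, ]
    mult <- df[df$method == "multiplicative" & df$band == b, ]
    expect_equal(mult$mean, raw$mean)
    expect_equal(mult$sd, raw$sd)
    expect_equal(mult$entropy, raw$entropy)
    expect_equal(mult$correlation, 1)
  }
})
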