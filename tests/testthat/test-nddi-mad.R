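test_that("NDDI follows the normalized-difference definition", {
  b <- matrix(0.2, 2, 2)
  expect_equal(compute_nddi(b, b), matrix(0, 2, 2))
  expect_equal(compute_nddi(matrix(0.30, 1, 1), matrix(0.10, 1, 1))[1, 1], 0.5)
  expect_equal(compute_nddi(matrix(0.4, 1, 1), matrix(0, 1, 1))[1, 1], 1)
  ## undefined where the band sum is non-positive
  out <- compute_nddi(matrix(c(0.2, 0), 1, 2), matrix(c(-0.2, 0), 1, 2))
  expect_true(all(is.na(out)))
  expect_error(compute_nddi(matrix(1, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("NDDI is bounded and antisymmetric under band swap", {
  set.seed(10)
  a <- matrix(runif(100, 0.01, 1), 10, 10)
  b <- matrix(runif(100, 0.01, 1), 10, 10)
  n1 <- compute_nddi(a, b)
  expect_true(all(abs(n1) <= 1))
  expect_equal(compute_nddi(b, a), -n1)
})

test_that("MAD matches its definition and a direct-loop oracle", {
  g <- tiny_geom(1, 1)
  ## hand oracle: ref (0.2, 0.4) vs pixel (0.3, 0.1) -> 0.2
  cube <- nddi_cube(array(c(0.3, 0.1), c(2, 1, 1)), g, n_per_year = 2)
  expect_equal(compute_mad(cube, c(0.2, 0.4))$values[1, 1], 0.2)
  ## self-distance is zero
  ref <- runif(2)
  cube0 <- nddi_cube(array(ref, c(2, 1, 1)), g, n_per_year = 2)
  expect_equal(compute_mad(cube0, ref)$values[1, 1], 0)

  ## direct-loop oracle on random 46-point series
  set.seed(11)
  n <- 46L
  npx <- 100L
  series <- matrix(runif(n * npx, -1, 1), n, npx)
  ref46 <- runif(n, -1, 1)
  cube46 <- nddi_cube(array(series, c(n, 10, 10)), tiny_geom(10, 10))
  got <- compute_mad(cube46, ref46)$values
  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    s <- 0
    for (k in 1:n) s <- s + abs(series[k, (j - 1) * 10 + i] - ref46[k])
    oracle[i, j] <- s / n
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("MAD is symmetric and invariant under a common sign flip", {
  set.seed(12)
  a <- runif(46, -1, 1); b <- runif(46, -1, 1)
  g <- tiny_geom(1, 1)
  mad_ab <- compute_mad(nddi_cube(array(a, c(46, 1, 1)), g), b)$values[1, 1]
  mad_ba <- compute_mad(nddi_cube(array(b, c(46, 1, 1)), g), a)$values[1, 1]
  mad_neg <- compute_mad(nddi_cube(array(-a, c(46, 1, 1)), g), -b)$values[1, 1]
  expect_equal(mad_ab, mad_ba)
  expect_equal(mad_ab, mad_neg)
})

test_that("pixels with sparse composite coverage are flagged and masked", {
  g <- tiny_geom(1, 2)
  vals <- array(runif(20), c(10, 1, 2))
  vals[1:3, 1, 1] <- NA  # 70% coverage < 80% -> masked
  vals[1, 1, 2] <- NA    # 90% coverage -> averaged over the rest
  cube <- nddi_cube(vals, g, n_per_year = 10)
  ref <- rep(0, 10)
  mm <- compute_mad(cube, ref)
  expect_true(is.na(mm$values[1, 1]))
  expect_equal(mm$values[1, 2], mean(abs(vals[2:10, 1, 2])))
  expect_equal(attr(mm, "flagged"), 1L)
})

test_that("p-tile threshold is the linear-interpolation quantile", {
  vals <- matrix(1:100, 10, 10)
  mm <- structure(list(geometry = tiny_geom(10, 10), values = vals),
                  class = "mad_map")
  thr <- ptile_threshold(mm, 0.25)
  expect_equal(thr, 25.75)
  expect_equal(sum(vals <= floor(thr)), 25L)
  ## near-total prior approaches the maximum
  expect_equal(ptile_threshold(mm, 1 - 1e-12), 100)
  ## two-valued map: prior 0.9 separates the populations
  vals2 <- matrix(c(rep(0.01, 90), rep(0.99, 10)), 10, 10)
  mm2 <- structure(list(geometry = tiny_geom(10, 10), values = vals2),
                   class = "mad_map")
  thr2 <- ptile_threshold(mm2, 0.9)
  expect_gt(thr2, 0.01); expect_lt(thr2, 0.99)
  expect_error(ptile_threshold(mm, 0), "prior_fraction")
  expect_warning(
    ptile_threshold(structure(list(values = matrix(2, 2, 2)),
                              class = "mad_map"), 0.5),
    "degenerate")
})

test_that("p-tile threshold is monotone in the prior fraction", {
  set.seed(13)
  mm <- structure(list(values = matrix(rexp(400), 20, 20)),
                  class = "mad_map")
  priors <- seq(0.05, 0.95, by = 0.05)
  thrs <- vapply(priors, function(p) ptile_threshold(mm, p), numeric(1))
  expect_true(all(diff(thrs) >= 0))
})

test_that("threshold segmentation is boundary-inclusive and mask-preserving", {
  vals <- matrix(c(0.1, 0.2, 0.3, NA), 2, 2)
  mm <- structure(list(geometry = tiny_geom(2, 2), values = vals),
                  class = "mad_map")
  lg <- legend_codes()
  below <- classify_desertified(mm, 0.05)
  expect_equal(sum(below$labels == lg[["desertified"]]), 0L)
  at_max <- classify_desertified(mm, 0.3)
  expect_equal(sum(at_max$labels == lg[["desertified"]]), 3L)
  ## boundary: MAD exactly at the threshold is desertified
  at_mid <- classify_desertified(mm, 0.2)
  expect_equal(sum(at_mid$labels == lg[["desertified"]]), 2L)
  expect_equal(at_mid$labels[is.na(vals)], lg[["nodata"]])
  expect_error(classify_desertified(mm, Inf), "finite")
})

test_that("area accounting multiplies cell counts by metric cell area", {
  lg <- legend_codes()
  lab <- matrix(lg[["others"]], 5, 5)
  lab[1:10] <- lg[["desertified"]]
  expect_equal(area_estimate(class_map(lab, tiny_geom(5, 5, 1000))), 10)
  expect_equal(area_estimate(class_map(matrix(lg[["others"]], 2, 2),
                                       tiny_geom(2, 2, 1000))), 0)
  all_d <- class_map(matrix(lg[["desertified"]], 3, 3), tiny_geom(3, 3, 500))
  expect_equal(area_estimate(all_d), 2.25)
  deg <- class_map(matrix(lg[["desertified"]], 2, 2),
                   grid_geometry(0, 0, 0.01, 2, 2, crs_tag = "EPSG:4326"))
  expect_error(area_estimate(deg), "non-metric")
})

test_that("relative error reproduces the published validation rows", {
  expect_equal(relative_error(1714806, 1726700), 0.69)
  expect_equal(relative_error(1758942, 1706700), 3.06)
  expect_equal(relative_error(1724094, 1701600), 1.32)
  expect_equal(relative_error(5, 5), 0)
  expect_error(relative_error(1, 0), "positive")
  tab <- area_record(2004, 1714806, 1726700)
  expect_equal(tab$relative_error_pct, 0.69)
})

test_that("reference curves average pure cells and order by seasonality", {
  sc <- small_scene()
  frame <- small_scene_frame()
  pure <- select_pure_pixels(frame)
  cube <- build_nddi_cube(sc$coarse_stacks)

  ## single pure cell: raw curve equals that cell's own series
  one <- pure[pure$class == "desertified", ][1, , drop = FALSE]
  ref1 <- build_reference_curve(cube, one, frame)
  pos <- which(frame$cell_ids == one$cell_id)
  rc <- arrayInd(pos, dim(frame$cell_ids))
  expect_equal(ref1$raw, cube$values[, rc[1], rc[2]])

  ## cancellation: two synthetic cells with series s and -s
  g2 <- tiny_geom(1, 2)
  s <- runif(46, -0.5, 0.5)
  cube2 <- nddi_cube(array(c(rbind(s, -s))[order(rep(1:2, 46))],
                           c(46, 1, 2)), g2)
  cube2$values[, 1, 1] <- s
  cube2$values[, 1, 2] <- -s
  frame2 <- build_grid_frame(g2, 1000)
  pure2 <- structure(data.frame(cell_id = 1:2, class = "desertified",
                                proportion = 1),
                     class = c("pure_pixel_set", "data.frame"))
  ref2 <- build_reference_curve(cube2, pure2, frame2)
  expect_equal(ref2$raw, rep(0, 46))

  ## the desertified curve is flatter than the vegetation curve
  refd <- build_reference_curve(cube, pure, frame, "desertified")
  refv <- build_reference_curve(cube, pure, frame, "vegetation")
  expect_lt(diff(range(refd$filtered)), diff(range(refv$filtered)))
  expect_error(build_reference_curve(cube, pure[0, ], frame), "no pure cells")
})
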