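test_that("time-delay embedding produces the right lagged vectors", {
  cfg2 <- embedding_config(2, 1)
  M <- embed_series(1:5, cfg2)
  expect_equal(nrow(M), 4L)
  expect_equal(M[1, ], c(2, 1))
  expect_equal(attr(M, "t"), 2:5)
  expect_equal(nrow(embed_series(rnorm(15), embedding_config(3, 1))), 13L)
  expect_error(embed_series(1:3, embedding_config(4, 1)), "too short")
  expect_error(embedding_config(1, 1), "E")
  expect_error(embedding_config(2, 0), "tau")
})

test_that("panel embedding never spans site boundaries", {
  panel <- data.frame(site_id = rep(1:2, each = 15), year = rep(2001:2015, 2),
                      v = rnorm(30))
  emb <- aeoscan:::embed_panel(panel, "v", embedding_config(3, 1))
  expect_equal(nrow(emb$M), 26L)
  expect_equal(as.vector(table(emb$site)), c(13L, 13L))
  ## each vector's coordinates come from its own site only
  for (i in seq_len(nrow(emb$M))) {
    s <- emb$site[i]; t0 <- emb$t[i]
    sub <- panel[panel$site_id == s, ]
    expect_equal(emb$M[i, ], sub$v[t0 - 0:2])
  }
  bad <- panel[-3, ]
  expect_error(aeoscan:::embed_panel(bad, "v", embedding_config(2, 1)),
               "contiguous")
})

test_that("cross mapping recovers identical series and ignores noise", {
  set.seed(31)
  x <- as.numeric(scale(cumsum(rnorm(200))))
  cfg <- embedding_config(2, 1)
  M <- embed_series(x, cfg)
  vals <- x[attr(M, "t")]
  rho_self <- simplex_cross_map(M, vals)
  expect_gt(rho_self, 0.95)

  ## independent white noise: no shared dynamics
  y <- rnorm(1000)
  My <- embed_series(y, cfg)
  z <- rnorm(nrow(My))
  expect_lt(abs(simplex_cross_map(My, z)), 0.1)

  expect_error(simplex_cross_map(M, vals[-1]), "align")
  expect_error(simplex_cross_map(M, vals, library = c(1, 1, 1)),
               "distinct")
})

test_that("the coupled-logistic pair shows the forcing asymmetry", {
  ## X forces Y strongly; Y's manifold should recover X better than
  ## X's manifold recovers Y
  set.seed(32)
  N <- 400
  x <- y <- numeric(N + 100)
  x[1] <- 0.4; y[1] <- 0.2
  for (t in 1:(N + 99)) {
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t] - 0.02 * y[t])
    y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - 0.1 * x[t])
  }
  x <- x[101:(N + 100)]; y <- y[101:(N + 100)]
  cfg <- embedding_config(3, 1)
  My <- embed_series(as.numeric(scale(y)), cfg)
  Mx <- embed_series(as.numeric(scale(x)), cfg)
  rho_x_from_My <- simplex_cross_map(My, as.numeric(scale(x))[attr(My, "t")])
  rho_y_from_Mx <- simplex_cross_map(Mx, as.numeric(scale(y))[attr(Mx, "t")])
  expect_gt(rho_x_from_My, rho_y_from_Mx)
})

test_that("compiled and reference cross-map kernels agree", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    M <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(stats::dist(M))
    v <- rnorm(n)
    lib <- sample.int(n, sample(10:n, 1), replace = TRUE)
    a <- aeoscan:::cross_map_core(D, v, lib, 1:n, 4L)
    b <- aeoscan:::cross_map_core_r(D, v, lib, 1:n, 4L)
    expect_equal(a, b, tolerance = 1e-12)
  }
  ## exact-match degeneracy: duplicated manifold points
  M2 <- matrix(rep(c(1, 2), each = 6), 6, 2)
  D2 <- as.matrix(stats::dist(M2))
  v2 <- c(5, 5, 5, 9, 9, 9)
  a2 <- aeoscan:::cross_map_core(D2, v2, 1:6, 1:6, 3L)
  b2 <- aeoscan:::cross_map_core_r(D2, v2, 1:6, 1:6, 3L)
  expect_equal(a2, b2)
})

test_that("embedding selection favors low-dimensional determinism", {
  ## deterministic 1-D chaotic map: small E suffices
  set.seed(34)
  x <- numeric(240); x[1] <- 0.31
  for (t in 1:239) x[t + 1] <- 3.9 * x[t] * (1 - x[t])
  panel <- data.frame(site_id = 1L, year = seq_along(x), v = x)
  cfg <- select_embedding(panel, "v", E_range = 2:4)
  expect_true(cfg$E %in% 2:4)
  expect_gt(max(attr(cfg, "skill"), na.rm = TRUE), 0.9)

  ## periodic signal is predictable at E >= 2
  s <- sin(2 * pi * (1:120) / 12)
  cfg_s <- select_embedding(data.frame(site_id = 1L, year = 1:120, v = s),
                            "v", E_range = 2:4)
  expect_gte(cfg_s$E, 2L)

  ## white noise: low skill warning, smallest feasible E wins ties
  set.seed(35)
  noise <- data.frame(site_id = rep(1:4, each = 30), year = rep(1:30, 4),
                      v = rnorm(120))
  expect_warning(select_embedding(noise, "v"), "low")
})

test_that("ccm curves detect self-causation and reject independence", {
  panel <- small_panel()
  panel$X2 <- panel$X
  self <- ccm_curve(panel, cause = "X2", effect = "X",
                    cfg = embedding_config(2, 1), lengths = c(20, 200),
                    n_boot = 100, seed = 41)
  expect_true(all(self$rho_mean > 0.9))
  expect_lt(self$p_value, 0.05)

  set.seed(42)
  ind <- data.frame(site_id = rep(1:20, each = 15),
                    year = rep(2001:2015, 20),
                    a = rnorm(300), b = rnorm(300))
  r_ind <- ccm_curve(ind, cause = "a", effect = "b",
                     cfg = embedding_config(2, 1), lengths = c(20, 200),
                     n_boot = 100, seed = 43)
  expect_lt(abs(r_ind$rho_mean[[1]]), 0.15)
  expect_lt(abs(r_ind$rho_mean[[2]]), 0.15)
  expect_gt(r_ind$p_value, 0.05)
})

test_that("the true forcing direction converges on the coupled panel", {
  panel <- small_panel()
  r_true <- ccm_curve(panel, cause = "X", effect = "Y",
                      lengths = c(20, 100, 400), n_boot = 200, seed = 44)
  r_weak <- ccm_curve(panel, cause = "Y", effect = "X",
                      lengths = c(20, 100, 400), n_boot = 200, seed = 44)
  expect_gt(r_true$rho_mean[[3]], r_true$rho_mean[[1]])
  expect_lt(r_true$p_value, 0.05)
  ## the coupling is bidirectional (weakly so for Y -> X): the weak
  ## direction may also converge, but never more decisively, and its
  ## skill stays below the true direction's
  expect_gte(r_weak$p_value, r_true$p_value)
  expect_gt(r_true$rho_full, r_weak$rho_full)
  ## full-library deterministic skill sits inside the bootstrap band
  expect_lt(abs(r_true$rho_full - r_true$rho_mean[[3]]),
            4 * r_true$rho_sd[[3]] + 0.05)
})

test_that("cross-map skill is invariant under affine cause rescaling", {
  panel <- small_panel()
  panel$Xr <- 100 * panel$X - 7
  a <- ccm_curve(panel, cause = "X", effect = "Y",
                 cfg = embedding_config(3, 1), lengths = c(30, 300),
                 n_boot = 100, seed = 45)
  b <- ccm_curve(panel, cause = "Xr", effect = "Y",
                 cfg = embedding_config(3, 1), lengths = c(30, 300),
                 n_boot = 100, seed = 45)
  expect_equal(a$rho_mean, b$rho_mean, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value)
})

test_that("the convergence test measures paired bootstrap dominance", {
  expect_equal(convergence_test(rep(0.1, 200), rep(0.5, 200)), 0)
  set.seed(46)
  same <- rnorm(2000)
  other <- rnorm(2000)
  expect_equal(convergence_test(same, other), 0.5, tolerance = 0.05)
  expect_warning(convergence_test(rnorm(50), rnorm(50)), "unstable")
  expect_error(convergence_test(rnorm(10), rnorm(9)), "equal")
})
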