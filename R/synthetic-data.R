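## Synthetic inputs with known ground truth: a desert-margin scene
## (coarse 46-composite reflectance time series + a fine multispectral /
## panchromatic pair + class truth maps) and a coupled-logistic site
## panel for the causality module. Everything is generated from one seed
## and is bit-reproducible.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic scene specification
#'
#' Describes the emulated desert-margin landscape: a coarse reflectance
#' lattice (1 km cells, 46 annual composites of a red and an NIR band),
#' a nested fine multispectral scene (4 bands) with a panchromatic band
#' at yet finer resolution, and the class layout. Class patches are
#' carved from a smoothed random field so they are spatially contiguous;
#' a configurable share of coarse cells is mixed (two classes) so the
#' pure-pixel selection has something to reject.
#'
#' @param coarse_n_rows,coarse_n_cols Coarse grid size (default 100 x
#'   100).
#' @param coarse_cell Coarse cell size in metres (default 1000).
#' @param fine_factor Fine pixels per coarse cell side (default 4).
#' @param pan_factor Pan pixels per fine pixel side (default 2).
#' @param desertified_fraction,vegetation_fraction Truth class fractions
#'   of the coarse grid (remainder is `others`).
#' @param mixed_fraction Share of coarse cells given a minority class
#'   admixture (default 0.15).
#' @param mix_minority Range of the minority share in mixed cells.
#' @param noise_sd Reflectance noise s.d. of the coarse composites
#'   (default 0.05).
#' @param fine_noise_sd Sensor noise s.d. of the fine scene (reflectance
#'   units, applied before the digital-number scaling).
#' @param albedo_sd S.d. of the common smooth surface-brightness field
#'   multiplying every fine band.
#' @param veg_density_sd Amplitude of the smooth vegetation-density
#'   field in the NIR band (reflectance units; the visible bands respond
#'   weakly and negatively).
#' @param pan_texture_sd Amplitude of the pan-resolution scene texture
#'   (spatial detail below the multispectral pixel size).
#' @param dn_scale Digital-number scaling of the fine scene and pan band
#'   (default 255, 8-bit-style imagery; the coarse composites stay in
#'   reflectance units).
#' @param n_composites Composites per year (default 46, the 8-day
#'   calendar).
#' @param smooth_window Width of the moving-average patch smoother.
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(coarse_n_rows = 100L, coarse_n_cols = 100L,
                       coarse_cell = 1000, fine_factor = 4L,
                       pan_factor = 2L,
                       desertified_fraction = 0.3,
                       vegetation_fraction = 0.4,
                       mixed_fraction = 0.15,
                       mix_minority = c(0.1, 0.4),
                       noise_sd = 0.05, fine_noise_sd = 0.02,
                       albedo_sd = 0.08, veg_density_sd = 0.12,
                       pan_texture_sd = 0.03, dn_scale = 255,
                       n_composites = 46L, smooth_window = 9L,
                       seed = 1L) {
  if (desertified_fraction + vegetation_fraction > 1)
    stop("class fractions must sum to <= 1")
  if (desertified_fraction <= 0) stop("desertified_fraction must be > 0")
  stopifnot(fine_factor >= 1L, pan_factor >= 1L, noise_sd >= 0,
            mix_minority[1] >= 0, mix_minority[2] <= 0.5)
  structure(as.list(environment()), class = "scene_spec")
}

## Per-class coarse band signatures over the annual cycle: column 1 red,
## column 2 NIR. Desertified land is bright in the red and nearly
## seasonless; vegetation has a strong mid-season NIR peak (and a red
## dip), so its red-minus-NIR index plunges in the growing season;
## others sit between.
class_signatures <- function(n = 46L) {
  k <- seq_len(n)
  bump <- exp(-(k - (n + 1) / 2)^2 / (2 * (n / 8)^2))
  list(
    desertified = cbind(red = 0.35 + 0.01 * sin(2 * pi * k / n),
                        nir = 0.30 + 0.005 * sin(2 * pi * k / n)),
    vegetation  = cbind(red = 0.10 - 0.03 * bump,
                        nir = 0.25 + 0.25 * bump),
    others      = cbind(red = 0.20 - 0.01 * bump,
                        nir = 0.22 + 0.06 * bump)
  )
}

## Fine 4-band signatures (blue, green, red, NIR) at mid-season.
fine_signatures <- function() {
  rbind(desertified = c(0.20, 0.26, 0.35, 0.30),
        vegetation  = c(0.05, 0.09, 0.08, 0.45),
        others      = c(0.12, 0.16, 0.20, 0.25))
}

## moving-average smoothing of a matrix (circular, separable); the
## kernel is capped at the axis length so tiny grids stay valid
smooth_field <- function(m, w) {
  w_r <- min(w, nrow(m)); w_c <- min(w, ncol(m))
  m <- apply(m, 2L, function(col)
    stats::filter(col, rep(1 / w_r, w_r), circular = TRUE))
  t(apply(m, 1L, function(row)
    stats::filter(row, rep(1 / w_c, w_c), circular = TRUE)))
}

#' Generate a synthetic desert-margin scene with ground truth
#'
#' Draws the class layout, the coarse two-band 46-composite reflectance
#' series, the fine 4-band scene and its panchromatic band, and returns
#' every truth object needed to score the downstream modules. Coarse
#' reflectance is the per-cell class-proportion-weighted mixture of the
#' class signatures plus Gaussian noise (clamped at 0.001), which makes
#' the coarse stack the exact block mean of the implied fine reflectance
#' field in the zero-noise limit.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `spec`, `fine_ms` ([band_stack()], 4
#'   bands), `pan` (single band, finer), `coarse_stacks` (list of
#'   `n_composites` two-band stacks), `truth_fine` and `truth_coarse`
#'   ([class_map()]s), `proportions_truth` (cells x classes matrix in
#'   cell-id order), `truth_area_km2`, and `manifest`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  nr <- spec$coarse_n_rows; nc <- spec$coarse_n_cols
  N <- nr * nc
  lg <- legend_codes()
  classes <- c("desertified", "vegetation", "others")

  ## contiguous class patches: rank a smoothed Gaussian field
  field <- smooth_field(matrix(stats::rnorm(N), nr, nc), spec$smooth_window)
  ord <- order(field)  # column-major positions, driest first
  n_d <- round(spec$desertified_fraction * N)
  n_v <- round(spec$vegetation_fraction * N)
  maj <- matrix(lg[["others"]], nr, nc)
  maj[ord[seq_len(n_d)]] <- lg[["desertified"]]
  if (n_v > 0) maj[ord[n_d + seq_len(n_v)]] <- lg[["vegetation"]]

  ## per-cell class proportions (cell-id = row-major order)
  f <- spec$fine_factor
  id_pos <- as.vector(t(matrix(seq_len(N), nr, nc)))  # col-major pos by id
  P <- matrix(0, N, 3L, dimnames = list(NULL, classes))
  maj_by_id <- as.vector(t(maj))
  P[cbind(seq_len(N), maj_by_id)] <- 1
  n_mixed <- round(spec$mixed_fraction * N)
  minority_class <- integer(0)
  mixed_ids <- integer(0)
  if (n_mixed > 0 && f >= 2L) {
    mixed_ids <- sample.int(N, n_mixed)
    u <- stats::runif(n_mixed, spec$mix_minority[1], spec$mix_minority[2])
    minority_class <- vapply(maj_by_id[mixed_ids], function(m)
      sample(setdiff(1:3, m), 1L), integer(1))
    ## realized minority share snaps to a whole number of fine pixels
    m_px <- round(u * f * f)
    u_real <- m_px / (f * f)
    P[cbind(mixed_ids, maj_by_id[mixed_ids])] <- 1 - u_real
    P[cbind(mixed_ids, minority_class)] <- u_real
  }

  coarse_geom <- grid_geometry(0, 0, spec$coarse_cell, nr, nc)
  truth_coarse <- class_map(maj, coarse_geom)

  ## fine class map: minority pixels fill the head of each cell in
  ## raster order, so realized per-cell proportions equal P exactly
  fine_geom <- grid_geometry(0, 0, spec$coarse_cell / f, nr * f, nc * f)
  fine_lab <- maj[rep(seq_len(nr), each = f), rep(seq_len(nc), each = f)]
  if (length(mixed_ids)) {
    for (i in seq_along(mixed_ids)) {
      id <- mixed_ids[i]
      r0 <- ((id - 1L) %/% nc) * f  # id row-major
      c0 <- ((id - 1L) %% nc) * f
      m_px <- round(P[id, minority_class[i]] * f * f)
      if (m_px > 0) {
        cells <- arrayInd(seq_len(m_px), c(f, f))
        fine_lab[cbind(r0 + cells[, 1L], c0 + cells[, 2L])] <-
          lg[[classes[minority_class[i]]]]
      }
    }
  }
  truth_fine <- class_map(fine_lab, fine_geom)

  ## coarse composites: proportion-weighted signature mixture + noise
  sig <- class_signatures(spec$n_composites)
  sig_red <- vapply(classes, function(cl) sig[[cl]][, "red"],
                    numeric(spec$n_composites))
  sig_nir <- vapply(classes, function(cl) sig[[cl]][, "nir"],
                    numeric(spec$n_composites))
  red_k <- tcrossprod(sig_red, P)  # composites x cells (cell-id order)
  nir_k <- tcrossprod(sig_nir, P)
  coarse_stacks <- lapply(seq_len(spec$n_composites), function(k) {
    mk_band <- function(vals_by_id) {
      v <- vals_by_id + stats::rnorm(N, sd = spec$noise_sd)
      m <- matrix(NA_real_, nr, nc)
      m[id_pos] <- pmax(v, 0.001)
      m
    }
    band_stack(list(mk_band(red_k[k, ]), mk_band(nir_k[k, ])),
               coarse_geom, band_labels = c("band1", "band2"))
  })

  ## fine multispectral scene + pan, in integer sensor digital numbers.
  ## Within-class structure: a common smooth albedo (brightness) field
  ## multiplying every band, plus a smooth vegetation-density field
  ## expressed strongly in the NIR band and weakly (negatively) in the
  ## visible ones. The pan band's spectral response is visible-weighted,
  ## so it only partially sees the NIR structure -- the composition
  ## mismatch that separates the fusion methods' quality metrics.
  fsig <- fine_signatures()
  cls_idx <- match(fine_lab, lg[classes])  # 1..3 per fine pixel
  nfr <- fine_geom$n_rows; nfc <- fine_geom$n_cols
  norm_field <- function(n_r, n_c, w, sd_target) {
    fld <- smooth_field(matrix(stats::rnorm(n_r * n_c), n_r, n_c), w)
    fld / stats::sd(fld) * sd_target
  }
  albedo <- 1 + norm_field(nfr, nfc, 7L, spec$albedo_sd)
  veg_density <- norm_field(nfr, nfc, 5L, 1)
  dV <- c(-0.02, -0.02, -0.04, 1) * spec$veg_density_sd  # per-band response
  dn <- spec$dn_scale
  fine_noiseless <- lapply(1:4, function(b) {
    m <- matrix(fsig[cls_idx, b], nfr, nfc)
    pmax(m * albedo + dV[b] * veg_density, 0.001) * dn
  })
  fine_bands <- lapply(fine_noiseless, function(m)
    round(pmax(m + stats::rnorm(length(m), sd = spec$fine_noise_sd * dn), 1)))
  fine_ms <- band_stack(fine_bands, fine_geom,
                        band_labels = paste0("band", 1:4))
  pf <- spec$pan_factor
  pan_geom <- grid_geometry(0, 0, fine_geom$cell_size / pf,
                            fine_geom$n_rows * pf, fine_geom$n_cols * pf)
  pw <- c(0.2, 0.35, 0.35, 0.1)  # visible-weighted pan spectral response
  pan_base <- Reduce(`+`, Map(function(b, w) w * b, fine_noiseless, pw))
  pan_vals <- pan_base[rep(seq_len(nrow(pan_base)), each = pf),
                       rep(seq_len(ncol(pan_base)), each = pf)]
  ## sub-multispectral-pixel scene texture: spatial detail the pan band
  ## resolves but the multispectral bands cannot
  texture <- norm_field(pan_geom$n_rows, pan_geom$n_cols, 3L,
                        spec$pan_texture_sd * dn)
  pan_vals <- round(pmax(pan_vals + texture +
                           stats::rnorm(length(pan_vals),
                                        sd = spec$fine_noise_sd * dn / 2), 1))
  pan <- band_stack(pan_vals, pan_geom, band_labels = "pan")

  truth_area <- n_d * cell_area_km2(coarse_geom)
  list(spec = spec, fine_ms = fine_ms, pan = pan,
       coarse_stacks = coarse_stacks,
       truth_fine = truth_fine, truth_coarse = truth_coarse,
       proportions_truth = P, truth_area_km2 = truth_area,
       manifest = list(seed = spec$seed,
                       desertified_fraction = n_d / N,
                       n_desertified_cells = n_d,
                       n_mixed_cells = length(mixed_ids),
                       truth_area_km2 = truth_area))
}

#' Coupled-logistic panel specification
#'
#' Two logistic maps coupled per site:
#' `X[t+1] = X[t] * (r_x - r_x X[t] - beta_xy Y[t])` and
#' `Y[t+1] = Y[t] * (r_y - r_y Y[t] - beta_yx X[t])`, so `beta_yx` is the
#' strength with which X forces Y. Defaults make X the strong driver
#' (`beta_yx = 0.1` vs `beta_xy = 0.02`), the standard validation system
#' for cross-mapping causality.
#'
#' @param n_sites Number of independently initialised sites (default
#'   40).
#' @param n_years Observed years per site (default 15).
#' @param r_x,r_y Logistic growth rates (defaults 3.8 and 3.5).
#' @param beta_xy Forcing of X by Y (default 0.02).
#' @param beta_yx Forcing of Y by X (default 0.1).
#' @param noise_sd Observation noise s.d. (default 0.01).
#' @param burn_in Discarded initial iterations per site (default 100).
#' @param x_name,y_name Panel column names the two variables map onto.
#' @param start_year First observed year (default 2001).
#' @param seed Integer seed.
#' @return An object of class `coupled_system_spec`.
#' @export
coupled_system_spec <- function(n_sites = 40L, n_years = 15L,
                                r_x = 3.8, r_y = 3.5,
                                beta_xy = 0.02, beta_yx = 0.1,
                                noise_sd = 0.01, burn_in = 100L,
                                x_name = "X", y_name = "Y",
                                start_year = 2001L, seed = 1L) {
  if (beta_xy < 0 || beta_yx < 0) stop("couplings must be >= 0")
  stopifnot(n_sites >= 1L, n_years >= 3L)
  structure(as.list(environment()), class = "coupled_system_spec")
}

#' Generate a coupled-logistic site panel
#'
#' Iterates the coupled system per site after burn-in, adds observation
#' noise, and returns a wide site-year panel with the variables under
#' their requested names. Errors (naming the site) if the dynamics leave
#' the unit interval.
#'
#' @param spec A [coupled_system_spec()].
#' @return `data.frame` with columns `site_id`, `year`, and the two
#'   named variables; attribute `manifest` records the true couplings
#'   and the stronger direction.
#' @export
generate_coupled_panel <- function(spec = coupled_system_spec()) {
  stopifnot(inherits(spec, "coupled_system_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_sites), function(s) {
      x <- stats::runif(1, 0.2, 0.8)
      y <- stats::runif(1, 0.2, 0.8)
      total <- spec$burn_in + spec$n_years
      xs <- numeric(spec$n_years); ys <- numeric(spec$n_years)
      for (t in seq_len(total)) {
        x_new <- x * (spec$r_x - spec$r_x * x - spec$beta_xy * y)
        y_new <- y * (spec$r_y - spec$r_y * y - spec$beta_yx * x)
        if (!is.finite(x_new) || !is.finite(y_new) ||
            x_new <= 0 || x_new >= 1 || y_new <= 0 || y_new >= 1)
          stop("coupled system left (0, 1) at site ", s,
               "; reduce growth rates or couplings")
        x <- x_new; y <- y_new
        if (t > spec$burn_in) {
          xs[t - spec$burn_in] <- x
          ys[t - spec$burn_in] <- y
        }
      }
      data.frame(site_id = s,
                 year = spec$start_year + seq_len(spec$n_years) - 1L,
                 x = xs + stats::rnorm(spec$n_years, sd = spec$noise_sd),
                 y = ys + stats::rnorm(spec$n_years, sd = spec$noise_sd))
    })
    panel <- do.call(rbind, rows)
    names(panel)[3:4] <- c(spec$x_name, spec$y_name)
    stronger <- if (spec$beta_yx > spec$beta_xy) {
      paste(spec$x_name, "->", spec$y_name)
    } else if (spec$beta_xy > spec$beta_yx) {
      paste(spec$y_name, "->", spec$x_name)
    } else "none"
    attr(panel, "manifest") <- list(
      beta_xy = spec$beta_xy, beta_yx = spec$beta_yx,
      stronger_direction = stronger, seed = spec$seed,
      causal = spec$beta_xy > 0 || spec$beta_yx > 0)
    panel
  })
}

#' Sample stratified training points from a scene's truth map
#'
#' Emulates field interpretation keys: `n_points` fine pixels sampled in
#' a stratified way over the classes present in the truth map (equal
#' shares, remainder to the earlier legend classes), carrying the fine
#' scene's band values and the true labels.
#'
#' @param scene A [generate_scene()] result.
#' @param n_points Total points (default 33; 3 classes give 11 each).
#' @param seed Integer seed.
#' @return A [training_set()] with point provenance `pt_<class>_<i>`.
#' @export
generate_training_points <- function(scene, n_points = 33L, seed = 1L) {
  lab <- scene$truth_fine$labels
  lg <- legend_codes()
  present <- names(lg)[lg %in% setdiff(unique(as.vector(lab)), 0L)]
  if (!length(present)) stop("truth map has no labelled pixels")
  k <- length(present)
  if (n_points < k) stop("need at least one point per class")
  per <- rep(n_points %/% k, k) + c(rep(1L, n_points %% k),
                                    rep(0L, k - n_points %% k))
  with_seed(seed, {
    picks <- do.call(rbind, Map(function(cl, n_cl) {
      pos <- which(lab == lg[[cl]])
      if (length(pos) < n_cl)
        stop("class '", cl, "' has fewer pixels than requested points")
      data.frame(pos = sample(pos, n_cl), class = cl,
                 id = paste0("pt_", cl, "_", seq_len(n_cl)))
    }, present, per))
    samples <- vapply(scene$fine_ms$bands, function(b) b[picks$pos],
                      numeric(nrow(picks)))
    colnames(samples) <- scene$fine_ms$band_labels
    training_set(samples, picks$class, provenance = picks$id)
  })
}
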