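## Multispatial convergent cross mapping (CCM): time-delay embedding of
## short annual series replicated over many sites, simplex-projection
## cross mapping from the pooled ("composite") library, bootstrap skill
## curves over library length, and a convergence significance test.
## If X forces Y, then Y's lagged coordinates reconstruct a shadow of the
## joint attractor and nearest neighbours on Y's manifold recover X; the
## skill of that recovery converges upward as the library grows.

#' Embedding configuration for state-space reconstruction
#'
#' @param E Embedding dimension, `>= 2`.
#' @param tau Lag in time steps, `>= 1` (1 for annual data).
#' @param tp Prediction horizon (0: concurrent cross mapping).
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(E = 2L, tau = 1L, tp = 0L) {
  E <- as.integer(E); tau <- as.integer(tau); tp <- as.integer(tp)
  if (E < 2L) stop("E must be >= 2")
  if (tau < 1L) stop("tau must be >= 1")
  structure(list(E = E, tau = tau, tp = tp), class = "embedding_config")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("<embedding_config> E = %d, tau = %d, tp = %d\n",
              x$E, x$tau, x$tp))
  invisible(x)
}

#' Time-delay embedding of one series
#'
#' Builds the lagged coordinate vectors
#' `(x_t, x_{t-tau}, ..., x_{t-(E-1)tau})` for
#' `t = (E-1)tau + 1, ..., N`.
#'
#' @param series Numeric vector of one site's observations, in time
#'   order.
#' @param cfg An [embedding_config()] (or a list with `E` and `tau`).
#' @return Matrix with `N - (E-1)tau` rows and `E` columns; attribute
#'   `t` holds the time index of each vector's leading coordinate.
#' @export
embed_series <- function(series, cfg) {
  E <- cfg$E; tau <- cfg$tau
  N <- length(series)
  span <- (E - 1L) * tau
  if (N < span + 1L)
    stop("series too short for the embedding: need N >= ", span + 1L)
  t_idx <- (span + 1L):N
  M <- vapply(0:(E - 1L), function(j) series[t_idx - j * tau],
              numeric(length(t_idx)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  attr(M, "t") <- t_idx
  M
}

## Embed one variable of a site panel; vectors never span site boundaries.
## Returns the pooled manifold plus per-vector site/time bookkeeping and
## the aligned values of a second variable at each vector's time.
embed_panel <- function(panel, var, cfg, align_var = NULL) {
  stopifnot(var %in% names(panel))
  sites <- unique(panel$site_id)
  pieces <- lapply(sites, function(s) {
    sub <- panel[panel$site_id == s, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    if (any(diff(sub$year) != 1L))
      stop("years not contiguous for site ", s)
    M <- embed_series(sub[[var]], cfg)
    t_idx <- attr(M, "t")
    list(M = M, site = rep(s, nrow(M)), t = t_idx,
         aligned = if (is.null(align_var)) NULL else sub[[align_var]][t_idx],
         next_val = c(sub[[var]][t_idx[-length(t_idx)] + 1L], NA_real_))
  })
  list(M = do.call(rbind, lapply(pieces, `[[`, "M")),
       site = unlist(lapply(pieces, `[[`, "site")),
       t = unlist(lapply(pieces, `[[`, "t")),
       aligned = if (is.null(align_var)) NULL else
         unlist(lapply(pieces, `[[`, "aligned")),
       next_val = unlist(lapply(pieces, `[[`, "next_val")))
}

## Core nearest-neighbour prediction. D: full pairwise distance matrix of
## the manifold; lib: library vector indices (possibly with repeats);
## targets: vector indices to predict at; k: number of neighbours (E+1).
## Leave-one-out: library entries equal to the target index are excluded.
## Hot path: compiled kernel; cross_map_core_r is the plain-R reference
## implementation kept for cross-checking.
cross_map_core <- function(D, values, lib, targets, k) {
  .cross_map_rho_cpp(D, as.numeric(values), as.integer(lib),
                     as.integer(targets), as.integer(k))
}

cross_map_core_r <- function(D, values, lib, targets, k) {
  pred <- rep(NA_real_, length(targets))
  lib_vals <- values[lib]
  for (i in seq_along(targets)) {
    t0 <- targets[i]
    d <- D[t0, lib]
    d[lib == t0] <- Inf
    usable <- sum(is.finite(d))
    if (usable == 0L) next
    kk <- min(k, usable)
    ord <- order(d)[seq_len(kk)]
    dk <- d[ord]
    if (dk[1L] == 0) {
      zero <- dk == 0
      w <- zero / sum(zero)          # all weight on exact matches
    } else {
      w <- exp(-dk / dk[1L])
      w <- w / sum(w)
    }
    pred[i] <- sum(w * lib_vals[ord])
  }
  ok <- !is.na(pred)
  if (sum(ok) < 3L) return(NA_real_)
  obs <- values[targets[ok]]
  if (stats::sd(obs) == 0 || stats::sd(pred[ok]) == 0) return(NA_real_)
  stats::cor(pred[ok], obs)
}

#' Simplex-projection cross mapping
#'
#' Predicts the candidate cause variable from the effect variable's
#' shadow manifold: for each target vector, the `E + 1` nearest library
#' neighbours (Euclidean) are weighted by `exp(-d_i / d_min)` (uniform
#' weights over exact matches when `d_min = 0`) and their cause values
#' averaged; skill is the Pearson correlation between predictions and
#' observed cause values over the targets. High skill cross mapping X
#' from Y's manifold is evidence that X forces Y.
#'
#' @param effect_manifold Lagged-vector matrix of the effect variable
#'   (rows = vectors), e.g. from [embed_series()].
#' @param cause_values Cause variable at each vector's time, length
#'   `nrow(effect_manifold)`.
#' @param library Row indices forming the library (repeats allowed);
#'   entries equal to a target index are excluded for that target
#'   (leave-one-out).
#' @param targets Row indices to predict at (default: all vectors).
#' @return Cross-map skill rho in `[-1, 1]`.
#' @export
simplex_cross_map <- function(effect_manifold, cause_values,
                              library = seq_len(nrow(effect_manifold)),
                              targets = seq_len(nrow(effect_manifold))) {
  M <- as.matrix(effect_manifold)
  if (length(cause_values) != nrow(M))
    stop("cause_values must align with the manifold rows")
  if (!length(library) || !length(targets))
    stop("library and targets must be nonempty")
  k <- ncol(M) + 1L
  if (length(unique(library)) < k)
    stop("library must contain at least E + 1 = ", k, " distinct vectors")
  D <- as.matrix(stats::dist(M))
  cross_map_core(D, cause_values, library, targets, k)
}

#' Choose the embedding dimension by simplex self-prediction
#'
#' For each candidate `E`, embeds the variable site by site, predicts
#' each vector's next value from its `E + 1` nearest neighbours
#' (leave-one-out over the pooled library) and scores the prediction by
#' Pearson correlation. Returns the smallest `E` attaining the maximum
#' skill. A warning is issued when even the best skill is low
#' (undistinguished dynamics, e.g. white noise).
#'
#' @param panel Wide site-year `data.frame` (`site_id`, `year`,
#'   variables), e.g. from [generate_coupled_panel()].
#' @param var Variable name to embed.
#' @param E_range Candidate embedding dimensions (default `2:4`; 15-year
#'   series cannot support more).
#' @param tau Lag (default 1).
#' @param warn_skill Skill below which the low-skill warning fires.
#' @return An [embedding_config()] with attribute `skill` (named vector
#'   of per-E self-prediction skills).
#' @export
select_embedding <- function(panel, var, E_range = 2:4, tau = 1L,
                             warn_skill = 0.2) {
  skills <- vapply(E_range, function(E) {
    cfg <- embedding_config(E, tau)
    emb <- tryCatch(embed_panel(panel, var, cfg), error = function(e) NULL)
    if (is.null(emb)) return(NA_real_)
    ok <- !is.na(emb$next_val)
    if (sum(ok) < ncol(emb$M) + 2L) return(NA_real_)
    M <- emb$M
    D <- as.matrix(stats::dist(M))
    idx <- which(ok)
    cross_map_core(D, replace(rep(NA_real_, nrow(M)), ok, emb$next_val[ok]),
                   lib = idx, targets = idx, k = E + 1L)
  }, numeric(1))
  names(skills) <- paste0("E", E_range)
  if (all(is.na(skills))) stop("no feasible embedding dimension in E_range")
  best <- E_range[which.max(replace(skills, is.na(skills), -Inf))]
  if (max(skills, na.rm = TRUE) < warn_skill)
    warning("self-prediction skill is low for every E; ",
            "the series may be undistinguished noise")
  cfg <- embedding_config(best, tau)
  attr(cfg, "skill") <- skills
  cfg
}

#' Multispatial CCM skill curve with bootstrap convergence test
#'
#' Pools the effect variable's lagged vectors across all sites into one
#' composite library, then for each library length `L` draws `n_boot`
#' bootstrap libraries of `L` vectors (with replacement; optionally whole
#' sites), cross maps the cause variable at every pooled vector, and
#' records the skill. Convergence -- skill at the longest library
#' exceeding skill at the shortest -- is the causal signal; its
#' significance comes from [convergence_test()]. Variables are z-scored
#' across the panel before embedding.
#'
#' @param panel Wide site-year `data.frame` (`site_id`, `year`, numeric
#'   variables).
#' @param cause Name of the candidate cause variable (the one being
#'   predicted).
#' @param effect Name of the candidate effect variable (the one
#'   embedded).
#' @param cfg An [embedding_config()]; `NULL` selects `E` by
#'   [select_embedding()] on the effect variable.
#' @param lengths Ascending library lengths; default an 8-point grid
#'   from `E + 2` to the pooled library size.
#' @param n_boot Bootstrap iterations per length (default 1000).
#' @param seed Optional integer seed (the global RNG state is restored
#'   afterwards).
#' @param resample `"vectors"` (default) resamples pooled vectors;
#'   `"sites"` resamples whole sites.
#' @return An object of class `ccm_result`: list with `direction`,
#'   `cfg`, `library_lengths`, `rho_mean`, `rho_sd`, `rho_full`
#'   (deterministic leave-one-out skill at full library), `rho_boot`
#'   (list of bootstrap draws per length), `n_boot`, `p_value`.
#' @export
ccm_curve <- function(panel, cause, effect, cfg = NULL, lengths = NULL,
                      n_boot = 1000L, seed = NULL,
                      resample = c("vectors", "sites")) {
  resample <- match.arg(resample)
  stopifnot(cause %in% names(panel), effect %in% names(panel))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pz <- panel
  for (v in setdiff(names(pz), c("site_id", "year")))
    pz[[v]] <- as.numeric(scale(pz[[v]]))
  if (is.null(cfg)) cfg <- select_embedding(pz, effect)
  emb <- embed_panel(pz, effect, cfg, align_var = cause)
  n <- nrow(emb$M)
  k <- cfg$E + 1L
  if (n < k + 2L) stop("insufficient pooled vectors (", n, ") for E = ", cfg$E)
  if (is.null(lengths))
    lengths <- unique(round(seq(cfg$E + 2L, n, length.out = 8L)))
  lengths <- sort(unique(as.integer(lengths)))
  if (max(lengths) > n)
    stop("library length ", max(lengths), " exceeds pool size ", n)
  D <- as.matrix(stats::dist(emb$M))
  cause_v <- emb$aligned
  targets <- seq_len(n)
  site_of <- emb$site
  site_levels <- unique(site_of)
  site_members <- split(targets, site_of)
  boot_lib <- function(L) {
    if (resample == "vectors") {
      sample.int(n, L, replace = TRUE)
    } else {
      lib <- integer(0)
      while (length(lib) < L) {
        s <- sample(site_levels, 1L)
        lib <- c(lib, site_members[[as.character(s)]])
      }
      lib[seq_len(L)]
    }
  }
  rho_boot <- lapply(lengths, function(L) {
    vapply(seq_len(n_boot), function(b) {
      cross_map_core(D, cause_v, boot_lib(L), targets, k)
    }, numeric(1))
  })
  names(rho_boot) <- as.character(lengths)
  rho_full <- cross_map_core(D, cause_v, targets, targets, k)
  p <- convergence_test(rho_boot[[1L]], rho_boot[[length(rho_boot)]])
  structure(list(direction = c(cause = cause, effect = effect),
                 cfg = cfg, library_lengths = lengths,
                 rho_mean = vapply(rho_boot, mean, numeric(1), na.rm = TRUE),
                 rho_sd = vapply(rho_boot, stats::sd, numeric(1), na.rm = TRUE),
                 rho_full = rho_full, rho_boot = rho_boot,
                 n_boot = as.integer(n_boot), p_value = p),
            class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf("<ccm_result> does '%s' force '%s'? (cross map '%s' from M_%s)\n",
              x$direction[["cause"]], x$direction[["effect"]],
              x$direction[["cause"]], x$direction[["effect"]]))
  cat(sprintf("  E = %d, tau = %d, %d bootstrap iterations\n",
              x$cfg$E, x$cfg$tau, x$n_boot))
  tab <- data.frame(L = x$library_lengths, rho_mean = round(x$rho_mean, 3),
                    rho_sd = round(x$rho_sd, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("  full-library rho = %.3f, convergence p = %.4g\n",
              x$rho_full, x$p_value))
  invisible(x)
}

#' Bootstrap convergence significance test
#'
#' `p` is the fraction of paired bootstrap iterations in which the skill
#' at the longest library does not exceed the skill at the shortest:
#' small `p` is evidence that cross-map skill increases with library
#' length, the convergence property that distinguishes causal forcing
#' from mere correlation.
#'
#' @param rhos_at_lmin,rhos_at_lmax Equal-length vectors of bootstrap
#'   skill draws at the shortest and longest library lengths.
#' @return p-value in `[0, 1]`.
#' @export
convergence_test <- function(rhos_at_lmin, rhos_at_lmax) {
  if (length(rhos_at_lmin) != length(rhos_at_lmax))
    stop("need equal numbers of bootstrap draws at both lengths")
  ok <- !is.na(rhos_at_lmin) & !is.na(rhos_at_lmax)
  n <- sum(ok)
  if (n < 100L)
    warning("fewer than 100 usable bootstrap pairs; p-value is unstable")
  if (n == 0L) return(NA_real_)
  mean(rhos_at_lmax[ok] <= rhos_at_lmin[ok])
}

#' Export a CCM skill curve as a data frame
#'
#' @param x A `ccm_result`.
#' @param ... Unused.
#' @return `data.frame` with columns `cause`, `effect`, `L`, `rho_mean`,
#'   `rho_sd`.
#' @export
as.data.frame.ccm_result <- function(x, ...) {
  data.frame(cause = x$direction[["cause"]], effect = x$direction[["effect"]],
             L = x$library_lengths, rho_mean = unname(x$rho_mean),
             rho_sd = unname(x$rho_sd))
}
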