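## Shared fixtures. The small scene is generated once per test run and
## reused read-only across files.

tiny_geom <- function(nr = 2, nc = 2, cell = 1000, origin = c(0, 0)) {
  grid_geometry(origin[1], origin[2], cell, nr, nc)
}

tiny_stack <- function(..., cell = 1000, labels = NULL) {
  bands <- list(...)
  g <- tiny_geom(nrow(bands[[1]]), ncol(bands[[1]]), cell)
  band_stack(bands, g, band_labels = labels)
}

.scene_cache <- new.env(parent = emptyenv())

small_scene <- function() {
  if (is.null(.scene_cache$scene))
    .scene_cache$scene <- generate_scene(
      scene_spec(coarse_n_rows = 20, coarse_n_cols = 20, seed = 7))
  .scene_cache$scene
}

small_panel <- function() {
  if (is.null(.scene_cache$panel))
    .scene_cache$panel <- generate_coupled_panel(coupled_system_spec(seed = 7))
  .scene_cache$panel
}

## truth-based linkage: frame with proportions from the truth map
small_scene_frame <- function() {
  if (is.null(.scene_cache$frame)) {
    sc <- small_scene()
    frame <- build_grid_frame(sc$fine_ms$geometry,
                              sc$coarse_stacks[[1]]$geometry$cell_size)
    .scene_cache$frame <- class_proportions(sc$truth_fine, frame)
  }
  .scene_cache$frame
}
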