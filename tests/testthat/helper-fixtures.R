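# Fixtures are built in code: small count matrices with known structure.

# A reference with strongly on/off ("binary") planted markers: each type's
# markers are highly expressed in that type and (almost) silent elsewhere,
# on top of a shared expressed background.
make_onoff_reference <- function(n_types = 3, markers_per_type = 8,
                                 cells_per_type = 40, n_background = 30,
                                 marker_count = 300, background_count = 50,
                                 seed = 1) {
  set.seed(seed)
  types <- paste0("T", seq_len(n_types))
  marker_ids <- as.vector(vapply(types, function(ty) {
    sprintf("mk_%s_%02d", ty, seq_len(markers_per_type))
  }, character(markers_per_type)))
  owner <- rep(types, each = markers_per_type)
  bg_ids <- sprintf("bg_%03d", seq_len(n_background))
  gene_ids <- c(marker_ids, bg_ids)
  cell_ids <- as.vector(vapply(types, function(ty) {
    sprintf("c_%s_%03d", ty, seq_len(cells_per_type))
  }, character(cells_per_type)))
  cell_type <- rep(types, each = cells_per_type)

  counts <- matrix(0L, length(gene_ids), length(cell_ids),
                   dimnames = list(gene_ids, cell_ids))
  for (j in seq_along(cell_ids)) {
    mu <- c(ifelse(owner == cell_type[j], marker_count, 0.02),
            rep(background_count, n_background))
    counts[, j] <- rnbinom(length(mu), size = 1 / 0.3, mu = mu)
  }
  list(
    counts = counts,
    annotations = tibble::tibble(column_id = cell_ids, group = cell_type,
                                 condition = NA_character_),
    truth = tibble::tibble(cell_type = owner, gene_id = marker_ids)
  )
}

# Tiny simulation config used across tests (kept small for speed).
tiny_sim_config <- function(...) {
  sim_config(n_genes = 300, n_de = 45, n_per_arm = 5, markers_per_type = 20,
             ref_cells_per_type = 60, ...)
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)
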