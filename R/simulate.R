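## Synthetic sctRNA-seq generator: negative-binomial counts with known DE
## truth, planted cell-type identities (appended marker profiles), and
## tunable, optionally condition-confounded contamination.

#' Simulation configuration
#'
#' Collects all generator parameters with the package defaults: 20,000
#' genes of which 3,000 are differentially expressed, 2 clusters (cell
#' types), 2 conditions with 10 samples per cluster and arm, 50 markers
#' per type, mean absolute log2 fold change 1.5.  Contamination fractions
#' per scenario: `low` draws alpha from N(0.12, 0.03), `high` from
#' N(0.30, 0.05); confounding `low` shifts the case-arm mean by +0.05,
#' `high` uses case N(0.35, 0.05) vs control N(0.10, 0.03); all draws are
#' truncated to `[0, 0.95]`.
#'
#' @param n_genes Number of base (non-marker) genes.
#' @param n_de Number of differentially expressed genes among them.
#' @param n_types Number of simulated clusters / reference cell types.
#' @param n_per_arm Samples per cluster per condition.
#' @param markers_per_type Marker genes appended per type.
#' @param mean_log2_fc Mean absolute log2 fold change of DE genes; the
#'   per-gene magnitude is truncated normal with sd `0.25 * mean_log2_fc`
#'   and random sign.
#' @param contamination One of `"none"`, `"low"`, `"high"`.
#' @param confound One of `"none"`, `"low"`, `"high"`.
#' @param nb_dispersion Baseline NB dispersion; the per-gene value is
#'   `nb_dispersion + 1/mu`.
#' @param inter_sd SD (log2) of per-cluster deviations of base-gene means:
#'   the "inter-cluster noise" that makes cluster profiles differ.
#' @param intra_sd SD (log2) of per-sample biological jitter applied to
#'   expected means ("intra-cluster noise").
#' @param library_size Expected library size of test samples.
#' @param marker_base_range,marker_boost_range Ranges (log2(1+CPM)) of the
#'   shared baseline expression of marker genes and of the own-type boost.
#' @param ref_cells_per_type,ref_library_size,ref_dispersion Size, depth
#'   and NB dispersion of the generated single-cell reference.
#' @param mean_log2_mu,sd_log2_mu Parameters of the log-normal base-gene
#'   mean distribution (`log2 mu ~ N(mean, sd)`).
#' @param alpha_params Optional explicit contamination parameters: a list
#'   with elements `case` and `control`, each `c(mean, sd)`, overriding
#'   the scenario presets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000L, n_de = 3000L, n_types = 2L,
                       n_per_arm = 10L, markers_per_type = 50L,
                       mean_log2_fc = 1.5,
                       contamination = c("none", "low", "high"),
                       confound = c("none", "low", "high"),
                       nb_dispersion = 0.2, inter_sd = 2, intra_sd = 0.3,
                       library_size = 2e6,
                       marker_base_range = c(0, 8),
                       marker_boost_range = c(2, 4),
                       ref_cells_per_type = 200L, ref_library_size = 1e6,
                       ref_dispersion = 0.5,
                       mean_log2_mu = 4, sd_log2_mu = 2,
                       alpha_params = NULL) {
  contamination <- match.arg(contamination)
  confound <- match.arg(confound)
  if (n_de < 0 || n_de > n_genes) abort("need 0 <= n_de <= n_genes")
  if (n_types < 2) abort("need at least 2 types")
  stopifnot(n_genes > 0, n_per_arm > 0, markers_per_type > 0,
            library_size > 0, nb_dispersion >= 0, inter_sd >= 0,
            intra_sd >= 0, mean_log2_fc > 0)
  structure(
    list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
         n_types = as.integer(n_types), n_per_arm = as.integer(n_per_arm),
         markers_per_type = as.integer(markers_per_type),
         mean_log2_fc = mean_log2_fc, contamination = contamination,
         confound = confound, nb_dispersion = nb_dispersion,
         inter_sd = inter_sd, intra_sd = intra_sd,
         library_size = library_size,
         marker_base_range = marker_base_range,
         marker_boost_range = marker_boost_range,
         ref_cells_per_type = as.integer(ref_cells_per_type),
         ref_library_size = ref_library_size,
         ref_dispersion = ref_dispersion,
         mean_log2_mu = mean_log2_mu, sd_log2_mu = sd_log2_mu,
         alpha_params = alpha_params),
    class = "sim_config")
}

.scenario_alpha_params <- function(contamination, confound) {
  if (contamination == "none") {
    return(list(case = c(0, 0), control = c(0, 0)))
  }
  base <- switch(contamination, low = c(0.12, 0.03), high = c(0.30, 0.05))
  switch(confound,
         none = list(case = base, control = base),
         low = list(case = c(base[1] + 0.05, base[2]), control = base),
         high = list(case = c(0.35, 0.05), control = c(0.10, 0.03)))
}

.rtrunc_norm <- function(n, mean, sd, lower = 0, upper = 0.95) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

## NB draw that degrades gracefully to Poisson as dispersion -> 0
.rnb <- function(n, mu, phi) {
  out <- numeric(n)
  tiny <- phi < 1e-8
  if (any(tiny)) out[tiny] <- rpois(sum(tiny), mu[tiny])
  if (any(!tiny)) out[!tiny] <- rnbinom(sum(!tiny), size = 1 / phi[!tiny], mu = mu[!tiny])
  out
}

## Draw a counts matrix column-by-column around expected CPM profiles.
## profile_cpm: genes x columns expected CPM (each column sums to 1e6);
## jitter_sd applies per-gene, per-column log2-normal biological noise.
.draw_counts <- function(profile_cpm, library_size, dispersion, jitter_sd = 0) {
  n_genes <- nrow(profile_cpm)
  out <- matrix(0, n_genes, ncol(profile_cpm), dimnames = dimnames(profile_cpm))
  for (j in seq_len(ncol(profile_cpm))) {
    mu <- profile_cpm[, j] * library_size / 1e6
    if (jitter_sd > 0) mu <- mu * 2^rnorm(n_genes, 0, jitter_sd)
    out[, j] <- .rnb(n_genes, mu, dispersion)
  }
  out
}

.norm_cpm <- function(w) sweep(w, 2, colSums(w), "/") * 1e6

.profile_col <- function(type, condition) paste(type, condition, sep = ".")

#' Simulate baseline counts with known DE truth
#'
#' Draws per-gene baseline means from a log-normal (`log2 mu ~ N(4, 2)` by
#' default), marks `n_de` genes as differentially expressed with truncated
#' normal log2 fold-change magnitudes and random sign (the case-condition
#' mean is multiplied by `2^(+-lfc)` in every cluster), gives every cluster
#' its own deviation of each gene's mean (`2^N(0, inter_sd)`, the
#' inter-cluster noise), and draws negative-binomial counts at the
#' configured library size with per-gene dispersion `nb_dispersion + 1/mu`
#' plus per-sample log-normal jitter (`intra_sd`).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `sct_sim` with elements `counts` (genes x
#'   samples), `gene_truth`, `sample_truth`, `profiles` (expected CPM per
#'   type x condition), `annotations` and `config`.
#' @export
simulate_base_counts <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  types <- sprintf("type%d", seq_len(cfg$n_types))
  conditions <- c("case", "control")

  mu <- 2^rnorm(cfg$n_genes, cfg$mean_log2_mu, cfg$sd_log2_mu)
  dispersion <- cfg$nb_dispersion + 1 / mu

  is_de <- rep(FALSE, cfg$n_genes)
  log2_fc <- rep(0, cfg$n_genes)
  if (cfg$n_de > 0) {
    de_idx <- sample.int(cfg$n_genes, cfg$n_de)
    is_de[de_idx] <- TRUE
    mag <- rnorm(cfg$n_de, cfg$mean_log2_fc, 0.25 * cfg$mean_log2_fc)
    while (any(mag <= 0)) {
      mag[mag <= 0] <- rnorm(sum(mag <= 0), cfg$mean_log2_fc, 0.25 * cfg$mean_log2_fc)
    }
    log2_fc[de_idx] <- mag * sample(c(-1, 1), cfg$n_de, replace = TRUE)
  }

  ## inter-cluster noise: per-cluster deviation of every base gene
  eps <- matrix(rnorm(cfg$n_genes * cfg$n_types, 0, cfg$inter_sd),
                cfg$n_genes, cfg$n_types, dimnames = list(gene_ids, types))

  ## expected (unnormalized) weights per type x condition
  prof <- matrix(0, cfg$n_genes, cfg$n_types * 2,
                 dimnames = list(gene_ids,
                                 as.vector(outer(types, conditions, .profile_col))))
  for (ty in types) {
    base_w <- mu * 2^eps[, ty]
    prof[, .profile_col(ty, "control")] <- base_w
    prof[, .profile_col(ty, "case")] <- base_w * 2^log2_fc
  }
  prof <- .norm_cpm(prof)

  sample_truth <- tidyr::expand_grid(cluster = types, condition = conditions,
                                     rep = seq_len(cfg$n_per_arm)) |>
    dplyr::mutate(sample_id = sprintf("s_%s_%s_%02d", .data$cluster,
                                      .data$condition, .data$rep),
                  alpha = 0) |>
    dplyr::select("sample_id", "cluster", "condition", "alpha")
  sample_truth$contaminant_weights <- rep(list(setNames(numeric(0), character(0))),
                                          nrow(sample_truth))

  sample_cpm <- prof[, .profile_col(sample_truth$cluster, sample_truth$condition),
                     drop = FALSE]
  colnames(sample_cpm) <- sample_truth$sample_id
  counts <- .draw_counts(sample_cpm, cfg$library_size, dispersion, cfg$intra_sd)

  gene_truth <- tibble(gene_id = gene_ids, is_de = is_de, log2_fc = log2_fc,
                       marker_of = NA_character_, mu = mu,
                       dispersion = dispersion)
  annotations <- tibble(column_id = sample_truth$sample_id,
                        group = sample_truth$cluster,
                        condition = sample_truth$condition)
  structure(list(counts = counts, gene_truth = gene_truth,
                 sample_truth = sample_truth, profiles = prof,
                 annotations = annotations, config = cfg),
            class = "sct_sim")
}

#' Append cell-type identities (marker profiles)
#'
#' Adds marker genes to a simulated dataset so that each cluster carries
#' the expression signature of its reference cell type.  By default the
#' marker centroids are designed in-package: each marker gene gets a
#' shared baseline log2(1+CPM) drawn from `marker_base_range` (identical
#' across types, emulating the graded, correlated expression of real
#' marker genes across related cell types) plus an own-type boost from
#' `marker_boost_range`.  Marker counts are drawn around the own-cluster
#' centroid converted back to CPM (`2^centroid - 1`), so that before noise
#' and contamination a cluster's marker vector correlates with its own
#' centroid at r = 1.  Marker genes are never differentially expressed.
#'
#' @param sim An `sct_sim` from [simulate_base_counts()].
#' @param marker_centroids Optional designed centroid matrix
#'   (log2(1+CPM), marker genes x types) replacing the built-in design;
#'   its gene ids must not collide with the base genes.
#' @param seed Optional integer seed.
#' @return The extended `sct_sim`: marker rows appended to `counts`,
#'   `gene_truth` and `profiles`; elements `markers` (tibble `cell_type`,
#'   `gene_id`) and `marker_centroids` added.
#' @export
attach_identity <- function(sim, marker_centroids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(sim, "sct_sim"))
  cfg <- sim$config
  types <- sprintf("type%d", seq_len(cfg$n_types))

  if (is.null(marker_centroids)) {
    n_mark <- cfg$markers_per_type * cfg$n_types
    marker_ids <- as.vector(vapply(types, function(ty) {
      sprintf("marker_%s_%02d", ty, seq_len(cfg$markers_per_type))
    }, character(cfg$markers_per_type)))
    owner <- rep(types, each = cfg$markers_per_type)
    base <- runif(n_mark, cfg$marker_base_range[1], cfg$marker_base_range[2])
    boost <- runif(n_mark, cfg$marker_boost_range[1], cfg$marker_boost_range[2])
    marker_centroids <- matrix(base, n_mark, cfg$n_types,
                               dimnames = list(marker_ids, types))
    marker_centroids[cbind(seq_len(n_mark), match(owner, types))] <-
      base + boost
  } else {
    marker_ids <- rownames(marker_centroids)
    owner <- colnames(marker_centroids)[apply(marker_centroids, 1, which.max)]
  }
  collide <- intersect(marker_ids, rownames(sim$counts))
  if (length(collide)) {
    abort(sprintf("marker gene id(s) collide with base genes: %s",
                  paste(head(collide, 3), collapse = ", ")))
  }

  ## marker expected CPM per type (condition-independent: markers not DE)
  marker_w <- 2^marker_centroids - 1
  prof_new <- rbind(
    sim$profiles,
    marker_w[, sub("\\..*$", "", colnames(sim$profiles)), drop = FALSE]
  )
  prof_new <- .norm_cpm(prof_new)

  marker_mu_own <- marker_w[cbind(seq_along(marker_ids), match(owner, types))]
  marker_disp <- cfg$nb_dispersion + 1 / pmax(marker_mu_own, 0.1)

  ## draw marker counts around the sample's own-cluster profile
  st <- sim$sample_truth
  marker_cpm <- prof_new[marker_ids,
                         .profile_col(st$cluster, st$condition), drop = FALSE]
  colnames(marker_cpm) <- st$sample_id
  marker_counts <- .draw_counts(marker_cpm, cfg$library_size, marker_disp,
                                cfg$intra_sd)

  sim$counts <- rbind(sim$counts, marker_counts)
  sim$profiles <- prof_new
  sim$gene_truth <- dplyr::bind_rows(
    sim$gene_truth,
    tibble(gene_id = marker_ids, is_de = FALSE, log2_fc = 0,
           marker_of = owner, mu = marker_mu_own, dispersion = marker_disp)
  )
  sim$markers <- tibble(cell_type = owner, gene_id = marker_ids)
  sim$marker_centroids <- marker_centroids
  sim
}

#' Assign per-sample contamination fractions
#'
#' Draws each sample's contamination fraction alpha from the scenario's
#' truncated normal distribution: identical in both arms when `confound`
#' is `"none"`, shifted or separated between case and control otherwise
#' (see [sim_config()]).  Contaminant weights default to an equal split of
#' alpha across the other clusters.
#'
#' @param sim An `sct_sim`.
#' @param contamination,confound Scenario levels; default to the values in
#'   the simulation's config.
#' @param alpha Optional explicit per-sample alpha vector (recycled),
#'   overriding the scenario draw.
#' @param seed Optional integer seed.
#' @return The `sct_sim` with `sample_truth$alpha` and
#'   `sample_truth$contaminant_weights` filled in.
#' @export
assign_alpha <- function(sim, contamination = NULL, confound = NULL,
                         alpha = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(sim, "sct_sim"))
  cfg <- sim$config
  st <- sim$sample_truth
  if (is.null(alpha)) {
    contamination <- contamination %||% cfg$contamination
    confound <- confound %||% cfg$confound
    pars <- cfg$alpha_params %||% .scenario_alpha_params(contamination, confound)
    a <- numeric(nrow(st))
    for (cond in c("case", "control")) {
      rows <- st$condition == cond
      a[rows] <- .rtrunc_norm(sum(rows), pars[[cond]][1], pars[[cond]][2])
    }
  } else {
    a <- pmin(pmax(rep_len(alpha, nrow(st)), 0), 0.95)
  }
  st$alpha <- a
  types <- sprintf("type%d", seq_len(cfg$n_types))
  st$contaminant_weights <- lapply(seq_len(nrow(st)), function(i) {
    others <- setdiff(types, st$cluster[i])
    setNames(rep(st$alpha[i] / length(others), length(others)), others)
  })
  sim$sample_truth <- st
  sim
}

#' Apply mixture contamination to simulated samples
#'
#' For every sample with alpha > 0, replaces its counts by a fresh
#' negative-binomial draw around the mixed expected profile
#' `(1 - alpha) * own + sum(w_c * profile_c)` (contaminant profiles taken
#' at the sample's condition), at the sample's library size and the same
#' per-gene dispersions.  Samples with alpha = 0 keep their pure draw, so
#' alpha = 0 reproduces the pure expectation.
#'
#' @param sim An `sct_sim` whose alphas have been assigned.
#' @param seed Optional integer seed.
#' @return The `sct_sim` with contaminated `counts`.
#' @export
apply_contamination <- function(sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(sim, "sct_sim"))
  cfg <- sim$config
  st <- sim$sample_truth
  disp <- sim$gene_truth$dispersion[match(rownames(sim$counts),
                                          sim$gene_truth$gene_id)]
  for (i in seq_len(nrow(st))) {
    a <- st$alpha[i]
    if (a <= 0) next
    w <- st$contaminant_weights[[i]]
    if (abs(sum(w) - a) > 1e-8) {
      abort(sprintf("sample '%s': contaminant weights sum to %.4f, not alpha = %.4f",
                    st$sample_id[i], sum(w), a))
    }
    own <- sim$profiles[, .profile_col(st$cluster[i], st$condition[i])]
    mixed <- (1 - a) * own
    for (ty in names(w)) {
      mixed <- mixed + w[[ty]] * sim$profiles[, .profile_col(ty, st$condition[i])]
    }
    mu <- mixed * cfg$library_size / 1e6
    if (cfg$intra_sd > 0) mu <- mu * 2^rnorm(length(mu), 0, cfg$intra_sd)
    sim$counts[, st$sample_id[i]] <- .rnb(length(mu), mu, disp)
  }
  sim
}

## Generate the single-cell reference for the simulated types and derive
## the reference products (centroids, expected correlations) through the
## same pipeline used for real data.
.simulate_reference <- function(sim) {
  cfg <- sim$config
  types <- sprintf("type%d", seq_len(cfg$n_types))
  cell_ids <- as.vector(vapply(types, function(ty) {
    sprintf("cell_%s_%03d", ty, seq_len(cfg$ref_cells_per_type))
  }, character(cfg$ref_cells_per_type)))
  cell_types <- rep(types, each = cfg$ref_cells_per_type)
  ## reference cells are condition-free: control (baseline) profiles
  ref_cpm <- sim$profiles[, .profile_col(cell_types, "control"), drop = FALSE]
  colnames(ref_cpm) <- cell_ids
  disp <- cfg$ref_dispersion +
    1 / pmax(sim$gene_truth$mu[match(rownames(ref_cpm), sim$gene_truth$gene_id)], 0.1)
  counts <- .draw_counts(ref_cpm, cfg$ref_library_size, disp)
  annotations <- tibble(column_id = cell_ids, group = cell_types,
                        condition = NA_character_)
  list(counts = counts, annotations = annotations)
}

#' Simulate a complete sctRNA-seq experiment
#'
#' Runs the full generator: baseline counts with DE truth
#' ([simulate_base_counts()]), planted cell identities
#' ([attach_identity()]), scenario contamination ([assign_alpha()],
#' [apply_contamination()]), plus a matched single-cell reference from
#' which centroids and expected correlations are derived with the standard
#' reference pipeline.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @param alpha Optional explicit per-sample contamination fractions
#'   (recycled over samples), overriding the scenario draw.
#' @return An `sct_sim` list: `counts`, `annotations`, `gene_truth`,
#'   `sample_truth`, `markers`, `marker_centroids`, `profiles`,
#'   `reference` (list of `counts`, `annotations`), `centroids`
#'   (reference-derived), `expected` (expected-correlation tibble),
#'   `config`.
#' @export
simulate_sct <- function(config = sim_config(), seed = NULL, alpha = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_base_counts(config)
  sim <- attach_identity(sim)
  sim <- assign_alpha(sim, alpha = alpha)
  sim <- apply_contamination(sim)
  sim$reference <- .simulate_reference(sim)
  sim$centroids <- compute_centroids(sim$reference$counts, sim$reference$annotations)
  sim$expected <- expected_correlations(sim$reference$counts,
                                        sim$reference$annotations,
                                        sim$markers, sim$centroids,
                                        n_cells_per_type = 100L)
  sim
}

#' @export
print.sct_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated sctRNA-seq dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  %d clusters, %d samples/arm, %d DE genes, %d markers/type\n",
              cfg$n_types, cfg$n_per_arm, cfg$n_de, cfg$markers_per_type))
  cat(sprintf("  contamination: %s, confound: %s; mean alpha = %.3f\n",
              cfg$contamination, cfg$confound, mean(x$sample_truth$alpha)))
  invisible(x)
}
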