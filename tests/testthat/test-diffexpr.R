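test_that("prefilter implements the strict more-than-half zero rule", {
  cond <- rep(c("case", "control"), each = 4)
  counts <- rbind(
    drop_me = c(0L, 0L, 0L, 5L, 4L, 6L, 3L, 7L),   # 3 of 4 zeros in case
    keep_half = c(0L, 0L, 2L, 3L, 0L, 0L, 4L, 5L), # exactly half per arm
    keep_full = c(5L, 6L, 4L, 8L, 9L, 3L, 7L, 2L)
  )
  colnames(counts) <- sprintf("s%d", 1:8)
  out <- prefilter_genes(counts, cond)
  expect_identical(rownames(out), c("keep_half", "keep_full"))
  expect_identical(attr(out, "n_removed"), 1L)
  all_zero <- matrix(0L, 2, 8, dimnames = list(c("a", "b"), colnames(counts)))
  expect_error(prefilter_genes(all_zero, cond), "every gene")
  expect_error(prefilter_genes(counts, rep(c("case", "control"), c(7, 1))),
               "2 samples")
})

test_that("the NB GLM recovers a planted fold change", {
  set.seed(101)
  n <- 10
  design <- cbind(condition = rep(c(0, 1), each = n))
  mu <- c(rep(100, n), rep(400, n))  # 4-fold, log2 fc = 2
  y <- rnbinom(2 * n, mu = mu, size = 1 / 0.05)
  fit <- fit_nb_glm(y, design)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficient - 2), 3 * fit$se)
  expect_lt(fit$wald_p, 1e-4)
})

test_that("the NB GLM agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(102)
  n <- 15
  design <- cbind(condition = rep(c(0, 1), each = n),
                  cov = rnorm(2 * n))
  y <- rnbinom(2 * n, mu = exp(4 + 0.8 * design[, 1] + 0.3 * design[, 2]),
               size = 1 / 0.15)
  fit <- fit_nb_glm(y, design)
  oracle <- MASS::glm.nb(y ~ design)
  expect_equal(fit$coefficient * log(2), unname(coef(oracle)[2]),
               tolerance = 1e-3)
  expect_equal(fit$dispersion, 1 / oracle$theta, tolerance = 0.05)
  expect_equal(fit$loglik, as.numeric(stats::logLik(oracle)), tolerance = 1e-4)
})

test_that("NB Wald p-values are calibrated under the null", {
  set.seed(103)
  n <- 50
  design <- cbind(condition = rep(c(0, 1), each = n))
  p <- vapply(1:1000, function(i) {
    y <- rnbinom(2 * n, mu = 100, size = 1 / 0.1)
    fit_nb_glm(y, design)$wald_p
  }, numeric(1))
  rej <- mean(p < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rej, 0.05 - half)
  expect_lt(rej, 0.05 + half)
})

test_that("degenerate genes and designs are flagged, not fitted", {
  design <- cbind(condition = rep(c(0, 1), each = 4))
  out <- fit_nb_glm(rep(0L, 8), design)
  expect_false(out$converged)
  expect_equal(out$wald_p, 1)
  # collinear design (duplicate column) cannot be fitted
  out2 <- fit_nb_glm(rpois(8, 10), cbind(design, design[, 1]))
  expect_false(out2$converged)
})

test_that("run_de with degenerate covariates equals the plain model", {
  cfg <- sim_config(n_genes = 120, n_de = 20, n_per_arm = 6,
                    markers_per_type = 5, ref_cells_per_type = 10)
  sim <- simulate_base_counts(cfg, seed = 55)
  st <- sim$sample_truth
  in1 <- st$sample_id[st$cluster == "type1"]
  ann <- tibble::tibble(column_id = in1,
                        condition = st$condition[match(in1, st$sample_id)])
  cts <- sim$counts[seq_len(cfg$n_genes), in1]
  plain <- run_de(cts, ann)
  zero_cov <- tibble::tibble(sample_id = in1, junk = 0)
  expect_warning(same <- run_de(cts, ann, covariates = zero_cov),
                 "zero-variance")
  expect_equal(tidy(same), tidy(plain))
})

test_that("run_de is invariant to sample order and prunes collinearity", {
  cfg <- sim_config(n_genes = 100, n_de = 15, n_per_arm = 6,
                    markers_per_type = 5, ref_cells_per_type = 10)
  sim <- simulate_base_counts(cfg, seed = 56)
  st <- sim$sample_truth
  in1 <- st$sample_id[st$cluster == "type1"]
  ann <- tibble::tibble(column_id = in1,
                        condition = st$condition[match(in1, st$sample_id)])
  cts <- sim$counts[seq_len(cfg$n_genes), in1]
  de1 <- run_de(cts, ann)
  perm <- sample(length(in1))
  de2 <- run_de(cts[, perm], ann[perm, ])
  expect_equal(de1$wald_p, de2$wald_p, tolerance = 1e-8)
  # a duplicated covariate is pruned, keeping the higher-ranked column
  set.seed(1)
  cov <- tibble::tibble(sample_id = in1, first = rnorm(12))
  cov$shadow <- cov$first * 1.0000001
  expect_warning(de3 <- run_de(cts, ann, covariates = cov), "higher-ranked")
  expect_identical(attr(de3, "model_spec"), c("condition", "first"))
})

test_that("q-values are BH-monotone and call sets are nested in the FDR", {
  cfg <- sim_config(n_genes = 150, n_de = 30, n_per_arm = 8,
                    markers_per_type = 5, ref_cells_per_type = 10)
  sim <- simulate_base_counts(cfg, seed = 57)
  st <- sim$sample_truth
  in1 <- st$sample_id[st$cluster == "type1"]
  ann <- tibble::tibble(column_id = in1,
                        condition = st$condition[match(in1, st$sample_id)])
  de <- run_de(sim$counts[seq_len(cfg$n_genes), in1], ann)
  ord <- order(de$wald_p)
  expect_true(all(diff(de$q_value[ord]) >= -1e-12))
  expect_true(all(de$q_value >= de$wald_p - 1e-12))
  calls05 <- de$gene_id[de$q_value < 0.05]
  calls10 <- de$gene_id[de$q_value < 0.10]
  expect_true(all(calls05 %in% calls10))
})

test_that("AIC comparison uses strict improvement and shared genes", {
  de <- tibble::tibble(gene_id = c("a", "b", "c"), aic = c(10, 20, 30),
                       converged = TRUE)
  expect_equal(as.numeric(compare_models_aic(de, de)), 0)
  better <- dplyr::mutate(de, aic = aic - c(1, 0, 1))
  expect_equal(as.numeric(compare_models_aic(better, de)), 2 / 3)
  other <- dplyr::mutate(de, gene_id = c("x", "y", "z"))
  expect_error(compare_models_aic(de, other), "shared")
})

test_that("a pure-noise covariate is preferred by AIC at the chi-square rate", {
  # nested models differing by one unrelated covariate: delta AIC = 2 - X^2(1),
  # so the covariate model wins with probability P(X^2(1) > 2) ~ 0.157
  set.seed(104)
  n <- 30
  cond <- rep(c(0, 1), each = n)
  noise <- rnorm(2 * n)
  wins <- vapply(1:600, function(i) {
    y <- rnbinom(2 * n, mu = 80, size = 1 / 0.15)
    with_cov <- fit_nb_glm(y, cbind(condition = cond, noise = noise))
    without <- fit_nb_glm(y, cbind(condition = cond))
    as.numeric(with_cov$aic < without$aic)
  }, numeric(1))
  expect_gt(mean(wins), 0.10)
  expect_lt(mean(wins), 0.23)
})

test_that("a covariate tracking a planted confounder is preferred by AIC", {
  # contamination-like setting: log-mean depends on a per-sample exposure
  # that is correlated with condition; the exposure enters as a covariate
  set.seed(105)
  n <- 12
  cond <- rep(c(0, 1), each = n)
  exposure <- runif(2 * n, 0, 0.6) + 0.25 * cond
  wins <- vapply(1:150, function(i) {
    slope <- rnorm(1, 0, 1.5)
    y <- rnbinom(2 * n, mu = exp(4 + slope * exposure), size = 1 / 0.1)
    with_cov <- fit_nb_glm(y, cbind(condition = cond, exposure = exposure))
    without <- fit_nb_glm(y, cbind(condition = cond))
    as.numeric(with_cov$aic < without$aic)
  }, numeric(1))
  expect_gt(mean(wins), 0.5)
})

test_that("evaluation metrics match the hand-worked four-gene example", {
  result <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    wald_p = c(0.01, 0.2, 0.05, 0.9),
    q_value = p.adjust(c(0.01, 0.2, 0.05, 0.9), "BH")
  )
  truth <- tibble::tibble(gene_id = paste0("g", 1:4),
                          is_de = c(TRUE, TRUE, FALSE, FALSE))
  # at this threshold the called set is {g1, g3}: tp = 1, fp = 1, fn = 1
  m <- evaluate_calls(result, truth, fdr = 0.15)
  expect_equal(m$fpf, 0.5)
  expect_equal(m$fnf, 0.5)
  expect_equal(m$auroc, 0.75)
  # perfect separation
  perfect <- tibble::tibble(gene_id = paste0("g", 1:4),
                            wald_p = c(1e-6, 1e-5, 0.5, 0.9),
                            q_value = c(1e-5, 1e-4, 0.6, 0.9))
  mp <- evaluate_calls(perfect, truth, fdr = 0.1)
  expect_equal(mp$auroc, 1.0)
  expect_equal(mp$fpf, 0)
  expect_equal(mp$fnf, 0)
})

test_that("AUROC matches a brute-force all-pairs oracle, including ties", {
  set.seed(106)
  n <- 300
  p <- round(runif(n), 2)  # rounding forces ties
  is_de <- runif(n) < 0.3
  result <- tibble::tibble(gene_id = paste0("g", 1:n), wald_p = p,
                           q_value = p.adjust(p, "BH"))
  truth <- tibble::tibble(gene_id = paste0("g", 1:n), is_de = is_de)
  got <- evaluate_calls(result, truth)$auroc
  pairs <- outer(p[is_de], p[!is_de], function(a, b) (a < b) + 0.5 * (a == b))
  expect_equal(got, mean(pairs))
})

test_that("AUROC is near one half when p-values carry no signal", {
  set.seed(107)
  n <- 500
  result <- tibble::tibble(gene_id = paste0("g", 1:n), wald_p = runif(n),
                           q_value = 1)
  truth <- tibble::tibble(gene_id = paste0("g", 1:n), is_de = runif(n) < 0.5)
  expect_lt(abs(evaluate_calls(result, truth)$auroc - 0.5), 0.08)
})

test_that("minimum hypergeometric overlap matches exact enumeration", {
  # universe of 4, top-2 vs top-2 with overlap 2: p = 1 / choose(4, 2) = 1/6
  a <- c("g1", "g2", "g3", "g4")
  b <- c("g2", "g1", "g4", "g3")
  p <- min_hypergeometric_overlap(a, b, step = 2)
  expect_equal(as.numeric(p), 1 / 6)
  # identical rankings of 100 genes: at t = 10 the overlap is full
  u <- paste0("g", 1:100)
  p2 <- min_hypergeometric_overlap(u, u, step = 10)
  expect_lte(as.numeric(p2), phyper(9, 10, 90, 10, lower.tail = FALSE))
  expect_error(min_hypergeometric_overlap(u, u, step = 0), "step")
  expect_error(min_hypergeometric_overlap(u, rev(paste0("x", 1:100)), step = 10),
               "universe")
})

test_that("random rankings rarely reach extreme overlap p-values", {
  set.seed(108)
  u <- paste0("g", 1:60)
  n_thresh <- 6
  hits <- vapply(1:200, function(i) {
    p <- min_hypergeometric_overlap(sample(u), sample(u), step = 10)
    as.numeric(p < 0.05 / n_thresh)
  }, numeric(1))
  expect_lte(mean(hits), 0.12)
})
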