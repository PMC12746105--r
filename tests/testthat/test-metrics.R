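test_that("libsize_normalize fixes row totals", {
  m <- rbind(c1 = c(1, 1, 2), c2 = c(0, 0, 5))
  colnames(m) <- paste0("b", 1:3)
  out <- libsize_normalize(m, scale = 4)
  expect_equal(unname(out["c1", ]), c(1, 1, 2))
  expect_equal(unname(out["c2", ]), c(0, 0, 4))
  expect_true(all(abs(rowSums(out) - 4) < 1e-12))

  m0 <- rbind(c1 = c(1, 1), c2 = c(0, 0))
  colnames(m0) <- c("b1", "b2")
  expect_warning(out0 <- libsize_normalize(m0), "zero total")
  expect_equal(unname(out0["c2", ]), c(0, 0))
})

test_that("corr_to_ground_truth matches hand cases and excludes degenerate cells", {
  truth <- rbind(A = c(1, 2, 3), B = c(3, 2, 1))
  colnames(truth) <- paste0("b", 1:3)
  m <- rbind(c1 = c(1, 2, 3),   # equals truth A
             c2 = c(3, 2, 1),   # reversed truth A
             c3 = c(10, 20, 30),# scaled truth A
             c4 = c(5, 5, 5))   # constant -> undefined
  colnames(m) <- paste0("b", 1:3)
  labels <- data.frame(cell_id = paste0("c", 1:4),
                       cell_type = c("A", "A", "A", "B"))
  r <- corr_to_ground_truth(m, truth, labels)
  expect_equal(unname(r$per_cell[c("c1", "c2", "c3")]), c(1, -1, 1))
  expect_true(is.na(r$per_cell["c4"]))
  expect_equal(r$n_evaluated, 3L)
  expect_equal(r$summary, 1)

  # summary invariant to positive row rescaling
  scaled <- m * c(2, 0.5, 7, 1)
  expect_equal(corr_to_ground_truth(scaled, truth, labels)$summary, r$summary)
})

test_that("sip_score is the masked signal fraction", {
  m <- rbind(c1 = c(5, 3, 2), c2 = c(0, 0, 0))
  colnames(m) <- paste0("b", 1:3)
  s <- sip_score(m, c(FALSE, TRUE, FALSE))
  expect_equal(unname(s$per_cell["c1"]), 0.3)
  expect_true(is.na(s$per_cell["c2"]))

  one <- rbind(c1 = c(5, 3, 2))
  colnames(one) <- paste0("b", 1:3)
  expect_equal(unname(sip_score(one, c(TRUE, FALSE, FALSE))$per_cell), 0.5)
  expect_equal(unname(sip_score(one, rep(TRUE, 3))$per_cell), 1)
  expect_equal(unname(sip_score(one, rep(FALSE, 3))$per_cell), 0)
})

test_that("SiP stays in [0,1] and is invariant to per-cell rescaling", {
  set.seed(12)
  m <- matrix(rpois(400, 3), nrow = 20,
              dimnames = list(paste0("c", 1:20), paste0("b", 1:20)))
  m[1, ] <- m[1, ] + 1 # ensure no zero-total cell
  mask <- runif(20) < 0.3
  s <- sip_score(m, mask)
  expect_true(all(s$per_cell >= 0 & s$per_cell <= 1, na.rm = TRUE))
  s2 <- sip_score(m * runif(20, 0.5, 10), mask)
  expect_equal(s2$per_cell, s$per_cell)
})

test_that("sip_null brackets the expected masked fraction under uniform signal", {
  layout <- genome_layout("chr1", 5e6)
  grid <- tile_genome(layout, 10000) # 500 bins
  m <- matrix(1, nrow = 5, ncol = 500,
              dimnames = list(paste0("c", 1:5),
                              S4Vectors::mcols(grid)$bin_id))
  starts <- (0:19) * 250000
  peaks <- gr0(rep("chr1", 20), starts, starts + 50000, layout)
  q <- sip_null(m, peaks, grid, n_sets = 400, seed = 2)
  # analytic null: an interior bin is covered by one uniformly placed peak
  # of width w with probability (w + bw - 1) / (L - w + 1)
  p <- (50000 + 10000 - 1) / (5e6 - 50000 + 1)
  frac <- 1 - (1 - p)^20
  expect_lt(abs(q["q25"] - frac), 0.02 + 1e-9)
  expect_lt(abs(q["q75"] - frac), 0.02 + 1e-9)
  expect_identical(q, sip_null(m, peaks, grid, n_sets = 400, seed = 2))
})

test_that("observed SiP on an enriched fixture exceeds the null band", {
  fx <- make_fixture(n_types = 2, cells_per_type = 20, n_bins = 200,
                     frac_marked = 0.1, fold = 10, depth = 3000, seed = 4)
  norm <- libsize_normalize(fx$counts)
  obs <- sip_score(norm, bins_in_peaks(fx$grid, fx$peaks))$summary
  q <- sip_null(norm, fx$peaks, fx$grid, n_sets = 200, seed = 5)
  expect_gt(obs, q["q75"])
})

test_that("celltype-specific features rank by log2 enrichment", {
  tab <- rbind(A = c(10, 0, 5, 2), B = c(0, 8, 5, 1))
  colnames(tab) <- paste0("g", 1:4)
  top <- celltype_specific_features(tab, k = 2, eps = 1)
  # A: log2 ratios log2(11/1), log2(1/9), 0, log2(3/2) -> g1, g4
  expect_equal(top$A, c("g1", "g4"))
  expect_equal(top$B, c("g2", "g3"))

  only_a <- rbind(A = c(0, 7, 0), B = c(1, 0, 1), C = c(1, 0, 1))
  colnames(only_a) <- paste0("g", 1:3)
  expect_equal(celltype_specific_features(only_a, k = 1)$A, "g2")

  same <- rbind(A = c(1, 2), B = c(1, 2))
  colnames(same) <- c("g1", "g2")
  expect_equal(celltype_specific_features(same, k = 2)$A, c("g1", "g2"))
  expect_error(celltype_specific_features(same, k = 3), "k exceeds")
})

test_that("expected_similarity reproduces hand-computed ES values", {
  # orthogonal, equal-sized types: S = I, ES = 1/k
  m <- rbind(c1 = c(1, 0, 0), c2 = c(1, 0, 0),
             c3 = c(0, 1, 0), c4 = c(0, 1, 0),
             c5 = c(0, 0, 1), c6 = c(0, 0, 1))
  colnames(m) <- paste0("b", 1:3)
  labels <- data.frame(cell_id = rownames(m),
                       cell_type = rep(c("A", "B", "C"), each = 2))
  sim <- expected_similarity(m, labels)
  expect_equal(sim$ES, 1 / 3, tolerance = 1e-12)

  # identical pseudobulks: ES = 1
  m2 <- rbind(c1 = c(1, 2), c2 = c(1, 2))
  colnames(m2) <- c("b1", "b2")
  l2 <- data.frame(cell_id = c("c1", "c2"), cell_type = c("A", "B"))
  expect_equal(expected_similarity(m2, l2)$ES, 1, tolerance = 1e-12)

  # two types with S12 = 0.5 and equal weights: ES = 0.75
  m3 <- rbind(c1 = c(1, 0), c2 = c(0.5, sqrt(3) / 2))
  colnames(m3) <- c("b1", "b2")
  sim3 <- expected_similarity(m3, l2)
  expect_equal(sim3$S[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(sim3$ES, 0.75, tolerance = 1e-12)

  m4 <- rbind(c1 = c(1, 1), c2 = c(0, 0))
  colnames(m4) <- c("b1", "b2")
  expect_error(expected_similarity(m4, l2), "zero pseudobulk")
})

test_that("ES equals the brute-force double sum on random instances", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(20 * k * 15, 3) + runif(20 * k * 15), nrow = 20 * k)
    rownames(m) <- paste0("c", seq_len(nrow(m)))
    colnames(m) <- paste0("b", 1:15)
    labels <- data.frame(cell_id = rownames(m),
                         cell_type = sample(rep(paste0("t", 1:k), 20)))
    sim <- expected_similarity(m, labels)
    expect_equal(sim$ES, brute_es(sim$W, sim$S), tolerance = 1e-12)
  }
})

test_that("highly_variable_bins ranks by variance with stable ties", {
  m <- rbind(c1 = c(1, 0, 0), c2 = c(1, 2, 1))
  colnames(m) <- paste0("b", 1:3)
  # variances: 0, 2, 0.5 -> order b2, b3, b1
  expect_equal(highly_variable_bins(m, 1), c(2L, 3L, 1L))
  expect_equal(highly_variable_bins(m, 0.5), c(2L, 3L))
  const <- cbind(m, b4 = c(1, 1))
  expect_equal(tail(highly_variable_bins(const, 1), 1), 4L)
})

test_that("simic equals the type count for orthogonal identical types", {
  k_types <- 4
  per <- 10
  base <- matrix(0, nrow = k_types * per, ncol = 2 * k_types)
  for (t in seq_len(k_types))
    base[(t - 1) * per + seq_len(per), c(2 * t - 1, 2 * t)] <- rep(c(1, 2),
                                                                   each = per)
  rownames(base) <- paste0("c", seq_len(nrow(base)))
  colnames(base) <- paste0("b", seq_len(ncol(base)))
  labels <- data.frame(cell_id = rownames(base),
                       cell_type = rep(paste0("t", seq_len(k_types)),
                                       each = per))
  out <- simic(base, labels, k = 5, top_frac = 1)
  expect_equal(unname(out$per_cell), rep(1, nrow(base)))
  expect_equal(out$es, 1 / k_types, tolerance = 1e-12)
  expect_equal(out$simic, k_types, tolerance = 1e-12)
})

test_that("simic separates structured from structureless fixtures", {
  structured <- make_fixture(n_types = 3, cells_per_type = 40, n_bins = 400,
                             frac_marked = 0.12, fold = 8, depth = 4000,
                             seed = 6)
  null <- make_fixture(n_types = 3, cells_per_type = 40, n_bins = 400,
                       frac_marked = 0.12, fold = 1, depth = 4000, seed = 6)
  s1 <- simic(libsize_normalize(structured$counts), structured$labels)
  s0 <- simic(libsize_normalize(null$counts), null$labels)
  expect_gt(s1$simic, s0$simic)
  expect_lt(abs(s0$simic - 1), 0.05)
})

test_that("knn prediction is perfect on separated types and matches its contract", {
  fx <- make_fixture(n_types = 3, cells_per_type = 20, n_bins = 300,
                     frac_marked = 0.15, fold = 20, depth = 5000, seed = 8)
  pred <- knn_cluster_predict(libsize_normalize(fx$counts), fx$labels, k = 10)
  expect_equal(unname(diag(pred$confusion)), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(pred$macro_sensitivity, 1)
  expect_equal(pred$macro_fpr, 0)
  expect_equal(unname(rowSums(pred$confusion)), rep(20L, 3), ignore_attr = TRUE)
})

test_that("knn predictions match the O(m^2) brute-force oracle", {
  set.seed(31)
  for (i in 1:3) {
    fx <- make_fixture(n_types = 2, cells_per_type = 25, n_bins = 120,
                       frac_marked = 0.15, fold = 3, depth = 800,
                       seed = 30 + i)
    norm <- as.matrix(libsize_normalize(fx$counts))
    types <- fx$labels$cell_type
    got <- knn_cluster_predict(norm, fx$labels, k = 7, top_frac = 1)
    oracle <- brute_knn_predict(norm, types, k = 7)
    expect_equal(unname(got$predicted[rownames(norm)]), oracle)
  }
})

test_that("shuffled labels on structureless data give chance-level sensitivity", {
  fx <- make_fixture(n_types = 2, cells_per_type = 60, n_bins = 400,
                     frac_marked = 0.1, fold = 1, depth = 3000, seed = 17)
  labels <- fx$labels
  set.seed(18)
  labels$cell_type <- sample(rep(c("A", "B"), c(80, 40)))
  # with a single random neighbor the predicted type is a draw from the
  # class proportions, so per-class sensitivity is the class proportion
  # within 3 sd of the corresponding binomial
  pred <- knn_cluster_predict(libsize_normalize(fx$counts), labels, k = 1)
  prop <- c(A = 80, B = 40) / 120
  for (t in c("A", "B")) {
    n_t <- sum(labels$cell_type == t)
    se <- sqrt(prop[[t]] * (1 - prop[[t]]) / n_t)
    sens <- pred$per_class$sensitivity[pred$per_class$cell_type == t]
    expect_lt(abs(sens - prop[[t]]), 3 * se + 0.05)
  }
})

test_that("enrichment profile is flat at one for uniform coverage", {
  layout <- genome_layout("chr1", 5e6)
  grid <- tile_genome(layout, 50000)
  m <- matrix(2, nrow = 3, ncol = 100,
              dimnames = list(paste0("c", 1:3),
                              S4Vectors::mcols(grid)$bin_id))
  peaks <- gr0(c("chr1", "chr1"), c(2e6, 3e6), c(2.1e6, 3.1e6), layout)
  prof <- enrichment_profile(m, peaks, grid, flank = 500000, seed = 1)
  expect_true(all(abs(prof$value - 1) < 1e-9))
  # global rescaling leaves the profile unchanged
  prof2 <- enrichment_profile(m * 13, peaks, grid, flank = 500000, seed = 1)
  expect_equal(prof2$value, prof$value)
})

test_that("enrichment profile peaks at the anchor for peak-borne signal", {
  fx <- make_fixture(n_types = 2, cells_per_type = 15, n_bins = 200,
                     frac_marked = 0.1, fold = 25, depth = 4000, seed = 9)
  merged <- merge_close_peaks(fx$peaks)
  prof <- enrichment_profile(libsize_normalize(fx$counts), merged, fx$grid,
                             anchor = "center", flank = 300000, seed = 2)
  at0 <- mean(prof$value[prof$offset == 0])
  away <- mean(prof$value[abs(prof$offset) >= 250000], na.rm = TRUE)
  expect_gt(at0, away)
  expect_error(enrichment_profile(libsize_normalize(fx$counts),
                                  GenomicRanges::GRanges(), fx$grid),
               "empty peak set")
})

test_that("pseudobulk_spearman is one on self and rank-preserving transforms", {
  fx <- make_fixture(n_types = 2, cells_per_type = 10, n_bins = 80,
                     frac_marked = 0.1, fold = 5, depth = 2000, seed = 10)
  mats <- list(raw = as.matrix(fx$counts),
               doubled = as.matrix(fx$counts) * 2)
  rho <- pseudobulk_spearman(mats, fx$labels, fx$grid)
  expect_equal(rho["raw", "raw"], 1)
  expect_equal(rho["raw", "doubled"], 1)

  # hand oracle on a 2-bin, 2-cluster example: Spearman of the
  # concatenated per-cluster RPKM vectors
  layout <- genome_layout("chr1", 100000)
  grid <- tile_genome(layout, 50000)
  ids <- S4Vectors::mcols(grid)$bin_id
  m1 <- rbind(c1 = c(10, 2), c2 = c(1, 5))
  m2 <- rbind(c1 = c(3, 6), c2 = c(8, 2))
  colnames(m1) <- colnames(m2) <- ids
  l <- data.frame(cell_id = c("c1", "c2"), cell_type = c("A", "B"))
  rho2 <- pseudobulk_spearman(list(x = m1, y = m2), l, grid)
  rpkm <- function(m) as.vector(m * 1e9 / outer(rowSums(m), c(50000, 50000)))
  expect_equal(rho2["x", "y"],
               cor(rank(rpkm(m1)), rank(rpkm(m2))), tolerance = 1e-12)
})

test_that("embedding grid search finds separable structure deterministically", {
  set.seed(41)
  blob <- rbind(matrix(rnorm(40 * 20, 0), nrow = 40),
                matrix(rnorm(40 * 20, 6), nrow = 40))
  blob <- blob - min(blob) # keep the count-matrix contract non-negative
  rownames(blob) <- paste0("c", 1:80)
  colnames(blob) <- paste0("b", 1:20)
  labels <- data.frame(cell_id = rownames(blob),
                       cell_type = rep(c("A", "B"), each = 40))
  res <- embedding_grid_search(blob, labels, var_fracs = 0.95,
                               pcs_grid = c(5L, 10L), nn_grid = c(10L, 15L),
                               seed = 7)
  expect_gt(res$best$silhouette, 0.5)
  expect_true(all(res$best$silhouette >= res$grid$silhouette, na.rm = TRUE))
  res2 <- embedding_grid_search(blob, labels, var_fracs = 0.95,
                                pcs_grid = c(5L, 10L), nn_grid = c(10L, 15L),
                                seed = 7)
  expect_identical(res$best, res2$best)
  expect_identical(res$embedding, res2$embedding)
  # grid points beyond the data rank are skipped, not fatal
  res3 <- embedding_grid_search(blob, labels, var_fracs = 0.95,
                                pcs_grid = c(5L, 500L), nn_grid = 10L,
                                seed = 7)
  expect_equal(nrow(res3$skipped), 1L)
})
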