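# Evaluation metrics computed directly on raw, normalized or imputed
# cell x bin matrices: correlation to ground truth, Signal-in-Peaks (SiP),
# SIMIC, KNN cell-type prediction, enrichment metaprofiles, cross-method
# pseudobulk correlation, and a silhouette-driven embedding grid search.
#
# Per-cell metrics return a "metric_result": a list with the metric name,
# the per-cell values (NA where undefined), the summary statistic and the
# number of cells actually evaluated. Degenerate cells (constant or empty
# profiles) are excluded from summaries, never imputed as zero.

metric_result <- function(name, per_cell, summary_fun) {
  ok <- !is.na(per_cell)
  structure(list(metric = name,
                 per_cell = per_cell,
                 summary = if (any(ok)) summary_fun(per_cell[ok]) else NA_real_,
                 n_evaluated = sum(ok)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s: summary = %.4g over %d/%d cells\n",
              x$metric, x$summary, x$n_evaluated, length(x$per_cell)))
  invisible(x)
}

#' Library-size normalize a count matrix
#'
#' Scales each cell to a fixed total (counts per `scale`). Cells with a
#' zero total cannot be normalized and are left at zero with a warning.
#'
#' @param counts cell x bin matrix.
#' @param scale target row total (default 1e4).
#' @return Matrix of the same class and shape with row sums equal to
#'   `scale` (for nonempty cells).
#' @export
libsize_normalize <- function(counts, scale = 1e4) {
  check_count_matrix(counts)
  tot <- row_totals(counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " cells with zero total left unnormalized")
  f <- ifelse(tot > 0, scale / tot, 0)
  if (methods::is(counts, "Matrix")) {
    out <- Matrix::Diagonal(x = f) %*% counts
    dimnames(out) <- dimnames(counts)
    out
  } else {
    counts * f
  }
}

#' Per-cell Pearson correlation to the ground-truth pseudobulk
#'
#' Correlates every cell's profile with the ground-truth profile of its
#' cell type over all shared bins. Raw (pre-imputation) input should be
#' library-size normalized by the caller; imputed matrices are used as
#' returned by the algorithm. Cells (or truth rows) with constant profiles
#' have undefined correlation and are excluded from the median.
#'
#' @param matrix cell x bin matrix.
#' @param truth type x bin ground-truth pseudobulk matrix on the same bins.
#' @param labels cell annotation mapping cells to truth rows.
#' @return A `metric_result` summarized by the median.
#' @export
corr_to_ground_truth <- function(matrix, truth, labels) {
  check_count_matrix(matrix)
  check_labels(labels, rownames(matrix))
  if (ncol(matrix) != ncol(truth))
    stop("matrix and truth differ in bin count")
  types <- types_for(labels, rownames(matrix))
  if (!all(types %in% rownames(truth)))
    stop("cell types missing from truth: ",
         paste(setdiff(types, rownames(truth)), collapse = ", "))
  X <- as.matrix(matrix)
  Tm <- as.matrix(truth)
  r <- vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    y <- Tm[types[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  names(r) <- rownames(X)
  metric_result("correlation", r, stats::median)
}

#' Signal-in-Peaks (SiP) score
#'
#' Fraction of each cell's total signal falling in bins flagged by the
#' mask (typically [bins_in_peaks()] over filtered peak calls); the
#' single-bin analogue of FRiP. Cells with zero total signal are undefined.
#'
#' @param matrix cell x bin matrix.
#' @param mask logical per-bin vector, length `ncol(matrix)`.
#' @return A `metric_result` summarized by the median; values in `[0, 1]`.
#' @export
sip_score <- function(matrix, mask) {
  check_count_matrix(matrix)
  if (length(mask) != ncol(matrix))
    stop("mask length must equal the number of bins")
  tot <- row_totals(matrix)
  inpk <- row_totals(matrix[, mask, drop = FALSE])
  sip <- ifelse(tot > 0, inpk / tot, NA_real_)
  names(sip) <- rownames(matrix)
  metric_result("sip", sip, stats::median)
}

#' Permutation null for the SiP summary
#'
#' Recomputes the median SiP under `n_sets` random relocations of the
#' peaks ([shuffle_peaks()]) and returns the 25th and 75th percentiles of
#' the null summaries, the usual band against which an observed SiP is
#' judged.
#'
#' @param matrix cell x bin matrix on `grid`.
#' @param peaks peak `GRanges`.
#' @param grid bin `GRanges` carrying the genome layout.
#' @param n_sets number of permuted peak sets (default 1000).
#' @param seed integer seed.
#' @return Named numeric: `q25`, `q75` of the null median SiP.
#' @export
sip_null <- function(matrix, peaks, grid, n_sets = 1000L, seed = 1L) {
  layout <- GenomeInfoDb::seqinfo(grid)
  sets <- shuffle_peaks(peaks, layout, n_sets = n_sets, seed = seed)
  tot <- row_totals(matrix)
  nulls <- vapply(sets, function(p) {
    mask <- IRanges::overlapsAny(grid, p, ignore.strand = TRUE)
    sip <- ifelse(tot > 0, row_totals(matrix[, mask, drop = FALSE]) / tot,
                  NA_real_)
    stats::median(sip, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(stats::quantile(nulls, c(0.25, 0.75), names = FALSE),
                  c("q25", "q75"))
}

#' Cell-type-specific features by log2 enrichment
#'
#' For each cell type, ranks features (e.g. promoter counts) by
#' `log2((x_t + eps) / (mean over other types + eps))` and returns the
#' top `k`. Ties are broken by feature order.
#'
#' @param truth_counts type x feature matrix (e.g. pseudobulk promoter
#'   counts).
#' @param k features kept per type (default 250).
#' @param eps pseudocount (default 1).
#' @return Named list (one entry per type) of feature names, or indices if
#'   the matrix has no column names.
#' @export
celltype_specific_features <- function(truth_counts, k = 250L, eps = 1) {
  truth_counts <- as.matrix(truth_counts)
  if (k > ncol(truth_counts))
    stop("k exceeds the number of features")
  out <- lapply(seq_len(nrow(truth_counts)), function(t) {
    x <- truth_counts[t, ]
    others <- colMeans(truth_counts[-t, , drop = FALSE])
    enrich <- log2((x + eps) / (others + eps))
    top <- order(-enrich, seq_along(enrich))[seq_len(k)]
    if (is.null(colnames(truth_counts))) top else colnames(truth_counts)[top]
  })
  names(out) <- rownames(truth_counts)
  out
}

cosine_similarity <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop("zero pseudobulk vector: cosine similarity undefined for type(s) ",
         paste(rownames(M)[nrm == 0], collapse = ", "))
  S <- (M %*% t(M)) / outer(nrm, nrm)
  pmin(pmax(S, -1), 1)
}

#' Expected cell-type similarity
#'
#' Aggregates the matrix into per-type pseudobulks, computes the cosine
#' similarity `S` between all type pairs, weights each type by its cell
#' proportion `W`, and returns the abundance-weighted expected similarity
#' `ES = sum_ij W_i W_j S_ij` (diagonal included). `ES` is the similarity
#' a cell is expected to share with a uniformly random other cell, the
#' denominator of the SIMIC score.
#'
#' @param matrix cell x bin matrix (ground truth or any evaluation input).
#' @param labels cell annotation; at least two types.
#' @return List with `types`, `S` (similarity matrix), `W` (proportions)
#'   and `ES` (scalar).
#' @export
expected_similarity <- function(matrix, labels) {
  check_count_matrix(matrix)
  check_labels(labels, rownames(matrix))
  pb <- build_pseudobulks(matrix, labels)
  if (nrow(pb) < 2L) stop("at least two cell types are required")
  S <- cosine_similarity(as.matrix(pb))
  types <- types_for(labels, rownames(matrix))
  W <- as.vector(table(factor(types, levels = rownames(pb)))) / nrow(matrix)
  names(W) <- rownames(pb)
  list(types = rownames(pb), S = S, W = W,
       ES = as.numeric(t(W) %*% S %*% W))
}

#' Select highly variable bins
#'
#' Ranks bins by across-cell variance of the matrix as supplied (normalize
#' raw counts first if desired) and returns the top fraction; ties are
#' broken by bin order.
#'
#' @param matrix cell x bin matrix.
#' @param top_frac fraction of bins kept, in `(0, 1]` (default 0.05).
#' @return Integer bin indices, ordered by decreasing variance.
#' @export
highly_variable_bins <- function(matrix, top_frac = 0.05) {
  check_count_matrix(matrix)
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  m <- nrow(matrix)
  mu <- if (methods::is(matrix, "Matrix")) Matrix::colMeans(matrix) else colMeans(matrix)
  mu2 <- if (methods::is(matrix, "Matrix")) Matrix::colMeans(matrix^2) else colMeans(matrix^2)
  v <- (mu2 - mu^2) * m / max(m - 1, 1)
  k <- ceiling(top_frac * ncol(matrix))
  order(-v, seq_along(v))[seq_len(k)]
}

# Shared KNN machinery: Pearson-correlation distance on the top variable
# bins. Constant cells have undefined correlations and are excluded from
# both the neighbor pool and downstream averages. Ties in distance are
# broken by cell order; self is never a neighbor.
knn_graph <- function(matrix, k = 10L, top_frac = 0.05) {
  check_count_matrix(matrix)
  if (nrow(matrix) <= k) stop("need more cells than neighbors (m > k)")
  bins <- highly_variable_bins(matrix, top_frac)
  X <- as.matrix(matrix[, bins, drop = FALSE])
  usable <- apply(X, 1L, stats::sd) > 0
  Xu <- X[usable, , drop = FALSE]
  if (nrow(Xu) <= k)
    stop("too few non-constant cells for k = ", k)
  D <- 1 - stats::cor(t(Xu))
  nn_idx <- apply(D, 1L, function(d) {
    order(d, seq_along(d))[2:(k + 1L)] # position 1 is self (distance 0)
  })
  nn <- if (k == 1L) matrix(nn_idx, ncol = 1L) else t(nn_idx)
  list(neighbors = nn, cells = rownames(Xu), usable = usable,
       n_excluded = sum(!usable))
}

#' SIMIC: similarity-integrated metric for improved clustering
#'
#' Builds a KNN graph on Pearson-correlation distance over the top
#' variable bins, scores each cell by the mean cosine similarity between
#' its own cell type and the types of its `k` nearest neighbors, averages
#' these per-cell scores into `S_obs`, and normalizes by the expected
#' similarity `ES` ([expected_similarity()]):
#' `SIMIC = S_obs / ES`. A score of 1 means neighbors are no more similar
#' than random cells; values above 1 indicate cell-type structure (1.5 =
#' neighbors 50% more similar than expected).
#'
#' @param matrix cell x bin matrix under evaluation.
#' @param labels cell annotation.
#' @param sim optional similarity model from [expected_similarity()];
#'   defaults to one computed on `matrix` itself. Supply one computed on
#'   the ground truth to keep the reference fixed across methods.
#' @param k neighbors per cell (default 10).
#' @param top_frac fraction of variable bins (default 0.05).
#' @return List with `simic`, `s_obs`, `es`, `per_cell` scores and
#'   `n_evaluated`.
#' @export
simic <- function(matrix, labels, sim = NULL, k = 10L, top_frac = 0.05) {
  check_labels(labels, rownames(matrix))
  if (is.null(sim)) sim <- expected_similarity(matrix, labels)
  g <- knn_graph(matrix, k = k, top_frac = top_frac)
  types <- types_for(labels, g$cells)
  if (!all(types %in% sim$types))
    stop("labels contain types absent from the similarity model")
  per_cell <- vapply(seq_along(g$cells), function(i) {
    mean(sim$S[types[i], types[g$neighbors[i, ]]])
  }, numeric(1))
  names(per_cell) <- g$cells
  s_obs <- mean(per_cell)
  list(simic = s_obs / sim$ES, s_obs = s_obs, es = sim$ES,
       per_cell = per_cell, n_evaluated = length(per_cell),
       n_excluded = g$n_excluded)
}

#' KNN cell-type prediction
#'
#' Uses the same neighbor graph as [simic()]. For each cell, the fraction
#' of its `k` nearest neighbors of each type is divided by that type's
#' dataset proportion; the most enriched type is the prediction
#' (`mode = "abundance"` instead predicts the raw most frequent neighbor
#' type). Ties favor the larger raw neighbor count, then type order.
#' Returns the confusion matrix and per-class sensitivity and
#' false-positive rate with their macro averages — the operating point
#' summarizing a method's clustering usefulness.
#'
#' @param matrix cell x bin matrix.
#' @param labels cell annotation.
#' @param k neighbors (default 10).
#' @param top_frac fraction of variable bins (default 0.05).
#' @param mode `"enrichment"` (default) or `"abundance"`.
#' @return List with `confusion` (true x predicted), `per_class`
#'   (sensitivity, FPR), `macro_sensitivity`, `macro_fpr`, `predicted`.
#' @export
knn_cluster_predict <- function(matrix, labels, k = 10L, top_frac = 0.05,
                                mode = c("enrichment", "abundance")) {
  mode <- match.arg(mode)
  check_labels(labels, rownames(matrix))
  g <- knn_graph(matrix, k = k, top_frac = top_frac)
  types <- types_for(labels, g$cells)
  lev <- sort(unique(types))
  prop <- as.vector(table(factor(types, levels = lev))) / length(types)
  pred <- vapply(seq_along(g$cells), function(i) {
    cnt <- table(factor(types[g$neighbors[i, ]], levels = lev))
    score <- if (mode == "enrichment") as.vector(cnt) / (k * prop)
             else as.vector(cnt)
    # argmax; ties -> larger raw count, then type order
    best <- order(-score, -as.vector(cnt), seq_along(lev))[1L]
    lev[best]
  }, character(1))
  names(pred) <- g$cells
  confusion <- table(true = factor(types, levels = lev),
                     predicted = factor(pred, levels = lev))
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- sum(confusion) - tp - fn - fp
  per_class <- data.frame(cell_type = lev,
                          sensitivity = tp / (tp + fn),
                          fpr = fp / (fp + tn))
  list(confusion = confusion, per_class = per_class,
       macro_sensitivity = mean(per_class$sensitivity),
       macro_fpr = mean(per_class$fpr),
       predicted = pred, n_excluded = g$n_excluded)
}

#' Signal-enrichment metaprofile around peaks
#'
#' Samples up to `n_peaks` peaks (pre-merged with [merge_close_peaks()]),
#' extracts binned coverage in a window of `± flank` bp around the peak
#' center (or start), normalizes each region by its own mean coverage, and
#' averages regions per cell group. A flat profile at 1 indicates no
#' enrichment; a peak at offset 0 indicates signal concentrated at the
#' anchored sites.
#'
#' @param matrix cell x bin matrix on `grid`.
#' @param peaks merged peak `GRanges`.
#' @param grid bin `GRanges`.
#' @param labels optional cell annotation; with labels the profile is
#'   computed per cell type from pseudobulk coverage, otherwise one
#'   profile over all cells.
#' @param anchor `"center"` (point-source marks) or `"start"` (broad
#'   domains).
#' @param flank half-window in bp (default 5e5).
#' @param n_peaks regions sampled (default 1000).
#' @param seed integer seed for the peak sample.
#' @return Long-format data.frame: `group`, `offset` (bp, window start of
#'   each bin relative to the anchor), `value`; plus attribute
#'   `n_dropped` (zero-mean regions removed).
#' @export
enrichment_profile <- function(matrix, peaks, grid, labels = NULL,
                               anchor = c("center", "start"),
                               flank = 500000L, n_peaks = 1000L, seed = 1L) {
  anchor <- match.arg(anchor)
  check_count_matrix(matrix)
  if (length(peaks) == 0L) stop("empty peak set")
  if (ncol(matrix) != length(grid))
    stop("matrix bins and grid differ in length")
  bw <- as.integer(GenomicRanges::width(grid)[1L])
  set.seed(seed)
  if (length(peaks) > n_peaks)
    peaks <- peaks[sort(sample(length(peaks), n_peaks))]
  # group-level coverage vectors over bins
  cov <- if (is.null(labels)) {
    m <- rbind(all = if (methods::is(matrix, "Matrix"))
                 Matrix::colSums(matrix) else colSums(matrix))
    m
  } else {
    as.matrix(build_pseudobulks(matrix, labels))
  }
  anchors <- if (anchor == "center") {
    as.integer(floor((GenomicRanges::start(peaks) +
                      GenomicRanges::end(peaks)) / 2))
  } else {
    GenomicRanges::start(peaks)
  }
  offsets <- seq(-flank, flank - bw, by = bw)
  chr_peak <- as.character(GenomeInfoDb::seqnames(peaks))
  # map each (peak, offset) position to its grid bin, NA off-chromosome
  chr_bins <- as.character(GenomeInfoDb::seqnames(grid))
  first_bin <- match(unique(chr_bins), chr_bins)
  names(first_bin) <- unique(chr_bins)
  n_per_chr <- table(chr_bins)[unique(chr_bins)]
  lens <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(grid))
  bin_at <- function(chr, pos) {
    # pos is 1-based; returns grid row or NA
    ok <- pos >= 1 & pos <= lens[chr]
    idx <- first_bin[chr] + (pos - 1L) %/% bw
    idx[!ok] <- NA_integer_
    idx
  }
  profiles <- lapply(rownames(cov), function(grp) {
    sig <- cov[grp, ]
    region <- vapply(seq_along(peaks), function(p) {
      idx <- bin_at(rep(chr_peak[p], length(offsets)), anchors[p] + offsets)
      vals <- ifelse(is.na(idx), NA_real_, sig[idx])
      mu <- mean(vals, na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) rep(NA_real_, length(offsets))
      else vals / mu
    }, numeric(length(offsets)))
    dropped <- sum(colSums(!is.na(region)) == 0)
    prof <- rowMeans(region, na.rm = TRUE)
    list(prof = prof, dropped = dropped)
  })
  out <- do.call(rbind, Map(function(grp, pr) {
    data.frame(group = grp, offset = offsets, value = pr$prof)
  }, rownames(cov), profiles))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(vapply(profiles, `[[`, numeric(1), "dropped"))
  out
}

#' Cross-method pseudobulk Spearman correlation
#'
#' For each method's matrix, computes per-cluster RPKM
#' (`count * 1e9 / (cluster total * bin width)`), concatenates all
#' (bin, cluster) values into one vector per method, and returns the
#' pairwise Spearman correlation matrix. Clusters with zero total are
#' undefined and handled pairwise-complete.
#'
#' @param matrices named list of cell x bin matrices on the same bins.
#' @param labels shared cell annotation.
#' @param grid bin `GRanges` supplying bin widths.
#' @return method x method Spearman correlation matrix.
#' @export
pseudobulk_spearman <- function(matrices, labels, grid) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  widths <- GenomicRanges::width(grid)
  vecs <- vapply(matrices, function(m) {
    pb <- as.matrix(build_pseudobulks(m, labels))
    tot <- rowSums(pb)
    rpkm <- pb * 1e9 / outer(tot, widths)
    rpkm[tot == 0, ] <- NA_real_
    as.vector(rpkm)
  }, numeric(nrow(build_pseudobulks(matrices[[1]], labels)) * length(grid)))
  stats::cor(vecs, method = "spearman", use = "pairwise.complete.obs")
}

#' Silhouette-driven PCA/UMAP parameter search
#'
#' Grid-searches the fraction of most variable bins, the number of
#' principal components and the UMAP neighborhood size; each
#' configuration is scored by the average silhouette width of the known
#' cell-type labels in the 2-D UMAP embedding, and the best configuration
#' and its embedding are returned. Grid points whose input rank cannot
#' support the requested number of components are skipped.
#'
#' @param matrix cell x bin matrix (CPM-normalized raw data or imputed
#'   output).
#' @param labels cell annotation.
#' @param var_fracs fractions of most variable bins (default 0.90, 0.95).
#' @param pcs_grid candidate numbers of principal components, within
#'   5..50 (default `c(5, 15, 30, 50)`).
#' @param nn_grid UMAP neighborhood sizes (default 10, 15, 20).
#' @param seed integer seed (UMAP is run single-threaded for
#'   reproducibility).
#' @return List with `best` (parameters and silhouette), `embedding`
#'   (m x 2), `grid` (all evaluated configurations) and `skipped`.
#' @export
embedding_grid_search <- function(matrix, labels,
                                  var_fracs = c(0.90, 0.95),
                                  pcs_grid = c(5L, 15L, 30L, 50L),
                                  nn_grid = c(10L, 15L, 20L),
                                  seed = 1L) {
  check_count_matrix(matrix)
  check_labels(labels, rownames(matrix))
  if (nrow(matrix) <= max(nn_grid))
    stop("need more cells than the largest neighborhood size")
  cl <- as.integer(factor(types_for(labels, rownames(matrix))))
  combos <- expand.grid(var_frac = var_fracs, n_pcs = pcs_grid,
                        n_neighbors = nn_grid, KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(combos))
  skipped <- integer(0)
  for (i in seq_len(nrow(combos))) {
    vf <- combos$var_frac[i]; npc <- combos$n_pcs[i]; nn <- combos$n_neighbors[i]
    X <- as.matrix(matrix[, highly_variable_bins(matrix, vf), drop = FALSE])
    max_rank <- min(nrow(X) - 1L, ncol(X))
    if (npc > max_rank) { skipped <- c(skipped, i); next }
    pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = npc)
    if (ncol(pca$x) < npc) { skipped <- c(skipped, i); next }
    set.seed(seed)
    emb <- uwot::umap(pca$x, n_neighbors = nn, n_threads = 1,
                      n_sgd_threads = 1)
    sil <- mean(cluster::silhouette(cl, stats::dist(emb))[, "sil_width"])
    results[[i]] <- list(silhouette = sil, embedding = emb)
  }
  evaluated <- which(!vapply(results, is.null, logical(1)))
  if (!length(evaluated)) stop("every grid point was skipped")
  sils <- vapply(results[evaluated], `[[`, numeric(1), "silhouette")
  best_i <- evaluated[which.max(sils)]
  grid_tab <- combos
  grid_tab$silhouette <- vapply(results, function(r)
    if (is.null(r)) NA_real_ else r$silhouette, numeric(1))
  emb <- results[[best_i]]$embedding
  rownames(emb) <- rownames(matrix)
  list(best = c(as.list(combos[best_i, ]),
                silhouette = results[[best_i]]$silhouette),
       embedding = emb, grid = grid_tab, skipped = combos[skipped, ])
}
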