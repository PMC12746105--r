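# Shared helpers and independent oracles used across the suite.

# Build a GRanges from BED-style (0-based half-open) coordinates, the
# convention in which interval examples are easiest to state.
gr0 <- function(chrom, start0, end0, layout = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  gr
}

ranges_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}

# Small labeled matrix: n_per type A and B cells over given bin count.
toy_counts <- function(n_per = 3, n_bins = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(2 * n_per * n_bins, 5), nrow = 2 * n_per)
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  colnames(m) <- paste0("b", seq_len(n_bins))
  list(counts = m,
       labels = data.frame(cell_id = rownames(m),
                           cell_type = rep(c("A", "B"), each = n_per)))
}

# O(n * p) overlap scan over BED-style coordinates.
brute_bins_in_peaks <- function(grid, peaks) {
  g <- ranges_df(grid); p <- ranges_df(peaks)
  vapply(seq_len(nrow(g)), function(i) {
    any(p$chrom == g$chrom[i] & p$start0 < g$end0[i] & p$end0 > g$start0[i])
  }, logical(1))
}

# Double-loop evaluation of the expected-similarity sum.
brute_es <- function(W, S) {
  es <- 0
  for (i in seq_along(W)) for (j in seq_along(W))
    es <- es + W[i] * W[j] * S[i, j]
  unname(es)
}

# O(m^2) KNN cell-type predictor: explicit loops, enrichment rule.
brute_knn_predict <- function(X, types, k) {
  m <- nrow(X)
  lev <- sort(unique(types))
  prop <- as.vector(table(factor(types, levels = lev))) / m
  pred <- character(m)
  for (i in seq_len(m)) {
    d <- numeric(m)
    for (j in seq_len(m)) d[j] <- 1 - cor(X[i, ], X[j, ])
    nb <- setdiff(order(d, seq_len(m)), i)[seq_len(k)]
    cnt <- as.vector(table(factor(types[nb], levels = lev)))
    score <- cnt / (k * prop)
    pred[i] <- lev[order(-score, -cnt, seq_along(lev))[1]]
  }
  pred
}
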