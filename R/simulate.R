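# In-silico scenario generation: cell filtering, ground-truth pseudobulks,
# genome-wide expansion, uniform noise at a controlled signal-to-noise
# ratio, multinomial downsampling, and a self-contained fixture generator.
#
# A count matrix is an m x n (cells x bins) base matrix or Matrix sparse
# matrix with unique rownames (cell ids) and colnames (bin ids). Cell
# labels are a data.frame with columns cell_id and cell_type.

check_count_matrix <- function(counts, integer_only = FALSE) {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix")))
    stop("counts must be a matrix or Matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("counts must have at least one cell and one bin")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts needs unique rownames (cell ids)")
  if (min(counts) < 0) stop("counts must be non-negative")
  if (integer_only && any(counts != round(counts)))
    stop("raw counts must be integers")
  invisible(counts)
}

check_labels <- function(labels, cells) {
  if (!all(c("cell_id", "cell_type") %in% names(labels)))
    stop("labels need columns cell_id and cell_type")
  if (anyDuplicated(labels$cell_id)) stop("duplicate cell ids in labels")
  missing <- setdiff(cells, labels$cell_id)
  if (length(missing))
    stop("unlabeled cells: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  invisible(labels)
}

# cell_type per cell, in the matrix row order
types_for <- function(labels, cells) {
  labels$cell_type[match(cells, labels$cell_id)]
}

row_totals <- function(m) {
  if (methods::is(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
}

#' Filter cells on read depth and fraction of zero counts
#'
#' Keeps cells with at least `min_reads` total counts, then removes cells
#' whose fraction of zero-count bins lies more than `zero_frac_sd`
#' standard deviations below the mean zero fraction of the depth-filtered
#' cells. Cells with unusually few zeros in sparse assays tend to carry
#' unspecific cuts rather than real signal.
#'
#' @param counts raw integer cell x bin matrix.
#' @param min_reads minimum total reads per cell (e.g. 500 for H3K4me1/3,
#'   1000 for broader marks).
#' @param zero_frac_sd standard-deviation cutoff for the zero-fraction rule
#'   (default 2).
#' @return The filtered count matrix.
#' @export
filter_cells <- function(counts, min_reads, zero_frac_sd = 2) {
  check_count_matrix(counts, integer_only = TRUE)
  deep <- counts[row_totals(counts) >= min_reads, , drop = FALSE]
  if (nrow(deep) == 0L)
    stop("no cells pass min_reads = ", min_reads,
         "; lower the threshold or check the input")
  zf <- row_totals(deep == 0) / ncol(deep)
  s <- stats::sd(zf)
  keep <- if (is.na(s) || s == 0) rep(TRUE, nrow(deep))
          else zf >= mean(zf) - zero_frac_sd * s
  out <- deep[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("zero-fraction rule removed all cells; relax zero_frac_sd")
  out
}

#' Aggregate counts per cell type into ground-truth pseudobulks
#'
#' @param counts cell x bin matrix.
#' @param labels cell annotation (`cell_id`, `cell_type`).
#' @return A dense type x bin matrix; row `t` is the column-wise sum over
#'   cells of type `t`, so total mass is conserved.
#' @export
build_pseudobulks <- function(counts, labels) {
  check_count_matrix(counts)
  check_labels(labels, rownames(counts))
  types <- types_for(labels, rownames(counts))
  groups <- sort(unique(types))
  pb <- do.call(rbind, lapply(groups, function(t) {
    sub <- counts[types == t, , drop = FALSE]
    if (methods::is(sub, "Matrix")) Matrix::colSums(sub) else colSums(sub)
  }))
  rownames(pb) <- groups
  colnames(pb) <- colnames(counts)
  pb
}

#' Expand pseudobulks to a per-cell, genome-wide matrix
#'
#' Builds the noiseless per-cell matrix P: every cell's row is the
#' pseudobulk profile of its type, projected onto the genome-wide bin grid
#' (bins not covered by any pseudobulk feature are zero). Cells of the same
#' type therefore have identical rows.
#'
#' @param pseudobulks type x feature matrix from [build_pseudobulks()].
#' @param labels cell annotation; one output row per labeled cell.
#' @param grid bin `GRanges` from [tile_genome()]; pseudobulk feature names
#'   must match its `bin_id` column.
#' @return Sparse cell x genome-bin matrix.
#' @export
expand_to_cells <- function(pseudobulks, labels, grid) {
  wide <- project_to_grid(pseudobulks, grid)
  trow <- match(labels$cell_type, rownames(pseudobulks))
  if (anyNA(trow))
    stop("labels contain cell types without a pseudobulk: ",
         paste(unique(labels$cell_type[is.na(trow)]), collapse = ", "))
  out <- wide[trow, , drop = FALSE]
  rownames(out) <- labels$cell_id
  out
}

# Project a type x feature matrix onto genome-wide grid bins (zero where
# no feature maps); feature names must match the grid's bin_id column.
project_to_grid <- function(pseudobulks, grid) {
  ids <- S4Vectors::mcols(grid)$bin_id
  idx <- match(colnames(pseudobulks), ids)
  if (anyNA(idx))
    stop("pseudobulk features not on the bin grid: ",
         paste(utils::head(colnames(pseudobulks)[is.na(idx)], 5),
               collapse = ", "))
  wide <- Matrix::Matrix(0, nrow = nrow(pseudobulks), ncol = length(grid),
                         sparse = TRUE,
                         dimnames = list(rownames(pseudobulks), ids))
  wide[, idx] <- as.matrix(pseudobulks)
  wide
}

#' Add uniform noise at a controlled signal-to-noise ratio
#'
#' Implements `N = P + noise * l` where the per-bin noise intensity is the
#' average count per bin. In the default `per_cell` mode each cell `i`
#' receives `l * rowmean_i` in every bin; in `global` mode every entry
#' receives `l * grand mean`. Both modes add a total noise mass of
#' `l * sum(P)`, so the global signal-to-noise ratio (signal mass / added
#' noise mass) is exactly `1 / l`. The result is a real-valued intensity
#' matrix; integrality and sparsity are restored by [downsample_counts()].
#'
#' @param P genome-expanded cell x bin matrix (see [expand_to_cells()]).
#' @param l noise level, `>= 0`. `l = 0` returns `P` unchanged.
#' @param mode `"per_cell"` (default) or `"global"`.
#' @return Dense numeric matrix of the same shape.
#' @export
add_noise <- function(P, l, mode = c("per_cell", "global")) {
  mode <- match.arg(mode)
  check_count_matrix(P)
  if (l < 0) stop("noise level l must be non-negative")
  P <- as.matrix(P)
  if (l == 0) return(P)
  if (mode == "per_cell") {
    P + l * rowMeans(P)
  } else {
    P + l * sum(P) / length(P)
  }
}

#' Downsample each cell to a fixed read depth
#'
#' Draws exactly `depth` reads per cell by multinomial sampling with
#' probabilities proportional to the cell's intensities — the canonical
#' model of uniform read thinning. Output rows sum to `depth` exactly.
#'
#' @param N cell x bin intensity matrix with positive row totals.
#' @param depth target reads per cell.
#' @param seed integer seed for reproducibility.
#' @return Sparse integer cell x bin matrix.
#' @export
downsample_counts <- function(N, depth, seed = 1L) {
  check_count_matrix(N)
  if (depth < 1) stop("depth must be a positive integer")
  tot <- row_totals(N)
  if (any(tot <= 0))
    stop("cells with zero total intensity cannot be downsampled: ",
         paste(utils::head(rownames(N)[tot <= 0], 5), collapse = ", "))
  set.seed(seed)
  N <- as.matrix(N)
  out <- t(apply(N, 1L, function(p) stats::rmultinom(1L, depth, p)[, 1L]))
  dimnames(out) <- dimnames(N)
  Matrix::Matrix(out, sparse = TRUE)
}

# Deterministic child-seed derivation: one stream per scenario index, kept
# inside the 32-bit integer range.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + index * 9973) %% 2147483647)
}

#' Generate the full noise x depth scenario grid
#'
#' For each (noise level, depth) pair, builds one in-silico dataset from
#' the labeled input counts: pseudobulk aggregation, genome-wide expansion,
#' uniform noise ([add_noise()]) and multinomial downsampling
#' ([downsample_counts()]) under a scenario-specific child seed. The
#' default grids (10 noise levels x 3 depths) produce 30 datasets, the
#' standard benchmarking design for one modality. Extreme extra levels
#' (e.g. `l = 10, 50`) may be appended to `noise_levels`.
#'
#' @param counts filtered raw cell x feature matrix.
#' @param labels cell annotation covering all cells.
#' @param grid genome-wide bin `GRanges`.
#' @param noise_levels numeric vector of noise levels `l`.
#' @param depths integer vector of target reads per cell.
#' @param seed master seed; each scenario derives its own child seed.
#' @param balanced_n if set, subsample (without replacement) every cell
#'   type to `balanced_n` cells before expansion; types with fewer cells
#'   are an error.
#' @param noise_mode passed to [add_noise()].
#' @return A list with `pseudobulks` (type x feature ground truth),
#'   `pseudobulks_genome` (type x genome-bin), `labels` (possibly
#'   balanced), and `scenarios`: a list of `list(spec, counts)` where
#'   `spec` holds `noise_level`, `depth`, `seed` and `label`.
#' @export
generate_scenario_grid <- function(counts, labels, grid,
                                   noise_levels = c(0, 0.25, 0.35, 0.5, 0.75,
                                                    1, 1.25, 2, 3.5, 5),
                                   depths = c(100L, 1000L, 10000L),
                                   seed = 1L, balanced_n = NULL,
                                   noise_mode = "per_cell") {
  check_count_matrix(counts)
  check_labels(labels, rownames(counts))
  labels <- labels[labels$cell_id %in% rownames(counts), , drop = FALSE]
  if (!is.null(balanced_n)) {
    set.seed(child_seed(seed, 0L))
    keep <- unlist(lapply(split(labels$cell_id, labels$cell_type), function(ids) {
      if (length(ids) < balanced_n)
        stop("cell type with fewer than balanced_n = ", balanced_n, " cells")
      sample(ids, balanced_n)
    }), use.names = FALSE)
    labels <- labels[labels$cell_id %in% keep, , drop = FALSE]
    counts <- counts[labels$cell_id, , drop = FALSE]
  }
  pb <- build_pseudobulks(counts, labels)
  P <- expand_to_cells(pb, labels, grid)
  pb_genome <- as.matrix(project_to_grid(pb, grid))
  combos <- expand.grid(depth = depths, noise_level = noise_levels,
                        KEEP.OUT.ATTRS = FALSE)
  scenarios <- lapply(seq_len(nrow(combos)), function(i) {
    l <- combos$noise_level[i]
    depth <- as.integer(combos$depth[i])
    s <- child_seed(seed, i)
    N <- add_noise(P, l, mode = noise_mode)
    list(spec = list(noise_level = l, depth = depth, seed = s,
                     label = sprintf("l%s_d%d", format(l), depth)),
         counts = downsample_counts(N, depth, seed = s))
  })
  list(pseudobulks = pb, pseudobulks_genome = pb_genome,
       labels = labels, scenarios = scenarios)
}

#' Generate a synthetic multi-cell-type fixture
#'
#' Builds a toy genome and a labeled count matrix with known cell-type
#' structure: each type owns a disjoint set of "marked" bins in which its
#' cells draw Poisson counts at `fold` times the background rate. The
#' marked bins double as the peak set. `fold = 1` yields a structureless
#' null dataset in which labels carry no signal.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param n_bins total genome bins (50 kb each, split over two
#'   chromosomes).
#' @param frac_marked fraction of all bins that are marked, split evenly
#'   across types.
#' @param fold enrichment of a type's rate in its own marked bins (`>= 1`).
#' @param base_rate background Poisson rate per bin before depth scaling.
#' @param depth expected total counts per cell.
#' @param seed integer seed.
#' @return List with `counts` (sparse cell x bin), `labels`, `peaks`
#'   (`GRanges` over the marked bins), `grid`, `layout` and
#'   `marked_bins` (per-type bin indices).
#' @export
make_fixture <- function(n_types = 4L, cells_per_type = 100L, n_bins = 2000L,
                         frac_marked = 0.1, fold = 8, base_rate = 1,
                         depth = 5000L, seed = 1L) {
  if (frac_marked <= 0 || frac_marked >= 1) stop("frac_marked must be in (0,1)")
  if (fold < 1) stop("fold must be >= 1")
  bin_width <- 50000L
  n1 <- ceiling(n_bins / 2)
  layout <- genome_layout(c("chrA", "chrB"),
                          c(n1, n_bins - n1) * bin_width)
  grid <- tile_genome(layout, bin_width)
  stopifnot(length(grid) == n_bins)
  per_type <- floor(frac_marked * n_bins / n_types)
  if (per_type < 1 || per_type * n_types > n_bins)
    stop("marked-bin demand incompatible with n_bins")
  set.seed(seed)
  marked_all <- sample(n_bins, per_type * n_types)
  marked <- split(marked_all, rep(seq_len(n_types), each = per_type))
  types <- paste0("type", seq_len(n_types))
  names(marked) <- types
  m <- n_types * cells_per_type
  cell_type <- rep(types, each = cells_per_type)
  rate <- matrix(base_rate, nrow = m, ncol = n_bins)
  for (t in seq_len(n_types))
    rate[cell_type == types[t], marked[[t]]] <- base_rate * fold
  rate <- rate * depth / rowSums(rate)
  counts <- matrix(stats::rpois(length(rate), rate), nrow = m)
  rownames(counts) <- sprintf("cell%04d", seq_len(m))
  colnames(counts) <- S4Vectors::mcols(grid)$bin_id
  peaks <- GenomicRanges::reduce(GenomicRanges::sort(grid[sort(marked_all)]))
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       labels = data.frame(cell_id = rownames(counts), cell_type = cell_type),
       peaks = peaks, grid = grid, layout = layout, marked_bins = marked)
}
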