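# Genomic coordinate model: genome layouts, fixed-width bin grids, peak
# filtering/merging, bin-peak overlap, promoter windows and peak shuffling.
#
# Intervals are held as GRanges (1-based, closed). All text interfaces
# (BED, chrom.sizes, features.tsv) use the BED convention, 0-based
# half-open; conversion happens at read/write time. The edge-to-edge gap
# between two non-overlapping intervals is identical in both conventions,
# so gap-based rules below can be stated once.

#' Describe a genome as an ordered set of chromosome lengths
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths positive integer lengths (bp), same order.
#' @return A [GenomeInfoDb::Seqinfo] object used as the genome layout by
#'   all interval operations.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(100000, 60000))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  if (length(chrom_names) == 0L) stop("empty genome layout")
  if (anyDuplicated(chrom_names)) stop("duplicate chromosome names")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != round(chrom_lengths)))
    stop("chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom_names),
                        seqlengths = as.integer(chrom_lengths))
}

#' Tile a genome into fixed-width bins
#'
#' Bins are adjacent, non-overlapping, start at the first base of each
#' chromosome, and the last bin of a chromosome is clipped at the
#' chromosome end, so each chromosome contributes `ceiling(length / width)`
#' bins. 50 kb is the standard resolution for sortChIC-scale data; 10 kb
#' suits scCUT&Tag.
#'
#' @param layout a `Seqinfo` from [genome_layout()].
#' @param bin_width bin width in bp (default 50000).
#' @return A `GRanges` of bins ordered by chromosome then position, with a
#'   `bin_id` metadata column (`chrom:start-end`, BED coordinates).
#' @export
tile_genome <- function(layout, bin_width = 50000L) {
  stopifnot(methods::is(layout, "Seqinfo"))
  if (length(layout) == 0L) stop("empty genome layout")
  if (bin_width <= 0) stop("bin_width must be positive")
  bins <- GenomicRanges::tileGenome(layout, tilewidth = bin_width,
                                    cut.last.tile.in.chrom = TRUE)
  S4Vectors::mcols(bins)$bin_id <- bin_ids(bins)
  bins
}

# BED-style identifiers for a set of ranges
bin_ids <- function(gr) {
  paste0(as.character(GenomeInfoDb::seqnames(gr)), ":",
         GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

#' Filter peak calls by isolation, proximity merging and minimum width
#'
#' Applies three rules, in order: (1) drop peaks whose edge-to-edge gap to
#' the nearest same-chromosome peak exceeds `isolation_range` (a peak with
#' no neighbor on its chromosome is dropped too); (2) merge peaks whose
#' edge-to-edge gap is at most `merge_gap`; (3) drop merged intervals
#' narrower than `min_width`. This mirrors the post-processing typically
#' applied to broad-domain callers before computing signal-in-peaks, where
#' scattered isolated calls and sub-domain fragments are uninformative.
#'
#' @param peaks `GRanges` of peak calls.
#' @param isolation_range maximum gap (bp) to the nearest peak for a peak
#'   to be retained (default 50000).
#' @param merge_gap maximum gap (bp) between peaks that are merged
#'   (default 5000).
#' @param min_width minimum width (bp) of a merged interval (default 10000).
#' @param isolate_after_merge if `TRUE`, apply the isolation rule after
#'   merging instead of before.
#' @return Filtered, sorted `GRanges`.
#' @export
filter_peaks <- function(peaks, isolation_range = 50000L, merge_gap = 5000L,
                         min_width = 10000L, isolate_after_merge = FALSE) {
  stopifnot(methods::is(peaks, "GRanges"))
  peaks <- GenomicRanges::sort(peaks)
  drop_isolated <- function(gr) {
    if (length(gr) == 0L) return(gr)
    hits <- GenomicRanges::distanceToNearest(gr)
    keep <- logical(length(gr))
    keep[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(hits)$distance <= isolation_range
    gr[keep]
  }
  merge_close <- function(gr)
    GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  if (isolate_after_merge) {
    peaks <- drop_isolated(merge_close(peaks))
  } else {
    peaks <- merge_close(drop_isolated(peaks))
  }
  peaks[GenomicRanges::width(peaks) >= min_width]
}

#' Merge peaks separated by less than a given gap
#'
#' Transitive merge of intervals whose edge-to-edge gap is strictly less
#' than `gap`; used to consolidate fragmented domains before enrichment
#' profiling.
#'
#' @param peaks `GRanges`.
#' @param gap separation threshold in bp (default 50000).
#' @return Sorted, non-overlapping `GRanges`.
#' @export
merge_close_peaks <- function(peaks, gap = 50000L) {
  stopifnot(methods::is(peaks, "GRanges"))
  GenomicRanges::reduce(GenomicRanges::sort(peaks), min.gapwidth = gap)
}

#' Flag bins overlapping any peak
#'
#' @param grid bin `GRanges` from [tile_genome()].
#' @param peaks peak `GRanges` on the same layout.
#' @return Logical vector, one entry per bin; `TRUE` where the bin shares
#'   at least 1 bp with a peak.
#' @export
bins_in_peaks <- function(grid, peaks) {
  stopifnot(methods::is(grid, "GRanges"), methods::is(peaks, "GRanges"))
  known <- GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(grid))
  bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(peaks))), known)
  if (length(bad))
    stop("peaks on chromosomes absent from the bin grid: ",
         paste(bad, collapse = ", "))
  IRanges::overlapsAny(grid, peaks, ignore.strand = TRUE)
}

#' Build promoter windows around transcription start sites
#'
#' The window spans `upstream` bp before to `downstream` bp after the TSS
#' in the direction of transcription (defaults 500 bp upstream, 2 kb
#' downstream), clipped at chromosome bounds. In BED coordinates the
#' window is `[pos - upstream, pos + downstream)` on the plus strand and
#' its mirror image `[pos - downstream, pos + upstream)` on the minus
#' strand.
#'
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (0-based TSS
#'   coordinate) and `strand` (`+` or `-`).
#' @param layout `Seqinfo` genome layout.
#' @param upstream,downstream window extents in bp.
#' @return `GRanges` of promoter windows with a `gene` metadata column.
#' @export
promoter_windows <- function(tss, layout, upstream = 500L, downstream = 2000L) {
  required <- c("gene", "chrom", "pos", "strand")
  if (!all(required %in% names(tss)))
    stop("tss needs columns: ", paste(required, collapse = ", "))
  if (!all(tss$strand %in% c("+", "-")))
    stop("every TSS needs a strand of '+' or '-'")
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$pos - upstream, tss$pos - downstream)
  end0 <- ifelse(plus, tss$pos + downstream, tss$pos + upstream)
  lens <- GenomeInfoDb::seqlengths(layout)[tss$chrom]
  if (anyNA(lens))
    stop("TSS on chromosomes absent from the layout: ",
         paste(unique(tss$chrom[is.na(lens)]), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(start0, 0) + 1L,
                              end = pmin(end0, lens)),
    strand = tss$strand,
    gene = tss$gene,
    seqinfo = layout)
}

#' Randomly relocate peaks within their chromosomes
#'
#' Generates `n_sets` permuted peak sets. Every peak keeps its width and
#' chromosome; its start is drawn uniformly over the positions at which the
#' peak still fits. Used to build permutation nulls for signal-in-peaks.
#'
#' @param peaks `GRanges`; widths must not exceed their chromosome length.
#' @param layout `Seqinfo` genome layout.
#' @param n_sets number of permuted sets (default 1000).
#' @param seed integer seed; the same seed reproduces the same sets.
#' @return List of `GRanges` of length `n_sets`.
#' @export
shuffle_peaks <- function(peaks, layout, n_sets = 1000L, seed = 1L) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(layout, "Seqinfo"))
  chr <- as.character(GenomeInfoDb::seqnames(peaks))
  len <- GenomeInfoDb::seqlengths(layout)[chr]
  w <- GenomicRanges::width(peaks)
  if (any(is.na(len)))
    stop("peaks on chromosomes absent from the layout")
  if (any(w > len))
    stop("peak wider than its chromosome")
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    # starts uniform over [1, len - w + 1] (1-based), preserving width
    start <- floor(stats::runif(length(peaks)) * (len - w + 1)) + 1
    GenomicRanges::GRanges(
      seqnames = chr,
      ranges = IRanges::IRanges(start = as.integer(start), width = w),
      seqinfo = layout)
  })
}
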