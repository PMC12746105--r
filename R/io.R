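# Readers and writers for the framework's on-disk formats: Matrix Market
# counts with barcode/feature sidecars, dense TSV matrices, BED peaks,
# chrom.sizes tables, label tables and TSS tables.
#
# On disk, coordinates follow the BED convention (0-based half-open);
# in memory, intervals are GRanges (1-based closed). features.tsv carries
# BED-style chrom/start/end per bin.

sidecar_paths <- function(mtx_path) {
  dir <- dirname(mtx_path)
  list(barcodes = file.path(dir, "barcodes.tsv"),
       features = file.path(dir, "features.tsv"))
}

#' Read a count matrix from Matrix Market or dense TSV
#'
#' `.mtx` files are read with their sibling `barcodes.tsv` /
#' `features.tsv`; orientation is auto-detected by matching the sidecar
#' lengths to the matrix dimensions and normalized to cells x features
#' (for a square matrix `orientation` must be given). Any other extension
#' is parsed as dense TSV with a header row of feature names and a first
#' column of cell ids.
#'
#' @param path path to `.mtx` or TSV file.
#' @param orientation `"auto"`, `"cells_by_features"` or
#'   `"features_by_cells"` (MTX only).
#' @return cell x feature matrix (sparse for MTX input).
#' @export
read_count_matrix <- function(path,
                              orientation = c("auto", "cells_by_features",
                                              "features_by_cells")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    sc <- sidecar_paths(path)
    if (!file.exists(sc$barcodes) || !file.exists(sc$features))
      stop("missing barcodes.tsv / features.tsv next to ", path)
    barcodes <- utils::read.delim(sc$barcodes, header = FALSE)[[1]]
    feat <- utils::read.delim(sc$features, header = FALSE,
                              stringsAsFactors = FALSE)
    features <- if (ncol(feat) >= 3)
      paste0(feat[[1]], ":", feat[[2]], "-", feat[[3]]) else feat[[1]]
    if (orientation == "auto") {
      if (nrow(m) == length(barcodes) && ncol(m) == length(features) &&
          length(barcodes) != length(features)) {
        orientation <- "cells_by_features"
      } else if (nrow(m) == length(features) && ncol(m) == length(barcodes) &&
                 length(barcodes) != length(features)) {
        orientation <- "features_by_cells"
      } else if (nrow(m) == ncol(m) && length(barcodes) == length(features)) {
        stop("square matrix: orientation is ambiguous, pass orientation=")
      } else {
        stop("matrix dimensions (", nrow(m), " x ", ncol(m),
             ") do not match sidecars (", length(barcodes), " barcodes, ",
             length(features), " features)")
      }
    }
    if (orientation == "features_by_cells") m <- Matrix::t(m)
    if (nrow(m) != length(barcodes) || ncol(m) != length(features))
      stop("matrix dimensions do not match sidecars")
    dimnames(m) <- list(as.character(barcodes), features)
  } else {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("malformed dense matrix: non-numeric entries")
  }
  if (min(m) < 0) stop("negative entries in count matrix")
  m
}

#' Write a count matrix as Matrix Market or dense TSV
#'
#' MTX output is written features x cells (the usual single-cell layout)
#' with `barcodes.tsv` and `features.tsv` sidecars; feature ids of the
#' form `chrom:start-end` are expanded into three BED-style columns.
#' Output is deterministic for identical input.
#'
#' @param matrix cell x feature matrix.
#' @param path output path (`.mtx` or `.tsv`).
#' @param format `"mtx"` or `"tsv"`; default follows the extension.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path,
                               format = if (grepl("\\.mtx$", path)) "mtx"
                                        else "tsv") {
  check_count_matrix(matrix)
  format <- match.arg(format, c("mtx", "tsv"))
  if (format == "mtx") {
    sc <- sidecar_paths(path)
    Matrix::writeMM(methods::as(Matrix::t(
      Matrix::Matrix(matrix, sparse = TRUE)), "generalMatrix"), path)
    writeLines(rownames(matrix), sc$barcodes)
    feats <- colnames(matrix)
    coords <- regmatches(feats, regexec("^([^:]+):([0-9]+)-([0-9]+)$", feats))
    if (all(lengths(coords) == 4L)) {
      tab <- do.call(rbind, coords)[, 2:4, drop = FALSE]
      utils::write.table(tab, sc$features, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(feats, sc$features)
    }
  } else {
    tab <- as.matrix(matrix)
    out <- data.frame(cell_id = rownames(tab), tab, check.names = FALSE)
    utils::write.table(format(out, digits = 6, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell label table
#'
#' Tab-separated `cell_id`, `cell_type`; a header row is detected and
#' skipped.
#' @param path labels TSV.
#' @return data.frame with `cell_id` and `cell_type`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty labels file: ", path)
  if (ncol(tab) < 2L) stop("labels file needs two columns (cell_id, cell_type)")
  if (identical(tolower(as.character(tab[1, 1:2])), c("cell_id", "cell_type")))
    tab <- tab[-1, , drop = FALSE]
  out <- data.frame(cell_id = as.character(tab[[1]]),
                    cell_type = as.character(tab[[2]]))
  if (anyDuplicated(out$cell_id)) stop("duplicate cell ids in ", path)
  out
}

#' Read a chrom.sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#' @param path chrom.sizes file.
#' @return `Seqinfo` genome layout.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(len) || any(len != round(len)))
    stop("non-integer chromosome length in ", path)
  genome_layout(as.character(tab[[1]]), len)
}

#' Write a chrom.sizes table
#' @param layout `Seqinfo`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(layout),
               GenomeInfoDb::seqlengths(layout)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED3/BED6 intervals
#'
#' 0-based half-open on disk, converted to `GRanges`. Intervals are
#' validated against the layout when one is given.
#'
#' @param path BED file.
#' @param layout optional `Seqinfo`; unknown chromosomes or out-of-bounds
#'   intervals are errors.
#' @return Sorted `GRanges`.
#' @export
read_bed <- function(path, layout = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty BED file: ", path)
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns")
  start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
  if (any(end0 <= start0)) stop("BED interval with end <= start in ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tab[[1]]),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = if (ncol(tab) >= 6) tab[[6]] else "*")
  if (!is.null(layout)) {
    bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                   GenomeInfoDb::seqnames(layout))
    if (length(bad))
      stop("BED chromosome(s) absent from layout: ", paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
    if (any(GenomicRanges::end(gr) >
            GenomeInfoDb::seqlengths(layout)[as.character(
              GenomeInfoDb::seqnames(gr))]))
      stop("BED interval beyond chromosome end in ", path)
  }
  GenomicRanges::sort(gr)
}

#' Write intervals as BED3
#' @param gr `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  utils::write.table(
    data.frame(as.character(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated `gene`, `chrom`, `pos` (0-based), `strand`; header
#' detected and skipped.
#' @param path TSS TSV.
#' @return data.frame suitable for [promoter_windows()].
#' @export
read_tss <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("TSS table needs columns gene, chrom, pos, strand")
  if (identical(tolower(as.character(tab[1, 1])), "gene"))
    tab <- tab[-1, , drop = FALSE]
  data.frame(gene = as.character(tab[[1]]), chrom = as.character(tab[[2]]),
             pos = as.numeric(tab[[3]]), strand = as.character(tab[[4]]))
}

#' Read labels, genome layout and optional peaks together
#'
#' @param labels_path labels TSV.
#' @param chromsizes_path chrom.sizes TSV.
#' @param bed_path optional peak BED, validated against the layout.
#' @return List with `labels`, `layout` and `peaks` (`NULL` when no BED).
#' @export
read_annotations <- function(labels_path, chromsizes_path, bed_path = NULL) {
  layout <- read_chrom_sizes(chromsizes_path)
  list(labels = read_labels(labels_path),
       layout = layout,
       peaks = if (!is.null(bed_path)) read_bed(bed_path, layout) else NULL)
}
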