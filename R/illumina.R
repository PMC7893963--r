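#' Intron-tolerant gene assignment
#'
#' Assigns a read to a gene when every aligned block falls inside that
#' gene's span (exons plus introns) on the matching strand.  This counts
#' intron-containing nuclear reads the way stripping intron sequence before
#' re-alignment would, without re-aligning.  Reads whose blocks touch more
#' than one gene span, or no gene span, are unassigned.
#'
#' @param read_blocks integer matrix of aligned blocks (0-based half-open).
#' @param chrom chromosome of the read.
#' @param models a `gene_models` object.
#' @param strand read strand; `NULL` disables strand matching (antisense
#'   reads are never assigned under the default stranded 3' chemistry).
#' @return the `gene_id`, or `NA_character_` when intergenic or ambiguous.
#' @export
assign_gene_intron_tolerant <- function(read_blocks, chrom, models,
                                        strand = NULL) {
  idx <- gene_index(models)
  lo <- min(read_blocks[, 1])
  hi <- max(read_blocks[, 2])
  hit <- idx$chrom == chrom & idx$start < hi & idx$end > lo
  if (sum(hit) != 1) return(NA_character_)
  g <- idx[hit, ]
  if (!is.null(strand) && g$strand != strand) return(NA_character_)
  if (g$start <= lo && g$end >= hi) g$gene_id else NA_character_
}

#' Build the abundance layer from guide records
#'
#' Entry (nucleus, gene) is the number of distinct UMIs observed for that
#' pair; duplicate (barcode, umi, gene) rows collapse to one molecule.
#'
#' @param guide_records guide record data.frame
#'   (see [read_guide_records()]).
#' @param models a `gene_models` object; records carrying a gene id absent
#'   from the models are skipped with a warning.
#' @return a `layer_matrix` of layer `"abundance"`.
#' @export
build_abundance_matrix <- function(guide_records, models) {
  g <- guide_records
  known <- g$gene_id %in% names(models)
  if (any(!known)) {
    warning(sum(!known), " guide record(s) with unknown gene_id skipped")
    g <- g[known, , drop = FALSE]
  }
  g <- unique(g[, c("barcode", "umi", "gene_id")])
  if (nrow(g) == 0)
    return(layer_matrix(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = double(0), dims = c(0, 0),
      dimnames = list(character(0), character(0))), "abundance"))
  bcs <- sort(unique(g$barcode))
  gids <- names(models)[names(models) %in% unique(g$gene_id)]
  m <- Matrix::sparseMatrix(
    i = match(g$barcode, bcs), j = match(g$gene_id, gids), x = 1,
    dims = c(length(bcs), length(gids)), dimnames = list(bcs, gids))
  layer_matrix(m, "abundance")
}

#' Quality-control thresholds
#'
#' The root preset discards genes expressed in fewer than 3 nuclei and
#' removes nuclei with fewer than 350 or more than 2300 detected genes
#' (both comparisons strict); `qc_thresholds(400, 3000, 1)` reproduces the
#' endosperm preset, which filters nuclei only.
#'
#' @param min_genes_per_cell,max_genes_per_cell nucleus detected-gene
#'   bounds (kept iff `min <= n <= max`).
#' @param min_cells_per_gene gene support bound (kept iff expressed in at
#'   least this many nuclei).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 350L,
                          max_genes_per_cell = 2300L,
                          min_cells_per_gene = 3L) {
  if (min_genes_per_cell >= max_genes_per_cell)
    stop("min_genes_per_cell must be < max_genes_per_cell")
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_genes_per_cell = as.integer(max_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Filter a layer matrix by gene and nucleus QC
#'
#' Genes are filtered before nuclei, and the two filters are re-applied to
#' a fixed point so the result is stable under re-application.
#'
#' @param matrix a `layer_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `layer_matrix`.  Raises an error when the
#'   thresholds eliminate every nucleus.
#' @export
qc_filter <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "layer_matrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- matrix$counts
  repeat {
    gene_support <- Matrix::colSums(m > 0)
    keep_g <- gene_support >= thresholds$min_cells_per_gene
    m2 <- m[, keep_g, drop = FALSE]
    genes_per_cell <- Matrix::rowSums(m2 > 0)
    keep_c <- genes_per_cell >= thresholds$min_genes_per_cell &
      genes_per_cell <= thresholds$max_genes_per_cell
    m2 <- m2[keep_c, , drop = FALSE]
    if (nrow(m2) == 0)
      stop("QC thresholds eliminated all nuclei")
    if (all(dim(m2) == dim(m))) break
    m <- m2
  }
  layer_matrix(m, matrix$layer)
}

#' Build the genomic bin index of guide records
#'
#' Buckets guide records into non-overlapping `bin_size`-bp genomic bins
#' (a record at position p lives in bin `floor(p / bin_size)`), so that
#' candidate retrieval for a long read only touches the bins overlapping
#' or adjacent to its mapped span.
#'
#' @param guide_records guide record data.frame.
#' @param bin_size bin width in bp (500 by default).
#' @return a `bin_index`.
#' @export
build_bin_index <- function(guide_records, bin_size = 500L) {
  g <- validate_guide_records(guide_records)
  ord <- g$position %/% as.integer(bin_size)
  key <- paste0(g$chrom, ":", ord)
  structure(list(records = g, bin_size = as.integer(bin_size),
                 bins = split(seq_len(nrow(g)), key)),
            class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("<bin_index: %d records in %d bins of %d bp>\n",
              nrow(x$records), length(x$bins), x$bin_size))
  invisible(x)
}

#' Retrieve guide records near a genomic interval
#'
#' Returns the records of every bin overlapping `[start, end)` plus
#' `adjacent` extra bins on each side (clamped at the chromosome origin).
#' `adjacent = Inf` disables binning and returns every record, for
#' exhaustive oracle runs.
#'
#' @param index a [build_bin_index()] result.
#' @param chrom,start,end query interval (0-based half-open).
#' @param adjacent number of flanking bins included beyond the overlapped
#'   ones.
#' @return data.frame of guide records.
#' @export
lookup_bins <- function(index, chrom, start, end, adjacent = 1L) {
  stopifnot(inherits(index, "bin_index"))
  if (is.infinite(adjacent)) return(index$records)
  bs <- index$bin_size
  b0 <- max(0L, start %/% bs - as.integer(adjacent))
  b1 <- (end - 1L) %/% bs + as.integer(adjacent)
  keys <- paste0(chrom, ":", b0:b1)
  idx <- unlist(index$bins[keys], use.names = FALSE)
  index$records[idx, , drop = FALSE]
}
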