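#' Sparse nuclei-by-features layer matrix
#'
#' One layer of the multilayer representation: a sparse nonnegative integer
#' matrix with nuclei (cell barcodes) as rows and features as columns,
#' tagged with its layer kind.  Feature ids are namespaced by layer
#' (`"gene"` for abundance, `"gene|spliced"` / `"gene|unspliced"` for the
#' splicing layer, `"gene|PA1"` ... for the APA layer).
#'
#' @param counts a matrix or `dgCMatrix` with rownames (nucleus barcodes)
#'   and colnames (feature ids).
#' @param layer one of `"abundance"`, `"splicing"`, `"apa"`.
#' @return a `layer_matrix`.
#' @export
layer_matrix <- function(counts, layer = c("abundance", "splicing", "apa")) {
  layer <- match.arg(layer)
  if (is.matrix(counts)) storage.mode(counts) <- "double"
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (!is(counts, "dMatrix")) counts <- counts * 1  # pattern/logical input
  counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("layer matrix counts must be nonnegative")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("layer matrix needs nucleus and feature names")
  structure(list(counts = counts, layer = layer), class = "layer_matrix")
}

#' @export
print.layer_matrix <- function(x, ...) {
  cat(sprintf("<layer_matrix '%s': %d nuclei x %d features, %d nonzeros>\n",
              x$layer, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.layer_matrix <- function(x) dim(x$counts)

#' Nucleus barcodes of a layer matrix
#' @param x a `layer_matrix`.
#' @return character vector of row (nucleus) names.
#' @export
nuclei <- function(x) rownames(x$counts)

#' Feature ids of a layer matrix
#' @param x a `layer_matrix`.
#' @return character vector of column (feature) names.
#' @export
features <- function(x) colnames(x$counts)

#' Write a layer matrix in 10x-style MatrixMarket layout
#'
#' Writes `matrix.mtx` (nuclei x features triplets), `barcodes.tsv` (row
#' names) and `features.tsv` (feature id + layer tag) into `dir`.  The
#' layout round-trips losslessly through [read_layer_matrix()].
#'
#' @param matrix a `layer_matrix`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_layer_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "layer_matrix"))
  m <- matrix$counts
  if (length(rownames(m)) != nrow(m) || length(colnames(m)) != ncol(m))
    stop("barcode/feature names do not match matrix dimensions")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = colnames(m), layer = matrix$layer),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a layer matrix written by [write_layer_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return a `layer_matrix`.
#' @export
read_layer_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  fpath <- file.path(dir, "features.tsv")
  ft <- if (file.size(fpath) > 0)
    read.delim(fpath, header = FALSE, stringsAsFactors = FALSE)
  else data.frame(V1 = character(0), V2 = character(0))
  if (length(bc) != nrow(m) || nrow(ft) != ncol(m))
    stop("barcode/feature sidecars do not match matrix dimensions")
  dimnames(m) <- list(bc, ft[[1]])
  layer <- if (nrow(ft) > 0) ft[[2]][1] else "abundance"
  layer_matrix(m, layer = layer)
}

#' Read Illumina-derived guide records
#'
#' Guide records are the (barcode, UMI, gene, position) combinations
#' identified from the accurate short-read library of the same cDNA pool;
#' they define the search space for long-read barcode rescue.
#'
#' @param path TSV with columns `barcode`, `umi`, `gene_id`, `chrom`,
#'   `position` (0-based bp).
#' @param barcode_len,umi_len enforced lengths (10x chemistry: 16 and 10).
#' @return data.frame of validated records.
#' @export
read_guide_records <- function(path, barcode_len = 16L, umi_len = 10L) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "umi", "gene_id", "chrom", "position")
  if (!all(need %in% names(g)))
    stop("guide TSV must have columns: ", paste(need, collapse = ", "))
  validate_guide_records(g[need], barcode_len, umi_len)
}

validate_guide_records <- function(g, barcode_len = 16L, umi_len = 10L) {
  if (any(nchar(g$barcode) != barcode_len) ||
      any(grepl("[^ACGT]", g$barcode)))
    stop("barcodes must be ", barcode_len, "-nt over {A,C,G,T}")
  if (any(nchar(g$umi) != umi_len) || any(grepl("[^ACGT]", g$umi)))
    stop("UMIs must be ", umi_len, "-nt over {A,C,G,T}")
  if (any(g$position < 0)) stop("guide positions must be nonnegative")
  g$position <- as.integer(g$position)
  g
}

#' Write guide records
#' @param records guide record data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param ids,seqs read names and sequences (read orientation).
#' @param path output path.  Constant placeholder qualities are written.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
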