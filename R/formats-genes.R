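#' Gene model container
#'
#' A `gene_models` object is a named list of genes, each holding sorted
#' non-overlapping exons and the introns derived as the gaps between
#' consecutive exons.  All coordinates are 0-based half-open genomic bp;
#' GTF/GFF input (1-based closed) is converted at the boundary, so a GTF
#' exon `1..100` becomes `[0, 100)`.
#'
#' @param gene_id,chrom,strand gene identity and location.
#' @param exons integer matrix (`start`, `end`), 0-based half-open.
#' @return a `gene_model` list with derived `introns`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  introns <- if (nrow(exons) > 1)
    cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
  else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (nrow(introns) > 0 && any(introns[, 2] - introns[, 1] < 1))
    stop("zero-length intron in gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, introns = introns,
                 start = exons[1, 1], end = exons[nrow(exons), 2]),
            class = "gene_model")
}

new_gene_models <- function(genes) {
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  idx <- data.frame(
    gene_id = names(genes),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    start = vapply(genes, `[[`, integer(1), "start"),
    end = vapply(genes, `[[`, integer(1), "end"),
    n_introns = vapply(genes, function(g) nrow(g$introns), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(genes, index = idx, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  idx <- attr(x, "index")
  cat(sprintf("<gene_models: %d genes on %d chromosome(s)>\n",
              nrow(idx), length(unique(idx$chrom))))
  invisible(x)
}

#' @export
`[.gene_models` <- function(x, i) {
  new_gene_models(unclass(x)[i])
}

#' Summary index of a gene model set
#'
#' @param models a `gene_models` object.
#' @return data.frame with one row per gene (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_introns`).
#' @export
gene_index <- function(models) attr(models, "index")

#' Read gene models from GTF/GFF3
#'
#' Builds one [gene_model] per gene from the exon features of an annotation
#' file, converting to 0-based half-open coordinates and deriving introns.
#' Exon order in the file is irrelevant.  If explicit gene features are
#' present, exons falling outside their gene's bounds raise an error naming
#' the gene.
#'
#' @param gtf_source path to a GTF or GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(gtf_source) {
  gr <- rtracklayer::import(gtf_source)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$gene_id)
  ex <- gr[type == "exon"]
  exid <- gid[type == "exon"]
  if (length(ex) == 0) stop("no exon features in ", gtf_source)
  if (any(type == "gene")) {
    gn <- gr[type == "gene"]
    gnid <- gid[type == "gene"]
    for (i in seq_along(gn)) {
      e <- ex[exid == gnid[i]]
      if (length(e) > 0 &&
          (min(IRanges::start(e)) < IRanges::start(gn[i]) ||
           max(IRanges::end(e)) > IRanges::end(gn[i])))
        stop("exon outside gene bounds for gene ", gnid[i])
    }
  }
  genes <- lapply(split(seq_along(ex), exid), function(ii) {
    e <- ex[ii]
    e <- IRanges::reduce(e)  # merge duplicate/overlapping exon records
    gene_model(gene_id = exid[ii[1]],
               chrom = as.character(GenomeInfoDb::seqnames(e))[1],
               strand = as.character(BiocGenerics::strand(e))[1],
               exons = cbind(IRanges::start(e) - 1L, IRanges::end(e)))
  })
  new_gene_models(genes)
}

#' Write gene models as GTF
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- unlist(lapply(models, function(g) {
    gene_line <- sprintf(
      "%s\tnucleolong\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
    exon_lines <- sprintf(
      "%s\tnucleolong\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      g$chrom, g$exons[, 1] + 1L, g$exons[, 2], g$strand, g$gene_id)
    c(gene_line, exon_lines)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
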