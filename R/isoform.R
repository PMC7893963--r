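#' Fraction of an intron covered by aligned blocks
#'
#' @param read_blocks integer matrix of aligned blocks (0-based half-open).
#' @param intron length-2 vector or 1-row matrix `(start, end)`.
#' @return covered bases / intron length, in `[0, 1]`.
#' @export
intron_mapping_ratio <- function(read_blocks, intron) {
  intron <- as.integer(intron)
  len <- intron[2] - intron[1]
  stopifnot(len >= 1)
  ov <- pmin(read_blocks[, 2], intron[2]) - pmax(read_blocks[, 1], intron[1])
  sum(pmax(ov, 0L)) / len
}

#' Call the splicing status of one molecule
#'
#' An intron is retained when the molecule's blocks cover more than
#' `ratio_threshold` of it (strictly; exactly half covered is not
#' retained).  Introns lying entirely outside the molecule's aligned span
#' (5'-truncated reads) are unobserved: they contribute evidence neither
#' way and their flag is `NA`.  A molecule is `unspliced` when at least one
#' observed intron is retained, `spliced` when all observed introns are
#' clean (intronless genes are spliced by definition), and `indeterminate`
#' when no intron of an intron-bearing gene was observed.
#'
#' @param read_blocks aligned blocks of the molecule.
#' @param gene_model the molecule's [gene_model].
#' @param ratio_threshold retention threshold on the intron mapping ratio.
#' @return list with `flags` (logical per intron, `NA` = unobserved) and
#'   `status`.
#' @export
call_splicing <- function(read_blocks, gene_model, ratio_threshold = 0.5) {
  introns <- gene_model$introns
  if (nrow(introns) == 0)
    return(list(flags = logical(0), status = "spliced"))
  span_lo <- min(read_blocks[, 1])
  span_hi <- max(read_blocks[, 2])
  flags <- rep(NA, nrow(introns))
  for (i in seq_len(nrow(introns))) {
    if (introns[i, 2] <= span_lo || introns[i, 1] >= span_hi) next
    flags[i] <- intron_mapping_ratio(read_blocks, introns[i, ]) >
      ratio_threshold
  }
  status <- if (all(is.na(flags))) "indeterminate"
    else if (any(flags, na.rm = TRUE)) "unspliced" else "spliced"
  list(flags = flags, status = status)
}

#' Genomic polyA site of a molecule
#'
#' The aligned 3' terminus, strand-aware: the rightmost block end on the
#' plus strand, the leftmost block start on the minus strand (the strand is
#' the mRNA/gene strand, not the strand the cDNA read mapped to).
#'
#' @param read_blocks aligned blocks of the molecule.
#' @param strand gene strand, `"+"` or `"-"`.
#' @return integer genomic position.
#' @export
extract_polya_site <- function(read_blocks, strand) {
  if (strand == "+") max(read_blocks[, 2]) else min(read_blocks[, 1])
}

#' Single-linkage clustering of polyA sites
#'
#' Sorts the sites and cuts wherever the gap between consecutive sites
#' exceeds `threshold` nt, so chains of sites each within `threshold` of
#' the next merge into one cluster.  The representative is the median
#' member (lower of the two middles for even sizes).  Clustering is
#' invariant to input permutation; it is intended per gene and strand.
#'
#' @param sites integer vector of genomic polyA positions.
#' @param threshold maximal intra-cluster gap in nt.
#' @return list of clusters, each with `members` (sorted positions, one per
#'   input site) and `representative`; ordered by genomic position.
#' @export
cluster_polya_sites <- function(sites, threshold = 24L) {
  if (length(sites) == 0) return(list())
  s <- sort(as.integer(sites))
  cut_after <- which(diff(s) > threshold)
  bounds <- c(0L, cut_after, length(s))
  lapply(seq_len(length(bounds) - 1L), function(k) {
    m <- s[(bounds[k] + 1L):bounds[k + 1L]]
    list(members = m, representative = m[ceiling(length(m) / 2)])
  })
}

#' Derive per-molecule isoform calls and the splicing/APA layers
#'
#' Runs [call_splicing()] and [extract_polya_site()] on every molecule,
#' clusters polyA sites per gene with [cluster_polya_sites()], and labels
#' each molecule with its polyA cluster.
#'
#' @param molecules a `molecule_set` from [build_molecules()].
#' @param models a `gene_models`.
#' @param pa_threshold polyA cluster gap threshold in nt.
#' @param ir_threshold intron-retention ratio threshold.
#' @return data.frame of per-molecule calls: `barcode`, `umi`, `gene_id`,
#'   `status`, `flags` (";"-joined, `NA` for unobserved), `pa_site`,
#'   `pa_cluster` (feature id `gene|PAk`), `pa_representative`.
#' @export
call_isoforms <- function(molecules, models, pa_threshold = 24L,
                          ir_threshold = 0.5) {
  n <- nrow(molecules)
  status <- character(n)
  flags <- character(n)
  pa_site <- integer(n)
  for (i in seq_len(n)) {
    gm <- models[[molecules$gene_id[i]]]
    cs <- call_splicing(molecules$blocks[[i]], gm, ir_threshold)
    status[i] <- cs$status
    flags[i] <- paste(as.integer(cs$flags), collapse = ";")
    pa_site[i] <- extract_polya_site(molecules$blocks[[i]],
                                     molecules$gene_strand[i])
  }
  calls <- data.frame(barcode = molecules$barcode, umi = molecules$umi,
                      gene_id = molecules$gene_id, status = status,
                      flags = flags, pa_site = pa_site,
                      pa_cluster = NA_character_,
                      pa_representative = NA_integer_,
                      stringsAsFactors = FALSE)
  for (g in unique(calls$gene_id)) {
    ii <- which(calls$gene_id == g)
    cl <- cluster_polya_sites(calls$pa_site[ii], pa_threshold)
    reps <- vapply(cl, `[[`, integer(1), "representative")
    lo <- vapply(cl, function(x) x$members[1], integer(1))
    hi <- vapply(cl, function(x) x$members[length(x$members)], integer(1))
    k <- vapply(calls$pa_site[ii], function(p)
      which(p >= lo & p <= hi)[1], integer(1))
    calls$pa_cluster[ii] <- sprintf("%s|PA%d", g, k)
    calls$pa_representative[ii] <- reps[k]
  }
  calls
}

count_layer <- function(barcode, feature, layer) {
  if (length(barcode) == 0)
    return(layer_matrix(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = double(0), dims = c(0, 0),
      dimnames = list(character(0), character(0))), layer))
  bcs <- sort(unique(barcode))
  fts <- sort(unique(feature))
  m <- Matrix::sparseMatrix(i = match(barcode, bcs),
                            j = match(feature, fts), x = 1,
                            dims = c(length(bcs), length(fts)),
                            dimnames = list(bcs, fts))
  layer_matrix(m, layer)
}

#' Build the splicing layer
#'
#' Two features per gene, `gene|spliced` and `gene|unspliced`; the entry is
#' the number of molecules of that nucleus and gene with that status.
#' Indeterminate molecules (no observed intron) are excluded; intronless
#' genes populate only their `|spliced` feature.
#'
#' @param calls output of [call_isoforms()].
#' @return a `layer_matrix` of layer `"splicing"`.
#' @export
build_splicing_matrix <- function(calls) {
  d <- calls[calls$status %in% c("spliced", "unspliced"), , drop = FALSE]
  count_layer(d$barcode, paste0(d$gene_id, "|", d$status), "splicing")
}

#' Build the APA layer
#'
#' One feature per polyA site cluster; the entry is the number of molecules
#' of that nucleus ending in that cluster.  Clusters partition each gene's
#' molecules, so per gene the APA counts sum to the molecule count.
#'
#' @param calls output of [call_isoforms()].
#' @return a `layer_matrix` of layer `"apa"`.
#' @export
build_apa_matrix <- function(calls) {
  if (any(is.na(calls$pa_cluster)))
    stop("internal error: molecule without a polyA cluster")
  count_layer(calls$barcode, calls$pa_cluster, "apa")
}

#' Per-nucleus incompletely spliced ratio
#'
#' Fraction of a nucleus's determinate molecules that are unspliced
#' (carry at least one retained intron); molecules of intronless genes
#' count as spliced.  Nuclei without determinate molecules are `NA`.
#'
#' @param calls output of [call_isoforms()].
#' @param nucleus optional barcode(s) to restrict to; default all nuclei in
#'   `calls`.
#' @return named numeric vector of ratios in `[0, 1]`.
#' @export
incompletely_spliced_ratio <- function(calls, nucleus = NULL) {
  d <- calls[calls$status %in% c("spliced", "unspliced"), , drop = FALSE]
  bcs <- if (is.null(nucleus)) sort(unique(calls$barcode)) else nucleus
  out <- setNames(rep(NA_real_, length(bcs)), bcs)
  tot <- table(factor(d$barcode, levels = bcs))
  uns <- table(factor(d$barcode[d$status == "unspliced"], levels = bcs))
  has <- tot > 0
  out[has] <- as.numeric(uns[has]) / as.numeric(tot[has])
  out
}
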