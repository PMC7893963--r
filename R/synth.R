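#' Simulation configuration
#'
#' Parameters of the synthetic single-nucleus long-read experiment.  The
#' defaults describe the desk-scale study conditions used throughout the
#' test suite: 10x-style reads (16-nt barcode, 10-nt UMI, 30-nt adapter,
#' 20-nt polyT) over a compact genome, with a 5% per-base channel error rate
#' matching the ~95% per-base accuracy typical of Nanopore basecalls, split
#' 2:1:1 between substitutions, insertions and deletions.
#'
#' @param n_genes,n_nuclei,n_celltypes,reads_per_nucleus experiment sizes
#'   (`reads_per_nucleus` counts molecules per nucleus; each molecule yields
#'   `reads_per_molecule` reads).
#' @param per_base_error_rate probability that a base of a simulated long
#'   read suffers one channel error.
#' @param error_mix relative weights of substitution/insertion/deletion
#'   among channel errors.
#' @param intron_retention_prob per-intron retention probability; a scalar,
#'   or a `n_celltypes x n_genes` matrix giving the probability applied to
#'   every intron of a gene for nuclei of a cell type.
#' @param celltype_gene_weights optional `n_celltypes x n_genes` sampling
#'   weight matrix for molecule gene choice; by default each cell type
#'   up-weights its own block of marker genes 6-fold.
#' @param pa_site_offsets optional list (one entry per gene) of genomic
#'   offsets from the gene 3' end defining that gene's polyA sites; `NULL`
#'   samples one or two sites per gene.
#' @param reads_per_molecule reads sequenced per cDNA molecule (UMI
#'   duplication level).
#' @param p_truncate5 probability that a molecule's read is 5'-truncated,
#'   leaving its upstream introns unobserved.
#' @param intron_range inclusive bounds on the number of introns per gene;
#'   `c(1, 1)` plants single-intron genes so each nucleus's unspliced
#'   fraction estimates the per-intron retention probability directly.
#' @param barcode_len,umi_len,adapter_len,polyt_len read structure lengths.
#' @param genome_len optional genome length; an error is raised if the
#'   requested genes do not fit.  `NULL` sizes the genome automatically.
#' @param seed mandatory RNG seed; every simulation product is a pure
#'   function of the configuration.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 60L, n_nuclei = 120L,
                              n_celltypes = 3L, reads_per_nucleus = 30L,
                              per_base_error_rate = 0.05,
                              error_mix = c(sub = 2, ins = 1, del = 1),
                              intron_retention_prob = 0.25,
                              celltype_gene_weights = NULL,
                              pa_site_offsets = NULL,
                              reads_per_molecule = 1L,
                              p_truncate5 = 0.1,
                              intron_range = c(1L, 5L),
                              barcode_len = 16L, umi_len = 10L,
                              adapter_len = 30L, polyt_len = 20L,
                              genome_len = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  counts <- c(n_genes, n_nuclei, n_celltypes, reads_per_nucleus,
              reads_per_molecule)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (per_base_error_rate < 0 || per_base_error_rate > 1)
    stop("per_base_error_rate must be in [0, 1]")
  if (any(intron_retention_prob < 0) || any(intron_retention_prob > 1))
    stop("intron_retention_prob must be in [0, 1]")
  if (p_truncate5 < 0 || p_truncate5 > 1) stop("p_truncate5 must be in [0, 1]")
  if (length(intron_range) != 2 || intron_range[1] < 1 ||
      intron_range[2] < intron_range[1])
    stop("intron_range must be increasing and >= 1")
  if (is.matrix(intron_retention_prob) &&
      !all(dim(intron_retention_prob) == c(n_celltypes, n_genes)))
    stop("intron_retention_prob matrix must be n_celltypes x n_genes")
  if (!is.null(celltype_gene_weights) &&
      !all(dim(celltype_gene_weights) == c(n_celltypes, n_genes)))
    stop("celltype_gene_weights must be n_celltypes x n_genes")
  structure(list(
    n_genes = as.integer(n_genes), n_nuclei = as.integer(n_nuclei),
    n_celltypes = as.integer(n_celltypes),
    reads_per_nucleus = as.integer(reads_per_nucleus),
    per_base_error_rate = per_base_error_rate,
    error_mix = error_mix / sum(error_mix),
    intron_retention_prob = intron_retention_prob,
    celltype_gene_weights = celltype_gene_weights,
    pa_site_offsets = pa_site_offsets,
    reads_per_molecule = as.integer(reads_per_molecule),
    p_truncate5 = p_truncate5, intron_range = as.integer(intron_range),
    barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
    adapter_len = as.integer(adapter_len), polyt_len = as.integer(polyt_len),
    genome_len = genome_len, seed = as.integer(seed)),
    class = "sim_config")
}

# interval helpers on (start, end) 0-based half-open integer matrices
merge_intervals <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

clip_intervals <- function(m, lo, hi) {
  s <- pmax(m[, 1], lo)
  e <- pmin(m[, 2], hi)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

#' Simulate a reference genome and gene models
#'
#' Lays out `n_genes` multi-exon genes (1-5 introns each, last exon long
#' enough to host alternative polyA sites) along a single synthetic
#' chromosome with at least 2 kb intergenic spacing, so 500-bp genomic bins
#' never mix neighbouring genes.  Byte-identical output under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character, one chromosome), `models`
#'   (a `gene_models`), `pa_sites` (per-gene genomic polyA site positions),
#'   and `chrom_lengths`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cursor <- 1000L
  genes <- vector("list", config$n_genes)
  pa_sites <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", g)
    n_introns <- if (config$intron_range[1] == config$intron_range[2])
      config$intron_range[1]
    else sample(config$intron_range[1]:config$intron_range[2], 1)
    exon_lens <- c(sample(80:250, n_introns, replace = TRUE),
                   sample(220:320, 1))  # roomy terminal exon for APA
    intron_lens <- sample(60:200, n_introns, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") {  # terminal exon sits leftmost on the genome
      exon_lens <- rev(exon_lens)
    }
    starts <- cursor + cumsum(c(0L, head(exon_lens, -1) + intron_lens))
    exons <- cbind(starts, starts + exon_lens)
    genes[[g]] <- gene_model(gid, "chrS", strand, exons)
    gend <- if (strand == "+") max(exons[, 2]) else min(exons[, 1])
    sites <- gend
    if (runif(1) < 0.5) {
      off <- sample(60:150, 1)
      sites <- c(gend, if (strand == "+") gend - off else gend + off)
    }
    if (!is.null(config$pa_site_offsets)) {
      offs <- config$pa_site_offsets[[g]]
      sites <- if (strand == "+") gend - offs else gend + offs
    }
    pa_sites[[g]] <- as.integer(sites)
    cursor <- max(exons[, 2]) + 2000L + sample(0:500, 1)
  }
  names(pa_sites) <- vapply(genes, `[[`, character(1), "gene_id")
  glen <- cursor + 1000L
  if (!is.null(config$genome_len)) {
    if (config$genome_len < glen)
      stop("genome_len ", config$genome_len, " too small for ",
           config$n_genes, " genes (need >= ", glen, ")")
    glen <- as.integer(config$genome_len)
  }
  genome <- c(chrS = paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                           collapse = ""))
  list(genome = genome, models = new_gene_models(genes), pa_sites = pa_sites,
       chrom_lengths = c(chrS = glen))
}

# apply the channel error model to one sequence; every errored base suffers
# exactly one event (substitution to a different base, insertion of a random
# base after it, or deletion)
mutate_seq <- function(s, rate, mix) {
  if (rate <= 0 || !nzchar(s))
    return(list(seq = s, n_sub = 0L, n_ins = 0L, n_del = 0L))
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) == 0)
    return(list(seq = s, n_sub = 0L, n_ins = 0L, n_del = 0L))
  type <- sample(c("S", "I", "D"), length(hit), replace = TRUE, prob = mix)
  bases <- c("A", "C", "G", "T")
  pieces <- as.list(ch)
  for (k in seq_along(hit)) {
    i <- hit[k]
    if (type[k] == "S") {
      pieces[[i]] <- sample(setdiff(bases, ch[i]), 1)
    } else if (type[k] == "I") {
      pieces[[i]] <- c(ch[i], sample(bases, 1))
    } else {
      pieces[[i]] <- character(0)
    }
  }
  list(seq = paste(unlist(pieces), collapse = ""),
       n_sub = sum(type == "S"), n_ins = sum(type == "I"),
       n_del = sum(type == "D"))
}

#' Simulate long reads, guide records and the truth table
#'
#' Draws molecules per nucleus (gene by cell-type weights, per-intron
#' retention by cell-type probabilities, polyA site from the gene's site
#' list), builds each long read as
#' `adapter + barcode + UMI + polyT + revcomp(transcript fragment)`, applies
#' the channel error model, and emits the true alignment geometry directly
#' alongside an error-free guide record per molecule (the short-read library
#' is treated as truth).
#'
#' @param config a [simulation_config()].
#' @param ref output of [simulate_reference()] under the same config.
#' @return list with `reads` (a `long_read_set` of true alignments),
#'   `guide` (guide record data.frame), `truth` (per-read truth rows),
#'   `nuclei` (barcode/cell-type table) and `models`.
#' @export
simulate_reads <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  models <- ref$models
  genome <- ref$genome[["chrS"]]
  n_t <- config$n_celltypes
  celltypes <- paste0("T", seq_len(n_t))
  barcodes <- unique(rand_dna(config$n_nuclei * 2L, config$barcode_len))
  if (length(barcodes) < config$n_nuclei)
    stop("failed to draw distinct barcodes")  # astronomically unlikely
  barcodes <- barcodes[seq_len(config$n_nuclei)]
  nucleus_type <- rep_len(celltypes, config$n_nuclei)

  W <- config$celltype_gene_weights
  if (is.null(W)) {
    W <- matrix(1, n_t, config$n_genes)
    block <- rep_len(seq_len(n_t), config$n_genes)
    for (t in seq_len(n_t)) W[t, block == t] <- 6
  }
  R <- config$intron_retention_prob
  if (!is.matrix(R)) R <- matrix(R, n_t, config$n_genes)

  adapter <- paste(sample(c("A", "C", "G", "T"), config$adapter_len,
                          replace = TRUE), collapse = "")
  polyt <- paste(rep("T", config$polyt_len), collapse = "")
  gids <- names(models)

  n_mol <- config$n_nuclei * config$reads_per_nucleus
  n_reads <- n_mol * config$reads_per_molecule
  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  guide <- vector("list", n_mol)
  ri <- 0L
  for (nu in seq_len(config$n_nuclei)) {
    bc <- barcodes[nu]
    tt <- match(nucleus_type[nu], celltypes)
    gene_draw <- sample.int(config$n_genes, config$reads_per_nucleus,
                            replace = TRUE, prob = W[tt, ])
    for (mm in seq_len(config$reads_per_nucleus)) {
      gi <- gene_draw[mm]
      gm <- models[[gi]]
      umi <- rand_dna(1L, config$umi_len)
      retained <- rbinom(nrow(gm$introns), 1L, R[tt, gi]) == 1L
      sites <- ref$pa_sites[[gm$gene_id]]
      pw <- c(0.7, rep(0.3 / max(1, length(sites) - 1),
                       max(0, length(sites) - 1)))
      pa <- sites[sample.int(length(sites), 1, prob = pw[seq_along(sites)])]
      covered <- rbind(gm$exons, gm$introns[retained, , drop = FALSE])
      covered <- merge_intervals(covered)
      if (gm$strand == "+") {
        covered <- clip_intervals(covered, gm$start, pa)
      } else {
        covered <- clip_intervals(covered, pa, gm$end)
      }
      if (runif(1) < config$p_truncate5) {
        span <- if (gm$strand == "+") c(gm$start, pa) else c(pa, gm$end)
        if (span[2] - span[1] > 250) {
          cut <- sample(seq(span[1] + 50L, span[2] - 200L), 1)
          covered <- if (gm$strand == "+")
            clip_intervals(covered, cut, span[2])
          else clip_intervals(covered, span[1], cut)
        }
      }
      mrna <- paste(substring(genome, covered[, 1] + 1L, covered[, 2]),
                    collapse = "")
      if (gm$strand == "-") mrna <- revcomp(mrna)
      prefix0 <- paste0(adapter, bc, umi, polyt)
      cdna0 <- revcomp(mrna)
      mi <- (nu - 1L) * config$reads_per_nucleus + mm
      guide[[mi]] <- data.frame(barcode = bc, umi = umi,
                                gene_id = gm$gene_id, chrom = gm$chrom,
                                position = pa, stringsAsFactors = FALSE)
      for (dup in seq_len(config$reads_per_molecule)) {
        ri <- ri + 1L
        mp <- mutate_seq(prefix0, config$per_base_error_rate, config$error_mix)
        mc <- mutate_seq(cdna0, config$per_base_error_rate, config$error_mix)
        rid <- sprintf("R%07d", ri)
        reads[[ri]] <- long_read(
          read_id = rid, chrom = gm$chrom,
          strand = if (gm$strand == "+") "-" else "+",
          blocks = covered, clip5 = nchar(mp$seq), clip3 = 0L,
          seq = paste0(mp$seq, mc$seq))
        truth[[ri]] <- data.frame(
          read_id = rid, barcode = bc, umi = umi, gene_id = gm$gene_id,
          celltype = nucleus_type[nu], pa_site = pa,
          retained = paste(as.integer(retained), collapse = ";"),
          n_introns = nrow(gm$introns),
          n_sub = mp$n_sub + mc$n_sub, n_ins = mp$n_ins + mc$n_ins,
          n_del = mp$n_del + mc$n_del,
          template_len = nchar(prefix0) + nchar(cdna0),
          stringsAsFactors = FALSE)
      }
    }
  }
  guide <- unique(do.call(rbind, guide))
  truth <- do.call(rbind, truth)
  list(reads = new_long_read_set(reads), guide = guide, truth = truth,
       nuclei = data.frame(barcode = barcodes, celltype = nucleus_type,
                           stringsAsFactors = FALSE),
       models = models, adapter = adapter)
}

#' Run the full simulation
#'
#' @param config a [simulation_config()].
#' @return list combining [simulate_reference()] and [simulate_reads()]
#'   outputs.
#' @export
simulate_dataset <- function(config) {
  ref <- simulate_reference(config)
  sim <- simulate_reads(config, ref)
  c(list(config = config, genome = ref$genome, pa_sites = ref$pa_sites,
         chrom_lengths = ref$chrom_lengths), sim)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `reads.fastq`, `alignments.sam`,
#' `guide.tsv`, `truth.tsv` and `nuclei.tsv` into `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gset <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(gset, file.path(dir, "genome.fa"))
  write_gene_models(sim$models, file.path(dir, "annotation.gtf"))
  write_fastq(vapply(sim$reads, `[[`, character(1), "read_id"),
              vapply(sim$reads, `[[`, character(1), "seq"),
              file.path(dir, "reads.fastq"))
  write_long_alignments(sim$reads, sim$chrom_lengths,
                        file.path(dir, "alignments.sam"))
  write_guide_records(sim$guide, file.path(dir, "guide.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$nuclei, file.path(dir, "nuclei.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
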