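#' Alignment scoring scheme
#'
#' Blastn-style scoring used for flank alignment: reward +1, penalty -1,
#' zero gap-open cost and -2 per gap base, with exact 7-mer words as seeds.
#'
#' @param match,mismatch,gap_open,gap_extend local-alignment scores
#'   (`gap_extend` is charged per gap base).
#' @param seed_word_size exact-word length used by [seed_scan()].
#' @return an `alignment_scheme`.
#' @export
alignment_scheme <- function(match = 1L, mismatch = -1L, gap_open = 0L,
                             gap_extend = -2L, seed_word_size = 7L) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_word_size = as.integer(seed_word_size)),
            class = "alignment_scheme")
}

#' Filter long-read alignments before barcode assignment
#'
#' Drops multi-mapped reads (any secondary or supplementary record) and
#' potential chimeras: reads whose 5' or 3' unmapped flank exceeds 150 nt.
#' Because the barcode-bearing end of a 10x-style read legitimately carries
#' adapter + barcode + UMI structure in its clip, a structural allowance
#' (default 56 nt = 30 + 16 + 10) is granted on at most one end before the
#' 150-nt rule is applied; `allowance = 0` restores the literal rule.
#'
#' @param reads a `long_read_set`.
#' @param max_clip chimera threshold in nt (strict: a clip of exactly
#'   `max_clip` is kept).
#' @param allowance structural allowance granted on one end.
#' @return list with `kept` (a `long_read_set` of primary records) and
#'   `dropped` (data.frame of `read_id`, `reason`).
#' @export
filter_long_reads <- function(reads, max_clip = 150L, allowance = 56L) {
  ids <- vapply(reads, `[[`, character(1), "read_id")
  multi <- vapply(reads, function(r) r$secondary || r$supplementary,
                  logical(1))
  multi_ids <- unique(ids[multi])
  kept <- list()
  dropped <- list()
  for (r in reads) {
    if (r$read_id %in% multi_ids) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(read_id = r$read_id, reason = "multi_mapped")
      next
    }
    ok <- (r$clip5 <= max_clip + allowance && r$clip3 <= max_clip) ||
      (r$clip5 <= max_clip && r$clip3 <= max_clip + allowance)
    if (!ok) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(read_id = r$read_id, reason = "chimeric")
      next
    }
    kept[[length(kept) + 1L]] <- r
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(read_id = character(0), reason = character(0))
  list(kept = new_long_read_set(kept), dropped = dropped)
}

#' Exact-word seed scan
#'
#' Finds every offset in `flank` where an exact `word_size`-mer of `query`
#' occurs (overlapping occurrences included).  An empty result means the
#' candidate is skipped before Smith-Waterman, mirroring Blastn seeding.
#'
#' @param flank,query nucleotide strings.
#' @param word_size exact word length (query must be at least this long).
#' @return integer vector of 1-based offsets into `flank`.
#' @export
seed_scan <- function(flank, query, word_size = 7L) {
  nq <- nchar(query)
  if (nq < word_size) stop("query shorter than word_size")
  nf <- nchar(flank)
  if (nf < word_size) return(integer(0))
  fk <- substring(flank, 1:(nf - word_size + 1L), word_size:nf)
  qk <- unique(substring(query, 1:(nq - word_size + 1L), word_size:nq))
  which(fk %in% qk)
}

# k-mer set of a string (internal, used for fast per-candidate seed checks)
kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Smith-Waterman local alignment with segment error counts
#'
#' Standard local alignment of `query` against `subject` under `scheme`
#' (linear gap penalty of `gap_extend` per gap base).  The error count is
#' mismatches + gap bases inside the optimal local alignment + query bases
#' left unaligned, so a truncated query counts its missing bases as errors.
#' Errors are split between the first `barcode_len` query positions and the
#' remainder, implementing the per-segment cap on barcode versus UMI errors.
#'
#' @param subject,query nucleotide strings (query is the barcode-UMI
#'   candidate).
#' @param scheme an [alignment_scheme()].
#' @param barcode_len boundary between the barcode and UMI segments of the
#'   query; defaults to the whole query (single segment).
#' @return list with `score`, `errors`, `errors_bc`, `errors_umi`, and the
#'   1-based aligned spans on subject and query.
#' @export
smith_waterman <- function(subject, query, scheme = alignment_scheme(),
                           barcode_len = nchar(query)) {
  if (!nzchar(query)) stop("query must be nonempty")
  cpp_sw(subject, query, scheme$match, scheme$mismatch, scheme$gap_extend,
         as.integer(barcode_len))
}

assignment_row <- function(read_id, status, barcode = NA_character_,
                           umi = NA_character_, gene_id = NA_character_,
                           barcode_errors = NA_integer_,
                           umi_errors = NA_integer_,
                           n_best_candidates = NA_integer_) {
  data.frame(read_id = read_id, barcode = barcode, umi = umi,
             gene_id = gene_id, barcode_errors = barcode_errors,
             umi_errors = umi_errors, n_best_candidates = n_best_candidates,
             status = status, stringsAsFactors = FALSE)
}

#' Assign a barcode and UMI to one long read
#'
#' Retrieves candidate (barcode, UMI) pairs from the bins overlapping or
#' adjacent to the read's mapped span, aligns each 26-nt candidate against
#' both unmapped flanks and their reverse complements, and keeps the
#' closest match (fewest mismatch/gap errors).  A read is `assigned` only
#' when a single distinct pair attains the minimum and its barcode and UMI
#' each carry at most `max_errors` errors; distinct pairs tying at an
#' assignable minimum make the read `ambiguous`; `no_candidate` means the
#' bin lookup returned nothing.
#'
#' @param read a [long_read] that passed [filter_long_reads()].
#' @param bin_index a [build_bin_index()] over the guide records.
#' @param scheme an [alignment_scheme()].
#' @param max_errors per-segment error cap (3: the barcode and the UMI may
#'   each carry up to three errors).
#' @param use_seeds skip candidates sharing no exact seed word with any
#'   flank (Blastn-style acceleration); `FALSE` forces exhaustive dynamic
#'   programming over every candidate.
#' @param adjacent bins added on each side of the overlapped bins
#'   (`Inf` disables binning).
#' @return a one-row assignment data.frame (`read_id`, `barcode`, `umi`,
#'   `gene_id`, `barcode_errors`, `umi_errors`, `n_best_candidates`,
#'   `status`).
#' @export
assign_read <- function(read, bin_index, scheme = alignment_scheme(),
                        max_errors = 3L, use_seeds = TRUE, adjacent = 1L) {
  fl <- extract_flanks(read)
  span_lo <- read$blocks[1, 1]
  span_hi <- read$blocks[nrow(read$blocks), 2]
  cand <- lookup_bins(bin_index, read$chrom, span_lo, span_hi, adjacent)
  if (nrow(cand) == 0)
    return(assignment_row(read$read_id, "no_candidate"))
  flanks <- c(fl$five_prime, fl$three_prime)
  flanks <- flanks[nzchar(flanks)]
  if (length(flanks) == 0)
    return(assignment_row(read$read_id, "over_threshold",
                          n_best_candidates = 0L))
  flanks <- c(flanks, revcomp(flanks))
  pairs <- unique(cand[, c("barcode", "umi")])
  queries <- paste0(pairs$barcode, pairs$umi)
  if (use_seeds) {
    w <- scheme$seed_word_size
    fset <- unique(unlist(lapply(flanks, kmer_set, k = w)))
    seeded <- vapply(queries, function(q) any(kmer_set(q, w) %in% fset),
                     logical(1))
    pairs <- pairs[seeded, , drop = FALSE]
    queries <- queries[seeded]
  }
  if (length(queries) == 0)
    return(assignment_row(read$read_id, "over_threshold",
                          n_best_candidates = 0L))
  sw <- cpp_sw_candidates(flanks, queries, scheme$match, scheme$mismatch,
                          scheme$gap_extend, nchar(pairs$barcode[1]))
  total <- sw[, "errors"]
  best <- which(total == min(total))
  n_best <- length(best)
  passes <- sw[best, "errors_bc"] <= max_errors &
    sw[best, "errors_umi"] <= max_errors
  if (!any(passes))
    return(assignment_row(read$read_id, "over_threshold",
                          n_best_candidates = n_best))
  if (n_best > 1)
    return(assignment_row(read$read_id, "ambiguous",
                          n_best_candidates = n_best))
  b <- best[1]
  gene <- cand$gene_id[cand$barcode == pairs$barcode[b] &
                         cand$umi == pairs$umi[b]][1]
  assignment_row(read$read_id, "assigned", barcode = pairs$barcode[b],
                 umi = pairs$umi[b], gene_id = gene,
                 barcode_errors = sw[b, "errors_bc"],
                 umi_errors = sw[b, "errors_umi"],
                 n_best_candidates = 1L)
}

#' Assign barcodes and UMIs to a set of filtered reads
#'
#' Driver over [assign_read()]; emits exactly one assignment row per
#' read id.
#'
#' @inheritParams assign_read
#' @param reads a `long_read_set` (the `kept` part of
#'   [filter_long_reads()]).
#' @return assignment data.frame, one row per read.
#' @export
assign_barcodes <- function(reads, bin_index, scheme = alignment_scheme(),
                            max_errors = 3L, use_seeds = TRUE,
                            adjacent = 1L) {
  rows <- lapply(reads, assign_read, bin_index = bin_index, scheme = scheme,
                 max_errors = max_errors, use_seeds = use_seeds,
                 adjacent = adjacent)
  do.call(rbind, rows)
}

#' Consensus sequence of reads sharing a UMI
#'
#' With a single read the read itself is returned.  With several, the
#' longest read (ties broken by sequence order, so the result is
#' independent of input order) becomes the backbone; every other read is
#' aligned to it locally and each backbone column takes the majority base,
#' ties keeping the backbone base.
#'
#' @param seqs character vector of read sequences for one
#'   (barcode, UMI, gene) molecule.
#' @param scheme an [alignment_scheme()].
#' @return the consensus sequence.
#' @export
consensus_per_molecule <- function(seqs, scheme = alignment_scheme()) {
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1) return(seqs)
  o <- order(-nchar(seqs), seqs)
  backbone <- seqs[o[1]]
  cpp_consensus(backbone, seqs[o[-1]], scheme$match, scheme$mismatch,
                scheme$gap_extend)
}

#' Collapse assigned reads into per-UMI molecules
#'
#' Groups `assigned` reads by (barcode, UMI, gene), computes the consensus
#' sequence per group, and keeps the alignment geometry of the read with
#' the widest aligned footprint as the molecule's representative blocks.
#'
#' @param reads the `long_read_set` that was assigned.
#' @param assignments output of [assign_barcodes()].
#' @param models a `gene_models` (provides each molecule's gene strand).
#' @param scheme an [alignment_scheme()] for consensus alignment.
#' @return a `molecule_set`: data.frame with one row per molecule
#'   (`barcode`, `umi`, `gene_id`, `chrom`, `gene_strand`,
#'   `n_supporting_reads`, `consensus_seq`) and a `blocks` list column of
#'   representative alignment blocks.
#' @export
build_molecules <- function(reads, assignments, models,
                            scheme = alignment_scheme()) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  by_id <- setNames(seq_along(reads),
                    vapply(reads, `[[`, character(1), "read_id"))
  key <- paste(a$barcode, a$umi, a$gene_id, sep = "\r")
  groups <- split(seq_len(nrow(a)), key)
  rows <- lapply(groups, function(ii) {
    rr <- lapply(a$read_id[ii], function(id) reads[[by_id[[id]]]])
    widths <- vapply(rr, function(r) sum(r$blocks[, 2] - r$blocks[, 1]),
                     integer(1))
    rep_read <- rr[[order(-widths,
                          vapply(rr, `[[`, character(1), "read_id"))[1]]]
    gm <- models[[a$gene_id[ii[1]]]]
    list(barcode = a$barcode[ii[1]], umi = a$umi[ii[1]],
         gene_id = a$gene_id[ii[1]], chrom = rep_read$chrom,
         gene_strand = if (is.null(gm)) NA_character_ else gm$strand,
         n_supporting_reads = length(ii),
         consensus_seq = consensus_per_molecule(
           vapply(rr, `[[`, character(1), "seq"), scheme),
         blocks = rep_read$blocks)
  })
  mol <- data.frame(
    barcode = vapply(rows, `[[`, character(1), "barcode"),
    umi = vapply(rows, `[[`, character(1), "umi"),
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    gene_strand = vapply(rows, `[[`, character(1), "gene_strand"),
    n_supporting_reads = vapply(rows, `[[`, integer(1),
                                "n_supporting_reads"),
    consensus_seq = vapply(rows, `[[`, character(1), "consensus_seq"),
    row.names = NULL, stringsAsFactors = FALSE)
  mol$blocks <- lapply(rows, `[[`, "blocks")
  class(mol) <- c("molecule_set", "data.frame")
  mol
}
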