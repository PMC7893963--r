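#' A single aligned long read
#'
#' Constructs the record used throughout the pipeline for one mapped long
#' read.  Coordinates are 0-based half-open genomic intervals; `blocks` are
#' the CIGAR M/D runs with N (spliced) gaps separating blocks.  `clip5` and
#' `clip3` are the unmapped flank lengths in *read orientation* (the physical
#' 5' end of the molecule as sequenced), and `seq` is stored in read
#' orientation as well, so `substr(seq, 1, clip5)` is always the physical 5'
#' flank regardless of which genome strand the read mapped to.
#'
#' @param read_id read name.
#' @param chrom,strand mapped chromosome and strand (`"+"`/`"-"`).
#' @param blocks integer matrix with columns `start`, `end` (0-based
#'   half-open), sorted and non-overlapping.
#' @param clip5,clip3 unmapped prefix/suffix lengths in read orientation.
#' @param seq read sequence in read orientation (may be `NA` for flagged
#'   secondary records).
#' @param mapq mapping quality.
#' @param secondary,supplementary SAM flag bits 0x100 / 0x800.
#' @return a `long_read` list.
#' @export
long_read <- function(read_id, chrom, strand, blocks, clip5, clip3, seq,
                      mapq = 60L, secondary = FALSE, supplementary = FALSE) {
  blocks <- matrix(as.integer(blocks), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(blocks) > 1) {
    o <- order(blocks[, 1])
    blocks <- blocks[o, , drop = FALSE]
    if (any(blocks[-1, 1] < blocks[-nrow(blocks), 2]))
      stop("blocks of read ", read_id, " overlap")
  }
  structure(list(read_id = read_id, chrom = chrom, strand = strand,
                 blocks = blocks, clip5 = as.integer(clip5),
                 clip3 = as.integer(clip3), seq = seq, mapq = as.integer(mapq),
                 secondary = isTRUE(secondary),
                 supplementary = isTRUE(supplementary)),
            class = "long_read")
}

#' @export
print.long_read <- function(x, ...) {
  cat(sprintf("<long_read %s %s:%d-%d(%s) blocks=%d clip5=%d clip3=%d>\n",
              x$read_id, x$chrom, x$blocks[1, 1], x$blocks[nrow(x$blocks), 2],
              x$strand, nrow(x$blocks), x$clip5, x$clip3))
  invisible(x)
}

new_long_read_set <- function(reads) {
  structure(reads, class = "long_read_set")
}

#' @export
print.long_read_set <- function(x, ...) {
  cat(sprintf("<long_read_set of %d alignment records>\n", length(x)))
  invisible(x)
}

#' @export
`[.long_read_set` <- function(x, i) new_long_read_set(unclass(x)[i])

#' @export
as.data.frame.long_read_set <- function(x, ...) {
  data.frame(
    read_id = vapply(x, `[[`, character(1), "read_id"),
    chrom = vapply(x, `[[`, character(1), "chrom"),
    strand = vapply(x, `[[`, character(1), "strand"),
    start = vapply(x, function(r) r$blocks[1, 1], integer(1)),
    end = vapply(x, function(r) r$blocks[nrow(r$blocks), 2], integer(1)),
    clip5 = vapply(x, `[[`, integer(1), "clip5"),
    clip3 = vapply(x, `[[`, integer(1), "clip3"),
    mapq = vapply(x, `[[`, integer(1), "mapq"),
    secondary = vapply(x, `[[`, logical(1), "secondary"),
    supplementary = vapply(x, `[[`, logical(1), "supplementary"),
    stringsAsFactors = FALSE)
}

# split an exploded CIGAR into left clip, right clip (optionally counting
# hard clips) and check well-formedness
cigar_clips <- function(ops, lens, with_hard) {
  keep <- if (with_hard) c("S", "H") else "S"
  left <- 0L
  i <- 1L
  while (i <= length(ops) && ops[i] %in% c("S", "H")) {
    if (ops[i] %in% keep) left <- left + lens[i]
    i <- i + 1L
  }
  right <- 0L
  j <- length(ops)
  while (j >= 1L && ops[j] %in% c("S", "H")) {
    if (ops[j] %in% keep) right <- right + lens[j]
    j <- j - 1L
  }
  c(left = left, right = right)
}

#' Read long-read alignments from SAM/BAM
#'
#' Ingests primary and flagged secondary/supplementary alignment records and
#' returns one [long_read] per record, with clip lengths and sequences
#' expressed in read orientation.  When a FASTQ/FASTA of the original reads
#' is supplied its sequences take precedence over the SAM `SEQ` column and
#' hard-clipped bases are counted into the clip lengths; a cell barcode can
#' live in a hard-clipped region that only the FASTQ retains.
#'
#' @param sam_source path to a SAM or BAM file.
#' @param fastq_source optional path to the FASTQ/FASTA with original read
#'   sequences.
#' @return a `long_read_set` (list of [long_read] records).  Records whose
#'   sequence is unavailable from either source are dropped with a warning,
#'   except secondary/supplementary records, which are retained (sequence
#'   `NA`) so that multi-mapping can be detected downstream.
#' @export
read_long_alignments <- function(sam_source, fastq_source = NULL) {
  bam <- sam_source
  if (grepl("\\.sam$", sam_source, ignore.case = TRUE)) {
    # htslib silently drops unparseable records; check CIGARs up front so a
    # malformed record is a loud error carrying its read id
    ln <- readLines(sam_source)
    ln <- ln[!startsWith(ln, "@")]
    if (length(ln)) {
      f <- strsplit(ln, "\t", fixed = TRUE)
      cig <- vapply(f, `[[`, character(1), 6L)
      bad <- cig != "*" & !grepl("^([0-9]+[MIDNSHP=X])+$", cig)
      if (any(bad))
        stop("malformed CIGAR for read(s): ",
             paste(vapply(f[bad], `[[`, character(1), 1L), collapse = ", "))
    }
    dest <- tempfile()
    bam <- Rsamtools::asBam(sam_source, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  fq <- NULL
  if (!is.null(fastq_source)) {
    fmt <- if (grepl("\\.(fq|fastq)$", fastq_source, ignore.case = TRUE))
      "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(fastq_source, format = fmt)
    fq <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  bad <- mapped & !grepl("^([0-9]+[MIDNSHP=X])+$", b$cigar)
  if (any(bad))
    stop("malformed CIGAR for read(s): ",
         paste(b$qname[bad], collapse = ", "))
  idx <- which(mapped)
  cig <- b$cigar[idx]
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  blk <- GenomicAlignments::extractAlignmentRangesOnReference(
    cig, pos = b$pos[idx], drop.D.ranges = FALSE)
  reads <- vector("list", length(idx))
  drop <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    flag <- b$flag[i]
    minus <- bitwAnd(flag, 16L) > 0L
    sec <- bitwAnd(flag, 256L) > 0L
    sup <- bitwAnd(flag, 2048L) > 0L
    qname <- b$qname[i]
    sq <- NULL
    use_fastq <- FALSE
    if (!is.null(fq) && !is.na(fq[qname])) {
      sq <- unname(fq[qname])
      use_fastq <- TRUE
    } else {
      s <- as.character(b$seq[i])
      if (nzchar(s) && !identical(s, "*")) {
        sq <- if (minus) revcomp(s) else s
      }
    }
    if (is.null(sq) && !(sec || sup)) {
      warning("read ", qname, " has no sequence in SAM or FASTQ; skipped")
      drop[k] <- TRUE
      next
    }
    cl <- cigar_clips(ops[[k]], lens[[k]], with_hard = use_fastq)
    clip5 <- if (minus) cl["right"] else cl["left"]
    clip3 <- if (minus) cl["left"] else cl["right"]
    ir <- blk[[k]]
    reads[[k]] <- long_read(
      read_id = qname, chrom = as.character(b$rname[i]),
      strand = if (minus) "-" else "+",
      blocks = cbind(IRanges::start(ir) - 1L, IRanges::end(ir)),
      clip5 = clip5, clip3 = clip3,
      seq = if (is.null(sq)) NA_character_ else sq,
      mapq = b$mapq[i], secondary = sec, supplementary = sup)
  }
  new_long_read_set(reads[!drop])
}

# build a CIGAR string for a synthetic read whose block geometry is known.
# The read-consumed length (len(seq) - clips) may differ from the reference
# footprint after indel errors; the difference is balanced with a trailing
# I or D run so the record stays self-consistent.
blocks_to_cigar <- function(blocks, clip_left, clip_right, read_len) {
  ref_lens <- blocks[, 2] - blocks[, 1]
  gaps <- if (nrow(blocks) > 1) blocks[-1, 1] - blocks[-nrow(blocks), 2]
          else integer(0)
  target <- read_len - clip_left - clip_right
  delta <- target - sum(ref_lens)
  parts <- character(0)
  if (clip_left > 0) parts <- c(parts, paste0(clip_left, "S"))
  for (i in seq_len(nrow(blocks))) {
    m <- ref_lens[i]
    extra <- ""
    if (i == nrow(blocks)) {
      if (delta < 0) {
        m <- m + delta            # shorten trailing match run ...
        extra <- paste0(-delta, "D")  # ... its tail becomes a deletion
      } else if (delta > 0) {
        extra <- paste0(delta, "I")
      }
    }
    parts <- c(parts, paste0(m, "M"), extra)
    if (i < nrow(blocks)) parts <- c(parts, paste0(gaps[i], "N"))
  }
  if (clip_right > 0) parts <- c(parts, paste0(clip_right, "S"))
  paste(parts[nzchar(parts)], collapse = "")
}

#' Write alignments as SAM
#'
#' Plain-text SAM writer for synthetic alignment records, so that simulated
#' data can be round-tripped through [read_long_alignments()].
#'
#' @param reads a `long_read_set`.
#' @param chrom_lengths named integer vector of reference lengths.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_long_alignments <- function(reads, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  lines <- vapply(reads, function(r) {
    minus <- r$strand == "-"
    flag <- (if (minus) 16L else 0L) +
      (if (r$secondary) 256L else 0L) + (if (r$supplementary) 2048L else 0L)
    seq_out <- if (is.na(r$seq)) "*" else if (minus) revcomp(r$seq) else r$seq
    clip_left <- if (minus) r$clip3 else r$clip5
    clip_right <- if (minus) r$clip5 else r$clip3
    cig <- blocks_to_cigar(r$blocks, clip_left, clip_right,
                           if (is.na(r$seq)) sum(r$blocks[, 2] - r$blocks[, 1]) +
                             clip_left + clip_right else nchar(r$seq))
    paste(r$read_id, flag, r$chrom, r$blocks[1, 1] + 1L, r$mapq, cig,
          "*", 0L, 0L, seq_out, "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Extract the unmapped flanks of a read
#'
#' Returns the soft/hard-clipped prefix and suffix of the read in read
#' orientation: the regions where the adapter, cell barcode, UMI and polyT
#' tract reside on a 10x-style long read.
#'
#' @param read a [long_read].
#' @return list with `read_id`, `five_prime`, `three_prime` character flanks.
#' @export
extract_flanks <- function(read) {
  n <- nchar(read$seq)
  list(read_id = read$read_id,
       five_prime = if (read$clip5 > 0) substr(read$seq, 1L, read$clip5) else "",
       three_prime = if (read$clip3 > 0)
         substr(read$seq, n - read$clip3 + 1L, n) else "")
}
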