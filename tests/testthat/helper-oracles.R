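# Independent full-matrix Smith-Waterman oracle in plain R.  Mirrors the
# documented tie contract of smith_waterman() (first maximal cell in
# row-major order; traceback prefers diagonal, then up, then left) but
# shares no code with the package's C++ implementation.
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2,
                      bc_len = nchar(b)) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    h <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    H[i + 1, j + 1] <- h
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  errs <- c(0L, 0L)
  seg <- function(p) if (p <= bc_len) 1L else 2L
  bump <- function(p) errs[seg(p)] <<- errs[seg(p)] + 1L
  if (best > 0) {
    i <- bi; j <- bj
    while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
      h <- H[i + 1, j + 1]
      s <- if (A[i] == B[j]) match else mismatch
      if (H[i, j] + s == h) {
        if (A[i] != B[j]) bump(j)
        i <- i - 1; j <- j - 1
      } else if (H[i, j + 1] + gap == h) {
        bump(min(j + 1, m))
        i <- i - 1
      } else {
        bump(j)
        j <- j - 1
      }
    }
    qs <- j + 1; qe <- bj
    for (q in seq_len(qs - 1)) bump(q)
    for (q in seq_len(m - qe)) bump(qe + q)
  } else {
    for (q in seq_len(m)) bump(q)
  }
  list(score = best, errors = sum(errs), errors_bc = errs[1],
       errors_umi = errs[2])
}

# Brute-force single-linkage oracle: connected components of the graph
# whose edges join every pair of sites within the distance threshold.
pas_oracle_membership <- function(sites, threshold = 24) {
  n <- length(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(sites[i] - sites[j]) <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(sites)]))
}

# membership vector (cluster ordinal per input site) from the package's
# cluster list, for comparison against the union-find oracle
pas_membership <- function(sites, clusters) {
  lo <- vapply(clusters, function(x) x$members[1], integer(1))
  hi <- vapply(clusters, function(x) x$members[length(x$members)],
               integer(1))
  vapply(as.integer(sites), function(p) which(p >= lo & p <= hi)[1],
         integer(1))
}

# tiny guide-table constructor for assignment unit tests
guide_df <- function(barcode, umi, gene_id = "G0001", chrom = "chrS",
                     position = 100L) {
  data.frame(barcode = barcode, umi = umi, gene_id = gene_id,
             chrom = chrom, position = position, stringsAsFactors = FALSE)
}

# a minimal mapped read whose 5' flank is given explicitly; the aligned
# part is an arbitrary 80-bp block at `pos`
flank_read <- function(flank, read_id = "r1", pos = 100L, chrom = "chrS") {
  body <- paste(rep("ACGT", 20), collapse = "")
  long_read(read_id, chrom, "+", cbind(pos, pos + 80L),
            clip5 = nchar(flank), clip3 = 0L, seq = paste0(flank, body))
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# substitute one base at position i
sub_at <- function(s, i, to) {
  substr(s, i, i) <- to
  s
}
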