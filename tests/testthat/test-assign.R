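test_that("chimera filtering is strict at 150 nt and grants one allowance", {
  mk <- function(id, c5, c3, sec = FALSE, sup = FALSE) {
    n <- c5 + 80L + c3
    long_read(id, "chrS", "+", cbind(100L, 180L), c5, c3,
              paste(rep("A", n), collapse = ""), secondary = sec,
              supplementary = sup)
  }
  reads <- nucleolong:::new_long_read_set(list(
    mk("keep150", 150L, 0L), mk("drop151", 151L, 0L),
    mk("allow200", 200L, 0L), mk("both_long", 200L, 200L),
    mk("dup", 10L, 0L), mk("dup", 10L, 0L, sup = TRUE)))
  # literal rule: allowance 0
  f0 <- filter_long_reads(reads, allowance = 0L)
  kept0 <- vapply(f0$kept, `[[`, character(1), "read_id")
  expect_true("keep150" %in% kept0)
  expect_false("drop151" %in% kept0)
  expect_false("allow200" %in% kept0)
  expect_equal(f0$dropped$reason[f0$dropped$read_id == "drop151"], "chimeric")
  # default allowance tolerates the barcode structure on one end only
  f1 <- filter_long_reads(reads)
  kept1 <- vapply(f1$kept, `[[`, character(1), "read_id")
  expect_true(all(c("keep150", "drop151", "allow200") %in% kept1))
  expect_false("both_long" %in% kept1)
  # any supplementary record drops every record of that read id
  expect_false("dup" %in% kept1)
  expect_true(all(f1$dropped$reason[f1$dropped$read_id == "dup"] ==
                    "multi_mapped"))
})

test_that("seed scan finds exact words and matches a brute-force oracle", {
  q <- "ACGTACGTACGTACGTACGTACGTAC"  # 26-nt
  flank <- paste0("TTTTT", q, "GGGGG")
  seeds <- seed_scan(flank, q)
  expect_gte(length(seeds), nchar(q) - 6)
  expect_equal(seed_scan(paste(rep("A", 50), collapse = ""), "CGCGCGCGCG"),
               integer(0))
  expect_error(seed_scan(flank, "ACGT"), "word_size")
  set.seed(17)
  for (i in 1:50) {
    fl <- rand_seq(1, sample(20:120, 1))
    qq <- rand_seq(1, sample(7:26, 1))
    got <- seed_scan(fl, qq)
    qmers <- substring(qq, 1:(nchar(qq) - 6), 7:nchar(qq))
    want <- which(vapply(1:(nchar(fl) - 6), function(p)
      substr(fl, p, p + 6) %in% qmers, logical(1)))
    expect_equal(got, want)
  }
})

test_that("Smith-Waterman matches hand-derived scores and error counts", {
  a <- "ACGTACGTACGTACGT"
  r <- smith_waterman(a, a)
  expect_equal(r$score, 16)
  expect_equal(r$errors, 0)
  # one internal substitution: 15 matches - 1 mismatch
  b <- sub_at(a, 7, "A")
  r2 <- smith_waterman(a, b)
  expect_equal(r2$score, 14)
  expect_equal(r2$errors, 1)
  # truncated query counts its missing bases as errors
  r3 <- smith_waterman("ACGTACGT", "ACGTACGTTTTT")
  expect_equal(r3$errors, 4)
  # barcode/UMI split: error beyond position 16 lands in the UMI segment
  q <- paste0(a, "CCCCCCCCCC")
  r4 <- smith_waterman(paste0("GG", sub_at(q, 20, "A"), "GG"), q,
                       barcode_len = 16)
  expect_equal(r4$errors_bc, 0)
  expect_equal(r4$errors_umi, 1)
})

test_that("Smith-Waterman agrees with an independent DP oracle", {
  set.seed(23)
  for (i in 1:200) {
    a <- rand_seq(1, sample(5:30, 1))
    b <- rand_seq(1, sample(5:30, 1))
    bc_len <- sample.int(nchar(b), 1)
    got <- smith_waterman(a, b, barcode_len = bc_len)
    want <- sw_oracle(a, b, bc_len = bc_len)
    expect_equal(got$score, want$score)
    expect_equal(got$errors, want$errors)
    expect_equal(got$errors_bc, want$errors_bc)
    expect_equal(got$errors_umi, want$errors_umi)
  }
})

test_that("assign_read implements the error cap and ambiguity rules", {
  bc <- "ACGTTGCAACGTTGCA"
  umi <- "GATTACAGAT"
  flank <- paste0(rand_seq(1, 30), bc, umi, paste(rep("T", 20), collapse = ""))
  bi1 <- build_bin_index(guide_df(bc, umi))
  read <- flank_read(flank)
  a <- assign_read(read, bi1)
  expect_equal(a$status, "assigned")
  expect_equal(a$barcode, bc)
  expect_equal(a$umi, umi)
  expect_equal(a$barcode_errors + a$umi_errors, 0L)
  # sole candidate with four internal barcode substitutions -> over_threshold
  bc4 <- sub_at(sub_at(sub_at(sub_at(bc, 4, "A"), 7, "T"), 10, "A"), 13, "C")
  a4 <- assign_read(read, build_bin_index(guide_df(bc4, umi)))
  expect_equal(a4$status, "over_threshold")
  expect_true(is.na(a4$barcode))
  # three errors are still assignable
  bc3 <- sub_at(sub_at(sub_at(bc, 5, "G"), 9, "G"), 13, "C")
  a3 <- assign_read(read, build_bin_index(guide_df(bc3, umi)))
  expect_equal(a3$status, "assigned")
  expect_equal(a3$barcode_errors, 3L)
  # two distinct pairs tying at one error -> ambiguous
  g2 <- guide_df(c(sub_at(bc, 8, "G"), sub_at(bc, 9, "G")), c(umi, umi))
  at <- assign_read(read, build_bin_index(g2))
  expect_equal(at$status, "ambiguous")
  expect_equal(at$n_best_candidates, 2L)
  # the same pair reachable twice (two genes) is not ambiguous
  g3 <- rbind(guide_df(bc, umi, gene_id = "gX", position = 100L),
              guide_df(bc, umi, gene_id = "gY", position = 120L))
  expect_equal(assign_read(read, build_bin_index(g3))$status, "assigned")
  # empty bins -> no_candidate
  far <- build_bin_index(guide_df(bc, umi, position = 99000L))
  expect_equal(assign_read(read, far)$status, "no_candidate")
})

test_that("barcode rescue on error-free reads is perfect", {
  cfg <- simulation_config(n_genes = 10, n_nuclei = 20,
                           reads_per_nucleus = 8,
                           per_base_error_rate = 0, seed = 2)
  sim <- simulate_dataset(cfg)
  flt <- filter_long_reads(sim$reads)
  asn <- assign_barcodes(flt$kept, build_bin_index(sim$guide))
  expect_equal(nrow(asn), length(flt$kept))
  expect_equal(anyDuplicated(asn$read_id), 0L)
  ok <- asn$status == "assigned"
  m <- merge(asn[ok, ], sim$truth, by = "read_id")
  expect_true(all(m$barcode.x == m$barcode.y & m$umi.x == m$umi.y))
  expect_true(all(m$barcode_errors == 0 & m$umi_errors == 0))
})

test_that("raising the error cap never decreases assigned reads", {
  cfg <- simulation_config(n_genes = 8, n_nuclei = 15, reads_per_nucleus = 6,
                           per_base_error_rate = 0.12, seed = 19)
  sim <- simulate_dataset(cfg)
  flt <- filter_long_reads(sim$reads)
  bi <- build_bin_index(sim$guide)
  counts <- vapply(0:5, function(t)
    sum(assign_barcodes(flt$kept, bi, max_errors = t)$status == "assigned"),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("consensus of duplicate reads reproduces and polishes the molecule", {
  s <- rand_seq(1, 200)
  expect_identical(consensus_per_molecule(s), s)
  expect_identical(consensus_per_molecule(rep(s, 3)), s)
  # five noisy copies at 5% error recover a sequence closer to truth than
  # any single copy in the vast majority of trials
  set.seed(31)
  closer <- vapply(1:30, function(i) {
    truth <- rand_seq(1, 200)
    copies <- vapply(1:5, function(j)
      nucleolong:::mutate_seq(truth, 0.05, c(2, 1, 1) / 4)$seq, character(1))
    cons <- consensus_per_molecule(copies)
    d <- utils::adist(c(cons, copies), truth)
    d[1] < min(d[-1])
  }, logical(1))
  expect_gte(mean(closer), 0.9)
  # order invariance
  set.seed(8)
  copies <- vapply(1:4, function(j)
    nucleolong:::mutate_seq(s, 0.05, c(2, 1, 1) / 4)$seq, character(1))
  expect_identical(consensus_per_molecule(copies),
                   consensus_per_molecule(rev(copies)))
})
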