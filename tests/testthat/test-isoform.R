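test_that("intron mapping ratio is coverage over intron length", {
  intron <- c(100L, 200L)
  expect_equal(intron_mapping_ratio(cbind(140L, 200L), intron), 0.6)
  expect_equal(intron_mapping_ratio(cbind(100L, 150L), intron), 0.5)
  # a read that skips the intron via an N gap covers none of it
  expect_equal(intron_mapping_ratio(cbind(c(50L, 200L), c(100L, 250L)),
                                    intron), 0)
  expect_equal(intron_mapping_ratio(cbind(0L, 500L), intron), 1)
})

test_that("splicing calls apply the strict >50% rule per observed intron", {
  gm <- gene_model("g", "chrS", "+",
                   cbind(c(0L, 200L, 400L, 600L), c(100L, 300L, 500L, 700L)))
  # introns: [100,200), [300,400), [500,600)
  # all introns skipped -> spliced
  cs <- call_splicing(cbind(c(0L, 200L, 400L, 600L),
                            c(100L, 300L, 500L, 700L)), gm)
  expect_equal(cs$status, "spliced")
  expect_equal(cs$flags, c(FALSE, FALSE, FALSE))
  # exactly half an intron covered is NOT retained; 51% is
  half <- cbind(c(0L, 200L, 400L, 600L), c(150L, 300L, 500L, 700L))
  expect_equal(call_splicing(half, gm)$status, "spliced")
  over <- cbind(c(0L, 200L, 400L, 600L), c(151L, 300L, 500L, 700L))
  cs2 <- call_splicing(over, gm)
  expect_equal(cs2$status, "unspliced")
  expect_equal(cs2$flags[1], TRUE)
  # one of three introns 80% covered -> unspliced
  cs3 <- call_splicing(cbind(c(0L, 120L, 400L, 600L),
                             c(100L, 300L, 500L, 700L)), gm)
  expect_equal(cs3$status, "unspliced")
  # 5'-truncated read: introns before its span are unobserved (NA)
  cs4 <- call_splicing(cbind(c(400L, 600L), c(500L, 700L)), gm)
  expect_true(all(is.na(cs4$flags[1:2])))
  expect_equal(cs4$flags[3], FALSE)
  expect_equal(cs4$status, "spliced")
  # covering only the last exon observes no intron -> indeterminate
  expect_equal(call_splicing(cbind(600L, 700L), gm)$status, "indeterminate")
  # intronless gene -> spliced with empty flags
  g0 <- gene_model("g0", "chrS", "+", cbind(0L, 500L))
  cs5 <- call_splicing(cbind(10L, 400L), g0)
  expect_equal(cs5$status, "spliced")
  expect_length(cs5$flags, 0)
})

test_that("splicing calls are invariant to block order and strand mirroring", {
  gm <- gene_model("g", "chrS", "+",
                   cbind(c(0L, 200L, 400L), c(100L, 300L, 500L)))
  blocks <- cbind(c(0L, 180L, 400L), c(100L, 300L, 500L))
  shuffled <- blocks[c(3, 1, 2), ]
  expect_equal(call_splicing(blocks, gm), call_splicing(shuffled, gm))
  # mirror the whole instance around coordinate 500
  mirror <- function(m) cbind(500L - m[, 2], 500L - m[, 1])
  gmm <- gene_model("g", "chrS", "-", mirror(gm$exons))
  csm <- call_splicing(mirror(blocks), gmm)
  cs <- call_splicing(blocks, gm)
  expect_equal(csm$status, cs$status)
  expect_equal(csm$flags, rev(cs$flags))
})

test_that("polyA sites are the strand-aware aligned 3' termini", {
  blocks <- cbind(c(2000L, 4500L), c(2600L, 5000L))
  expect_equal(extract_polya_site(blocks, "+"), 5000L)
  expect_equal(extract_polya_site(blocks, "-"), 2000L)
  expect_equal(extract_polya_site(blocks, "+"),
               extract_polya_site(blocks, "+"))
})

test_that("polyA clustering is single-linkage with the 24-nt gap rule", {
  cl <- cluster_polya_sites(c(100L, 110L, 200L))
  expect_length(cl, 2)
  expect_equal(cl[[1]]$members, c(100L, 110L))
  expect_equal(cl[[1]]$representative, 100L)  # lower of two middles
  expect_equal(cl[[2]]$representative, 200L)
  # chaining: consecutive gaps of exactly 24 merge into one cluster
  expect_length(cluster_polya_sites(c(0L, 24L, 48L)), 1)
  # a gap of 25 splits
  expect_length(cluster_polya_sites(c(0L, 25L)), 2)
  expect_length(cluster_polya_sites(c(0L, 24L)), 1)
  # permutation invariance
  set.seed(4)
  s <- sample.int(1000L, 60, replace = TRUE)
  expect_identical(cluster_polya_sites(s), cluster_polya_sites(sample(s)))
  # odd-size median
  expect_equal(cluster_polya_sites(c(10L, 20L, 30L))[[1]]$representative, 20L)
})

test_that("polyA clustering equals the brute-force union-find oracle", {
  set.seed(14)
  for (i in 1:20) {
    s <- sample.int(2000L, sample(5:120, 1), replace = TRUE)
    cl <- cluster_polya_sites(s)
    expect_equal(pas_membership(s, cl), pas_oracle_membership(s))
  }
})

sim_layers <- function(cfg) {
  sim <- simulate_dataset(cfg)
  flt <- filter_long_reads(sim$reads)
  asn <- assign_barcodes(flt$kept, build_bin_index(sim$guide))
  mol <- build_molecules(flt$kept, asn, sim$models)
  calls <- call_isoforms(mol, sim$models)
  list(sim = sim, mol = mol, calls = calls)
}

test_that("splicing and APA layers conserve molecule counts per gene", {
  x <- sim_layers(simulation_config(n_genes = 10, n_nuclei = 15,
                                    reads_per_nucleus = 10, seed = 27))
  spl <- build_splicing_matrix(x$calls)
  apa <- build_apa_matrix(x$calls)
  for (g in unique(x$calls$gene_id)) {
    det <- x$calls$status %in% c("spliced", "unspliced")
    n_det <- sum(x$calls$gene_id == g & det)
    n_all <- sum(x$calls$gene_id == g)
    spl_cols <- grep(paste0("^", g, "\\|"), features(spl), value = TRUE)
    apa_cols <- grep(paste0("^", g, "\\|PA"), features(apa), value = TRUE)
    expect_equal(sum(spl$counts[, spl_cols]), n_det)
    expect_equal(sum(apa$counts[, apa_cols]), n_all)
  }
  # per nucleus and gene, spliced + unspliced = determinate molecules
  one <- x$calls[x$calls$status != "indeterminate", ]
  tab <- table(one$barcode, one$gene_id)
  for (b in sample(rownames(tab), 5)) for (g in colnames(tab)) {
    cols <- intersect(paste0(g, c("|spliced", "|unspliced")), features(spl))
    expect_equal(sum(spl$counts[b, cols]), unname(tab[b, g]))
  }
})

test_that("incompletely spliced ratio counts unspliced over determinate", {
  calls <- data.frame(
    barcode = rep(c("b1", "b2", "b3"), c(10, 4, 2)),
    status = c(rep("unspliced", 3), rep("spliced", 7),
               rep("spliced", 4), rep("indeterminate", 2)),
    stringsAsFactors = FALSE)
  r <- incompletely_spliced_ratio(calls)
  expect_equal(unname(r["b1"]), 0.3)
  expect_equal(unname(r["b2"]), 0)   # all-intronless nuclei are fully spliced
  expect_true(is.na(r["b3"]))        # no determinate molecule -> missing
})

test_that("simulated retention probabilities are recovered by the calls", {
  cfg <- simulation_config(n_genes = 12, n_nuclei = 10,
                           reads_per_nucleus = 60, n_celltypes = 1,
                           intron_retention_prob = 0.4,
                           intron_range = c(1, 1), p_truncate5 = 0,
                           per_base_error_rate = 0.05, seed = 15)
  x <- sim_layers(cfg)
  r <- incompletely_spliced_ratio(x$calls)
  expect_lt(abs(mean(r, na.rm = TRUE) - 0.4), 0.05)
})
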