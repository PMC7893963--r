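toy_layer <- function(seed, nuclei, genes, layer = "abundance",
                      lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(length(nuclei) * length(genes), lambda),
              length(nuclei), length(genes),
              dimnames = list(nuclei, genes))
  layer_matrix(m, layer)
}

test_that("normalize_and_merge standardizes each layer over shared nuclei", {
  bcs <- sprintf("b%02d", 1:20)
  ab <- toy_layer(1, bcs, sprintf("g%02d", 1:15))
  spl <- toy_layer(2, bcs[1:18], sprintf("g%02d|spliced", 1:8), "splicing")
  mm <- normalize_and_merge(list(ab, spl))
  expect_equal(nrow(mm$x), 18)
  expect_equal(ncol(mm$x), 15 + 8)
  expect_equal(mm$provenance, rep(c("abundance", "splicing"), c(15, 8)))
  expect_lt(max(abs(colMeans(mm$x))), 1e-9)
  sds <- apply(mm$x, 2, sd)
  expect_lt(max(abs(sds[sds > 0] - 1)), 1e-9)
  # single-layer merge is the normalized layer itself
  mm1 <- normalize_and_merge(list(ab))
  expect_equal(ncol(mm1$x), 15)
  # disjoint nuclei is an error
  ab2 <- toy_layer(3, sprintf("x%02d", 1:5), "g1")
  expect_error(normalize_and_merge(list(ab, ab2)), "shared")
})

test_that("clustering is deterministic and recovers separated groups", {
  set.seed(5)
  n <- 60
  grp <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("b%02d", 1:n), NULL))
  x[grp == 2, 1:10] <- x[grp == 2, 1:10] + 6
  l1 <- cluster_nuclei(x, n_pcs = 10, seed = 1)
  l2 <- cluster_nuclei(x, n_pcs = 10, seed = 1)
  expect_identical(l1, l2)
  expect_equal(length(unique(l1)), 2)
  expect_equal(mclust::adjustedRandIndex(l1, grp), 1)
  expect_error(cluster_nuclei(x, n_pcs = 60), "n_pcs")
})

test_that("marker scoring assigns planted types and handles edge cases", {
  set.seed(6)
  n <- 40
  genes <- sprintf("g%02d", 1:30)
  counts <- matrix(rpois(n * 30, 2), n, 30,
                   dimnames = list(sprintf("b%02d", 1:n), genes))
  type <- rep(c("TA", "TB"), each = n / 2)
  counts[type == "TA", 1:5] <- counts[type == "TA", 1:5] + 12
  counts[type == "TB", 6:10] <- counts[type == "TB", 6:10] + 12
  expr <- normalize_counts(layer_matrix(counts, "abundance"))
  markers <- list(TA = genes[1:5], TB = genes[6:10])
  sc <- score_cell_types(expr, markers, seed = 3)
  expect_gte(mean(sc$assignment == type), 0.95)
  # marker-set order does not change assignments
  sc2 <- score_cell_types(expr, rev(markers), seed = 3)
  expect_identical(sc$assignment, sc2$assignment)
  # a nucleus expressing no marker program scores <= 0 -> unknown
  flat <- matrix(5, 4, 30, dimnames = list(letters[1:4], genes))
  scf <- score_cell_types(normalize_counts(layer_matrix(flat, "abundance")),
                          markers, seed = 3)
  expect_true(all(scf$assignment == "unknown"))
  # unresolvable marker sets are skipped with a warning
  expect_warning(score_cell_types(expr, c(markers, list(TC = "absent"))),
                 "TC")
  # cluster annotation is the modal type
  ann <- annotate_clusters(sc$assignment,
                           setNames(as.integer(type == "TA") + 1L,
                                    rownames(expr)))
  expect_equal(ann$cell_type[ann$cluster == 2], "TA")
})

test_that("fisher test matches stats::fisher.test and handles degeneracy", {
  set.seed(7)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 6), 2)
    got <- fisher_splicing_test(tb)
    if (got$degenerate) {
      expect_true(any(rowSums(tb) == 0) || any(colSums(tb) == 0))
      expect_equal(got$p_value, 1)
    } else {
      expect_equal(got$p_value, fisher.test(tb)$p.value, tolerance = 1e-12)
    }
  }
  expect_equal(fisher_splicing_test(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_splicing_test(t1)$p_value,
               fisher_splicing_test(t(t1))$p_value)
  expect_true(fisher_splicing_test(matrix(c(0, 0, 3, 4), 2))$degenerate)
})

test_that("one-sided KS test detects stochastically greater ratios", {
  expect_equal(ks_ratio_test(c(.1, .2, .3, .4), c(.1, .2, .3, .4))$statistic,
               0)
  r <- ks_ratio_test(c(.8, .85, .9, .95), c(.1, .2, .3, .4))
  expect_equal(r$statistic, 1)
  expect_lt(r$p_value, 0.05)
  # the test is one-sided: the reverse direction is not significant
  r2 <- ks_ratio_test(c(.1, .2, .3, .4), c(.8, .85, .9, .95))
  expect_gt(r2$p_value, 0.5)
  # agreement with a permutation estimate on a seeded case
  set.seed(9)
  x <- rbeta(40, 4, 2)
  y <- rbeta(60, 2, 4)
  obs <- ks_ratio_test(x, y)
  pool <- c(x, y)
  perm <- replicate(2000, {
    idx <- sample.int(100, 40)
    ks_ratio_test(pool[idx], pool[-idx])$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.02 + 3 * sqrt(p_perm / 2000))
  expect_warning(ks_ratio_test(c(.1, .2), c(.3, .4, .5)), "unreliable")
})

test_that("enriched genes pass the out-group and fold-change filters", {
  set.seed(10)
  n <- 40
  genes <- c("marker", "uniform", sprintf("g%02d", 1:10))
  counts <- matrix(rpois(n * 12, 3), n, 12,
                   dimnames = list(sprintf("b%02d", 1:n), genes))
  labels <- rep(c(1L, 2L), each = n / 2)
  counts[labels == 1, "marker"] <- 20
  counts[labels == 2, "marker"] <- 0
  counts[, "uniform"] <- 7
  expr <- normalize_counts(layer_matrix(counts, "abundance"))
  eg <- enriched_genes(expr, labels)
  expect_equal(eg[["1"]]$gene[1], "marker")
  expect_false("uniform" %in% eg[["1"]]$gene)
  expect_false("marker" %in% eg[["2"]]$gene)
  # disabling the filters reduces to the pure Wilcoxon ranking
  all1 <- enriched_genes(expr, labels, max_out_group_fraction = 1,
                         min_fold_change = 0)
  expect_equal(nrow(all1[["1"]]), length(genes))
  expect_equal(all1[["1"]]$gene[1], "marker")
  # singleton clusters are skipped with a warning
  lab2 <- labels
  lab2[1] <- 3L
  expect_warning(enriched_genes(expr, lab2), "fewer than 2")
})
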