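#' Depth-normalize and log-transform a layer
#'
#' Scales each nucleus's counts to the layer's median depth, then applies
#' `log1p`.  This is the normalized expression used for marker scoring and
#' enriched-gene testing.
#'
#' @param layer a `layer_matrix`.
#' @return dense numeric matrix (nuclei x features).
#' @export
normalize_counts <- function(layer) {
  m <- as.matrix(layer$counts)
  depth <- rowSums(m)
  target <- median(depth[depth > 0])
  f <- ifelse(depth > 0, target / depth, 0)
  log1p(m * f)
}

#' Normalize and merge layers into a multilayer matrix
#'
#' Each layer is independently depth-normalized to its median depth,
#' log1p-transformed and feature-standardized (mean 0, sd 1), then the
#' layers are concatenated horizontally over the nuclei common to all of
#' them.  Standardizing per layer gives the layers equal footing so a wide
#' APA block cannot dominate the abundance block; `weights` rescales whole
#' layers if unequal weighting is wanted.
#'
#' @param layers named or unnamed list of `layer_matrix` objects.
#' @param weights numeric, one per layer (recycled).
#' @return a `multilayer_matrix`: list with `x` (dense nuclei x features),
#'   `provenance` (layer of origin per feature) and `nuclei`.
#' @export
normalize_and_merge <- function(layers, weights = 1) {
  if (length(layers) == 0) stop("need at least one layer")
  if (inherits(layers, "layer_matrix")) layers <- list(layers)
  weights <- rep_len(weights, length(layers))
  common <- Reduce(intersect, lapply(layers, nuclei))
  if (length(common) == 0) stop("no nuclei shared by all layers")
  blocks <- vector("list", length(layers))
  prov <- character(0)
  for (k in seq_along(layers)) {
    lm <- layers[[k]]
    sub <- layer_matrix(lm$counts[common, , drop = FALSE], lm$layer)
    x <- normalize_counts(sub)
    mu <- colMeans(x)
    sg <- apply(x, 2, sd)
    x <- sweep(x, 2, mu, "-")
    x <- sweep(x, 2, ifelse(sg > 0, sg, 1), "/")
    blocks[[k]] <- x * weights[k]
    prov <- c(prov, rep(lm$layer, ncol(x)))
  }
  x <- do.call(cbind, blocks)
  structure(list(x = x, provenance = prov, nuclei = common),
            class = "multilayer_matrix")
}

#' @export
print.multilayer_matrix <- function(x, ...) {
  cat(sprintf("<multilayer_matrix: %d nuclei x %d features (%s)>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Cluster nuclei by PCA + kNN graph + Louvain
#'
#' Principal components of the merged matrix feed a shared-nearest-
#' neighbour graph (Jaccard weights over the `n_neighbors`-neighbourhoods),
#' on which Louvain community detection yields the cluster labels.
#' Deterministic under a fixed seed.
#'
#' @param mm a `multilayer_matrix` (or plain numeric matrix).
#' @param n_pcs number of principal components (must be smaller than the
#'   number of nuclei).
#' @param n_neighbors neighbourhood size of the kNN graph.
#' @param resolution Louvain resolution.
#' @param seed RNG seed.
#' @return integer cluster labels named by nucleus barcode.
#' @export
cluster_nuclei <- function(mm, n_pcs = 30L, n_neighbors = 15L,
                           resolution = 1, seed = 0L) {
  x <- if (inherits(mm, "multilayer_matrix")) mm$x else mm
  n <- nrow(x)
  if (n < 2) stop("need at least 2 nuclei")
  if (n_pcs >= n)
    stop("n_pcs (", n_pcs, ") must be smaller than the number of nuclei (",
         n, "); lower n_pcs")
  n_pcs <- min(n_pcs, ncol(x))
  pcs <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  k <- min(n_neighbors, n - 1L)
  d <- as.matrix(dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1L)]))
  B <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(B)            # shared neighbours (self included)
  W <- S / (2 * (k + 1L) - S)           # Jaccard over neighbourhoods
  W <- as.matrix(W)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "max", weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  setNames(as.integer(igraph::membership(cl)), rownames(x))
}

#' Read marker gene sets
#'
#' @param path TSV with columns `cell_type`, `gene_id`.
#' @return named list mapping cell type to character vector of gene ids.
#' @export
read_marker_sets <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene_id") %in% names(d)))
    stop("marker TSV must have columns cell_type, gene_id")
  split(d$gene_id, d$cell_type)
}

#' Score cell types and assign nuclei
#'
#' For each cell type, the cell score is the mean normalized expression of
#' its marker set minus the mean of a control set matched on expression
#' level: genes are sliced into `n_bins` bins by mean expression and
#' `ref_size` control genes are drawn from the bin of each marker.  A
#' nucleus is assigned to the highest-scoring type when that score exceeds
#' zero, and is `unknown` otherwise.
#'
#' @param expr normalized expression matrix (nuclei x genes), e.g. from
#'   [normalize_counts()].
#' @param marker_sets named list of marker gene vectors
#'   (see [read_marker_sets()]).
#' @param n_bins number of expression bins for control matching.
#' @param ref_size control genes drawn per marker gene.
#' @param seed RNG seed for control sampling (derived per type, so results
#'   do not depend on marker-set order).
#' @return list with `scores` (nuclei x types), `assignment` (named
#'   character vector).
#' @export
score_cell_types <- function(expr, marker_sets, n_bins = 25L,
                             ref_size = 50L, seed = 0L) {
  genes <- colnames(expr)
  avg <- colMeans(expr)
  # keep bins populated enough to yield non-marker controls on small
  # gene universes (about 10 genes per bin at least)
  n_bins <- max(1L, min(n_bins, length(genes) %/% 10L))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  types <- sort(names(marker_sets))
  scores <- matrix(NA_real_, nrow(expr), length(types),
                   dimnames = list(rownames(expr), types))
  for (ty in types) {
    mk <- intersect(marker_sets[[ty]], genes)
    if (length(mk) == 0) {
      warning("no resolvable markers for cell type ", ty, "; skipped")
      next
    }
    set.seed((seed + sum(utf8ToInt(ty))) %% 2147483647L)
    ctrl <- unique(unlist(lapply(mk, function(g) {
      pool <- genes[bin == bin[match(g, genes)]]
      pool2 <- setdiff(pool, mk)  # a control set must not be the markers
      if (length(pool2) > 0) pool <- pool2
      pool[sample.int(length(pool), min(ref_size, length(pool)))]
    })))
    scores[, ty] <- rowMeans(expr[, mk, drop = FALSE]) -
      rowMeans(expr[, ctrl, drop = FALSE])
  }
  ok <- types[colSums(is.na(scores)) < nrow(scores)]
  sc <- scores[, ok, drop = FALSE]
  best <- max.col(replace(sc, is.na(sc), -Inf), ties.method = "first")
  assignment <- ifelse(sc[cbind(seq_len(nrow(sc)), best)] > 0,
                       ok[best], "unknown")
  list(scores = scores, assignment = setNames(assignment, rownames(expr)))
}

#' Annotate clusters by their modal cell type
#'
#' @param assignment per-nucleus cell-type assignment
#'   (from [score_cell_types()]).
#' @param labels per-nucleus cluster labels (from [cluster_nuclei()]).
#' @return data.frame with one row per cluster: `cluster`, `cell_type`
#'   (most frequent assignment), `n_nuclei`.
#' @export
annotate_clusters <- function(assignment, labels) {
  stopifnot(all(names(labels) %in% names(assignment)))
  a <- assignment[names(labels)]
  out <- lapply(sort(unique(labels)), function(k) {
    tab <- sort(table(a[labels == k]), decreasing = TRUE)
    data.frame(cluster = k, cell_type = names(tab)[1],
               n_nuclei = sum(labels == k))
  })
  do.call(rbind, out)
}

#' Two-sided Fisher exact test on a 2x2 splicing table
#'
#' Tests association between splicing status (spliced / unspliced counts)
#' and cluster membership by hypergeometric enumeration: conditioning on
#' the margins, the p-value sums the probabilities of all tables no more
#' probable than the observed one.  A table with a zero margin carries no
#' information and returns p = 1 flagged degenerate.
#'
#' @param tab 2x2 matrix of nonnegative integer counts, conventionally
#'   rows = (spliced, unspliced) and columns = the two clusters.
#' @return list with `p_value`, `odds_ratio` (sample), `degenerate`.
#' @export
fisher_splicing_test <- function(tab) {
  tab <- matrix(as.integer(tab), 2, 2)
  if (any(tab < 0)) stop("counts must be nonnegative")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  support <- max(0L, c1 - r2):min(r1, c1)
  dens <- dhyper(support, r1, r2, c1)
  d_obs <- dhyper(tab[1, 1], r1, r2, c1)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(1, p), odds_ratio = or, degenerate = FALSE)
}

#' One-sided Kolmogorov-Smirnov test on incompletely spliced ratios
#'
#' Tests whether the ratios of one cluster are stochastically greater than
#' those of the remaining nuclei (their empirical CDF lies below), using
#' the asymptotic one-sided two-sample KS distribution.
#'
#' @param cluster_ratios,other_ratios numeric samples of per-nucleus
#'   incompletely spliced ratios in `[0, 1]` (`NA` dropped).
#' @return list with `statistic` (one-sided D) and `p_value`.
#' @export
ks_ratio_test <- function(cluster_ratios, other_ratios) {
  x <- cluster_ratios[!is.na(cluster_ratios)]
  y <- other_ratios[!is.na(other_ratios)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  if (length(x) < 3 || length(y) < 3)
    warning("KS test on fewer than 3 ratios is unreliable")
  # x stochastically greater <=> CDF of x below that of y
  kt <- suppressWarnings(
    ks.test(x, y, alternative = "less", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Cluster-enriched genes (Wilcoxon one-vs-rest with expression filters)
#'
#' Ranks genes per cluster by the Wilcoxon rank-sum z-score of cluster
#' versus all other nuclei, then keeps genes detected in at most
#' `max_out_group_fraction` of the out-group nuclei and with a fold change
#' of at least `min_fold_change` (fold change of `expm1` means of the
#' log-normalized expression, as in single-cell rank-genes conventions).
#' Setting `max_out_group_fraction = 1` and `min_fold_change = 0` recovers
#' the unfiltered Wilcoxon ranking.
#'
#' @param expr normalized expression (nuclei x genes,
#'   see [normalize_counts()]).
#' @param labels per-nucleus cluster labels.
#' @param max_out_group_fraction,min_fold_change retention filters.
#' @return named list (one entry per cluster) of data.frames ranked by
#'   decreasing z: `gene`, `z`, `p_value`, `fold_change`, `out_fraction`.
#'   Clusters of size 1 are skipped with a warning.
#' @export
enriched_genes <- function(expr, labels, max_out_group_fraction = 0.25,
                           min_fold_change = 1.50) {
  stopifnot(nrow(expr) == length(labels))
  out <- list()
  for (k in sort(unique(labels))) {
    inn <- labels == k
    if (sum(inn) < 2) {
      warning("cluster ", k, " has fewer than 2 nuclei; skipped")
      next
    }
    n1 <- sum(inn); n2 <- sum(!inn)
    res <- lapply(colnames(expr), function(g) {
      v <- expr[, g]
      r <- rank(v)
      w <- sum(r[inn]) - n1 * (n1 + 1) / 2
      ties <- table(r)
      sigma <- sqrt(n1 * n2 / 12 *
                      ((n1 + n2 + 1) -
                         sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
      z <- if (sigma > 0) (w - n1 * n2 / 2) / sigma else 0
      fc <- (expm1(mean(v[inn])) + 1e-9) / (expm1(mean(v[!inn])) + 1e-9)
      data.frame(gene = g, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 fold_change = fc, out_fraction = mean(v[!inn] > 0))
    })
    res <- do.call(rbind, res)
    res <- res[res$out_fraction <= max_out_group_fraction &
                 res$fold_change >= min_fold_change, , drop = FALSE]
    res <- res[order(-res$z), , drop = FALSE]
    rownames(res) <- NULL
    out[[as.character(k)]] <- res
  }
  out
}
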