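# nucleolong

Single-nucleus RNA-seq of plant tissues avoids protoplasting, but nuclear
polyadenylated RNA is dominated by incompletely spliced pre-mRNA, and only
long reads can tell which introns a molecule retained and which
polyadenylation site it used. The obstacle is that at ~95% per-base
accuracy a long read's 16-nt cell barcode and 10-nt UMI cannot be read
directly. `nucleolong` is an R implementation of the guide-based rescue
strategy for this design, aimed at people building or validating long-read
single-cell pipelines:

1. **Barcode/UMI rescue.** The accurate short-read library from the same
   cDNA pool supplies guide records (barcode, UMI, gene, position). Guide
   records are bucketed in non-overlapped 500-bp genomic bins; for each
   mapped long read, the candidates from the bins overlapping or adjacent
   to its span are aligned against the read's unmapped flanks by seeded
   Smith–Waterman (word size 7; match +1, mismatch −1, gap open 0, gap
   extension −2). With error count
   E = mismatches + gap bases + unaligned query bases, a read is assigned
   its unique minimal-E candidate when barcode and UMI each carry ≤ 3
   errors; ties between distinct pairs remove the read. Reads sharing a
   (barcode, UMI, gene) collapse to one consensus molecule.
2. **Isoform layers.** A molecule is *unspliced* when any observed intron
   has a mapping ratio (covered fraction) strictly above 0.5. PolyA sites
   (strand-aware aligned 3′ termini) are clustered per gene by single
   linkage with a 24-nt gap threshold. This yields sparse nuclei × feature
   matrices: `gene|spliced` / `gene|unspliced` and `gene|PA1`, `gene|PA2`, …
3. **Multilayer analysis.** The splicing and APA layers are
   depth-normalized, log-transformed, standardized and concatenated with
   the abundance matrix; nuclei are clustered by PCA → SNN graph → Louvain;
   cell types are assigned by control-matched marker scores; differential
   splicing uses the Fisher exact test and per-cluster incompletely
   spliced ratios use a one-sided Kolmogorov–Smirnov test.

A fully seeded synthetic-data module generates a compact genome, gene
models, guide records and error-injected long reads
(adapter + barcode + UMI + polyT + cDNA, 5% default per-base error) with a
per-read truth table, so the entire pipeline is testable without any
external data or binaries.

## Worked example

```r
library(nucleolong)

cfg <- simulation_config(n_genes = 20, n_nuclei = 40,
                         reads_per_nucleus = 25, seed = 7)
sim <- simulate_dataset(cfg)

flt <- filter_long_reads(sim$reads)       # chimera / multi-map filter
bi  <- build_bin_index(sim$guide)         # 500-bp bins of guide records
asn <- assign_barcodes(flt$kept, bi)      # seeded Smith-Waterman rescue
table(asn$status)
#>      ambiguous       assigned over_threshold
#>              2            972             26

mol   <- build_molecules(flt$kept, asn, sim$models)   # per-UMI consensus
calls <- call_isoforms(mol, sim$models)               # splicing + polyA

abundance <- build_abundance_matrix(sim$guide, sim$models)
splicing  <- build_splicing_matrix(calls)
apa       <- build_apa_matrix(calls)
#> <layer_matrix 'abundance': 40 nuclei x 20 features, 457 nonzeros>
#> <layer_matrix 'splicing': 40 nuclei x 40 features, 590 nonzeros>
#> <layer_matrix 'apa': 40 nuclei x 32 features, 536 nonzeros>

merged <- normalize_and_merge(list(abundance, splicing, apa))
labels <- cluster_nuclei(merged, n_pcs = 15, seed = 1)
table(labels, setNames(sim$nuclei$celltype, sim$nuclei$barcode)[names(labels)])
#> labels T1 T2 T3
#>      1  0  0 13
#>      2  0 13  0
#>      3 14  0  0
```

972 of 1000 reads are rescued despite the 5% channel error (26 exceed the
3-error cap, 2 are ambiguous ties and removed), and multilayer clustering
recovers the three planted cell types exactly. Per-nucleus incompletely
spliced ratios and a differential-splicing test:

```r
round(summary(incompletely_spliced_ratio(calls)), 3)
#>  Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.217   0.430   0.523   0.517   0.609   0.727

g <- calls$gene_id[1]
in_cl <- calls$barcode %in% names(labels)[labels == 1]
tab <- table(factor(calls$status[calls$gene_id == g],
                    c("spliced", "unspliced")), in_cl[calls$gene_id == g])
fisher_splicing_test(tab)$p_value
#> [1] 0.005060434
```

The median ratio near 0.5 reflects the generator's default per-intron
retention probability (0.25 across genes with 1–5 introns); the Fisher
p-value tests whether gene `G0001`'s spliced/unspliced balance differs
between cluster 1 and the rest.

A thin command-line wrapper over the same functions ships in
`inst/cli/nucleolong` (subcommands `simulate`, `count`, `assign`,
`isoform`, `cluster`). The methods vignette
(`vignettes/multilayer-long-read-workflow.Rmd`) documents the model,
parameters and numerical choices.

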