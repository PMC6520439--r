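# cazprof

Contig-centric functional profiling of shotgun gut metagenomes: who is in
the community, and which carbohydrate-active enzymes (CAZymes) do their
genes encode?

`cazprof` is written for microbiome researchers comparing the biomass-
degrading capacity of gut communities across hosts — for example, asking
whether termites that farm fungus carry relatively more fungal-cell-wall-
degrading enzyme genes (chitinases EC 3.2.1.14, β-1,3/1,6-glucanases,
α-mannanases) than termites eating wood, whose communities skew toward
cellulases (EC 3.2.1.4) and xylanases (EC 3.2.1.8). It operates downstream
of assembly, gene prediction and read mapping, consuming the tables those
tools emit, so every analysis is reproducible from plain-text inputs.

## What it computes

* **Contig taxonomy by gene-vote LCA.** Homology hits per gene are filtered
  (E ≤ 1e-5, identity ≥ 30%), each gene takes its top hit's taxon
  (bit score, ties by E value then taxon id), and each contig receives the
  lowest common ancestor of its genes' taxa after discarding taxa supported
  by fewer than 10% of the contig's classified genes. Contigs without
  surviving votes are `UNCLASSIFIED`.
* **Coverage-normalized relative abundance.** Mapped reads are scaled to a
  10 Gb sequencing effort, coverage is `reads × read_length / contig_length`,
  and a contig's relative abundance is its coverage over the summed coverage;
  abundances roll up to any taxonomic rank with mass conserved.
* **Dual-evidence CAZyme calls.** A family is called for a gene only when
  HMM-domain evidence (E ≤ 1e-5, overlapping domains resolved to the longest
  matched interval) agrees with a conserved-peptide classifier (k = 6
  peptides, ≥ 2 distinct matches). EC numbers are assigned when at least two
  of three annotation channels agree, with partial ECs (`3.1.1.-`) matching
  full ECs on their first three fields.
* **Comparative profiles.** Sample × enzyme and taxon × enzyme matrices in
  relative-abundance units (×10^6 for display); per-enzyme log2 fold change
  against the cross-sample mean; centered log-ratio (CLR) transform; PCA
  with deterministic signs; hierarchical clustering.
* **A seeded synthetic-metagenome generator** with full ground truth (true
  community, contig taxa, gene annotations), so the whole pipeline is
  testable without external databases.

The package bundles a published nine-termite enzyme-abundance matrix
(`table1_profiles()`: 49 cell-wall-targeting enzymes × 9 species spanning
fungus-, soil-, dung-, humus-, litter- and wood-feeding hosts) as a worked
fixture.

## Worked example

Fold changes of the bundled nine-termite matrix against the nine-species
mean:

```r
library(cazprof)
m  <- table1_profiles()            # 9 species x 49 enzymes, units x 10^6
fc <- suppressWarnings(fold_change(m))   # warns: all-zero enzymes dropped
round(fc$ratio[c("Mn", "Od", "Mp", "Nc"),
               c("Chitinase", "Exo-1,3-beta-glucanase",
                 "Endo-1,4-beta-glucanase", "Endo-1,4-beta-xylanase")], 2)
#>    Chitinase Exo-1,3-beta-glucanase Endo-1,4-beta-glucanase Endo-1,4-beta-xylanase
#> Mn      5.03                   2.53                    0.55                   0.46
#> Od      0.80                   2.17                    0.89                   0.74
#> Mp      0.94                   2.44                    2.80                   2.14
#> Nc      1.05                   0.34                    3.24                   2.82
```

Chitinase genes in the fungus grower Mn sit 5-fold above the nine-species
mean, while the wood feeders Mp and Nc are 2–3-fold enriched for cellulase
and xylanase genes — the diet signal the matrix was built to show. CLR + PCA
separates the feeding groups:

```r
pc <- pca_profiles(clr(m))
round(pc$scores[c("Mn", "Od", "Nc"), ], 2)
#>      PC1   PC2
#> Mn  7.85  2.21
#> Od  7.27  0.98
#> Nc -2.98 -7.52
# PC1 40.6%, PC2 24.5% of variance: fungus growers right, wood feeders low
```

A fully synthetic, ground-truthed sample runs through the same stages:

```r
b    <- simulate_bundle(sim_config(seed = 1))
#> fixture_bundle: 1000 contigs, 4998 genes, 60 genera, seed 1
hits <- filter_hits(b$gene_hits)
gt   <- assign_gene_taxon(hits)
ct   <- contig_taxa(b$tree, gt, setNames(hits$contig_id, hits$gene_id)[names(gt)])
ab   <- abundance_profile(b$contigs, b$meta)
sum(ab)                                   # 1, by construction
taxon_abundance(ab, ct, b$tree, "phylum") # composition, UNCLASSIFIED pooled
```

`run_pipeline()` orchestrates all stages over a YAML-configured sample set
and writes provenance-stamped TSVs; `inst/scripts/cazprof.R` is a thin
command-line wrapper (`simulate`, `run`, `table1-demo`).

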