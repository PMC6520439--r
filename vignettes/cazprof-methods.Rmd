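---
title: "Methods: contig-centric CAZyme profiling of gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contig-centric CAZyme profiling of gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazprof)
```

## The problem

Shotgun metagenomes of animal gut communities are assembled into contigs,
genes are predicted on the contigs, and two questions follow: *who is there*
(which bacterial taxa do the contigs come from, and in what proportion) and
*what can they do* (which carbohydrate-active enzymes — CAZymes — do their
genes encode, and how abundant are those genes). `cazprof` implements a
complete, testable pipeline for both questions downstream of assembly, gene
prediction and read mapping. It consumes the tables those external tools
emit (tabular homology hits, HMM domain hits, per-contig read counts) rather
than running the searches itself, so every stage is reproducible from small
text fixtures.

The pipeline was designed around comparative questions of the type "do gut
communities of hosts with a fungal diet carry more fungal-cell-wall-degrading
enzyme genes (chitinases, β-1,3/1,6-glucanases, α-mannanases) than hosts
eating wood, litter, humus, dung or soil?", and it ships a published
nine-species termite enzyme-abundance matrix (`table1_profiles()`) as a
worked fixture for exactly that comparison.

## Contig taxonomy: gene-vote-filtered LCA

Each protein-coding gene receives taxonomy from its homology search hits.
Hits are first filtered: E values above `1e-5` and identities below 30% are
removed. Both rules are strict as stated, so a hit at exactly the boundary
survives. The surviving hit with the highest bit score wins the gene; ties
are broken by smaller E value, then lexicographically by subject taxon, so
the assignment is deterministic regardless of input order.

A contig's taxon is then a vote among its classified genes. The support of a
distinct taxon is the fraction of classified genes assigned *exactly* that
node; taxa with support strictly below 10% are discarded, and the contig
receives the lowest common ancestor (LCA) of the surviving genes' taxa. Two
boundary conventions matter and are fixed as follows:

* **Exact-node support.** A gene assigned to a genus does not count toward
  its family's support. This is the simplest reading of per-taxon vote
  counting; an implementation that propagates votes up the lineage would be
  more permissive at coarse ranks.
* **`UNCLASSIFIED`, not root.** A contig with no classified genes, or whose
  votes are all below the support floor, is reported `UNCLASSIFIED`. A root
  assignment would be uninformative and would silently inflate "classified"
  totals.
* A contig with a single classified gene is assigned that gene's taxon
  (support 100%).

One property deserves a caveat: adding further votes for the already-assigned
taxon keeps the assignment **provided the added votes themselves clear the
support floor**. A single added vote for an LCA node that was never directly
voted for can dilute an existing minority below 10% and move the consensus.
The property test therefore doubles the gene set rather than adding one vote.

Rank roll-ups (`lineage_at_rank()`, `taxon_abundance()`) walk the lineage to
a requested rank (`root`, `superkingdom`, `phylum`, `class`, `order`,
`family`, `genus`, `species`); lineages that skip the rank pool into
`UNCLASSIFIED`, so total abundance is conserved at every rank. Taxonomies are
read from the classical pipe-delimited nodes/names dump dialect; rank labels
outside the vocabulary are mapped to the nearest coarser known rank (the
nearest ancestor's rank) with a warning.

## Relative abundance: coverage normalization

Per-contig mapped-read counts are scaled to a common sequencing effort of
10 Gb (`target_bases/total_clean_bases`), coverage is estimated as
`scaled_reads × read_length / contig_length` (read length defaults to 150 bp,
the platform's), and relative abundance is coverage divided by the summed
coverage of all contigs. The 10 Gb factor cancels in relative abundance and
is kept as an explicit constant because it matters wherever absolute
coverages are exported. Contigs with zero mapped reads are retained at
abundance zero so matrix shapes are stable across samples. An alternative
estimator would use per-base depth from the alignments instead of
reads×length/contig-length; the two agree in expectation for uniformly
distributed reads and the count-based form is the one recoverable from the
tables this pipeline consumes.

## CAZyme families: dual-evidence consensus

Family calls require agreement of two independent evidence channels:

1. **HMM domains.** Domain hits are kept at E ≤ 1e-5 (inclusive). When
   retained domains overlap on the protein by at least one position, the hit
   with the longest *matched interval* is kept (ties by smaller E value,
   then family label) and the rule is reapplied until the intervals are
   pairwise disjoint. "Longest" is measured on the protein alignment, not on
   the HMM profile length, because overlap is defined on the protein;
   profile length is carried for reporting.
2. **Conserved peptides.** A family model is the set of k-mers (k = 6)
   occurring in at least `min_count = 2` training sequences, truncated to
   the `top_n = 200` most frequent (ties lexicographic), with
   sequence-occurrence counts as weights. A protein hits a family when at
   least `min_hits = 2` distinct model peptides occur in it as substrings.
   This is a deliberately simplified re-implementation of peptide-pattern
   classification: parameters are exposed, and fidelity to any particular
   external tool is a non-goal.

A family is called only when it appears in both channels' family sets for
the gene (set intersection); consensus is at the family level, without
requiring positional overlap between the peptide matches and the HMM domain.
Genes may carry several consensus families.

## EC numbers: multi-channel consensus

Three annotation channels (enzyme homology search, orthology-group search,
KEGG mapping) propose EC numbers per gene. An EC is assigned when at least
two distinct channels support it. A partial EC such as `3.1.1.-` supports
any full EC sharing its first three fields, and the most specific agreed
form is reported; the partial itself is assigned only when no matching full
EC qualifies. When several full ECs reach the channel threshold, all are
reported — downstream profiles treat genes as potentially multifunctional,
and published enzyme tables list partial ECs for the same reason. Malformed
EC strings are a parse error naming the record.

## Comparative profiles

`enzyme_profile()` builds the sample × enzyme matrix: the value for an EC is
the sum over genes assigned that EC of their contig's relative abundance,
multiplied by 10^6 for readability (so a cell of 209.59 means 2.0959×10^-4
of normalized coverage). A contig with several qualifying genes contributes
once per gene — gene-level, not contig-level, summation.
`taxon_enzyme_profile()` routes the same contributions through the contig's
taxon at a chosen rank (default `order`); column sums equal the flat profile,
so mass is conserved.

* **Fold change** compares each sample to the mean across all samples,
  column by column, and log2-transforms the ratio. All-zero columns carry no
  signal and are dropped with a warning rather than fabricated; zero cells
  over a positive mean give ratio 0 and a `-Inf` log sentinel, floored (to
  −10 by default) only in heatmap export. The raw-ratio matrix is returned
  alongside so users can apply other baselines.
* **CLR** treats each row as a composition: zeros are replaced
  multiplicatively with δ = half the smallest positive value in the matrix
  (strategy pluggable: a fixed δ, `"none"`, or a user function), rows are
  closed to proportions, logged and centered, so each output row sums to
  zero within 1e-9.
* **PCA** is a column-centered SVD with a deterministic sign convention (the
  largest-magnitude loading per component is made positive). Explained
  variance is reported against the total variance of the centered matrix, so
  truncated results have non-increasing fractions summing to at most one.
* **Clustering** defaults to Euclidean distance with average linkage, both
  configurable.

## The synthetic-data generator

`simulate_bundle()` produces a complete, ground-truthed input bundle from a
single seed: a balanced ranked taxonomy; a Dirichlet community over genera
(concentration 2 by default — moderately uneven, as gut communities are —
with presets that skew mass to chosen orders to mimic fungus-grower-like or
wood-feeder-like communities); contigs with log-normal lengths around 5 kb
(≈1 gene/kb, Poisson genes per contig); noisy gene hits; multinomial read
counts with expectation proportional to abundance × length; and three-channel
annotation evidence over a compact CAZyme family/EC/substrate inventory.

Noise structure, chosen for realism and fixed before any acceptance
measurement:

* With probability ε (default 0.05) a gene's top hit points to a uniformly
  random other genus.
* A configured fraction of genes (default 0.10) has uniformly weak evidence:
  their top hit *and* their decoys violate the E-value/identity filters, so
  they end up unclassified rather than randomly assigned. This mirrors how
  genes without close database relatives behave.
* Decoy (lower-scoring) hits come from the true genus half the time, because
  weaker homologs still cluster taxonomically.
* Each annotation channel reports the true label with probability `s`
  (default 0.9) and, independently, a random wrong label with probability
  `f` (default 0.05). False domain hits are placed off the true interval
  unless designated overlapping (rate 0.3 by default, and then drawn
  shorter, as spurious partial profile matches are), which keeps the
  configured overlap rate identifiable.

What the generator does **not** emulate: sequence content (proteins are
random strings except where the peptide classifier needs planted motifs),
assembly artifacts and chimeras, strain-level variation, read-level errors,
and database incompleteness that deletes whole lineages. Passing recovery
tests therefore demonstrates the pipeline's bookkeeping and statistical
behaviour under the stated noise model, not robustness to reference bias in
real data.

Two ground truths are recorded: the *expected* genus composition (from the
drawn coverage shares) and the *realized* one (from the realized read
counts). Noiseless end-to-end checks compare against the realized truth —
they verify the pipeline's arithmetic exactly; recovery checks compare
against the expected truth and absorb multinomial noise.

## Problem sizes and tolerances

The test suite and the acceptance script run on: 50-node random trees with
500+ random contigs for LCA oracle equivalence; a noisy bundle of 1,200
contigs, 60 genera, Poisson-25 genes/contig and 10^6 reads of 150 bp for
composition recovery (the recovery check conditions on contigs with ≥20
classified genes, hence the gene density; real gut samples run to ~5×10^7
reads, so this is conservative); and an 800-contig bundle with sensitivity
0.9 / false-positive rate 0.05 for the consensus-precision comparison.
Compositional sums are checked to 1e-9; exact reproductions to 1e-12;
stochastic recovery to the stated L1 ≤ 0.02.

## Known limitations

* Strict LCA only: no probabilistic lineage models, and no vote propagation
  from descendants to ancestors (which would change behaviour on contigs
  whose genes resolve at mixed depths).
* The peptide classifier is a transparent simplification; its parameters are
  honest knobs, not a re-implementation of any published tool's internals.
* Enzyme profiles weight genes by their contig's abundance; they are gene
  dosage estimates, not expression or activity.
* The pipeline consumes hit tables; database composition and search
  sensitivity are upstream concerns it cannot correct.
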