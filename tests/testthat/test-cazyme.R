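test_that("peptide model training keeps shared k-mers, checked by oracle", {
  # the only k-mer present in >= 2 sequences survives
  base <- c("AAAAAAGHSMGGAAAAAA", "CCCCCCGHSMGGCCCCCC", "DDDDDDGHSMGGDDDDDD")
  m <- train_peptide_model(base, family = "GH18")
  expect_equal(m$peptides[["GHSMGG"]], 3L)
  # a k-mer unique to one sequence is excluded
  expect_false("AAAAAA" %in% names(m$peptides))

  expect_error(train_peptide_model("SINGLE"), "2 sequences")
  expect_error(train_peptide_model(c("ABCDEF", "GHIKLM")), "cannot train")

  # random family with planted motifs: model contains every motif planted in
  # >= min_count sequences and counts agree with the brute-force counter
  set.seed(30)
  seqs <- vapply(1:8, function(i) {
    paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120, TRUE),
           collapse = "")
  }, "")
  motifs <- c("WWHHKK", "MMNNPP")
  for (mi in seq_along(motifs)) {
    for (j in 1:4) {
      pos <- j * 20 + mi * 8
      substr(seqs[j], pos, pos + 5) <- motifs[mi]
    }
  }
  m <- train_peptide_model(seqs, k = 6, min_count = 2, top_n = 500)
  oracle <- oracle_kmer_counts(seqs, 6)
  oracle <- oracle[oracle >= 2]
  expect_setequal(names(m$peptides), names(oracle))
  expect_equal(m$peptides[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  expect_true(all(c("WWHHKK", "MMNNPP") %in% names(m$peptides)))

  # top_n truncation keeps the most frequent, ties lexicographic
  m2 <- train_peptide_model(seqs, k = 6, min_count = 2, top_n = 3)
  srt <- oracle[order(-oracle, names(oracle))]
  expect_equal(names(m2$peptides), names(srt)[1:3])
})

test_that("peptide classification counts distinct model peptides", {
  gh18 <- structure(list(family = "GH18", k = 6L,
                         peptides = c(AAAGGG = 5L, CCCTTT = 3L,
                                      DDDEEE = 2L)),
                    class = "peptide_model")
  gh19 <- structure(list(family = "GH19", k = 6L,
                         peptides = c(WWWYYY = 4L, HHHMMM = 2L)),
                    class = "peptide_model")
  prot <- "XXAAAGGGXXCCCTTTXXDDDEEEXX"
  hits <- classify_peptides(prot, list(gh18, gh19), gene_id = "g1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "GH18")
  expect_equal(hits$n_matched, 3L)
  expect_equal(hits$score, 10L)
  # one below the threshold: no hit
  expect_equal(nrow(classify_peptides("XXAAAGGGXX", list(gh18))), 0L)
  expect_error(classify_peptides("", list(gh18)), "empty")

  # 100 random proteins vs models: agreement with the naive substring scan
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  models <- lapply(1:5, function(i) {
    structure(list(family = paste0("F", i), k = 6L,
                   peptides = setNames(
                     sample(2:9, 8, TRUE),
                     vapply(1:8, function(j)
                       paste0(sample(aa, 6, TRUE), collapse = ""), ""))),
              class = "peptide_model")
  })
  for (i in 1:100) {
    prot <- paste0(sample(aa, 150, TRUE), collapse = "")
    # plant a few peptides to create real matches
    for (m in sample(models, 2)) {
      for (p in sample(names(m$peptides), sample(0:3, 1))) {
        pos <- sample(140, 1)
        substr(prot, pos, pos + 5) <- p
      }
    }
    got <- classify_peptides(prot, models, min_hits = 2)
    for (m in models) {
      found <- oracle_peptide_matches(prot, names(m$peptides))
      if (length(found) >= 2) {
        row <- got[got$family == m$family, ]
        expect_equal(row$n_matched, length(found))
        expect_equal(row$score, sum(m$peptides[found]))
      } else {
        expect_false(m$family %in% got$family)
      }
    }
  }
})

test_that("domain-hit E-value filter is inclusive at the bound", {
  h <- data.frame(gene_id = "g", family = c("GH18", "GH19", "GH5"),
                  align_start = 1L, align_end = 50L, profile_length = 60L,
                  evalue = c(1e-5, 2e-5, 1e-8), stringsAsFactors = FALSE)
  expect_equal(filter_domain_hits(h)$family, c("GH18", "GH5"))
  set.seed(32)
  h2 <- data.frame(gene_id = "g", family = paste0("F", 1:200),
                   align_start = 1L, align_end = 50L, profile_length = 60L,
                   evalue = 10^runif(200, -9, -3), stringsAsFactors = FALSE)
  expect_equal(filter_domain_hits(h2),
               h2[sapply(h2$evalue, function(e) e <= 1e-5), ])
})

test_that("overlapping domains resolve to the longest matched profile", {
  h <- data.frame(gene_id = "g",
                  family = c("GH18", "GH19"),
                  align_start = c(10L, 250L), align_end = c(300L, 350L),
                  profile_length = c(320L, 120L), evalue = c(1e-20, 1e-30),
                  stringsAsFactors = FALSE)
  expect_equal(resolve_overlapping_domains(h)$family, "GH18")
  # disjoint intervals are both kept
  h2 <- data.frame(gene_id = "g", family = c("GH5", "GH10"),
                   align_start = c(1L, 200L), align_end = c(100L, 300L),
                   profile_length = 100L, evalue = 1e-10,
                   stringsAsFactors = FALSE)
  expect_equal(resolve_overlapping_domains(h2)$family, c("GH5", "GH10"))

  # random interval sets match the literal elimination oracle, and the
  # output is always pairwise non-overlapping
  set.seed(33)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    st <- sample(1:300, n, TRUE)
    len <- sample(10:150, n, TRUE)
    h3 <- data.frame(gene_id = "g", family = paste0("F", sample(9, n, TRUE)),
                     align_start = st, align_end = st + len - 1L,
                     profile_length = len, evalue = 10^(-sample(6:30, n, TRUE)),
                     stringsAsFactors = FALSE)
    got <- resolve_overlapping_domains(h3)
    expect_equal(got, oracle_resolve(h3), ignore_attr = TRUE)
    if (nrow(got) > 1) {
      for (a in seq_len(nrow(got) - 1)) {
        for (b in (a + 1):nrow(got)) {
          expect_true(got$align_start[a] > got$align_end[b] ||
                        got$align_end[a] < got$align_start[b])
        }
      }
    }
  }
})

test_that("consensus family calls are the per-gene channel intersection", {
  dom <- data.frame(gene_id = c("g1", "g2", "g3", "g3"),
                    family = c("GH18", "GH5", "GH10", "GH11"),
                    stringsAsFactors = FALSE)
  pep <- data.frame(gene_id = c("g1", "g3", "g4"),
                    family = c("GH18", "GH11", "GH2"),
                    stringsAsFactors = FALSE)
  calls <- consensus_families(dom, pep)
  expect_equal(calls,
               data.frame(gene_id = c("g1", "g3"),
                          family = c("GH18", "GH11"),
                          stringsAsFactors = FALSE))

  # random channel sets: calls equal the set intersection per gene and are
  # a subset of each channel
  set.seed(34)
  fams <- paste0("F", 1:12)
  genes <- paste0("g", 1:40)
  dom <- data.frame(gene_id = sample(genes, 120, TRUE),
                    family = sample(fams, 120, TRUE),
                    stringsAsFactors = FALSE)
  pep <- data.frame(gene_id = sample(genes, 120, TRUE),
                    family = sample(fams, 120, TRUE),
                    stringsAsFactors = FALSE)
  calls <- consensus_families(dom, pep)
  for (g in genes) {
    expected <- sort(intersect(dom$family[dom$gene_id == g],
                               pep$family[pep$gene_id == g]))
    expect_equal(calls$family[calls$gene_id == g], expected)
  }
})

test_that("EC assignment needs agreement of two channels, partials match by prefix", {
  ev <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g3", "g3"),
    channel = c("enzyme_homology", "kegg_mapper", "orthology_group",
                "enzyme_homology", "enzyme_homology", "kegg_mapper"),
    ec = c("3.2.1.14", "3.2.1.14", "3.2.1.4", "3.2.1.8", "3.1.1.-",
           "3.1.1.72"),
    stringsAsFactors = FALSE)
  out <- assign_ec(ev)
  # two channels agree on the full EC
  expect_equal(out[out$gene_id == "g1", ]$ec, "3.2.1.14")
  expect_equal(out[out$gene_id == "g1", ]$n_channels, 2L)
  # single-channel support is not assigned
  expect_false("g2" %in% out$gene_id)
  # partial EC supports the matching full EC; the specific form is reported
  expect_equal(out[out$gene_id == "g3", ]$ec, "3.1.1.72")
  expect_equal(out[out$gene_id == "g3", ]$n_channels, 2L)

  # two partials with no matching full EC: the partial itself is assigned
  ev2 <- data.frame(gene_id = "g4",
                    channel = c("enzyme_homology", "kegg_mapper"),
                    ec = "3.1.1.-", stringsAsFactors = FALSE)
  out2 <- assign_ec(ev2)
  expect_equal(out2$ec, "3.1.1.-")

  expect_error(assign_ec(data.frame(gene_id = "g", channel = "kegg_mapper",
                                    ec = "3.2.1", stringsAsFactors = FALSE)),
               "malformed EC")

  # duplicated votes from the same channel count once
  ev3 <- data.frame(gene_id = "g5", channel = "kegg_mapper",
                    ec = c("3.2.1.14", "3.2.1.14"), stringsAsFactors = FALSE)
  expect_equal(nrow(assign_ec(ev3)), 0L)
})

test_that("domain hit readers parse both dialects", {
  # domtblout dialect (22+ whitespace columns, comments)
  lines <- c(
    "# comment",
    paste("GH18.hmm - 320 ctg1_1 - 410 1.2e-30 95.2 0.1 1 1 2e-31 1.5e-28",
          "94.1 0.1 5 310 12 300 10 305 0.95 -"),
    paste("GH5.hmm - 280 ctg1_2 - 350 3e-10 40.0 0.0 1 1 4e-11 5e-9",
          "38.5 0.0 1 270 20 285 15 290 0.90 -"))
  f <- tempfile()
  writeLines(lines, f)
  d <- read_domtblout(f)
  expect_equal(d$gene_id, c("ctg1_1", "ctg1_2"))
  expect_equal(d$family, c("GH18", "GH5"))
  expect_equal(d$align_start, c(12L, 20L))
  expect_equal(d$align_end, c(300L, 285L))
  expect_equal(d$profile_length, c(320L, 280L))
  expect_equal(d$evalue, c(1.5e-28, 5e-9))

  f2 <- tempfile()
  write_domain_tsv(d, f2)
  expect_equal(read_domain_tsv(f2), d)
})

test_that("peptide models and proteins round-trip through their formats", {
  set.seed(35)
  fm <- make_family_models(sim_config(seed = 35), n_train = 4, n_peptides = 5)
  f <- tempfile()
  write_peptide_models(fm$models, f)
  back <- read_peptide_models(f)
  expect_setequal(names(back), names(fm$models))
  for (fam in names(back)) {
    expect_equal(sort(names(back[[fam]]$peptides)),
                 sort(names(fm$models[[fam]]$peptides)))
  }
  truth <- data.frame(gene_id = c("c1_1", "c1_2"),
                      family = c("GH18", "GH5"), stringsAsFactors = FALSE)
  prot <- make_proteins(truth, fm$models)
  fa <- tempfile(fileext = ".fa")
  write_fasta(prot, fa)
  expect_equal(read_fasta(fa), prot)
  # planted proteins classify to their family
  hits <- classify_peptides_all(prot, fm$models)
  for (i in seq_len(nrow(truth))) {
    expect_true(truth$family[i] %in%
                  hits$family[hits$gene_id == truth$gene_id[i]])
  }
})
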