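# Seeded synthetic-metagenome generator. Produces every input dialect the
# pipeline reads, together with the ground truth needed for recovery tests:
# a ranked taxonomy, a Dirichlet community, contigs carrying genes, noisy
# gene-level taxonomic hits, multinomial read counts, and three-channel
# family/EC annotation evidence with stated error rates.

#' Default enzyme-family inventory for simulations
#'
#' A compact set of CAZyme families with a representative EC number and
#' substrate class each, spanning fungal cell wall (chitin, beta-glucan,
#' alpha-mannan) and plant cell wall (cellulose, hemicellulose, pectin,
#' lignin) targets.
#'
#' @return data.frame with columns `family`, `ec`, `enzyme`, `substrate`.
#' @export
default_family_inventory <- function() {
  data.frame(
    family = c("GH18", "GH20", "GH55", "GH81", "GH30", "GH3", "GH13",
               "GH5", "GH10", "GH43", "GH38", "GH76", "GH26", "GH2",
               "GH27", "PL1", "AA1", "CE1"),
    ec = c("3.2.1.14", "3.2.1.52", "3.2.1.58", "3.2.1.39", "3.2.1.75",
           "3.2.1.21", "3.2.1.20", "3.2.1.4", "3.2.1.8", "3.2.1.37",
           "3.2.1.24", "3.2.1.101", "3.2.1.78", "3.2.1.23", "3.2.1.22",
           "4.2.2.2", "1.10.3.2", "3.1.1.72"),
    enzyme = c("Chitinase", "beta-N-Acetylhexosaminidase",
               "Exo-1,3-beta-glucanase", "Endo-1,3-beta-glucanase",
               "Endo-1,6-beta-glucosidase", "Exo-beta-glucosidase",
               "Endo-1,4-alpha-glucanase", "Endo-1,4-beta-glucanase",
               "Endo-1,4-beta-xylanase", "Exo-beta-1,4-xylosidase",
               "Exo-alpha-mannosidase", "Endo-1,6-alpha-mannanase",
               "Endo-1,4-beta-mannanase", "beta-Galactosidase",
               "Exo-alpha-galactosidase", "Pectate lyase", "Laccase",
               "Acetyl xylan esterase"),
    substrate = c("chitin", "chitin", "beta-glucan", "beta-glucan",
                  "beta-glucan", "beta-glucan", "alpha-glucan", "cellulose",
                  "hemicellulose", "hemicellulose", "mannan", "mannan",
                  "mannan", "galactan", "galactan", "pectin", "lignin",
                  "hemicellulose"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-metagenome generator with defaults
#' emulating the study design: dozens of genera across a handful of phyla, a
#' moderately uneven Dirichlet community, log-normal contig lengths around
#' the ~1 kb scale of short-read gut metagenome assemblies, 150-bp reads, a
#' 5% gene-level taxonomic misassignment rate, 10% of raw hits violating the
#' E-value/identity filters, and annotation channels with sensitivity 0.9
#' and false-positive rate 0.05.
#'
#' @param seed integer seed; all randomness in [simulate_bundle()] flows
#'   from it.
#' @param n_phyla,n_orders,n_genera taxon counts per rank (orders and genera
#'   are spread round-robin over the coarser rank).
#' @param concentration Dirichlet concentration of the community draw.
#' @param preset optional community preset: `"fungus_grower"` (first two
#'   orders dominate), `"wood_feeder"` (third order dominates), or `NULL`
#'   for a symmetric draw.
#' @param n_contigs number of contigs.
#' @param contig_length_meanlog,contig_length_sdlog log-normal contig-length
#'   parameters (bp).
#' @param genes_per_contig Poisson mean of genes per contig (at least 1 gene
#'   is always placed).
#' @param misassignment_rate probability that a gene's top hit points to a
#'   uniformly random wrong genus.
#' @param filter_violation_rate fraction of top hits drawn to violate the
#'   E-value/identity filters (such genes end up unclassified).
#' @param decoy_rate Poisson mean of additional lower-scoring decoy hits per
#'   gene.
#' @param read_depth total mapped reads in the sample.
#' @param read_length_bp read length (bp).
#' @param annotate_fraction fraction of genes carrying a planted
#'   CAZyme family / EC label.
#' @param sensitivity per-channel probability of reporting the true label.
#' @param false_positive_rate per-channel probability of also reporting a
#'   random wrong label.
#' @param overlap_rate probability that a false domain hit overlaps the true
#'   domain interval on the same protein.
#' @param inventory family/EC/substrate inventory data.frame (see
#'   [default_family_inventory()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_phyla = 5L, n_orders = 15L, n_genera = 60L,
                       concentration = 2,
                       preset = NULL,
                       n_contigs = 1000L,
                       contig_length_meanlog = log(5000),
                       contig_length_sdlog = 0.8,
                       genes_per_contig = 5,
                       misassignment_rate = 0.05,
                       filter_violation_rate = 0.10,
                       decoy_rate = 1,
                       read_depth = 2e5L,
                       read_length_bp = 150L,
                       annotate_fraction = 0.3,
                       sensitivity = 0.9,
                       false_positive_rate = 0.05,
                       overlap_rate = 0.3,
                       inventory = default_family_inventory()) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_phyla >= 1, cfg$n_orders >= 1, cfg$n_genera >= 1,
            cfg$n_contigs >= 1, cfg$concentration > 0,
            cfg$misassignment_rate >= 0, cfg$misassignment_rate < 1,
            cfg$filter_violation_rate >= 0, cfg$filter_violation_rate <= 1,
            cfg$sensitivity >= 0, cfg$sensitivity <= 1,
            cfg$false_positive_rate >= 0, cfg$false_positive_rate <= 1,
            cfg$read_depth > 0, cfg$read_length_bp > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Build a balanced ranked taxonomy for a simulation
#'
#' Deterministic given the configuration: phyla hang off the root (one class
#' each), orders are spread round-robin over classes, one family per order,
#' and genera are spread round-robin over families.
#'
#' @param config a [sim_config()].
#' @return A [taxonomy_tree].
#' @export
make_taxonomy <- function(config) {
  np <- config$n_phyla; no <- config$n_orders; ng <- config$n_genera
  rows <- list(data.frame(taxon_id = "1", parent_id = "1", rank = "root",
                          name = "root", stringsAsFactors = FALSE))
  phy <- paste0("p", seq_len(np))
  cls <- paste0("c", seq_len(np))
  rows$phy <- data.frame(taxon_id = phy, parent_id = "1", rank = "phylum",
                         name = paste0("Phylum_", seq_len(np)))
  rows$cls <- data.frame(taxon_id = cls, parent_id = phy, rank = "class",
                         name = paste0("Class_", seq_len(np)))
  ord <- paste0("o", seq_len(no))
  ord_parent <- cls[((seq_len(no) - 1L) %% np) + 1L]
  rows$ord <- data.frame(taxon_id = ord, parent_id = ord_parent,
                         rank = "order", name = paste0("Order_", seq_len(no)))
  fam <- paste0("f", seq_len(no))
  rows$fam <- data.frame(taxon_id = fam, parent_id = ord, rank = "family",
                         name = paste0("Family_", seq_len(no)))
  gen <- paste0("g", seq_len(ng))
  gen_parent <- fam[((seq_len(ng) - 1L) %% no) + 1L]
  rows$gen <- data.frame(taxon_id = gen, parent_id = gen_parent,
                         rank = "genus", name = paste0("Genus_", seq_len(ng)))
  taxonomy_tree(do.call(rbind, rows))
}

#' Draw a true genus-level community composition
#'
#' Dirichlet draw over the tree's genera; presets skew the concentration
#' towards chosen orders to mimic fungus-grower-like (first two orders heavy)
#' or wood-feeder-like (third order heavy) communities.
#'
#' @param config a [sim_config()].
#' @param tree taxonomy from [make_taxonomy()].
#' @return Named numeric vector `genus -> abundance`, summing to 1.
#' @export
make_community <- function(config, tree) {
  genera <- tree$nodes$taxon_id[tree$nodes$rank == "genus"]
  w <- rep(1, length(genera))
  if (!is.null(config$preset)) {
    ord <- vapply(genera, lineage_at_rank, "", tree = tree, rank = "order")
    heavy <- switch(config$preset,
                    fungus_grower = c("o1", "o2"),
                    wood_feeder = "o3",
                    stop("unknown preset: ", config$preset))
    w[ord %in% heavy] <- 8
  }
  x <- stats::rgamma(length(genera), shape = config$concentration * w)
  stats::setNames(x / sum(x), genera)
}

#' Generate contigs and the genes they carry
#'
#' Contigs are assigned true genera proportionally to the community,
#' log-normal lengths, and a Poisson (minimum 1) number of genes named
#' `<contig>_<n>`. The ground-truth per-contig coverage share splits each
#' represented genus's abundance equally over its contigs and renormalizes,
#' so expected read counts are proportional to abundance times length.
#'
#' @param config a [sim_config()].
#' @param community from [make_community()].
#' @return List with `contigs` (contig_id, length_bp, true_genus,
#'   coverage_share), and `genes` (gene_id, contig_id, true_genus).
#' @export
make_contigs_genes <- function(config, community) {
  n <- config$n_contigs
  id <- sprintf("ctg%05d", seq_len(n))
  genus <- sample(names(community), n, replace = TRUE, prob = community)
  len <- pmax(300L, as.integer(round(stats::rlnorm(
    n, config$contig_length_meanlog, config$contig_length_sdlog))))
  share <- community[genus] / as.vector(table(genus)[genus])
  share <- share / sum(share)
  ngenes <- pmax(1L, stats::rpois(n, config$genes_per_contig))
  genes <- data.frame(
    gene_id = paste0(rep(id, ngenes), "_",
                     unlist(lapply(ngenes, seq_len), use.names = FALSE)),
    contig_id = rep(id, ngenes),
    true_genus = rep(genus, ngenes),
    stringsAsFactors = FALSE
  )
  list(
    contigs = data.frame(contig_id = id, length_bp = len, true_genus = genus,
                         coverage_share = unname(share),
                         stringsAsFactors = FALSE),
    genes = genes
  )
}

#' Generate a noisy gene-level homology hit table
#'
#' Each gene gets one top hit: with probability `1 - misassignment_rate` it
#' points to the true genus, otherwise to a uniformly random other genus. A
#' configured fraction of top hits is drawn to violate the E-value or
#' identity filter (split evenly between the two causes), and Poisson-many
#' lower-scoring decoy hits are added per gene.
#'
#' @param config a [sim_config()].
#' @param genes gene table from [make_contigs_genes()].
#' @param tree taxonomy from [make_taxonomy()].
#' @return data.frame in the shape of [read_gene_hits()] output.
#' @export
make_gene_hits <- function(config, genes, tree) {
  genera <- tree$nodes$taxon_id[tree$nodes$rank == "genus"]
  n <- nrow(genes)
  wrong <- stats::runif(n) < config$misassignment_rate
  taxon <- genes$true_genus
  if (any(wrong)) {
    taxon[wrong] <- vapply(genes$true_genus[wrong], function(g) {
      sample(setdiff(genera, g), 1L)
    }, "")
  }
  violate <- stats::runif(n) < config$filter_violation_rate
  via_evalue <- violate & stats::runif(n) < 0.5
  via_ident <- violate & !via_evalue
  evalue <- 10^stats::runif(n, -50, -6)
  evalue[via_evalue] <- 10^stats::runif(sum(via_evalue), -4.9, -2)
  ident <- stats::runif(n, 35, 99)
  ident[via_ident] <- stats::runif(sum(via_ident), 5, 29.5)
  score <- stats::runif(n, 150, 300)
  top <- data.frame(
    gene_id = genes$gene_id, contig_id = genes$contig_id,
    subject_taxon = taxon, evalue = evalue, percent_identity = ident,
    bit_score = score, stringsAsFactors = FALSE
  )
  ndecoy <- stats::rpois(n, config$decoy_rate)
  idx <- rep(seq_len(n), ndecoy)
  if (length(idx)) {
    # decoys are weaker homologs: often the same genus, otherwise random;
    # genes whose top hit fails the filters have uniformly weak evidence,
    # so their decoys fail too
    same <- stats::runif(length(idx)) < 0.5
    dtax <- character(length(idx))
    dtax[same] <- taxon[idx][same]
    if (any(!same)) {
      dtax[!same] <- vapply(taxon[idx][!same], function(g) {
        sample(setdiff(genera, g), 1L)
      }, "")
    }
    dev <- 10^stats::runif(length(idx), -30, -6)
    did <- stats::runif(length(idx), 31, 90)
    bad <- violate[idx]
    dev[bad] <- 10^stats::runif(sum(bad), -4.5, -2)
    did[bad] <- stats::runif(sum(bad), 5, 29.5)
    decoy <- data.frame(
      gene_id = genes$gene_id[idx], contig_id = genes$contig_id[idx],
      subject_taxon = dtax, evalue = dev, percent_identity = did,
      bit_score = score[idx] - stats::runif(length(idx), 5, 50),
      stringsAsFactors = FALSE
    )
    top <- rbind(top, decoy)
  }
  out <- top[order(top$gene_id, -top$bit_score), ]
  rownames(out) <- NULL
  out
}

#' Draw mapped read counts per contig
#'
#' Reads are multinomial over contigs with probability proportional to the
#' contig's true coverage share times its length, so expected coverage is
#' proportional to the truth.
#'
#' @param config a [sim_config()].
#' @param contigs contig table from [make_contigs_genes()].
#' @return List: `contigs` (with a `mapped_reads` column) and `meta`
#'   (sample_id, total_clean_bases, read_length_bp).
#' @export
make_read_counts <- function(config, contigs) {
  p <- contigs$coverage_share * contigs$length_bp
  reads <- as.vector(stats::rmultinom(1L, config$read_depth, p / sum(p)))
  contigs$mapped_reads <- reads
  list(contigs = contigs,
       meta = list(sample_id = "sim",
                   total_clean_bases = config$read_depth *
                     config$read_length_bp,
                   read_length_bp = config$read_length_bp))
}

#' Generate three-channel annotation evidence with planted truth
#'
#' A configured fraction of genes receives a planted family (and its EC)
#' from the inventory. Each evidence channel then reports the true label
#' with probability `sensitivity` and, independently, a random wrong label
#' with probability `false_positive_rate`. Domain-hit coordinates are drawn
#' so that a configured fraction of false hits overlaps the true domain
#' interval (the false interval is drawn shorter, as spurious partial
#' profile matches are).
#'
#' @param config a [sim_config()].
#' @param genes gene table from [make_contigs_genes()].
#' @return List: `truth` (gene_id, family, ec, substrate), `domain_hits`,
#'   `peptide_hits`, `ec_evidence`.
#' @export
make_annotation_tables <- function(config, genes) {
  inv <- config$inventory
  sel <- stats::runif(nrow(genes)) < config$annotate_fraction
  g <- genes$gene_id[sel]
  fam_idx <- sample(nrow(inv), length(g), replace = TRUE)
  truth <- data.frame(gene_id = g, family = inv$family[fam_idx],
                      ec = inv$ec[fam_idx],
                      substrate = inv$substrate[fam_idx],
                      stringsAsFactors = FALSE)
  s <- config$sensitivity; f <- config$false_positive_rate
  other <- function(x, pool) {
    vapply(x, function(v) sample(setdiff(pool, v), 1L), "")
  }
  protein_len <- 400L

  domain_channel <- function() {
    tp <- stats::runif(nrow(truth)) < s
    t_len <- as.integer(stats::runif(nrow(truth), 150, 320))
    t_start <- as.integer(stats::runif(nrow(truth), 1,
                                       protein_len - t_len))
    true_hits <- data.frame(
      gene_id = truth$gene_id[tp], family = truth$family[tp],
      align_start = t_start[tp], align_end = (t_start + t_len - 1L)[tp],
      profile_length = as.integer(t_len[tp] * 1.1),
      evalue = 10^stats::runif(sum(tp), -30, -6), stringsAsFactors = FALSE
    )
    fp <- stats::runif(nrow(truth)) < f
    if (any(fp)) {
      nf <- sum(fp)
      f_len <- as.integer(stats::runif(nf, 40, 100))
      ovl <- stats::runif(nf) < config$overlap_rate & tp[fp]
      f_start <- integer(nf)
      fs <- t_start[fp]; fe <- (t_start + t_len - 1L)[fp]
      for (i in seq_len(nf)) {
        if (!tp[fp][i]) {
          # no true hit on this protein: place anywhere
          f_start[i] <- sample.int(protein_len - f_len[i], 1L)
        } else if (ovl[i]) {
          f_start[i] <- min(fs[i] + 5L, protein_len - f_len[i])
        } else {
          # place the spurious hit clear of the true domain
          left <- fs[i] - 1L
          right <- protein_len - fe[i]
          if (right >= left) {
            f_len[i] <- min(f_len[i], right - 1L)
            f_start[i] <- fe[i] + 1L + sample.int(right - f_len[i], 1L)
          } else {
            f_len[i] <- min(f_len[i], left - 1L)
            f_start[i] <- sample.int(left - f_len[i], 1L)
          }
        }
      }
      false_hits <- data.frame(
        gene_id = truth$gene_id[fp],
        family = other(truth$family[fp], inv$family),
        align_start = f_start, align_end = f_start + f_len - 1L,
        profile_length = as.integer(f_len * 1.1),
        evalue = 10^stats::runif(nf, -12, -6), stringsAsFactors = FALSE
      )
      true_hits <- rbind(true_hits, false_hits)
    }
    true_hits[order(true_hits$gene_id, true_hits$family), ]
  }
  domain_hits <- domain_channel()

  tp <- stats::runif(nrow(truth)) < s
  peptide_hits <- data.frame(
    gene_id = truth$gene_id[tp], family = truth$family[tp],
    n_matched = 2L + stats::rpois(sum(tp), 3),
    score = as.integer(stats::runif(sum(tp), 10, 300)),
    stringsAsFactors = FALSE
  )
  fp <- stats::runif(nrow(truth)) < f
  if (any(fp)) {
    peptide_hits <- rbind(peptide_hits, data.frame(
      gene_id = truth$gene_id[fp],
      family = other(truth$family[fp], inv$family),
      n_matched = 2L, score = as.integer(stats::runif(sum(fp), 4, 40)),
      stringsAsFactors = FALSE
    ))
  }
  peptide_hits <- peptide_hits[order(peptide_hits$gene_id,
                                     peptide_hits$family), ]

  channels <- c("enzyme_homology", "orthology_group", "kegg_mapper")
  ev <- lapply(channels, function(ch) {
    tp <- stats::runif(nrow(truth)) < s
    out <- data.frame(gene_id = truth$gene_id[tp], channel = ch,
                      ec = truth$ec[tp], stringsAsFactors = FALSE)
    fp <- stats::runif(nrow(truth)) < f
    if (any(fp)) {
      out <- rbind(out, data.frame(
        gene_id = truth$gene_id[fp], channel = ch,
        ec = other(truth$ec[fp], unique(inv$ec)), stringsAsFactors = FALSE))
    }
    out
  })
  ec_evidence <- do.call(rbind, ev)
  ec_evidence <- ec_evidence[order(ec_evidence$gene_id, ec_evidence$channel,
                                   ec_evidence$ec), ]
  rownames(ec_evidence) <- rownames(peptide_hits) <-
    rownames(domain_hits) <- NULL
  list(truth = truth, domain_hits = domain_hits,
       peptide_hits = peptide_hits, ec_evidence = ec_evidence)
}

#' Generate a complete ground-truthed fixture bundle
#'
#' Seeds the generator once from `config$seed` and chains
#' [make_taxonomy()], [make_community()], [make_contigs_genes()],
#' [make_gene_hits()], [make_read_counts()] and [make_annotation_tables()].
#' Regenerating with the same configuration is identical.
#'
#' @param config a [sim_config()].
#' @return List of class `fixture_bundle` with elements `config`, `tree`,
#'   `community`, `contigs`, `genes`, `gene_hits`, `domain_hits`,
#'   `peptide_hits`, `ec_evidence`, `meta`, and `truth` (true contig taxa,
#'   gene annotations, expected and realized genus compositions, realized
#'   contig abundance, realized enzyme profile).
#' @export
simulate_bundle <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- make_taxonomy(config)
  community <- make_community(config, tree)
  cg <- make_contigs_genes(config, community)
  gene_hits <- make_gene_hits(config, cg$genes, tree)
  rc <- make_read_counts(config, cg$contigs)
  ann <- make_annotation_tables(config, cg$genes)
  contigs <- rc$contigs

  cov <- contigs$mapped_reads * config$read_length_bp / contigs$length_bp
  abund <- stats::setNames(cov / sum(cov), contigs$contig_id)
  genus_expected <- tapply(contigs$coverage_share, contigs$true_genus, sum)
  genus_realized <- tapply(abund, contigs$true_genus, sum)
  ctg_ab <- abund[gene_to_contig(ann$truth$gene_id)]
  enzyme_truth <- tapply(ctg_ab * 1e6, ann$truth$ec, sum)

  structure(list(
    config = config, tree = tree, community = community,
    contigs = contigs, genes = cg$genes, gene_hits = gene_hits,
    domain_hits = ann$domain_hits, peptide_hits = ann$peptide_hits,
    ec_evidence = ann$ec_evidence, meta = rc$meta,
    truth = list(
      contig_genus = stats::setNames(contigs$true_genus, contigs$contig_id),
      gene_annotation = ann$truth,
      genus_composition = stats::setNames(as.vector(genus_expected),
                                          names(genus_expected)),
      genus_composition_realized = stats::setNames(as.vector(genus_realized),
                                                   names(genus_realized)),
      contig_abundance = abund,
      enzyme_profile = stats::setNames(as.vector(enzyme_truth),
                                       names(enzyme_truth))
    )
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle:", nrow(x$contigs), "contigs,", nrow(x$genes),
      "genes,", length(x$community), "genera, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a fixture bundle to disk in the dialects the pipeline reads
#'
#' Writes the taxonomy dump (nodes/names), the contig table, the 13-column
#' gene hit table, the simplified domain-hit TSV, the peptide-hit TSV, the
#' EC-evidence TSV, sample metadata and configuration as YAML, and the
#' ground-truth tables. Output is deterministic for a given bundle.
#'
#' @param bundle from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_taxonomy(bundle$tree, p("nodes.dmp"), p("names.dmp"))
  data.table::fwrite(bundle$contigs[c("contig_id", "length_bp",
                                      "mapped_reads")],
                     p("contigs.tsv"), sep = "\t")
  write_gene_hits(bundle$gene_hits, p("gene_hits.tsv"))
  write_domain_tsv(bundle$domain_hits, p("domain_hits.tsv"))
  data.table::fwrite(bundle$peptide_hits, p("peptide_hits.tsv"), sep = "\t")
  data.table::fwrite(bundle$ec_evidence, p("ec_evidence.tsv"), sep = "\t")
  cfg <- bundle$config
  cfg$inventory <- NULL
  yaml::write_yaml(list(sample = bundle$meta,
                        sim = lapply(unclass(cfg), function(v) v)),
                   p("sample_meta.yaml"))
  data.table::fwrite(bundle$truth$gene_annotation, p("truth_genes.tsv"),
                     sep = "\t")
  data.table::fwrite(bundle$contigs[c("contig_id", "true_genus",
                                      "coverage_share")],
                     p("truth_contigs.tsv"), sep = "\t")
  invisible(stats::setNames(
    file.path(dir, c("nodes.dmp", "names.dmp", "contigs.tsv",
                     "gene_hits.tsv", "domain_hits.tsv", "peptide_hits.tsv",
                     "ec_evidence.tsv", "sample_meta.yaml",
                     "truth_genes.tsv", "truth_contigs.tsv")),
    c("nodes", "names", "contigs", "gene_hits", "domain_hits",
      "peptide_hits", "ec_evidence", "meta", "truth_genes",
      "truth_contigs")))
}

#' Train peptide models on synthetic family proteins
#'
#' For each family in the inventory, generates random training proteins with
#' a planted set of family-specific peptides (each peptide inserted into
#' several training sequences) and trains a [train_peptide_model()] on them.
#' Draws from the session RNG; seed beforehand for reproducibility.
#'
#' @param config a [sim_config()].
#' @param n_train training sequences per family.
#' @param n_peptides planted peptides per family.
#' @param k peptide length.
#' @return List with `models` (named list of `peptide_model`) and
#'   `planted` (named list of planted peptide sets).
#' @export
make_family_models <- function(config, n_train = 6L, n_peptides = 10L,
                               k = 6L) {
  random_protein <- function(len) {
    paste0(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }
  fams <- config$inventory$family
  planted <- list()
  models <- list()
  for (fam in fams) {
    peps <- unique(vapply(seq_len(n_peptides), function(i) {
      paste0(sample(AA_ALPHABET, k, replace = TRUE), collapse = "")
    }, ""))
    seqs <- vapply(seq_len(n_train), function(i) random_protein(300L), "")
    for (pep in peps) {
      into <- sample(n_train, 3L)
      for (j in into) {
        pos <- sample(300L - k, 1L)
        substr(seqs[j], pos, pos + k - 1L) <- pep
      }
    }
    planted[[fam]] <- peps
    models[[fam]] <- train_peptide_model(seqs, family = fam, k = k)
  }
  list(models = models, planted = planted)
}

#' Synthesize proteins carrying planted family peptides
#'
#' Genes with a planted family get a random protein sequence with several of
#' that family's model peptides inserted; unannotated genes get plain random
#' sequences. Used to exercise [classify_peptides()] end to end.
#'
#' @param truth gene annotation truth (gene_id, family).
#' @param models named list of `peptide_model` objects.
#' @param len protein length.
#' @param n_insert peptides inserted per annotated gene.
#' @return Named character vector `gene_id -> protein sequence`.
#' @export
make_proteins <- function(truth, models, len = 400L, n_insert = 3L) {
  out <- vapply(seq_len(nrow(truth)), function(i) {
    s <- paste0(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    m <- models[[truth$family[i]]]
    peps <- sample(names(m$peptides), min(n_insert, length(m$peptides)))
    for (pep in peps) {
      pos <- sample(len - m$k, 1L)
      substr(s, pos, pos + m$k - 1L) <- pep
    }
    s
  }, "")
  stats::setNames(out, truth$gene_id)
}
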