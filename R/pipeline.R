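# Stage orchestration: run the taxonomy, abundance, annotation and profiling
# stages over a configured set of samples, with stable on-disk outputs.

default_thresholds <- function() {
  list(max_evalue_tax = 1e-5, min_identity = 30, min_support = 0.10,
       max_evalue_dom = 1e-5, min_channels = 2L, target_bases = 1e10,
       display_scale = 1e6, peptide_min_hits = 2L)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration carries the sample table (ids and input paths), the
#' taxonomy dump paths, thresholds (every filter cutoff is a named default:
#' E value 1e-5 and identity 30% for taxonomic hits, 10% gene support,
#' domain E value 1e-5, 2 evidence channels, 10 Gb scaling, 10^6 display
#' scale), rank choices and a seed.
#'
#' @param path YAML file path.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param config named list: `taxonomy` (nodes/names paths), `samples`
#'   (list of id, contig_table, gene_hits, domain_hits, peptide_hits,
#'   ec_evidence, total_clean_bases, read_length_bp), optional `thresholds`,
#'   `ranks`, `seed`.
#' @return The config with defaults filled, class `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$samples) || !length(config$samples)) {
    stop("run config needs at least one sample")
  }
  thr <- utils::modifyList(default_thresholds(),
                           config$thresholds %||% list())
  if (thr$min_support < 0 || thr$min_support > 1) {
    stop("min_support must be in [0, 1]")
  }
  if (thr$min_identity < 0 || thr$min_identity > 100) {
    stop("min_identity must be in [0, 100]")
  }
  config$thresholds <- thr
  config$ranks <- utils::modifyList(
    list(taxon_profile = c("phylum", "order", "genus"),
         taxon_enzyme = "order"),
    config$ranks %||% list())
  config$seed <- config$seed %||% 1L
  for (s in config$samples) {
    if (is.null(s$id)) stop("every sample needs an id")
    for (key in c("contig_table", "gene_hits", "domain_hits",
                  "peptide_hits", "ec_evidence")) {
      if (!is.null(s[[key]]) && !file.exists(s[[key]])) {
        stop("sample ", s$id, ": file not found: ", s[[key]])
      }
    }
    if (is.null(s$total_clean_bases) || s$total_clean_bases <= 0) {
      stop("sample ", s$id, ": total_clean_bases must be positive")
    }
  }
  if (!is.null(config$taxonomy)) {
    for (f in unlist(config$taxonomy)) {
      if (!file.exists(f)) stop("taxonomy file not found: ", f)
    }
  }
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

prov_line <- function(config) {
  paste0("# cazprof ",
         as.character(utils::packageVersion("cazprof")),
         " | config=", config_hash(config),
         " | seed=", config$seed)
}

write_tsv_prov <- function(x, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output TSV (skipping the provenance comment line)
#' @param path output file written by [run_pipeline()].
#' @return data.frame.
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

stage_deps <- c(taxonomy = "", abundance = "", annotate = "",
                profile = "abundance,annotate,taxonomy")

#' Run the profiling pipeline over configured samples
#'
#' Executes the requested stages in dependency order and writes every output
#' as a headered TSV whose first line is a provenance comment (package
#' version, configuration hash, seed). Re-running with the same
#' configuration overwrites deterministically.
#'
#' Stages: `taxonomy` (filter hits, top-hit gene taxa, gene-vote LCA contig
#' consensus), `abundance` (10 Gb scaling, coverage, relative abundance,
#' rank roll-ups), `annotate` (domain-hit filtering and overlap resolution,
#' dual-evidence family consensus, multi-channel EC assignment), `profile`
#' (sample-by-enzyme matrix, fold changes, CLR, PCA, clustering,
#' taxon-by-enzyme matrices).
#'
#' @param config a validated run config ([read_run_config()] /
#'   [validate_run_config()]) or a path to one.
#' @param stages subset of `c("taxonomy", "abundance", "annotate",
#'   "profile")`.
#' @param outdir output directory (created if needed); defaults to
#'   `config$outdir`.
#' @return Invisibly, a character vector of written paths.
#' @export
run_pipeline <- function(config,
                         stages = c("taxonomy", "abundance", "annotate",
                                    "profile"),
                         outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  stages <- match.arg(stages, c("taxonomy", "abundance", "annotate",
                                "profile"), several.ok = TRUE)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- prov_line(config)
  thr <- config$thresholds
  out <- function(f) file.path(outdir, f)
  written <- character()
  have <- function(f) file.exists(out(f))
  need <- function(f, stage, produced_by) {
    if (!have(f)) {
      stop("dependency error: stage '", stage, "' needs ", f,
           " from stage '", produced_by, "'; run it first")
    }
  }
  tree <- NULL
  if (!is.null(config$taxonomy)) {
    tree <- load_taxonomy(config$taxonomy$nodes, config$taxonomy$names)
  }

  if ("taxonomy" %in% stages) {
    if (is.null(tree)) stop("stage 'taxonomy' needs taxonomy dump paths")
    for (s in config$samples) {
      hits <- read_gene_hits(s$gene_hits)
      hits <- filter_hits(hits, thr$max_evalue_tax, thr$min_identity)
      gt <- assign_gene_taxon(hits)
      ct <- contig_taxa(tree, gt, stats::setNames(hits$contig_id,
                                                  hits$gene_id)[names(gt)],
                        min_support = thr$min_support)
      f <- paste0(s$id, "_contig_taxa.tsv")
      write_tsv_prov(data.frame(contig_id = names(ct), taxon_id = unname(ct),
                                stringsAsFactors = FALSE), out(f), prov)
      written <- c(written, out(f))
    }
  }

  if ("abundance" %in% stages) {
    for (s in config$samples) {
      contigs <- read_contig_table(s$contig_table)
      ab <- abundance_profile(
        contigs,
        list(total_clean_bases = s$total_clean_bases,
             read_length_bp = s$read_length_bp %||% 150),
        target_bases = thr$target_bases)
      f <- paste0(s$id, "_abundance.tsv")
      write_tsv_prov(data.frame(contig_id = names(ab), abundance = unname(ab),
                                stringsAsFactors = FALSE), out(f), prov)
      written <- c(written, out(f))
      tf <- paste0(s$id, "_contig_taxa.tsv")
      if (have(tf) && !is.null(tree)) {
        ctd <- read_pipeline_tsv(out(tf))
        ct <- stats::setNames(ctd$taxon_id, ctd$contig_id)
        rows <- list()
        for (rank in config$ranks$taxon_profile) {
          tp <- taxon_abundance(ab, ct, tree, rank)
          rows[[rank]] <- data.frame(rank = rank, taxon_id = names(tp),
                                     abundance = unname(tp),
                                     stringsAsFactors = FALSE)
        }
        f2 <- paste0(s$id, "_taxon_profile.tsv")
        write_tsv_prov(do.call(rbind, rows), out(f2), prov)
        written <- c(written, out(f2))
      }
    }
  }

  if ("annotate" %in% stages) {
    for (s in config$samples) {
      dom <- read_domain_tsv(s$domain_hits)
      dom <- filter_domain_hits(dom, thr$max_evalue_dom)
      dom <- resolve_domains_by_gene(dom)
      pep <- data.table::fread(s$peptide_hits, sep = "\t", header = TRUE,
                               data.table = FALSE)
      calls <- consensus_families(dom, pep)
      f <- paste0(s$id, "_consensus_families.tsv")
      write_tsv_prov(calls, out(f), prov)
      ev <- read_ec_evidence(s$ec_evidence)
      ecs <- assign_ec(ev, thr$min_channels)
      f2 <- paste0(s$id, "_ec_assignments.tsv")
      write_tsv_prov(ecs, out(f2), prov)
      written <- c(written, out(f), out(f2))
    }
  }

  if ("profile" %in% stages) {
    profiles <- list()
    for (s in config$samples) {
      need(paste0(s$id, "_abundance.tsv"), "profile", "abundance")
      need(paste0(s$id, "_ec_assignments.tsv"), "profile", "annotate")
      abd <- read_pipeline_tsv(out(paste0(s$id, "_abundance.tsv")))
      ab <- stats::setNames(abd$abundance, abd$contig_id)
      ecs <- read_pipeline_tsv(out(paste0(s$id, "_ec_assignments.tsv")))
      gc <- stats::setNames(gene_to_contig(ecs$gene_id), ecs$gene_id)
      profiles[[s$id]] <- enzyme_profile(ecs, gc, ab,
                                         display_scale = thr$display_scale)
      tf <- paste0(s$id, "_contig_taxa.tsv")
      if (have(tf) && !is.null(tree)) {
        ctd <- read_pipeline_tsv(out(tf))
        ct <- stats::setNames(ctd$taxon_id, ctd$contig_id)
        tep <- taxon_enzyme_profile(ecs, gc, ct, tree, ab,
                                    rank = config$ranks$taxon_enzyme,
                                    display_scale = thr$display_scale)
        f <- paste0(s$id, "_taxon_enzyme_matrix.tsv")
        write_tsv_prov(tep, out(f), prov)
        written <- c(written, out(f))
      }
    }
    mat <- profile_matrix(profiles)
    write_tsv_prov(mat, out("enzyme_matrix.tsv"), prov)
    written <- c(written, out("enzyme_matrix.tsv"))
    if (nrow(mat) >= 2L) {
      fc <- suppressWarnings(fold_change(mat))
      write_tsv_prov(fc$log2, out("fold_change_log2.tsv"), prov)
      tr <- clr(mat[rowSums(mat) > 0, , drop = FALSE])
      write_tsv_prov(tr, out("clr_matrix.tsv"), prov)
      if (nrow(tr) >= 2L) {
        pc <- pca_profiles(tr, n_components = min(2L, min(dim(tr)) - 1L))
        write_tsv_prov(pc$scores, out("pca_scores.tsv"), prov)
        hc <- hclust_profiles(tr)
        merges <- data.frame(step = seq_len(nrow(hc$merge)),
                             a = hc$merge[, 1], b = hc$merge[, 2],
                             height = hc$height)
        write_tsv_prov(merges, out("hclust_merges.tsv"), prov)
        written <- c(written, out("fold_change_log2.tsv"),
                     out("clr_matrix.tsv"), out("pca_scores.tsv"),
                     out("hclust_merges.tsv"))
      }
    }
  }
  invisible(written)
}
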