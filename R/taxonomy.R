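# Contig taxonomy: ranked taxonomy trees, homology-hit filtering, gene top-hit
# assignment, and gene-vote-filtered LCA consensus per contig.

#' Rank vocabulary used throughout the package, from coarsest to finest.
#'
#' @format Character vector of rank labels.
#' @export
TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
               "family", "genus", "species")

#' Sentinel label for contigs that could not be classified.
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

#' Build a validated taxonomy tree
#'
#' A taxonomy tree is a rooted, ranked tree of taxa. The root is the unique
#' node that is its own parent. Ranks follow [TAX_RANKS]; a node's rank is
#' never finer than any of its descendants' ranks is violated nowhere.
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name` (all character).
#' @return An object of class `taxonomy_tree`: the node table plus fast
#'   parent/rank/depth lookups.
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes <- data.frame(lapply(nodes[req], as.character), stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicated taxon_id: ", nodes$taxon_id[duplicated(nodes$taxon_id)][1])
  }
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  missing_parent <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(missing_parent)) {
    stop("parent taxon absent from node table: ", missing_parent[1])
  }
  roots <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(roots) != 1L) {
    stop("tree must have exactly one root (parent == self); found ",
         length(roots))
  }
  # depth by breadth-first relaxation; non-converging nodes sit on a cycle
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon_id)
  depth[roots] <- 0L
  repeat {
    todo <- names(depth)[is.na(depth)]
    if (!length(todo)) break
    reachable <- todo[!is.na(depth[parent[todo]])]
    if (!length(reachable)) {
      stop("cycle in parent links involving taxon: ", todo[1])
    }
    depth[reachable] <- depth[parent[reachable]] + 1L
  }
  rank <- stats::setNames(nodes$rank, nodes$taxon_id)
  unknown <- setdiff(unique(nodes$rank), TAX_RANKS)
  if (length(unknown)) {
    warning("unknown rank labels (", paste(unknown, collapse = ", "),
            ") mapped to the nearest coarser known rank")
    ord <- names(sort(depth))          # parents before children
    for (id in ord) {
      if (!(rank[id] %in% TAX_RANKS)) {
        rank[id] <- if (id == roots) "root" else rank[parent[id]]
      }
    }
    nodes$rank <- unname(rank[nodes$taxon_id])
  }
  pos <- stats::setNames(match(rank, TAX_RANKS), names(rank))
  bad <- names(rank)[pos < pos[parent[names(rank)]] & names(rank) != roots]
  if (length(bad)) {
    stop("rank of taxon ", bad[1], " is coarser than its parent's rank")
  }
  structure(
    list(nodes = nodes, parent = parent, rank = rank, depth = depth,
         root = roots),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "taxa, root =", x$root, "\n")
  cat("ranks:", paste(names(table(x$rank)), table(x$rank),
                      sep = ":", collapse = " "), "\n")
  invisible(x)
}

trim_field <- function(x) gsub("^[ \t]+|[ \t]+$", "", x)

parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trim_field(lines))]
  lapply(strsplit(sub("\\|[ \t]*$", "", lines), "|", fixed = TRUE), trim_field)
}

#' Load a taxonomy from pipe-delimited nodes/names dump files
#'
#' Reads the classical pipe-delimited taxonomy dump dialect: the nodes file
#' carries `id | parent id | rank | ...` and the names file
#' `id | name | unique name | name class`. When a name-class column is
#' present, rows labelled `scientific name` are preferred; otherwise the
#' first name per taxon is used. Rank labels outside [TAX_RANKS] are mapped
#' to the nearest coarser known rank with a warning.
#'
#' @param nodes_path,names_path paths to the dump files.
#' @return A [taxonomy_tree].
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  nf <- parse_dmp(nodes_path)
  nodes <- data.frame(
    taxon_id  = vapply(nf, `[`, "", 1L),
    parent_id = vapply(nf, `[`, "", 2L),
    rank      = vapply(nf, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  mf <- parse_dmp(names_path)
  nm <- data.frame(
    taxon_id = vapply(mf, `[`, "", 1L),
    name     = vapply(mf, `[`, "", 2L),
    class    = vapply(mf, function(f) if (length(f) >= 4L) f[4L] else "", ""),
    stringsAsFactors = FALSE
  )
  sci <- nm[nm$class == "scientific name", ]
  rest <- nm[!nm$taxon_id %in% sci$taxon_id, ]
  nm <- rbind(sci, rest[!duplicated(rest$taxon_id), ])
  nodes$name <- nm$name[match(nodes$taxon_id, nm$taxon_id)]
  nodes$name[is.na(nodes$name)] <- nodes$taxon_id[is.na(nodes$name)]
  taxonomy_tree(nodes)
}

#' Write a taxonomy tree as pipe-delimited dump files
#'
#' Inverse of [load_taxonomy()]; `load_taxonomy(write_taxonomy(tree))`
#' round-trips the node table.
#'
#' @param tree a [taxonomy_tree].
#' @param nodes_path,names_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_taxonomy <- function(tree, nodes_path, names_path) {
  n <- tree$nodes
  writeLines(paste(n$taxon_id, n$parent_id, n$rank, "", sep = "\t|\t"),
             nodes_path)
  writeLines(paste(n$taxon_id, n$name, "", "scientific name\t|", sep = "\t|\t"),
             names_path)
  invisible(c(nodes_path, names_path))
}

#' Filter homology-search hits on E-value and percent identity
#'
#' Hits with E value above `max_evalue` or identity below `min_identity` are
#' removed. Both removal rules are strict, so hits sitting exactly on a
#' boundary survive.
#'
#' @param hits data.frame of gene hits (see [read_gene_hits()]).
#' @param max_evalue maximum E value retained (default `1e-5`).
#' @param min_identity minimum percent identity retained (default 30).
#' @return The surviving subset, same columns.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_identity = 30) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) return(hits)
  hits[hits$evalue <= max_evalue & hits$percent_identity >= min_identity, ,
       drop = FALSE]
}

#' Assign each gene the taxon of its top hit
#'
#' The top hit per gene is the one with maximal bit score; ties are broken by
#' smaller E value, then lexicographically by subject taxon, so the result is
#' deterministic regardless of input order.
#'
#' @param hits data.frame of (already filtered) gene hits.
#' @return Named character vector: `gene_id -> taxon_id`. Genes with no hit
#'   are absent.
#' @export
assign_gene_taxon <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(character(), character()))
  o <- order(hits$gene_id, -hits$bit_score, hits$evalue, hits$subject_taxon,
             method = "radix")
  top <- hits[o, ][!duplicated(hits$gene_id[o]), ]
  stats::setNames(top$subject_taxon, top$gene_id)
}

#' Path from a taxon up to the root (self first)
#' @keywords internal
root_path <- function(tree, taxon) {
  path <- character(tree$depth[[taxon]] + 1L)
  i <- 1L
  while (TRUE) {
    path[i] <- taxon
    if (taxon == tree$root) break
    taxon <- tree$parent[[taxon]]
    i <- i + 1L
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [taxonomy_tree].
#' @param taxa nonempty character vector of taxon ids present in the tree.
#' @return The deepest taxon ancestral to (or equal to) every input taxon.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("lca() needs at least one taxon")
  miss <- setdiff(taxa, names(tree$parent))
  if (length(miss)) stop("taxon not in tree: ", miss[1])
  if (length(taxa) == 1L) return(taxa)
  common <- Reduce(intersect, lapply(taxa, root_path, tree = tree))
  common[which.max(tree$depth[common])]
}

#' Gene-vote-filtered LCA consensus taxon for one contig
#'
#' Each classified gene on a contig votes for its assigned taxon. The support
#' of a distinct taxon is the fraction of classified genes assigned exactly
#' that taxon; taxa with support strictly below `min_support` are discarded,
#' and the contig receives the LCA of the genes that remain. A contig with no
#' classified genes (or whose votes are all discarded) is [UNCLASSIFIED].
#'
#' @param tree a [taxonomy_tree].
#' @param gene_taxa character vector of the contig's classified genes' taxa
#'   (one entry per gene, repeats allowed).
#' @param min_support minimum vote fraction a taxon needs to survive
#'   (default 0.10; the comparison is strict, equality survives).
#' @return A taxon id, or [UNCLASSIFIED].
#' @export
contig_consensus_taxon <- function(tree, gene_taxa, min_support = 0.10) {
  gene_taxa <- as.character(gene_taxa)
  n <- length(gene_taxa)
  if (!n) return(UNCLASSIFIED)
  votes <- table(gene_taxa)
  keep <- names(votes)[as.vector(votes) / n >= min_support]
  if (!length(keep)) return(UNCLASSIFIED)
  lca(tree, keep)
}

#' Ancestor of a taxon at a requested rank
#'
#' Walks from the taxon towards the root and returns the first node (self
#' included) carrying the requested rank, or `NA` if the lineage skips it.
#'
#' @param tree a [taxonomy_tree].
#' @param taxon a taxon id present in the tree.
#' @param rank one of [TAX_RANKS].
#' @return A taxon id or `NA_character_`.
#' @export
lineage_at_rank <- function(tree, taxon, rank) {
  if (!rank %in% TAX_RANKS) {
    stop("unknown rank label: ", rank)
  }
  if (!taxon %in% names(tree$parent)) stop("taxon not in tree: ", taxon)
  while (TRUE) {
    if (tree$rank[[taxon]] == rank) return(taxon)
    if (taxon == tree$root) return(NA_character_)
    taxon <- tree$parent[[taxon]]
  }
}

#' Consensus taxa for many contigs at once
#'
#' Applies [contig_consensus_taxon()] to every contig represented in a gene
#' taxon map, grouping genes by contig.
#'
#' @param tree a [taxonomy_tree].
#' @param gene_taxa named character vector from [assign_gene_taxon()].
#' @param gene_contig named character vector `gene_id -> contig_id`.
#' @param min_support see [contig_consensus_taxon()].
#' @return Named character vector `contig_id -> taxon_id or UNCLASSIFIED`.
#' @export
contig_taxa <- function(tree, gene_taxa, gene_contig, min_support = 0.10) {
  contig <- gene_contig[names(gene_taxa)]
  if (anyNA(contig)) {
    stop("gene without contig mapping: ",
         names(gene_taxa)[is.na(contig)][1])
  }
  groups <- split(unname(gene_taxa), unname(contig))
  vapply(groups, contig_consensus_taxon, "", tree = tree,
         min_support = min_support)
}

#' Derive the contig id from a gene id
#'
#' Gene ids follow the `<contig>_<n>` convention of prodigal-style gene
#' callers; the contig id is everything before the final underscore-number.
#'
#' @param gene_id character vector of gene ids.
#' @return Character vector of contig ids.
#' @export
gene_to_contig <- function(gene_id) sub("_[0-9]+$", "", gene_id)

#' Read a tabular homology hit file
#'
#' Parses the 12-column tab-separated alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore). The subject-to-taxon mapping comes either
#' from a 13th column holding the taxon id, or from a two-column sidecar file
#' (`subject <tab> taxon_id`).
#'
#' @param path path to the hit table.
#' @param taxon_map optional path to the sidecar subject-to-taxon TSV, or a
#'   named character vector `subject -> taxon_id`.
#' @return data.frame with columns `gene_id`, `contig_id`, `subject_taxon`,
#'   `evalue`, `percent_identity`, `bit_score`.
#' @export
read_gene_hits <- function(path, taxon_map = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 12L) {
    stop("hit table ", path, " has ", ncol(dt), " columns; expected >= 12")
  }
  if (ncol(dt) >= 13L) {
    taxon <- as.character(dt[[13L]])
  } else if (is.null(taxon_map)) {
    stop("hit table has 12 columns and no taxon_map was given")
  } else {
    if (is.character(taxon_map) && length(taxon_map) == 1L &&
        file.exists(taxon_map)) {
      side <- data.table::fread(taxon_map, header = FALSE, sep = "\t",
                                data.table = FALSE)
      taxon_map <- stats::setNames(as.character(side[[2L]]),
                                   as.character(side[[1L]]))
    }
    taxon <- unname(taxon_map[as.character(dt[[2L]])])
    if (anyNA(taxon)) {
      stop("subject without taxon mapping: ",
           as.character(dt[[2L]])[is.na(taxon)][1])
    }
  }
  gene <- as.character(dt[[1L]])
  data.frame(
    gene_id = gene,
    contig_id = gene_to_contig(gene),
    subject_taxon = taxon,
    evalue = as.numeric(dt[[11L]]),
    percent_identity = as.numeric(dt[[3L]]),
    bit_score = as.numeric(dt[[12L]]),
    stringsAsFactors = FALSE
  )
}

#' Write gene hits in the 13-column tabular dialect
#'
#' Companion writer to [read_gene_hits()]; alignment coordinate columns that
#' the pipeline does not consume are written as placeholder values.
#'
#' @param hits data.frame as returned by [read_gene_hits()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_hits <- function(hits, path) {
  out <- data.frame(
    hits$gene_id, paste0("subj_", hits$subject_taxon), hits$percent_identity,
    100L, 0L, 0L, 1L, 100L, 1L, 100L, hits$evalue, hits$bit_score,
    hits$subject_taxon
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
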