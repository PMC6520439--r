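# Fixture builders and independent brute-force oracles. The oracles
# re-implement each rule in the most literal way possible (explicit loops
# over the node table / hit list) so they share no code with the package
# internals they check.

# small fixed tree: root -> 2 phyla -> classes -> orders -> families ->
# genera; handy for hand-checkable cases
toy_tree <- function() {
  nodes <- data.frame(
    taxon_id  = c("1", "p1", "p2", "c1", "c2", "o1", "o2", "f1", "f2",
                  "g1", "g2", "g3", "g4"),
    parent_id = c("1", "1", "1", "p1", "p2", "c1", "c2", "o1", "o2",
                  "f1", "f1", "f2", "f2"),
    rank = c("root", "phylum", "phylum", "class", "class", "order", "order",
             "family", "family", "genus", "genus", "genus", "genus"),
    name = c("root", "P1", "P2", "C1", "C2", "O1", "O2", "F1", "F2",
             "G1", "G2", "G3", "G4"),
    stringsAsFactors = FALSE
  )
  taxonomy_tree(nodes)
}

# random ranked tree with n nodes; every child's rank is strictly finer
# than its parent's
random_tree_nodes <- function(n = 50) {
  taxon_id <- paste0("t", seq_len(n))
  parent_id <- character(n)
  rank <- character(n)
  parent_id[1] <- taxon_id[1]
  rank[1] <- "root"
  pos <- integer(n)
  pos[1] <- 1L
  for (i in 2:n) {
    repeat {
      p <- sample(i - 1L, 1L)
      if (pos[p] < length(TAX_RANKS)) break
    }
    parent_id[i] <- taxon_id[p]
    pos[i] <- min(length(TAX_RANKS), pos[p] + sample(1:2, 1L))
    rank[i] <- TAX_RANKS[pos[i]]
  }
  data.frame(taxon_id = taxon_id, parent_id = parent_id, rank = rank,
             name = toupper(taxon_id), stringsAsFactors = FALSE)
}

# oracle: path from taxon to root using only the node data.frame
oracle_path <- function(nodes, taxon) {
  path <- character()
  while (TRUE) {
    path <- c(path, taxon)
    parent <- nodes$parent_id[nodes$taxon_id == taxon]
    if (parent == taxon) break
    taxon <- parent
  }
  path
}

# oracle LCA: intersect root paths, keep the common node furthest from root
oracle_lca <- function(nodes, taxa) {
  paths <- lapply(taxa, oracle_path, nodes = nodes)
  common <- paths[[1]]
  for (p in paths[-1]) common <- common[common %in% p]
  depths <- vapply(common, function(t) length(oracle_path(nodes, t)), 0L)
  common[which.max(depths)]
}

# oracle consensus: enumerate distinct taxa, count votes, apply the strict
# support filter, LCA of the survivors
oracle_consensus <- function(nodes, gene_taxa, min_support = 0.10) {
  if (!length(gene_taxa)) return(UNCLASSIFIED)
  distinct <- unique(gene_taxa)
  surv <- character()
  for (t in distinct) {
    if (sum(gene_taxa == t) / length(gene_taxa) >= min_support) {
      surv <- c(surv, t)
    }
  }
  if (!length(surv)) return(UNCLASSIFIED)
  oracle_lca(nodes, surv)
}

# oracle domain resolution: literal reading of the rule. Rank hits by
# (longer matched interval, smaller evalue, family); repeatedly keep the
# best-ranked remaining hit and discard everything overlapping it.
oracle_resolve <- function(hits) {
  better <- function(i, j) {
    li <- hits$align_end[i] - hits$align_start[i]
    lj <- hits$align_end[j] - hits$align_start[j]
    if (li != lj) return(li > lj)
    if (hits$evalue[i] != hits$evalue[j]) {
      return(hits$evalue[i] < hits$evalue[j])
    }
    hits$family[i] < hits$family[j]
  }
  overlaps <- function(i, j) {
    hits$align_start[i] <= hits$align_end[j] &&
      hits$align_end[i] >= hits$align_start[j]
  }
  remaining <- seq_len(nrow(hits))
  kept <- integer()
  while (length(remaining)) {
    best <- remaining[1]
    for (i in remaining[-1]) if (better(i, best)) best <- i
    kept <- c(kept, best)
    remaining <- remaining[!vapply(remaining, overlaps, NA, j = best)]
  }
  hits[sort(kept), , drop = FALSE]
}

# oracle k-mer counter: count, for each k-mer, the number of distinct
# sequences containing it, via nested loops
oracle_kmer_counts <- function(seqs, k) {
  env <- new.env()
  for (s in seqs) {
    seen <- character()
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (!(km %in% seen)) {
        seen <- c(seen, km)
        env[[km]] <- (if (is.null(env[[km]])) 0L else env[[km]]) + 1L
      }
    }
  }
  counts <- vapply(ls(env), function(k) env[[k]], 0L)
  counts
}

# oracle substring scan: which model peptides occur in the protein
oracle_peptide_matches <- function(protein, peptides) {
  found <- character()
  for (p in peptides) {
    hit <- FALSE
    for (i in seq_len(max(0, nchar(protein) - nchar(p) + 1))) {
      if (substr(protein, i, i + nchar(p) - 1) == p) {
        hit <- TRUE
        break
      }
    }
    if (hit) found <- c(found, p)
  }
  found
}

# align two named numeric vectors on the union of their names (absent = 0)
align_named <- function(a, b) {
  nm <- union(names(a), names(b))
  va <- stats::setNames(numeric(length(nm)), nm)
  vb <- va
  va[names(a)] <- a
  vb[names(b)] <- b
  list(a = va, b = vb)
}

l1_dist <- function(a, b) {
  al <- align_named(a, b)
  sum(abs(al$a - al$b))
}
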