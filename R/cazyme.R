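# CAZyme family calling by dual evidence (HMM domains + conserved peptides)
# and EC assignment by multi-channel consensus.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Train a conserved-peptide model for one enzyme family
#'
#' Enumerates all k-mers over the family's training proteins, keeps those
#' occurring in at least `min_count` distinct sequences, and retains the
#' `top_n` most frequent (ties broken lexicographically). The retained
#' peptides with their sequence-occurrence counts form the family model used
#' by [classify_peptides()].
#'
#' @param family_proteins character vector of at least two amino-acid
#'   sequences.
#' @param family family label stored on the model (e.g. `"GH18"`).
#' @param k peptide length (default 6).
#' @param min_count minimum number of distinct training sequences a peptide
#'   must occur in (default 2).
#' @param top_n maximum number of peptides retained (default 200).
#' @return An object of class `peptide_model`: list with `family`, `k`, and
#'   `peptides` (named integer vector, peptide -> count).
#' @export
train_peptide_model <- function(family_proteins, family = "family",
                                k = 6L, min_count = 2L, top_n = 200L) {
  if (length(family_proteins) < 2L) {
    stop("peptide model training needs at least 2 sequences")
  }
  per_seq <- lapply(family_proteins, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  counts <- table(unlist(per_seq))
  counts <- counts[counts >= min_count]
  if (!length(counts)) {
    stop("no peptide occurs in >= ", min_count, " sequences; cannot train")
  }
  o <- order(-as.vector(counts), names(counts), method = "radix")
  counts <- counts[o][seq_len(min(top_n, length(counts)))]
  structure(
    list(family = family, k = as.integer(k),
         peptides = stats::setNames(as.integer(counts), names(counts))),
    class = "peptide_model"
  )
}

#' Classify a protein against a set of peptide models
#'
#' For each family model, counts how many distinct model peptides occur as
#' substrings of the protein. A family hit is emitted when at least
#' `min_hits` peptides match; several families may be emitted for one
#' protein. The hit's score is the sum of the matched peptides' training
#' counts.
#'
#' @param protein one amino-acid sequence.
#' @param models list of `peptide_model` objects.
#' @param min_hits minimum distinct matching peptides per family (default 2).
#' @param gene_id id recorded on emitted hits.
#' @return data.frame with columns `gene_id`, `family`, `n_matched`,
#'   `score` (zero rows if nothing qualifies).
#' @export
classify_peptides <- function(protein, models, min_hits = 2L,
                              gene_id = NA_character_) {
  if (!nzchar(protein)) stop("protein sequence is empty")
  rows <- lapply(models, function(m) {
    found <- vapply(names(m$peptides), grepl, NA, x = protein, fixed = TRUE)
    n <- sum(found)
    if (n >= min_hits) {
      data.frame(gene_id = gene_id, family = m$family, n_matched = n,
                 score = sum(m$peptides[found]), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), family = character(),
                      n_matched = integer(), score = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Classify many proteins against peptide models
#'
#' @param proteins named character vector `gene_id -> sequence`.
#' @inheritParams classify_peptides
#' @return data.frame of peptide hits across all proteins.
#' @export
classify_peptides_all <- function(proteins, models, min_hits = 2L) {
  hits <- Map(classify_peptides, protein = proteins,
              gene_id = names(proteins),
              MoreArgs = list(models = models, min_hits = min_hits))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Filter HMM domain hits on E-value
#'
#' Hits are kept when their E value is at most `max_evalue` (inclusive
#' bound).
#'
#' @param hits data.frame of domain hits (see [read_domain_tsv()]).
#' @param max_evalue inclusive E-value ceiling (default `1e-5`).
#' @return Surviving subset.
#' @export
filter_domain_hits <- function(hits, max_evalue = 1e-5) {
  if (!nrow(hits)) return(hits)
  hits[hits$evalue <= max_evalue, , drop = FALSE]
}

domain_rank_order <- function(hits) {
  len <- hits$align_end - hits$align_start + 1L
  order(-len, hits$evalue, hits$family, method = "radix")
}

#' Resolve overlapping HMM domain hits on one gene
#'
#' Among hits whose aligned intervals on the protein overlap by at least one
#' position, the hit with the longest matched interval is kept (ties broken
#' by smaller E value, then family label), the overlapping losers are
#' discarded, and the rule is reapplied until the retained intervals are
#' pairwise disjoint. Non-overlapping hits are all kept.
#'
#' @param hits data.frame of filtered domain hits for a single gene, with
#'   columns `family`, `align_start`, `align_end`, `evalue` (plus any
#'   others, carried through).
#' @return Subset of `hits` with pairwise non-overlapping intervals.
#' @export
resolve_overlapping_domains <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  o <- domain_rank_order(hits)
  s <- hits$align_start[o]
  e <- hits$align_end[o]
  keep <- logical(length(o))
  for (i in seq_along(o)) {
    if (!any(keep & s <= e[i] & e >= s[i])) keep[i] <- TRUE
  }
  out <- hits[sort(o[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlaps gene by gene
#'
#' @param hits data.frame of filtered domain hits with a `gene_id` column.
#' @return data.frame with overlaps resolved within each gene.
#' @export
resolve_domains_by_gene <- function(hits) {
  if (!nrow(hits)) return(hits)
  parts <- split(hits, hits$gene_id)
  out <- do.call(rbind, lapply(parts, resolve_overlapping_domains))
  rownames(out) <- NULL
  out
}

#' Dual-evidence consensus CAZyme family calls
#'
#' A family is called for a gene only when it is supported by both evidence
#' channels: the retained (filtered, overlap-resolved) HMM domain hits and
#' the peptide classifier hits. The output is therefore a per-gene
#' intersection of the two channels' family sets.
#'
#' @param domain_hits data.frame with `gene_id`, `family` (post
#'   [filter_domain_hits()] and [resolve_domains_by_gene()]).
#' @param peptide_hits data.frame with `gene_id`, `family`.
#' @return data.frame `gene_id`, `family`, one row per consensus call,
#'   sorted for determinism.
#' @export
consensus_families <- function(domain_hits, peptide_hits) {
  a <- unique(data.frame(gene_id = domain_hits$gene_id,
                         family = domain_hits$family,
                         stringsAsFactors = FALSE))
  b <- unique(data.frame(gene_id = peptide_hits$gene_id,
                         family = peptide_hits$family,
                         stringsAsFactors = FALSE))
  out <- merge(a, b, by = c("gene_id", "family"))
  out <- out[order(out$gene_id, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

EC_REGEX <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

ec_prefix3 <- function(ec) sub("\\.[^.]+$", "", ec)

#' Assign EC numbers by multi-channel consensus
#'
#' Each annotation channel (enzyme homology search, orthology-group search,
#' KEGG mapping) proposes EC numbers per gene. An EC is assigned when it is
#' supported by at least `min_channels` distinct channels. A partial EC such
#' as `3.1.1.-` counts as support for any full EC sharing its first three
#' fields, and the most specific agreed form is reported; a partial EC is
#' itself reported only when no matching full EC qualifies.
#'
#' @param evidence data.frame with columns `gene_id`, `channel`, `ec`.
#' @param min_channels minimum distinct supporting channels (default 2).
#' @return data.frame `gene_id`, `ec`, `n_channels`, sorted; genes with no
#'   qualifying EC are absent.
#' @export
assign_ec <- function(evidence, min_channels = 2L) {
  if (!nrow(evidence)) {
    return(data.frame(gene_id = character(), ec = character(),
                      n_channels = integer(), stringsAsFactors = FALSE))
  }
  bad <- !grepl(EC_REGEX, evidence$ec)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("malformed EC string '", evidence$ec[i], "' for gene ",
         evidence$gene_id[i], " (channel ", evidence$channel[i], ")")
  }
  evidence <- unique(evidence[c("gene_id", "channel", "ec")])
  parts <- split(evidence, evidence$gene_id)
  rows <- lapply(parts, function(ev) {
    full <- ev[!endsWith(ev$ec, "-"), , drop = FALSE]
    part <- ev[endsWith(ev$ec, "-"), , drop = FALSE]
    res <- list()
    for (ec in unique(full$ec)) {
      chan <- union(full$channel[full$ec == ec],
                    part$channel[ec_prefix3(part$ec) == ec_prefix3(ec)])
      if (length(chan) >= min_channels) {
        res[[length(res) + 1L]] <- data.frame(
          gene_id = ev$gene_id[1], ec = ec, n_channels = length(chan),
          stringsAsFactors = FALSE)
      }
    }
    qualified_prefix <- vapply(res, function(r) ec_prefix3(r$ec), "")
    for (ec in unique(part$ec)) {
      if (ec_prefix3(ec) %in% qualified_prefix) next
      chan <- unique(part$channel[part$ec == ec])
      if (length(chan) >= min_channels) {
        res[[length(res) + 1L]] <- data.frame(
          gene_id = ev$gene_id[1], ec = ec, n_channels = length(chan),
          stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), ec = character(),
                      n_channels = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$ec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- readers / writers -----------------------------------------------------

#' Read HMM domain hits from a domtblout-dialect file
#'
#' Parses the per-domain tabular output of profile HMM searches (whitespace
#' separated, `#` comment lines). Column mapping follows the hmmscan
#' convention of CAZyme annotation: target name = HMM profile (family label,
#' any `.hmm` suffix stripped), query name = gene, `tlen` = profile length,
#' the independent domain E-value, and the alignment coordinates on the
#' protein.
#'
#' @param path path to the domtblout file.
#' @return data.frame with columns `gene_id`, `family`, `align_start`,
#'   `align_end`, `profile_length`, `evalue`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(), family = character(),
                      align_start = integer(), align_end = integer(),
                      profile_length = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "[ \t]+")
  get <- function(i) vapply(f, `[`, "", i)
  data.frame(
    gene_id = get(4L),
    family = sub("\\.hmm$", "", get(1L)),
    align_start = as.integer(get(18L)),
    align_end = as.integer(get(19L)),
    profile_length = as.integer(get(3L)),
    evalue = as.numeric(get(13L)),
    stringsAsFactors = FALSE
  )
}

#' Read domain hits from the simplified 6-column TSV
#'
#' Columns: gene, family, start, end, profile_len, evalue (header optional,
#' detected from the first line).
#'
#' @param path path to the TSV.
#' @return Same shape as [read_domtblout()].
#' @export
read_domain_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          data.table = FALSE)
  data.frame(
    gene_id = as.character(dt[[1L]]),
    family = as.character(dt[[2L]]),
    align_start = as.integer(dt[[3L]]),
    align_end = as.integer(dt[[4L]]),
    profile_length = as.integer(dt[[5L]]),
    evalue = as.numeric(dt[[6L]]),
    stringsAsFactors = FALSE
  )
}

#' Write domain hits as the simplified 6-column TSV
#' @param hits data.frame as from [read_domain_tsv()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_domain_tsv <- function(hits, path) {
  out <- hits[c("gene_id", "family", "align_start", "align_end",
                "profile_length", "evalue")]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read EC evidence (gene_id, channel, ec) from TSV
#' @param path tab-separated file with a header.
#' @return data.frame with the three character columns.
#' @export
read_ec_evidence <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  data.frame(gene_id = as.character(dt$gene_id),
             channel = as.character(dt$channel),
             ec = as.character(dt$ec), stringsAsFactors = FALSE)
}

#' Serialize peptide models to TSV (family, peptide, count)
#' @param models list of `peptide_model` objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_peptide_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(family = m$family, peptide = names(m$peptides),
               count = as.integer(m$peptides), stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Load peptide models from TSV (family, peptide, count)
#' @param path path written by [write_peptide_models()].
#' @return Named list of `peptide_model` objects.
#' @export
read_peptide_models <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  parts <- split(dt, dt$family)
  models <- lapply(parts, function(p) {
    structure(list(family = p$family[1], k = nchar(p$peptide[1]),
                   peptides = stats::setNames(as.integer(p$count), p$peptide)),
              class = "peptide_model")
  })
  models
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]; returns a plain named character
#' vector, ids truncated at the first whitespace.
#'
#' @param path FASTA path.
#' @return Named character vector `id -> sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write protein sequences to FASTA
#' @param seqs named character vector `id -> sequence`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
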