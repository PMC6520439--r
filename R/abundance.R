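# Coverage-normalized relative abundance of contigs and taxon roll-ups.

#' Scale mapped-read counts to a common sequencing effort
#'
#' Mapped read counts are rescaled so that every sample corresponds to the
#' same amount of clean sequence (10 Gb by default), making absolute coverage
#' values comparable across samples of different sizes. The factor cancels in
#' relative abundances but matters wherever coverages are exported.
#'
#' @param contigs data.frame with columns `contig_id`, `length_bp`,
#'   `mapped_reads`.
#' @param meta list or data.frame row with `total_clean_bases` (bp) and
#'   `read_length_bp`.
#' @param target_bases sequencing effort to scale to, in bases
#'   (default `1e10`, i.e. 10 Gb).
#' @return Named numeric vector `contig_id -> scaled read count`.
#' @export
scale_read_counts <- function(contigs, meta, target_bases = 1e10) {
  tcb <- meta$total_clean_bases
  if (is.null(tcb) || !is.finite(tcb) || tcb <= 0) {
    stop("total_clean_bases must be a positive number")
  }
  stats::setNames(contigs$mapped_reads * target_bases / tcb,
                  contigs$contig_id)
}

#' Per-contig coverage from scaled read counts
#'
#' Coverage is estimated from the contig length and the number of mapped
#' reads: `scaled_reads * read_length / contig_length`.
#'
#' @param length_bp contig length(s), bp (> 0).
#' @param scaled_reads (scaled) mapped read count(s).
#' @param read_length_bp read length, bp (default 150).
#' @return Numeric coverage value(s).
#' @export
contig_coverage <- function(length_bp, scaled_reads, read_length_bp = 150) {
  if (any(length_bp <= 0)) stop("contig length must be positive")
  scaled_reads * read_length_bp / length_bp
}

#' Relative abundance profile from contig coverages
#'
#' Each contig's relative abundance is its coverage divided by the summed
#' coverage of all contigs in the sample; the profile sums to one. Contigs
#' with zero mapped reads are retained with abundance zero.
#'
#' @param coverages named numeric vector `contig_id -> coverage`.
#' @return Named numeric vector `contig_id -> relative abundance` summing
#'   to 1.
#' @export
relative_abundance <- function(coverages) {
  if (!length(coverages) || all(coverages == 0)) {
    stop("all coverages are zero; relative abundance is undefined")
  }
  if (any(coverages < 0)) stop("coverages must be nonnegative")
  coverages / sum(coverages)
}

#' Convenience: abundance profile straight from a contig table
#'
#' Chains [scale_read_counts()], [contig_coverage()] and
#' [relative_abundance()].
#'
#' @inheritParams scale_read_counts
#' @return Named numeric vector of relative abundances.
#' @export
abundance_profile <- function(contigs, meta, target_bases = 1e10) {
  scaled <- scale_read_counts(contigs, meta, target_bases)
  rl <- meta$read_length_bp
  if (is.null(rl)) rl <- 150
  cov <- contig_coverage(contigs$length_bp, scaled, rl)
  relative_abundance(cov)
}

#' Roll contig abundances up to a taxonomic rank
#'
#' Contig abundances are summed per taxon after mapping each contig's
#' assigned taxon to its ancestor at the requested rank. Contigs that are
#' [UNCLASSIFIED], missing from the taxon map, or whose lineage skips the
#' rank pool into the [UNCLASSIFIED] bin, so total abundance is conserved.
#'
#' @param abundance named numeric vector `contig_id -> relative abundance`.
#' @param contig_taxa named character vector `contig_id -> taxon_id` or
#'   [UNCLASSIFIED].
#' @param tree a [taxonomy_tree].
#' @param rank one of [TAX_RANKS].
#' @return Named numeric vector `taxon_id (or UNCLASSIFIED) -> abundance`,
#'   summing to the same total as `abundance`.
#' @export
taxon_abundance <- function(abundance, contig_taxa, tree, rank) {
  if (!rank %in% TAX_RANKS) stop("unknown rank label: ", rank)
  assigned <- contig_taxa[names(abundance)]
  assigned[is.na(assigned)] <- UNCLASSIFIED
  distinct <- setdiff(unique(assigned), UNCLASSIFIED)
  at_rank <- vapply(distinct, lineage_at_rank, "", tree = tree, rank = rank,
                    USE.NAMES = TRUE)
  at_rank[is.na(at_rank)] <- UNCLASSIFIED
  at_rank[UNCLASSIFIED] <- UNCLASSIFIED
  groups <- unname(at_rank[assigned])
  out <- tapply(abundance, groups, sum)
  stats::setNames(as.vector(out), names(out))
}

#' Read a contig table (contig_id, length_bp, mapped_reads)
#'
#' @param path tab-separated file with a header row.
#' @return data.frame with the three columns, types coerced.
#' @export
read_contig_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("contig_id", "length_bp", "mapped_reads")
  if (!all(req %in% names(dt))) {
    stop("contig table ", path, " must have columns: ",
         paste(req, collapse = ", "))
  }
  data.frame(contig_id = as.character(dt$contig_id),
             length_bp = as.integer(dt$length_bp),
             mapped_reads = as.numeric(dt$mapped_reads),
             stringsAsFactors = FALSE)
}
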