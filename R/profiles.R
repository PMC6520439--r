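# Sample-by-enzyme and taxon-by-enzyme profile matrices and their
# comparative statistics: log2 fold change against the cross-sample mean,
# centered log-ratio transform, PCA, hierarchical clustering.

#' Enzyme abundance profile for one sample
#'
#' The relative abundance of an enzyme (EC number) in a sample is the sum,
#' over all genes assigned that EC, of the relative abundance of the gene's
#' contig, multiplied by `display_scale`. A contig carrying several
#' qualifying genes contributes once per gene.
#'
#' @param assignments data.frame with `gene_id`, `ec` (e.g. from
#'   [assign_ec()]).
#' @param gene_contig named character vector `gene_id -> contig_id` (a gene
#'   id vector is accepted and mapped via [gene_to_contig()]).
#' @param abundance named numeric vector `contig_id -> relative abundance`.
#' @param display_scale multiplier applied for readability (default `1e6`).
#' @param enzymes optional character vector fixing the output enzyme set
#'   (absent enzymes get 0).
#' @return Named numeric vector `ec -> scaled abundance`.
#' @export
enzyme_profile <- function(assignments, gene_contig, abundance,
                           display_scale = 1e6, enzymes = NULL) {
  contig <- unname(gene_contig[assignments$gene_id])
  unknown <- is.na(contig) | !(contig %in% names(abundance))
  if (any(unknown)) {
    stop("gene with unknown contig or missing abundance: ",
         assignments$gene_id[unknown][1])
  }
  vals <- abundance[contig] * display_scale
  out <- tapply(vals, assignments$ec, sum)
  out <- stats::setNames(as.vector(out), names(out))
  if (!is.null(enzymes)) {
    full <- stats::setNames(numeric(length(enzymes)), enzymes)
    full[intersect(names(out), enzymes)] <-
      out[intersect(names(out), enzymes)]
    out <- full
  }
  out
}

#' Stack per-sample enzyme profiles into a matrix
#'
#' @param profiles named list of named numeric vectors (one per sample).
#' @return Matrix, samples in rows, union of enzymes in columns (missing
#'   entries 0), both dimensions named.
#' @export
profile_matrix <- function(profiles) {
  cols <- sort(unique(unlist(lapply(profiles, names))))
  out <- matrix(0, nrow = length(profiles), ncol = length(cols),
                dimnames = list(names(profiles), cols))
  for (s in names(profiles)) out[s, names(profiles[[s]])] <- profiles[[s]]
  out
}

#' Taxon-by-enzyme profile for one sample
#'
#' Routes each assigned gene's abundance contribution to its contig's taxon
#' rolled up at `rank`; contributions from unclassified contigs or lineages
#' skipping the rank pool under [UNCLASSIFIED]. Column sums equal the
#' corresponding [enzyme_profile()] values, so mass is conserved.
#'
#' @inheritParams enzyme_profile
#' @param contig_taxa named character vector `contig_id -> taxon_id` or
#'   [UNCLASSIFIED].
#' @param tree a [taxonomy_tree].
#' @param rank roll-up rank (default `"order"`).
#' @return Matrix, taxa (plus [UNCLASSIFIED]) in rows, enzymes in columns.
#' @export
taxon_enzyme_profile <- function(assignments, gene_contig, contig_taxa, tree,
                                 abundance, rank = "order",
                                 display_scale = 1e6) {
  if (!rank %in% TAX_RANKS) stop("unknown rank label: ", rank)
  contig <- unname(gene_contig[assignments$gene_id])
  unknown <- is.na(contig) | !(contig %in% names(abundance))
  if (any(unknown)) {
    stop("gene with unknown contig or missing abundance: ",
         assignments$gene_id[unknown][1])
  }
  assigned <- contig_taxa[contig]
  assigned[is.na(assigned)] <- UNCLASSIFIED
  distinct <- setdiff(unique(assigned), UNCLASSIFIED)
  at_rank <- vapply(distinct, lineage_at_rank, "", tree = tree, rank = rank,
                    USE.NAMES = TRUE)
  at_rank[is.na(at_rank)] <- UNCLASSIFIED
  at_rank[UNCLASSIFIED] <- UNCLASSIFIED
  taxon <- unname(at_rank[assigned])
  vals <- abundance[contig] * display_scale
  taxa <- sort(unique(taxon))
  ecs <- sort(unique(assignments$ec))
  out <- matrix(0, length(taxa), length(ecs), dimnames = list(taxa, ecs))
  agg <- tapply(vals, list(taxon, assignments$ec), sum)
  agg[is.na(agg)] <- 0
  out[rownames(agg), colnames(agg)] <- agg
  out
}

#' Log2 fold change of each sample against the cross-sample mean
#'
#' For every enzyme (column), each sample's value is divided by the mean of
#' that column across all samples; the ratio is log2-transformed. Columns
#' whose mean is zero carry no signal and are dropped with a warning. A zero
#' cell over a positive mean yields ratio 0 and log2 `-Inf`; the sentinel is
#' kept in the numeric result and only floored in heatmap export.
#'
#' @param mat profile matrix, samples in rows (>= 2), enzymes in columns.
#' @return Object of class `fold_change`: list with `ratio` and `log2`
#'   matrices (zero-mean columns removed) and `baseline`, the column means
#'   used.
#' @export
fold_change <- function(mat) {
  if (nrow(mat) < 2L) stop("fold change needs at least 2 rows")
  baseline <- colMeans(mat)
  zero <- baseline == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero column(s): ",
            paste(utils::head(colnames(mat)[zero], 5), collapse = ", "))
    mat <- mat[, !zero, drop = FALSE]
    baseline <- baseline[!zero]
  }
  ratio <- sweep(mat, 2L, baseline, "/")
  structure(list(ratio = ratio, log2 = log2(ratio), baseline = baseline),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("fold_change:", nrow(x$ratio), "samples x", ncol(x$ratio),
      "enzymes (baseline = column mean)\n")
  invisible(x)
}

#' Centered log-ratio transform of a compositional matrix
#'
#' Each row is treated as a composition: zeros are replaced, the row is
#' closed to proportions, logged, and centered by subtracting the row mean of
#' the logs, so every output row sums to zero. The default zero replacement
#' is multiplicative, with delta equal to half the smallest positive value in
#' the matrix.
#'
#' @param mat nonnegative matrix, samples in rows (no all-zero rows).
#' @param zero_replacement `"multiplicative"` (default), `"none"` (error if
#'   zeros present), a positive number used as delta, or a function applied
#'   to the matrix that must return a strictly positive matrix.
#' @return Matrix of the same shape; rows sum to 0.
#' @export
clr <- function(mat, zero_replacement = "multiplicative") {
  if (ncol(mat) < 2L) stop("clr needs at least 2 columns")
  if (any(rowSums(mat) == 0)) {
    stop("all-zero row(s): ",
         paste(utils::head(rownames(mat)[rowSums(mat) == 0], 3),
               collapse = ", "))
  }
  if (any(mat < 0)) stop("clr input must be nonnegative")
  if (is.function(zero_replacement)) {
    mat <- zero_replacement(mat)
    if (any(mat <= 0)) stop("zero replacement left non-positive values")
  } else if (identical(zero_replacement, "none")) {
    if (any(mat == 0)) stop("matrix contains zeros and strategy is 'none'")
  } else {
    delta <- if (is.numeric(zero_replacement)) {
      zero_replacement
    } else if (identical(zero_replacement, "multiplicative")) {
      0.5 * min(mat[mat > 0])
    } else {
      stop("unknown zero replacement strategy: ", zero_replacement)
    }
    mat[mat == 0] <- delta
  }
  prop <- mat / rowSums(mat)
  lg <- log(prop)
  sweep(lg, 1L, rowMeans(lg), "-")
}

#' Principal component analysis of a (transformed) profile matrix
#'
#' Column-centered singular value decomposition. Signs are fixed
#' deterministically: within each component the loading of largest magnitude
#' is made positive. Explained-variance fractions are relative to the total
#' variance of the centered matrix, so they are non-increasing and sum to at
#' most one for a truncated result.
#'
#' @param mat numeric matrix, samples in rows (>= 2).
#' @param n_components number of components to keep (default 2).
#' @return Object of class `profile_pca`: list with `scores`
#'   (samples x components), `loadings` (variables x components) and
#'   `explained_variance`.
#' @export
pca_profiles <- function(mat, n_components = 2L) {
  if (nrow(mat) < 2L) stop("pca needs at least 2 rows")
  maxc <- min(dim(mat))
  if (n_components > maxc) {
    stop("n_components (", n_components, ") exceeds min(rows, cols) = ", maxc)
  }
  centered <- sweep(mat, 2L, colMeans(mat), "-")
  sv <- svd(centered)
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2L, flip, "*")
  v <- sweep(sv$v, 2L, flip, "*")
  idx <- seq_len(n_components)
  scores <- u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components)
  dimnames(scores) <- list(rownames(mat), paste0("PC", idx))
  loadings <- v[, idx, drop = FALSE]
  dimnames(loadings) <- list(colnames(mat), paste0("PC", idx))
  total <- sum(sv$d^2)
  ev <- if (total > 0) sv$d[idx]^2 / total else rep(0, n_components)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  cat("profile_pca:", nrow(x$scores), "samples,",
      ncol(x$scores), "components; explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Hierarchical clustering of profile rows
#'
#' @param mat numeric matrix, samples in rows (>= 2).
#' @param distance distance measure passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An [stats::hclust] object.
#' @export
hclust_profiles <- function(mat, distance = "euclidean",
                            linkage = "average") {
  if (nrow(mat) < 2L) stop("clustering needs at least 2 rows")
  stats::hclust(stats::dist(mat, method = distance), method = linkage)
}

# ---- bundled nine-termite enzyme matrix -------------------------------------

table1_path <- function(file) {
  system.file("extdata", file, package = "cazprof", mustWork = TRUE)
}

#' Bundled nine-termite cell-wall-enzyme abundance matrix
#'
#' Published relative abundances (display units, i.e. multiplied by 10^6) of
#' enzymes putatively targeting fungal and plant cell wall polysaccharides in
#' the gut metagenomes of nine termite species with different diets: two
#' fungus growers (Mn, Od), a soil feeder (Cu), a dung feeder (Aw), two humus
#' feeders (Nt, Th), a litter feeder (Co) and two wood feeders (Mp, Nc).
#'
#' @return Matrix with 9 species rows and one column per enzyme (enzyme names
#'   as column names; EC numbers and substrate classes via
#'   [table1_enzymes()]).
#' @export
table1_profiles <- function() {
  dt <- data.table::fread(table1_path("table1_enzyme_profiles.tsv"),
                          sep = "\t", header = TRUE, data.table = FALSE)
  species <- setdiff(names(dt), c("ec", "enzyme", "substrate"))
  m <- t(as.matrix(dt[species]))
  colnames(m) <- dt$enzyme
  m
}

#' Enzyme annotation of the bundled nine-termite matrix
#'
#' @return data.frame with columns `enzyme`, `ec`, `substrate` in the
#'   bundled matrix's column order. EC numbers are not unique (partial ECs
#'   cover several enzymes), which is why enzyme names key the matrix.
#' @export
table1_enzymes <- function() {
  dt <- data.table::fread(table1_path("table1_enzyme_profiles.tsv"),
                          sep = "\t", header = TRUE, data.table = FALSE)
  data.frame(enzyme = dt$enzyme, ec = dt$ec, substrate = dt$substrate,
             stringsAsFactors = FALSE)
}

#' Species metadata of the bundled nine-termite matrix
#'
#' @return data.frame with columns `code`, `species`, `diet`.
#' @export
table1_species <- function() {
  data.table::fread(table1_path("table1_species.tsv"), sep = "\t",
                    header = TRUE, data.table = FALSE)
}

#' Substrate lookup for enzymes of the bundled matrix
#'
#' @return Named character vector `enzyme -> substrate class`.
#' @export
substrate_map <- function() {
  e <- table1_enzymes()
  stats::setNames(e$substrate, e$enzyme)
}
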