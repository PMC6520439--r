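test_that("enzyme profile sums contig abundances per assigned EC", {
  ab <- c(k1 = 2.1e-4, k2 = 5e-4, k3 = 1 - 2.1e-4 - 5e-4)
  asg <- data.frame(gene_id = c("k1_1"), ec = "3.2.1.14",
                    stringsAsFactors = FALSE)
  gc <- c(k1_1 = "k1")
  p <- enzyme_profile(asg, gc, ab)
  expect_equal(p[["3.2.1.14"]], 210.0)
  # an enzyme with no genes reports exactly zero
  p2 <- enzyme_profile(asg, gc, ab, enzymes = c("3.2.1.14", "3.2.1.4"))
  expect_equal(p2[["3.2.1.4"]], 0)
  # a contig with several qualifying genes contributes once per gene
  asg3 <- data.frame(gene_id = c("k1_1", "k1_2"), ec = "3.2.1.14",
                     stringsAsFactors = FALSE)
  gc3 <- c(k1_1 = "k1", k1_2 = "k1")
  expect_equal(enzyme_profile(asg3, gc3, ab)[["3.2.1.14"]], 420.0)
  expect_error(enzyme_profile(asg, c(k1_1 = "nope"), ab), "unknown contig")

  # synthetic bundle: profile equals a brute-force join of the truth tables
  b <- simulate_bundle(sim_config(seed = 300, n_contigs = 200,
                                  read_depth = 5e4))
  ab <- b$truth$contig_abundance
  tr <- b$truth$gene_annotation
  gc <- setNames(gene_to_contig(tr$gene_id), tr$gene_id)
  got <- enzyme_profile(tr, gc, ab)
  manual <- sapply(sort(unique(tr$ec)), function(e) {
    s <- 0
    for (i in which(tr$ec == e)) s <- s + ab[[gene_to_contig(tr$gene_id[i])]]
    s * 1e6
  })
  expect_equal(got, manual[names(got)])
})

test_that("taxon-by-enzyme profile conserves column mass and routes by order", {
  tree <- toy_tree()
  ab <- c(k1 = 0.3, k2 = 0.3, k3 = 0.4)
  ct <- c(k1 = "g1", k2 = "g2", k3 = "g3")
  asg <- data.frame(gene_id = c("k1_1", "k2_1", "k3_1", "k3_2"),
                    ec = c("3.2.1.14", "3.2.1.14", "3.2.1.4", "3.2.1.14"),
                    stringsAsFactors = FALSE)
  gc <- setNames(gene_to_contig(asg$gene_id), asg$gene_id)
  tep <- taxon_enzyme_profile(asg, gc, ct, tree, ab, rank = "order")
  # all cellulase genes sit on an o2 contig: the whole column is in o2
  expect_equal(tep["o2", "3.2.1.4"], 0.4e6)
  expect_equal(tep["o1", "3.2.1.4"], 0)
  # column sums equal the flat enzyme profile
  ep <- enzyme_profile(asg, gc, ab)
  expect_equal(colSums(tep), ep[colnames(tep)])
  # unclassified contigs pool separately but conserve mass
  ct2 <- c(k1 = "g1", k2 = UNCLASSIFIED, k3 = "g3")
  tep2 <- taxon_enzyme_profile(asg, gc, ct2, tree, ab, rank = "order")
  expect_true(UNCLASSIFIED %in% rownames(tep2))
  expect_equal(colSums(tep2), ep[colnames(tep2)])

  # two orders planted at a 70/30 abundance split are recovered
  ab3 <- c(a = 0.7, b = 0.3)
  ct3 <- c(a = "g1", b = "g3")
  asg3 <- data.frame(gene_id = c("a_1", "b_1"), ec = "3.2.1.14",
                     stringsAsFactors = FALSE)
  gc3 <- c(a_1 = "a", b_1 = "b")
  tep3 <- taxon_enzyme_profile(asg3, gc3, ct3, tree, ab3, rank = "order")
  expect_equal(unname(tep3[, "3.2.1.14"] / sum(tep3[, "3.2.1.14"])),
               c(0.7, 0.3))
})

test_that("fold change compares each sample to the cross-sample mean", {
  m <- table1_profiles()
  fc <- suppressWarnings(fold_change(m))
  # chitinase in the fungus grower Mn sits ~5x above the nine-species mean
  expect_equal(fc$ratio["Mn", "Chitinase"], 209.59 / mean(m[, "Chitinase"]),
               tolerance = 1e-12)
  expect_equal(round(fc$ratio["Mn", "Chitinase"]), 5)
  expect_equal(fc$log2["Mn", "Chitinase"], log2(5.029489),
               tolerance = 1e-4)

  # every retained ratio equals the independent spreadsheet-style loop
  for (j in colnames(fc$ratio)) {
    mu <- sum(m[, j]) / nrow(m)
    for (i in rownames(m)) {
      expect_equal(fc$ratio[i, j], m[i, j] / mu, tolerance = 1e-12)
    }
  }
  # all-equal column gives ratio 1 / log2 0
  m2 <- cbind(a = rep(3, 4), b = c(1, 2, 3, 4))
  rownames(m2) <- paste0("s", 1:4)
  fc2 <- fold_change(m2)
  expect_equal(unname(fc2$ratio[, "a"]), rep(1, 4))
  expect_equal(unname(fc2$log2[, "a"]), rep(0, 4))
  # a row equal to the column means has fold change exactly 1
  m3 <- rbind(m2, s5 = colMeans(m2))
  fc3 <- fold_change(m3)
  expect_equal(unname(fc3$ratio["s5", ]), rep(1, 2), tolerance = 1e-12)

  expect_error(fold_change(m[1, , drop = FALSE]), "2 rows")
  # zero-mean columns dropped with a warning; zero cells over positive
  # means become -Inf sentinels
  expect_warning(fcz <- fold_change(m), "all-zero")
  expect_false("Chitosanase" %in% colnames(fcz$ratio))
  expect_true(is.infinite(fcz$log2["Mn", "Laccase"]) &&
                fcz$log2["Mn", "Laccase"] < 0)
})

test_that("clr rows are centered log ratios summing to zero", {
  # uniform composition maps to all zeros
  u <- matrix(rep(0.25, 8), 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(clr(u)), matrix(0, 2, 4))

  set.seed(40)
  m <- matrix(rgamma(60, 2), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("e", 1:10)))
  tr <- clr(m)
  expect_equal(unname(rowSums(tr)), rep(0, 6), tolerance = 1e-9)
  # brute-force formula oracle
  for (i in 1:6) {
    x <- m[i, ] / sum(m[i, ])
    expect_equal(unname(tr[i, ]), unname(log(x) - mean(log(x))))
  }
  # zero handling: multiplicative replacement with delta = half the
  # smallest positive value
  mz <- m
  mz[1, 1] <- 0
  trz <- clr(mz)
  delta <- 0.5 * min(mz[mz > 0])
  x <- mz[1, ]
  x[1] <- delta
  x <- x / sum(x)
  expect_equal(unname(trz[1, ]), unname(log(x) - mean(log(x))))
  expect_error(clr(mz, zero_replacement = "none"), "zeros")
  expect_error(clr(rbind(mz, s0 = 0)), "all-zero")
})

test_that("pca matches the covariance-eigen oracle with deterministic signs", {
  set.seed(41)
  m <- matrix(rnorm(9 * 20), 9, 20,
              dimnames = list(paste0("s", 1:9), paste0("v", 1:20)))
  p <- pca_profiles(m, n_components = 2)
  ev_oracle <- eigen(cov(m))$values
  expect_equal(p$explained_variance, (ev_oracle / sum(ev_oracle))[1:2],
               tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1)

  # identical rows get identical scores
  m2 <- rbind(m, s10 = m[1, ])
  p2 <- pca_profiles(m2)
  expect_equal(p2$scores["s10", ], p2$scores["s1", ])

  # full-rank reconstruction: scores %*% t(loadings) gives centered data
  k <- min(dim(m))
  pf <- pca_profiles(m, n_components = k)
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(pf$scores %*% t(pf$loadings), centered,
               ignore_attr = TRUE, tolerance = 1e-8)

  # sign convention: largest-magnitude loading per component is positive
  for (j in 1:2) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_profiles(m, n_components = 10), "exceeds")
})

test_that("hierarchical clustering agrees with a naive average-linkage oracle", {
  m2 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  hc <- hclust_profiles(m2)
  expect_equal(hc$height, 5)

  # coincident rows merge first at height zero
  m3 <- rbind(a = c(0, 0), b = c(1, 1), c = c(1, 1))
  hc3 <- hclust_profiles(m3)
  expect_equal(hc3$height[1], 0)
  expect_setequal(-hc3$merge[1, ], c(2, 3))

  # 9-row matrix: merge heights equal a brute-force agglomeration
  set.seed(42)
  m9 <- matrix(rnorm(9 * 5), 9, 5, dimnames = list(paste0("s", 1:9), NULL))
  hc9 <- hclust_profiles(m9)
  # naive average-linkage: track cluster member lists, merge the closest
  # pair by mean pairwise distance
  d <- as.matrix(dist(m9))
  clusters <- as.list(seq_len(9))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bh <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh) {
          bh <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(hc9$height, heights, tolerance = 1e-12)
})

test_that("the bundled nine-termite matrix behaves qualitatively as printed", {
  m <- table1_profiles()
  sp <- table1_species()
  expect_equal(dim(m), c(9L, 49L))
  expect_equal(rownames(m), sp$code)

  wood <- sp$code[sp$diet == "wood"]
  lac <- m[, "Laccase"]
  expect_true(all(lac[wood] > 0))
  expect_true(all(lac[setdiff(sp$code, wood)] == 0))

  zero_rows <- colnames(m)[colSums(m) == 0]
  expect_true(all(c("Chitosanase", "Cellobiohydrolase (reducing end)",
                    "Exo-1,3-alpha-glucanase") %in% zero_rows))
  # all-zero enzymes stay zero through the transforms: fold change drops
  # them rather than fabricating values, and CLR gives them a constant
  # (information-free) column
  fc <- suppressWarnings(fold_change(m))
  expect_length(intersect(zero_rows, colnames(fc$ratio)), 0L)
  tr <- clr(m)
  for (z in zero_rows) {
    expect_equal(stats::sd(tr[, z] - rowMeans(tr[, zero_rows])), 0,
                 tolerance = 1e-12)
  }
  # substrate lookup covers every enzyme
  sm <- substrate_map()
  expect_setequal(names(sm), colnames(m))
  expect_equal(unname(sm["Chitinase"]), "chitin")
})
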