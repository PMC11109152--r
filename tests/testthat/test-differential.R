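test_that("pseudobulk sums are exact and aggregate consistently", {
  m <- toy_counts(2, 4, vals = c(1, 0, 2, 5, 0, 1, 3, 2))
  cells <- tibble::tibble(cell_id = colnames(m),
                          sample = c("s1", "s1", "s2", "s2"),
                          celltype = c("a", "a", "a", "b"),
                          genotype = c("WT", "WT", "KO", "KO"))
  pb <- suppressWarnings(pseudobulk(m, cells, min_cells = 1))
  # hand sums (columns are c1=(1,0), c2=(2,5), c3=(0,1), c4=(3,2)):
  # group s1|a|WT = c1+c2, s2|a|KO = c3, s2|b|KO = c4
  expect_equal(unname(pb$counts[, "s1|a|WT"]), c(1 + 2, 0 + 5))
  expect_equal(unname(pb$counts[, "s2|a|KO"]), c(0, 1))
  expect_equal(unname(pb$counts[, "s2|b|KO"]), c(3, 2))

  # refinement re-aggregates to the coarse sums
  coarse <- suppressWarnings(pseudobulk(m, cells, groupby = "genotype",
                                        min_cells = 1))
  fine <- suppressWarnings(pseudobulk(m, cells,
                                      groupby = c("genotype", "celltype"),
                                      min_cells = 1))
  re <- sapply(c("WT", "KO"), function(g) {
    rowSums(fine$counts[, fine$meta$genotype == g, drop = FALSE])
  })
  expect_equal(unname(re), unname(coarse$counts[, c("WT", "KO")]))

  # small groups are dropped with a warning; missing metadata is an error
  expect_warning(pseudobulk(m, cells, min_cells = 2), "dropping")
  cells_na <- cells; cells_na$sample[2] <- NA
  expect_error(pseudobulk(m, cells_na, min_cells = 1), "c2")
})

test_that("size factors have geometric mean one and track depth ratios", {
  counts <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2)
  sf <- size_factors_mor(counts)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-9)
})

test_that("NB Wald test requires both genotypes and recovers a planted 2-fold change", {
  set.seed(2)
  n_groups <- 8
  meta <- tibble::tibble(
    sample = paste0("s", 1:n_groups),
    celltype = rep(c("a", "b"), n_groups / 2),
    genotype = rep(c("WT", "KO"), each = n_groups / 2),
    group = paste0("g", 1:n_groups), n_cells = 50L)
  mu <- 2000
  counts <- rbind(
    planted = rpois(n_groups, mu * ifelse(meta$genotype == "KO", 2, 1)),
    t(replicate(30, rpois(n_groups, mu))))
  rownames(counts) <- c("planted", paste0("null", 1:30))
  colnames(counts) <- meta$group
  pb <- structure(list(counts = counts, meta = meta, size_factors = NULL),
                  class = "pseudobulk")
  res <- nb_wald_test(pb)
  expect_true(all(res$converged))
  expect_equal(res$log2fc[res$peak == "planted"], 1, tolerance = 0.1)
  expect_identical(res$direction[res$peak == "planted"], "up")
  expect_true(all(res$fdr >= res$p, na.rm = TRUE))
  expect_identical(glance(res)$contrast, "genotypeKO")

  # a single genotype cannot be tested
  meta_one <- meta; meta_one$genotype <- "WT"
  pb1 <- structure(list(counts = counts, meta = meta_one, size_factors = NULL),
                   class = "pseudobulk")
  expect_error(nb_wald_test(pb1), "genotype")
})

test_that("Wilcoxon DORC testing matches exact rank-sum enumeration at small n", {
  # independent oracle: exact two-sided rank-sum tail by enumerating all
  # C(n1 + n2, n1) group assignments of the pooled ranks
  exact_wilcox_p <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    n1 <- length(x)
    obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(length(pooled), n1)
    stat <- apply(combs, 2, function(ix) sum(r[ix]))
    mu <- n1 * (length(pooled) + 1) / 2
    mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    sc <- matrix(c(x, y), 1, 13,
                 dimnames = list("d1", paste0("c", 1:13)))
    cells <- tibble::tibble(cell_id = colnames(sc),
                            genotype = c(rep("KO", 6), rep("WT", 7)),
                            celltype = "gmp")
    res <- wilcoxon_dorc_diff(sc, cells)
    expect_equal(res$p, exact_wilcox_p(x, y), tolerance = 1e-9)
    expect_equal(res$effect, mean(x) - mean(y), tolerance = 1e-12)
  }

  # complete separation of 10 vs 10 gives the extreme two-sided tail
  sc <- matrix(c(1:10, 101:110), 1, 20,
               dimnames = list("d1", paste0("c", 1:20)))
  cells <- tibble::tibble(cell_id = colnames(sc),
                          genotype = rep(c("WT", "KO"), each = 10),
                          celltype = "gmp")
  res <- wilcoxon_dorc_diff(sc, cells)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  # degenerate all-tied scores are skipped, as are single-genotype cell types
  sc2 <- matrix(1, 1, 20, dimnames = dimnames(sc))
  expect_identical(nrow(wilcoxon_dorc_diff(sc2, cells)), 0L)
  cells_one <- cells; cells_one$genotype <- "WT"
  expect_message(out <- wilcoxon_dorc_diff(sc, cells_one), "one genotype")
  expect_identical(nrow(out), 0L)
})

test_that("neighborhood fraction matches brute-force kNN and partitions sum to one", {
  # 6-cell toy with hand-checkable geometry on a line
  emb <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  labels <- c("A", "B", "A", "B", "A", "B")
  nf <- neighborhood_fraction(emb, labels, "A", k = 2)
  # neighbours: c1 -> {c2, c3}; c2 -> {c1, c3}; c3 -> {c2, c1};
  #             c4 -> {c5, c6}; c5 -> {c4, c6}; c6 -> {c5, c4}
  expect_equal(nf$fraction, c(1 / 2, 1, 1 / 2, 1 / 2, 0, 1 / 2))

  # all cells carrying the label score exactly one
  nf_all <- neighborhood_fraction(emb, rep("A", 6), "A", k = 3)
  expect_true(all(nf_all$fraction == 1))

  # fractions over a label partition sum to one per cell
  set.seed(5)
  emb2 <- matrix(rnorm(60 * 2), 60, 2)
  lab2 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  tot <- Reduce(`+`, lapply(c("x", "y", "z"), function(l) {
    neighborhood_fraction(emb2, lab2, l, k = 7)$fraction
  }))
  expect_equal(tot, rep(1, 60), tolerance = 1e-12)

  # uninformative embedding: mean fraction approximates the label frequency
  set.seed(6)
  emb3 <- matrix(rnorm(2000 * 3), 2000, 3)
  lab3 <- sample(c("q", "r"), 2000, replace = TRUE, prob = c(0.3, 0.7))
  nf3 <- neighborhood_fraction(emb3, lab3, "q", k = 50)
  expect_lt(abs(mean(nf3$fraction) - mean(lab3 == "q")), 0.02)
})

test_that("PCA embedding is deterministic, rank-aware and duplicates-preserving", {
  # a rank-1 count matrix is pure depth variation: after depth normalization
  # every cell is identical and the embedding collapses to a single point
  r1 <- outer(c(1, 2, 3, 4), c(1, 2, 3, 5))
  dimnames(r1) <- list(paste0("f", 1:4), paste0("c", 1:4))
  emb <- pca_embedding(Matrix::Matrix(r1, sparse = TRUE), n_pcs = 2)
  expect_lt(max(dist(emb)), 1e-9)

  # one dominant biological axis: PC1 carries almost all the variance
  set.seed(3)
  prof1 <- rgamma(30, 2); prof2 <- rgamma(30, 2)
  w <- seq(0, 1, length.out = 20)
  lam <- outer(prof1, w) + outer(prof2, 1 - w)
  m0 <- matrix(rpois(length(lam), 500 * lam), 30, 20,
               dimnames = list(paste0("f", 1:30), paste0("c", 1:20)))
  emb1 <- pca_embedding(Matrix::Matrix(m0, sparse = TRUE), n_pcs = 5)
  sdev <- attr(emb1, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.9)
  # deterministic sign convention: repeated runs agree exactly
  emb1b <- pca_embedding(Matrix::Matrix(m0, sparse = TRUE), n_pcs = 5)
  expect_identical(emb1, emb1b)

  # duplicated cells land on identical embedding rows
  m <- toy_counts(5, 3, vals = rpois(15, 4) + 1)
  m <- cbind(m, m[, 3, drop = FALSE])
  colnames(m) <- paste0("c", 1:4)
  emb2 <- pca_embedding(m, n_pcs = 2)
  expect_equal(emb2[3, ], emb2[4, ], tolerance = 1e-9)

  expect_error(pca_embedding(m, n_pcs = 10), "exceeds")
})
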