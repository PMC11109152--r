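test_that("a peak tracking its gene exactly yields r = 1 and the minimal p", {
  set.seed(3)
  n_cells <- 40
  expr <- rpois(n_cells, 20)
  # peak 1 equals the gene's expression; a balance peak keeps every cell's
  # ATAC total at 100 so depth normalization preserves ranks exactly;
  # 30 distal peaks provide background variety
  noise <- matrix(rpois(30 * n_cells, 20), 30)
  m <- rbind(expr, 100 - expr, noise, 900 - colSums(noise))
  n_peaks <- nrow(m)
  dimnames(m) <- list(paste0("p", 1:n_peaks), paste0("c", 1:n_cells))
  stopifnot(all(m >= 0), all(colSums(m) == 1000))
  atac <- Matrix::Matrix(m, sparse = TRUE)
  # two RNA genes with constant per-cell totals for the same reason
  rna <- Matrix::Matrix(rbind(g1 = expr, g2 = 100 - expr), sparse = TRUE)
  colnames(rna) <- colnames(m)
  centers <- c(100000L, 300000L, 200000L + 1000L * (1:30), 400000L)
  peaks <- tibble::tibble(peak_id = rownames(m), chrom = "chr1",
                          start = centers - 150L, end = centers + 151L)
  tss <- tibble::tibble(gene = "g1", chrom = "chr1", tss = 100000L, strand = "+")
  bg <- uniform_bg(n_peaks, n_background = 100, seed = 5)
  links <- link_peaks_to_genes(atac, rna, peaks, tss, bg)
  expect_identical(links$peak, "p1")
  expect_equal(links$r_obs, 1, tolerance = 1e-9)
  expect_equal(links$p_perm, 1 / 101, tolerance = 1e-12)
})

test_that("permutation p-values respect the add-one bounds", {
  sim <- small_sim()
  bg <- match_backgrounds(sim$peaks, n_background = 20, k_pool = 40, seed = 2)
  links <- link_peaks_to_genes(sim$atac, sim$rna, sim$peaks, sim$tss, bg,
                               n_perm = 20, p_cut = 1)
  expect_true(all(links$p_perm >= 1 / 21))
  expect_true(all(links$p_perm <= 1))
  expect_true(all(abs(links$distance) <= 10000L))
  expect_true(all(links$r_obs > 0))
})

test_that("DORC calling applies the >= 3 linked-peak rule", {
  links <- tibble::tibble(
    gene = c("a", "a", "b", "b", "b", "c", "d", "d", "d", "d"),
    peak = paste0("p", 1:10),
    r_obs = runif(10, 0.1, 0.9), p_perm = 0.01, distance = 0L)
  d <- call_dorcs(links)
  # hand grouping: a has 2 (excluded), b has 3 (boundary, included), c 1, d 4
  expect_identical(d$gene, c("d", "b"))
  expect_identical(d$n_peaks, c(4L, 3L))
  expect_identical(nrow(attr(d, "links")), 7L)
  expect_identical(nrow(call_dorcs(links, min_peaks = 5)), 0L)
})

test_that("DORC scores normalise by depth and residuals vanish under identity", {
  counts <- matrix(0, 4, 2, dimnames = list(paste0("p", 1:4), c("c1", "c2")))
  counts[, 1] <- c(1, 2, 3, 594) # total 600
  counts[, 2] <- c(4, 4, 4, 588) # total 600
  atac <- Matrix::Matrix(counts, sparse = TRUE)
  links <- tibble::tibble(gene = "g1", peak = paste0("p", 1:3),
                          r_obs = 0.5, p_perm = 0.01, distance = 0L)
  d <- call_dorcs(links)
  ds <- dorc_scores(atac, d)
  # cell 1: (1+2+3)/600 * median(600) = 6
  expect_equal(unname(ds$scores["g1", ]), c(6, 12), tolerance = 1e-12)

  # residuals are exactly zero when normalized expression matches the scores;
  # a second gene keeps per-cell RNA totals equal so normalization is benign
  rna <- Matrix::Matrix(rbind(g1 = c(6, 12), g2 = c(594, 588)), sparse = TRUE)
  colnames(rna) <- c("c1", "c2")
  ds2 <- dorc_scores(atac, d, rna = rna)
  expect_true(all(abs(ds2$residuals) < 1e-9))
})

test_that("smoothing with k = 1 is the identity", {
  sim <- small_sim()
  bg <- match_backgrounds(sim$peaks, n_background = 20, k_pool = 30, seed = 1)
  links <- link_peaks_to_genes(sim$atac, sim$rna, sim$peaks, sim$tss, bg,
                               n_perm = 20)
  d <- call_dorcs(links)
  expect_gt(nrow(d), 0)
  emb <- pca_embedding(sim$atac, n_pcs = 5)
  s1 <- dorc_scores(sim$atac, d, smooth_k = 1)
  s2 <- dorc_scores(sim$atac, d, embedding = emb, smooth_k = 1)
  expect_identical(s1$scores, s2$scores)
})

test_that("TF-DORC regulation classifies by correlation sign", {
  sc <- matrix(seq(1, 4, length.out = 12), 2, 6, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("c", 1:6)))
  sc["gB", ] <- rev(sc["gB", ])
  z <- rbind(TF1 = sc["gA", ], TF2 = -sc["gA", ])
  colnames(z) <- colnames(sc)
  out <- tf_dorc_regulation(z, sc, c(TF1 = "gA", TF2 = "gA"))
  expect_equal(out$r[out$tf == "TF1"], 1, tolerance = 1e-12)
  expect_identical(out$class[out$tf == "TF1"], "activator")
  expect_equal(out$r[out$tf == "TF2"], -1, tolerance = 1e-12)
  expect_identical(out$class[out$tf == "TF2"], "repressor")
  # TFs without a DORC cognate are skipped
  out2 <- tf_dorc_regulation(z, sc, c(TF1 = "gA", TF2 = "missing"))
  expect_identical(out2$tf, "TF1")
  expect_error(tf_dorc_regulation(z[, 1:2], sc[, 1:2], c(TF1 = "gA")),
               "shared units")
})

test_that("planted activator TFs are classified as activators on simulation", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_multiome(small_config(seed = seed, n_cells = 150L))
    bg <- match_backgrounds(sim$peaks, n_background = 20, k_pool = 30,
                            seed = seed)
    dev <- compute_deviations(sim$atac, sim$motifs$match, bg)
    links <- sim$truth$dorc_links
    d <- call_dorcs(tibble::tibble(gene = links$gene, peak = links$peak,
                                   r_obs = 0.5, p_perm = 0.01,
                                   distance = links$distance))
    ds <- dorc_scores(sim$atac, d)
    cog <- sim$motifs$meta[sim$motifs$meta$kind == "cognate", ]
    map <- stats::setNames(cog$cognate_gene, cog$motif)
    out <- tf_dorc_regulation(dev$z, ds, map[1])
    if (nrow(out) == 1 && out$class == "activator") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("retained links are invariant to relabelling the cells", {
  sim <- small_sim()
  bg <- match_backgrounds(sim$peaks, n_background = 20, k_pool = 30, seed = 3)
  l1 <- link_peaks_to_genes(sim$atac, sim$rna, sim$peaks, sim$tss, bg,
                            n_perm = 20)
  perm <- sample(ncol(sim$atac))
  l2 <- link_peaks_to_genes(sim$atac[, perm], sim$rna[, perm], sim$peaks,
                            sim$tss, bg, n_perm = 20)
  a1 <- dplyr::arrange(as.data.frame(l1), gene, peak)
  a2 <- dplyr::arrange(as.data.frame(l2), gene, peak)
  expect_identical(a1$gene, a2$gene)
  expect_identical(a1$peak, a2$peak)
  expect_equal(a1$r_obs, a2$r_obs, tolerance = 1e-9)
})
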