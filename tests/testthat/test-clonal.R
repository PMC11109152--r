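test_that("FPS reproduces the 3-4-5 toy and the zero-distance case", {
  tab <- fps_345_toy()
  expect_equal(sd(tab$A), 1, tolerance = 1e-12)
  expect_equal(sd(tab$B), 1, tolerance = 1e-12)
  fps <- functional_perturbation_score(tab)
  expect_equal(fps$score[fps$clone == "k1"], 5, tolerance = 1e-12)
  # clones with identical WT and KO rows score exactly zero
  expect_equal(fps$score[fps$clone == "k4"], 0, tolerance = 1e-12)
  expect_identical(fps$rank[fps$clone == "k1"], 1L)
})

test_that("FPS equals the full standardized distance matrix restricted to pairs", {
  set.seed(9)
  n <- 28; n_assay <- 8
  tab <- tibble::tibble(
    clone = rep(sprintf("cl%02d", 1:n), 2),
    genotype = rep(c("WT", "KO"), each = n))
  m <- matrix(rnorm(2 * n * n_assay, 10, 3), 2 * n, n_assay)
  for (a in seq_len(n_assay)) tab[[paste0("assay", a)]] <- m[, a]
  fps <- functional_perturbation_score(tab)
  # brute-force oracle: scale() then dist() over all rows, read pair entries
  dm <- as.matrix(dist(scale(m)))
  oracle <- dm[cbind(1:n, n + 1:n)]
  expect_equal(fps$score[match(sprintf("cl%02d", 1:n), fps$clone)], oracle,
               tolerance = 1e-10)
})

test_that("FPS is invariant under affine transforms of assay columns", {
  set.seed(10)
  tab <- tibble::tibble(
    clone = rep(sprintf("cl%d", 1:6), 2),
    genotype = rep(c("WT", "KO"), each = 6),
    A = rnorm(12), B = rnorm(12), C = rnorm(12))
  f1 <- functional_perturbation_score(tab)
  tab2 <- dplyr::mutate(tab, A = -3.7 * A + 11, C = 0.01 * C - 5)
  f2 <- functional_perturbation_score(tab2)
  expect_equal(f1$score, f2$score[match(f1$clone, f2$clone)],
               tolerance = 1e-10)

  # constant columns are dropped with a warning, not propagated as NaN
  tab3 <- dplyr::mutate(tab, B = 2)
  expect_warning(f3 <- functional_perturbation_score(tab3), "constant")
  expect_true(all(is.finite(f3$score)))

  # unpaired clones are rejected
  expect_error(functional_perturbation_score(tab[-1, ]), "exactly one WT")
})

test_that("clone-level correlations match hand computation", {
  set.seed(11)
  n <- 10
  assays <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("cl%02d", 1:n), c("a1", "a2", "a3")))
  tfz <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(rownames(assays), c("TF1", "TF2")))
  tfz[, 1] <- assays[, 2] # identical column -> r = 1
  cc <- correlate_function_with_tf(assays, tfz)
  expect_equal(dim(cc), c(3L, 2L))
  expect_equal(cc["a2", "TF1"], 1, tolerance = 1e-12)
  expect_equal(cc["a1", "TF2"], cor(assays[, 1], tfz[, 2]), tolerance = 1e-12)
  expect_equal(correlate_function_with_tf(assays, -assays)["a1", 1], -1,
               tolerance = 1e-12)
  expect_error(correlate_function_with_tf(assays[1:2, ], tfz[1:2, ]),
               "3 aligned")
})

test_that("feature ranking puts a score-identical feature first and masks ties", {
  set.seed(12)
  n <- 20
  scores <- tibble::tibble(clone = sprintf("cl%02d", 1:n),
                           score = sort(abs(rnorm(n)), decreasing = TRUE))
  feats <- matrix(rnorm(n * 30), n, 30,
                  dimnames = list(scores$clone, paste0("f", 1:30)))
  feats[, 1] <- scores$score
  feats[, 2] <- 7 # all tied
  out <- correlate_score_with_features(scores, feats)
  expect_identical(out$feature[1], "f1")
  expect_equal(out$r[1], 1, tolerance = 1e-9)
  expect_true(is.na(out$r[out$feature == "f2"]))
})

test_that("barcode extraction enforces flanks and constant bases", {
  f5 <- "GTCGACGGT"; f3 <- "ACCGGTAGA"
  cpos <- larry_constant_bases()
  good_bc <- paste(replace(rep("A", 28), as.integer(names(cpos)), cpos),
                   collapse = "")
  bad_bc <- good_bc
  substr(bad_bc, 5, 5) <- "C" # violates the constant T at position 5
  reads <- c(
    paste0("TTTT", f5, good_bc, f3, "GGGG"),
    paste0("AA", f5, good_bc, f3),
    paste0("CCCC", f5, bad_bc, f3, "GG"),      # constant-base mismatch
    paste0("CCCC", good_bc, f3, "GG"),          # flank5 absent
    paste0("CC", f5, good_bc, "TTTTTTTTT")      # flank3 absent
  )
  out <- extract_barcodes(reads, f5, f3)
  expect_identical(out$barcode, good_bc)
  expect_identical(out$count, 2L)
  expect_identical(attr(out, "n_assigned"), 2L)
  # emitted barcodes always satisfy the template
  expect_identical(substr(out$barcode, 5, 6), "TG")
})

test_that("error-correction merges variants, conserves counts, filters rare barcodes", {
  centroid <- strrep("A", 28)
  var1 <- paste0("C", strrep("A", 27))          # distance 1
  far <- strrep("G", 28)                        # far away, isolated
  raw <- tibble::tibble(barcode = c(centroid, var1, far),
                        count = c(100L, 3L, 9L))
  out <- correct_and_filter(raw)
  expect_identical(out$barcode, centroid)
  expect_identical(out$count, 103L)
  # counts conserved by merging before the min_count cut
  expect_identical(attr(out, "merged_total"), 112L)

  # a variant backed by too many reads (ratio < merge_ratio) stays separate
  raw2 <- tibble::tibble(barcode = c(centroid, var1), count = c(100L, 30L))
  out2 <- correct_and_filter(raw2)
  expect_identical(nrow(out2), 2L)

  # empty input passes through
  empty <- correct_and_filter(tibble::tibble(barcode = character(),
                                             count = integer()))
  expect_identical(nrow(empty), 0L)
})

test_that("simulated sequencing errors are corrected to within 5% of truth", {
  ab <- c(a = 100L, b = 500L, c = 2000L)
  bc <- simulate_barcode_reads(ab, error_rate = 0.01, seed = 33)
  raw <- extract_barcodes(bc$reads)
  corrected <- correct_and_filter(raw)
  expect_identical(nrow(corrected), 3L)
  # clone abundances: constant-base filtering removes the same expected
  # fraction of every clone's reads, so sizes are compared as fractions
  got <- corrected$count[match(bc$truth$barcode, corrected$barcode)]
  expect_true(all(abs((got / sum(got)) / (ab / sum(ab)) - 1) <= 0.05))
  # absolute counts sit just below truth by the constant-base loss 1-(1-e)^8
  expect_true(all(got <= bc$truth$count))
  expect_gt(min(got / bc$truth$count), 1 - 2 * (1 - 0.99^8))
  expect_true(all(corrected$count >= 10))
})

test_that("sister-sample comparison joins fractions and fits the regression", {
  a <- structure(tibble::tibble(barcode = c("AAA", "CCC", "GGG"),
                                count = c(100L, 200L, 700L)),
                 class = c("barcode_counts", "tbl_df", "tbl", "data.frame"))
  b <- a
  cmp <- paired_clone_sizes(a, b)
  expect_equal(cmp$slope, 1, tolerance = 1e-9)
  expect_equal(cmp$intercept, 0, tolerance = 1e-9)
  expect_identical(nrow(cmp$table), 3L)
  expect_identical(glance(cmp)$n_unmatched_a, 0L)

  b2 <- dplyr::mutate(a, barcode = c("TTT", "TTA", "TTC"))
  expect_error(paired_clone_sizes(a, b2), "no shared barcodes")
})

test_that("expanded clones sit above the sister-sample regression line", {
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    n <- 40
    base <- rpois(n, 300) + 50L
    expanded <- seq_len(5) # designated subset doubles in sample B
    cb <- base
    cb[expanded] <- cb[expanded] * 2L
    a <- tibble::tibble(barcode = sprintf("BC%02d", 1:n), count = base)
    b <- tibble::tibble(barcode = a$barcode,
                        count = as.integer(rpois(n, cb)))
    cmp <- paired_clone_sizes(a, b)
    ok <- cmp$table$above_line[match(sprintf("BC%02d", expanded),
                                     cmp$table$barcode)]
    if (all(ok)) hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})
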