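#' Deduplicate motifs by profile similarity
#'
#' Single-linkage clusters motifs whose match-profile correlation (absolute
#' value) reaches `cutoff`; at a fixed threshold single linkage is the
#' connected components of the thresholded similarity graph. Within each
#' cluster the motif with the highest deviation-Z variance (if `z` is given;
#' otherwise profile variance) is kept as the representative.
#'
#' @param motif_profiles Motifs x units numeric matrix (e.g. the transposed
#'   binary peak-match matrix).
#' @param cutoff Similarity threshold (default 0.8, inclusive).
#' @param z Optional motifs x cells deviation Z matrix used to pick the most
#'   variable representative.
#' @return Tibble: `motif`, `cluster`, `representative`.
#' @export
dedup_motifs <- function(motif_profiles, cutoff = 0.8, z = NULL) {
  m <- as.matrix(motif_profiles)
  if (nrow(m) < 2L) stop("need at least 2 motifs", call. = FALSE)
  motifs <- rownames(m) %||% sprintf("motif%03d", seq_len(nrow(m)))
  cc <- suppressWarnings(abs(stats::cor(t(m))))
  cc[is.na(cc)] <- 0 # constant profiles: undefined similarity -> own cluster
  adj <- cc >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  vv <- if (!is.null(z)) apply(as.matrix(z), 1L, stats::var) else apply(m, 1L, stats::var)
  tibble::tibble(motif = motifs, cluster = as.integer(comp), variance = vv) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(representative = dplyr::row_number(
      dplyr::desc(dplyr::coalesce(.data$variance, -Inf))) == 1L) |>
    dplyr::ungroup() |>
    dplyr::select(!"variance")
}

#' Jackstraw selection of significantly variable motifs
#'
#' Fits a PCA to the motif deviation Z matrix (motifs as variables, cells as
#' observations) and scores each motif by the maximum over the first `n_pcs`
#' components of squared loading times component variance. Each of `n_iter`
#' iterations permutes the cell values of a random `perm_frac` of motifs,
#' refits the PCA and pools the permuted motifs' statistics into a null;
#' a motif is significantly variable if its observed statistic has empirical
#' p-value at most `p_cut` against that null (add-one estimator).
#'
#' @param z Motifs x cells deviation Z matrix.
#' @param n_iter Number of permutation iterations (default 100).
#' @param n_pcs Number of leading components scored (default 10).
#' @param p_cut Significance threshold (default 0.05).
#' @param perm_frac Fraction of motifs permuted per iteration (default 0.1).
#' @param seed Integer seed.
#' @return Tibble: `motif`, `statistic`, `p`, `variable` (logical).
#' @export
jackstraw_variable_motifs <- function(z, n_iter = 100L, n_pcs = 10L,
                                      p_cut = 0.05, perm_frac = 0.1,
                                      seed = 1L) {
  z <- as.matrix(z)
  n_motifs <- nrow(z); n_cells <- ncol(z)
  if (n_cells < n_pcs) stop("need at least n_pcs cells", call. = FALSE)
  motifs <- rownames(z) %||% sprintf("motif%03d", seq_len(n_motifs))

  stat_of <- function(mat, rows = seq_len(nrow(mat))) {
    p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(p$rotation))
    load2 <- p$rotation[rows, seq_len(k), drop = FALSE]^2
    apply(sweep(load2, 2L, p$sdev[seq_len(k)]^2, "*"), 1L, max)
  }
  obs <- stat_of(z)

  m_perm <- max(1L, round(perm_frac * n_motifs))
  if (n_iter * m_perm < 100L) {
    warning("fewer than 100 null draws; jackstraw p-values are unstable",
            call. = FALSE)
  }
  set.seed(as.integer(seed))
  null <- numeric(0)
  for (it in seq_len(n_iter)) {
    rows <- sample.int(n_motifs, m_perm)
    zp <- z
    for (r in rows) zp[r, ] <- zp[r, sample.int(n_cells)]
    null <- c(null, stat_of(zp, rows))
  }
  p <- vapply(obs, function(s) (1 + sum(null >= s)) / (1 + length(null)),
              numeric(1))
  tibble::tibble(motif = motifs, statistic = obs, p = p,
                 variable = p <= p_cut)
}

#' Normalised, per-cell mean-centred accessibility
#'
#' Depth-normalises counts (per-cell total, median-scaled) and subtracts each
#' cell's mean, the representation used for TF high/low fold-change testing.
#'
#' @param atac Sparse peaks x cells counts.
#' @return Dense peaks x cells matrix.
#' @export
normalize_centered <- function(atac) {
  x <- as.matrix(depth_normalize(atac))
  sweep(x, 2L, colMeans(x), "-")
}

#' Peaks associated with a TF's high/low cell split
#'
#' Splits cells at the median deviation Z of one TF (high: `z > median`),
#' then tests each peak's normalised, per-cell mean-centred accessibility
#' between the two groups with a two-tailed Welch t-test, adjusting across
#' peaks by Benjamini-Hochberg. The reported fold-change is
#' `mean(high) - mean(low)` on the normalised scale.
#'
#' @param atac_norm Peaks x cells matrix from [normalize_centered()].
#' @param z `deviation_result` (or TF x cells matrix) holding the TF's Z row.
#' @param tf TF (row) name.
#' @param fdr_cut FDR threshold for significance (default 1e-06).
#' @return Tibble: `peak`, `fc`, `t`, `df`, `p`, `fdr`, `significant`.
#' @export
tf_peak_association <- function(atac_norm, z, tf, fdr_cut = 1e-06) {
  zz <- if (inherits(z, "deviation_result")) z$z else as.matrix(z)
  stopifnot(tf %in% rownames(zz), ncol(atac_norm) == ncol(zz))
  zv <- zz[tf, ]
  hi <- !is.na(zv) & zv > stats::median(zv, na.rm = TRUE)
  lo <- !is.na(zv) & !hi
  if (sum(hi) < 2L || sum(lo) < 2L) {
    stop("high/low split leaves a group with fewer than 2 cells", call. = FALSE)
  }
  welch <- function(x1, x2) {
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    list(fc = m1 - m2, t = t, df = df,
         p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  }
  w <- welch(atac_norm[, hi, drop = FALSE], atac_norm[, lo, drop = FALSE])
  p <- unname(w$p)
  p[is.na(p) | is.nan(p)] <- 1 # constant peaks: no evidence
  fdr <- stats::p.adjust(p, "BH")
  tibble::tibble(peak = rownames(atac_norm) %||% as.character(seq_along(p)),
                 fc = unname(w$fc), t = unname(w$t), df = unname(w$df),
                 p = p, fdr = fdr, significant = fdr <= fdr_cut)
}

#' Cluster peaks into co-accessible modules
#'
#' Builds a k-nearest-neighbour graph over peaks (Euclidean distance between
#' fold-change profile rows; an undirected, unweighted edge joins two peaks
#' when either lists the other among its neighbours, and distance ties at the
#' k-th neighbour are all included so identical profiles form one component)
#' and partitions it with Louvain community detection under a fixed seed.
#' Isolated peaks become singleton modules and are flagged.
#'
#' @param fc_matrix Significant-peaks x TFs fold-change matrix.
#' @param k Number of nearest neighbours (default 30).
#' @param seed Integer seed for Louvain.
#' @param resolution Louvain resolution (default 1).
#' @return A `module_result` list: `modules` (tibble `peak`, `module`,
#'   `singleton`), `annot` (binary peaks x modules sparse matrix), `fc_matrix`.
#' @export
cluster_peak_modules <- function(fc_matrix, k = 30L, seed = 1L,
                                 resolution = 1) {
  fc <- as.matrix(fc_matrix)
  n <- nrow(fc)
  if (n < k + 1L) stop("need at least k + 1 peaks", call. = FALSE)
  peaks <- rownames(fc) %||% sprintf("peak%05d", seq_len(n))
  d <- as.matrix(stats::dist(fc))
  ii <- jj <- integer(0)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    kth <- sort(di, partial = k)[k]
    nb <- setdiff(which(d[i, ] <= kth), i) # tie-inclusive at the k-th distance
    ii <- c(ii, rep.int(i, length(nb))); jj <- c(jj, nb)
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  und <- (adj + Matrix::t(adj)) > 0 # edge if either lists the other
  g <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- as.integer(igraph::membership(comm))
  singleton <- Matrix::rowSums(und) == 0
  modules <- tibble::tibble(peak = peaks, module = mem,
                            singleton = as.logical(singleton))
  annot <- Matrix::sparseMatrix(i = seq_len(n), j = mem, x = 1,
                                dims = c(n, max(mem)),
                                dimnames = list(peaks,
                                                sprintf("module%02d", seq_len(max(mem)))))
  structure(list(modules = modules, annot = annot, fc_matrix = fc),
            class = "module_result")
}

#' Derive co-accessible peak modules end to end
#'
#' Convenience wrapper chaining motif deduplication, jackstraw variable-motif
#' selection, per-TF high/low peak association, and module clustering of the
#' fold-change profiles of peaks significant for at least one variable TF.
#'
#' @param atac Sparse peaks x cells counts.
#' @param dev `deviation_result` over motifs for the same cells.
#' @param motif_match Binary peaks x motifs match matrix.
#' @param fdr_cut Per-TF association FDR threshold (default 1e-06).
#' @param k Module-graph neighbours (default 30).
#' @param seed Integer seed.
#' @param dedup_cutoff Motif similarity cutoff (default 0.8).
#' @param jackstraw_args List of overrides for
#'   [jackstraw_variable_motifs()].
#' @return A `module_result` (see [cluster_peak_modules()]) with the selected
#'   `variable_tfs` attached.
#' @export
derive_coaccess_modules <- function(atac, dev, motif_match, fdr_cut = 1e-06,
                                    k = 30L, seed = 1L, dedup_cutoff = 0.8,
                                    jackstraw_args = list()) {
  reps <- dedup_motifs(t(as.matrix(motif_match)), cutoff = dedup_cutoff,
                       z = dev$z)
  rep_motifs <- reps$motif[reps$representative]
  js <- do.call(jackstraw_variable_motifs,
                c(list(z = dev$z[rep_motifs, , drop = FALSE], seed = seed),
                  jackstraw_args))
  tfs <- js$motif[js$variable]
  if (length(tfs) == 0L) stop("no significantly variable motifs", call. = FALSE)
  an <- normalize_centered(atac)
  assoc <- lapply(tfs, function(tf) tf_peak_association(an, dev, tf, fdr_cut))
  sig <- sort(unique(unlist(lapply(assoc, function(a) a$peak[a$significant]))))
  if (length(sig) == 0L) stop("no significant peaks for any variable TF", call. = FALSE)
  fc <- vapply(assoc, function(a) a$fc[match(sig, a$peak)], numeric(length(sig)))
  dimnames(fc) <- list(sig, tfs)
  out <- cluster_peak_modules(fc, k = min(k, length(sig) - 1L), seed = seed)
  attr(out, "variable_tfs") <- tfs
  out
}
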