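#' Peak-gene cis-regulatory links with a matched-background permutation null
#'
#' Tests every (gene, peak) pair with the peak centre within `window` bp of
#' the gene's TSS for correlation between depth-normalised accessibility and
#' normalised expression across paired cells. For each candidate pair, the
#' null distribution is the same correlation recomputed with the peak's
#' `n_perm` GC/accessibility-matched background peaks; the permutation p-value
#' uses the add-one estimator `p = (1 + #[r_b >= r_obs]) / (1 + n_perm)`, so
#' it can never be exactly zero. Retained links have `r_obs > 0` and
#' `p_perm <= p_cut`.
#'
#' @param atac Sparse peaks x cells counts.
#' @param rna Sparse genes x cells counts, same cells in the same order.
#' @param peaks Peak tibble aligned with `atac` rows.
#' @param tss TSS tibble (`gene`, `chrom`, `tss`); genes absent from `rna`
#'   are skipped.
#' @param bg `background_sets` over the same peaks.
#' @param window Maximum TSS-to-peak-centre distance in bp (default 10,000).
#' @param n_perm Number of background correlations per pair (default
#'   `bg$n_background`).
#' @param p_cut Permutation p-value cutoff for retention (default 0.05).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble of retained links (`gene`, `peak`, `r_obs`, `p_perm`,
#'   `distance`) with attributes `n_candidates` (all in-window testable
#'   pairs) and `n_candidates_positive` (those with `r_obs > 0`).
#' @export
link_peaks_to_genes <- function(atac, rna, peaks, tss, bg,
                                window = 10000L, n_perm = bg$n_background,
                                p_cut = 0.05,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(identical(colnames(atac), colnames(rna)),
            identical(peaks$peak_id, rownames(atac)),
            n_perm <= bg$n_background)
  center <- floor((peaks$start + peaks$end) / 2)

  genes <- intersect(tss$gene, rownames(rna))
  tss_use <- tss[match(genes, tss$gene), ]
  cand <- purrr::map_dfr(seq_len(nrow(tss_use)), function(g) {
    hit <- which(peaks$chrom == tss_use$chrom[g] &
                   abs(center - tss_use$tss[g]) <= window)
    if (!length(hit)) return(NULL)
    tibble::tibble(gene = tss_use$gene[g], peak_ix = hit,
                   distance = as.integer(center[hit] - tss_use$tss[g]))
  })
  if (nrow(cand) == 0L) {
    out <- tibble::tibble(gene = character(), peak = character(),
                          r_obs = numeric(), p_perm = numeric(),
                          distance = integer())
    attr(out, "n_candidates") <- 0L
    attr(out, "n_candidates_positive") <- 0L
    return(out)
  }

  a_norm <- depth_normalize(atac)
  r_norm <- depth_normalize(rna)
  if (method == "spearman") {
    A <- row_rank_scale(a_norm)
    R <- row_rank_scale(r_norm)
  } else {
    A <- t(scale(t(as.matrix(a_norm))))
    R <- t(scale(t(as.matrix(r_norm))))
  }
  nc <- ncol(atac)
  gene_ix <- match(cand$gene, rownames(rna))
  pair_r <- function(pix) unname(rowSums(A[pix, , drop = FALSE] *
                                           R[gene_ix, , drop = FALSE]) / (nc - 1L))
  r_obs <- pair_r(cand$peak_ix)
  ge <- matrix(0L, nrow(cand), n_perm)
  for (b in seq_len(n_perm)) {
    r_b <- pair_r(bg$draws[cand$peak_ix, b])
    ge[, b] <- as.integer(!is.na(r_b) & !is.na(r_obs) & r_b >= r_obs)
  }
  p_perm <- (1 + rowSums(ge)) / (1 + n_perm)

  testable <- !is.na(r_obs)
  cand$r_obs <- r_obs
  cand$p_perm <- p_perm
  cand <- cand[testable, , drop = FALSE]
  keep <- cand$r_obs > 0 & cand$p_perm <= p_cut
  out <- tibble::tibble(gene = cand$gene[keep],
                        peak = peaks$peak_id[cand$peak_ix[keep]],
                        r_obs = cand$r_obs[keep],
                        p_perm = cand$p_perm[keep],
                        distance = cand$distance[keep])
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "n_candidates_positive") <- sum(cand$r_obs > 0)
  out
}

#' Call domains of regulatory chromatin (DORCs)
#'
#' Groups retained peak-gene links by gene and keeps genes with at least
#' `min_peaks` significantly associated peaks, ranked by descending peak
#' count.
#'
#' @param links Tibble from [link_peaks_to_genes()].
#' @param min_peaks Minimum number of linked peaks (default 3).
#' @return A `dorc_table` tibble (`gene`, `n_peaks`) with the per-gene link
#'   rows kept in `attr(, "links")`.
#' @export
call_dorcs <- function(links, min_peaks = 3L) {
  tab <- links |>
    dplyr::count(.data$gene, name = "n_peaks") |>
    dplyr::filter(.data$n_peaks >= min_peaks) |>
    dplyr::arrange(dplyr::desc(.data$n_peaks), .data$gene)
  out <- structure(tab, class = c("dorc_table", class(tab)))
  attr(out, "links") <- dplyr::filter(links, .data$gene %in% tab$gene)
  out
}

#' Per-cell DORC accessibility scores and accessibility-expression residuals
#'
#' The DORC score of gene g in cell i is the summed accessibility of g's
#' linked peaks, depth-normalised (`/ T_i * median(T)`). Optional kNN
#' smoothing averages each cell with its `smooth_k - 1` nearest neighbours in
#' a supplied embedding (self included; `smooth_k = 1` is the identity).
#' When expression is supplied, the residual is the row-z-scored accessibility
#' minus the row-z-scored normalised expression, so positive residuals mark
#' chromatin running ahead of transcription.
#'
#' @param atac Sparse peaks x cells counts.
#' @param dorcs A `dorc_table` from [call_dorcs()].
#' @param rna Optional genes x cells counts for residuals.
#' @param embedding Optional cells x dims matrix for smoothing.
#' @param smooth_k Neighbourhood size for smoothing (default 1 = off).
#' @return A `dorc_scores` list: `scores` (dorc x cell), `residuals` (or
#'   `NULL`), `masked_cells` (zero-depth cells).
#' @export
dorc_scores <- function(atac, dorcs, rna = NULL, embedding = NULL,
                        smooth_k = 1L) {
  links <- attr(dorcs, "links")
  stopifnot(!is.null(links), all(links$peak %in% rownames(atac)))
  genes <- dorcs$gene
  M <- Matrix::sparseMatrix(i = match(links$gene, genes),
                            j = match(links$peak, rownames(atac)),
                            x = 1, dims = c(length(genes), nrow(atac)),
                            dimnames = list(genes, rownames(atac)))
  tot <- Matrix::colSums(atac)
  masked <- tot == 0
  med <- stats::median(tot[!masked])
  sc <- as.matrix(M %*% atac)
  sc <- sweep(sc, 2L, ifelse(masked, NA_real_, tot), "/") * med

  if (smooth_k > 1L) {
    stopifnot(!is.null(embedding), nrow(embedding) == ncol(atac))
    nb <- cbind(seq_len(ncol(atac)), knn_brute(embedding, smooth_k - 1L))
    sm <- sc
    for (i in seq_len(ncol(sc))) sm[, i] <- rowMeans(sc[, nb[i, ], drop = FALSE])
    sc <- sm
  }

  res <- NULL
  if (!is.null(rna)) {
    stopifnot(identical(colnames(rna), colnames(atac)))
    expr <- depth_normalize(rna)[match(genes, rownames(rna)), , drop = FALSE]
    res <- row_zscore(sc) - row_zscore(as.matrix(expr))
    dimnames(res) <- dimnames(sc)
  }
  structure(list(scores = sc, residuals = res,
                 masked_cells = colnames(atac)[masked]),
            class = "dorc_scores")
}

#' Classify TFs as activators or repressors of their cognate DORCs
#'
#' Correlates each TF's motif deviation Z-score with the DORC accessibility
#' score of its cognate gene across the shared units (cells, or
#' clone-aggregated profiles — the function only requires matching columns).
#' Positive correlation marks an activator, negative a repressor.
#'
#' @param motif_z Deviation matrix (TF x units) or a `deviation_result` (its
#'   `z` is used).
#' @param scores A `dorc_scores` object or a dorc x units matrix.
#' @param tf_to_gene Named character vector `TF -> cognate gene`; TFs whose
#'   cognate gene has no DORC are skipped.
#' @param min_abs_r Reporting threshold on `|r|` (default 0.1).
#' @param method Correlation type (default Pearson).
#' @return Tibble: `tf`, `gene`, `r`, `class` (`"activator"`/`"repressor"`),
#'   `reported` (`|r| >= min_abs_r`).
#' @export
tf_dorc_regulation <- function(motif_z, scores, tf_to_gene, min_abs_r = 0.1,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  z <- if (inherits(motif_z, "deviation_result")) motif_z$z else as.matrix(motif_z)
  sc <- if (inherits(scores, "dorc_scores")) scores$scores else as.matrix(scores)
  shared <- intersect(colnames(z), colnames(sc))
  if (length(shared) < 3L) stop("fewer than 3 shared units between inputs", call. = FALSE)
  tfs <- intersect(names(tf_to_gene), rownames(z))
  tfs <- tfs[tf_to_gene[tfs] %in% rownames(sc)]
  purrr::map_dfr(tfs, function(tf) {
    r <- suppressWarnings(stats::cor(z[tf, shared], sc[tf_to_gene[[tf]], shared],
                                     method = method,
                                     use = "pairwise.complete.obs"))
    tibble::tibble(tf = tf, gene = tf_to_gene[[tf]], r = r,
                   class = ifelse(r > 0, "activator", "repressor"),
                   reported = !is.na(r) & abs(r) >= min_abs_r)
  })
}
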