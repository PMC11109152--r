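#' Pseudobulk aggregation of single-cell counts
#'
#' Sums raw counts within groups defined by the requested metadata columns
#' (sample, cell type and genotype by default), producing replicate-level
#' count profiles for negative-binomial differential testing. Groups with
#' fewer than `min_cells` member cells are dropped with a warning.
#'
#' @param atac Sparse peaks x cells counts.
#' @param cells Cell metadata tibble with `cell_id` plus the `groupby`
#'   columns; missing values are an error naming the offending cells.
#' @param groupby Metadata columns defining groups.
#' @param min_cells Minimum group size (default 10).
#' @return A `pseudobulk` list: `counts` (peaks x groups dense integer
#'   matrix), `meta` (tibble of group metadata with `n_cells`),
#'   `size_factors` (`NULL` until estimated).
#' @export
pseudobulk <- function(atac, cells,
                       groupby = c("sample", "celltype", "genotype"),
                       min_cells = 10L) {
  stopifnot(identical(cells$cell_id, colnames(atac)),
            all(groupby %in% names(cells)))
  miss <- Reduce(`|`, lapply(groupby, function(g) is.na(cells[[g]])))
  if (any(miss)) {
    stop("missing grouping metadata for cells: ",
         paste(utils::head(cells$cell_id[miss], 5L), collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(cells[groupby], sep = "|"))
  lev <- unique(key)
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = match(key, lev), x = 1,
                              dims = c(length(key), length(lev)))
  sums <- as.matrix(atac %*% ind)
  meta <- dplyr::distinct(dplyr::select(cells, dplyr::all_of(groupby)))
  meta <- meta[match(lev, do.call(paste, c(meta, sep = "|"))), ]
  meta$group <- lev
  meta$n_cells <- as.integer(table(key)[lev])
  keep <- meta$n_cells >= min_cells
  if (any(!keep)) {
    warning(sprintf("dropping %d pseudobulk group(s) with < %d cells",
                    sum(!keep), min_cells), call. = FALSE)
  }
  sums <- sums[, keep, drop = FALSE]
  colnames(sums) <- meta$group[keep]
  rownames(sums) <- rownames(atac)
  structure(list(counts = sums,
                 meta = tibble::as_tibble(meta[keep, , drop = FALSE]),
                 size_factors = NULL),
            class = "pseudobulk")
}

#' Median-of-ratios size factors
#'
#' DESeq-style estimator: per-peak geometric means over groups (peaks with a
#' zero anywhere are excluded from the reference), each group's factor is the
#' median ratio of its counts to the reference, and factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Peaks x groups count matrix.
#' @return Positive numeric vector, one per group, geometric mean 1.
#' @export
size_factors_mor <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) stop("no peak has all-positive counts; cannot estimate size factors",
                     call. = FALSE)
  sf <- apply(counts, 2L, function(x) {
    r <- (log(x) - lg)[ok & x > 0]
    exp(stats::median(r))
  })
  sf / exp(mean(log(sf)))
}

#' Pseudobulk negative-binomial Wald differential accessibility
#'
#' Fits, per peak, a negative-binomial GLM with log link on the pseudobulk
#' counts with design `~ genotype + celltype` (dispersion estimated per peak
#' by maximum likelihood, no shrinkage) and log size-factor offsets, and
#' tests the genotype coefficient with a two-sided Wald test against the
#' standard normal, adjusting across peaks by Benjamini-Hochberg. Peaks whose
#' fit does not converge are flagged and excluded from the FDR correction.
#'
#' @param pb A `pseudobulk` object whose metadata contains `genotype` and the
#'   covariate columns.
#' @param covariates Character vector of adjustment covariates (default
#'   `"celltype"`).
#' @param ref_genotype Reference level of genotype (default `"WT"`).
#' @param fdr_cut Significance threshold on adjusted p (default 0.01).
#' @return A `diff_peak_result` tibble: `peak`, `log2fc`, `se`, `stat`,
#'   `p`, `fdr`, `direction` (`"up"`, `"down"`, `"ns"`), `converged`; the
#'   contrast genotype and `fdr_cut` are carried as attributes.
#' @export
nb_wald_test <- function(pb, covariates = "celltype", ref_genotype = "WT",
                         fdr_cut = 0.01) {
  stopifnot(inherits(pb, "pseudobulk"), "genotype" %in% names(pb$meta),
            all(covariates %in% names(pb$meta)))
  gl <- unique(pb$meta$genotype)
  if (length(gl) < 2L) stop("need both genotypes in the pseudobulk groups", call. = FALSE)
  if (any(table(pb$meta$genotype) < 2L)) {
    stop("need at least 2 pseudobulk groups per genotype", call. = FALSE)
  }
  sf <- pb$size_factors %||% size_factors_mor(pb$counts)
  meta <- pb$meta
  meta$genotype <- stats::relevel(factor(meta$genotype), ref = ref_genotype)
  for (cv in covariates) meta[[cv]] <- factor(meta[[cv]])
  covariates <- covariates[vapply(covariates,
                                  function(cv) nlevels(meta[[cv]]) > 1L, logical(1))]
  form <- stats::reformulate(c("genotype", covariates, "offset(log_sf_)"),
                             response = "y")
  coef_name <- paste0("genotype", setdiff(levels(meta$genotype), ref_genotype)[1])

  fit_one <- function(y) {
    dat <- cbind(data.frame(y = y, log_sf_ = log(sf)), meta)
    est <- tryCatch({
      fit <- suppressWarnings(MASS::glm.nb(form, data = dat,
                                           control = stats::glm.control(maxit = 50)))
      s <- summary(fit)$coefficients
      c(s[coef_name, "Estimate"], s[coef_name, "Std. Error"], 1)
    }, error = function(e) c(NA_real_, NA_real_, 0))
    if (is.na(est[1])) {
      # Poisson-limit fallback for peaks where the NB dispersion diverges
      est <- tryCatch({
        fit <- suppressWarnings(stats::glm(form, data = dat,
                                           family = stats::poisson()))
        s <- summary(fit)$coefficients
        c(s[coef_name, "Estimate"], s[coef_name, "Std. Error"], 1)
      }, error = function(e) c(NA_real_, NA_real_, 0))
    }
    est
  }
  est <- t(apply(pb$counts, 1L, fit_one))
  beta <- unname(est[, 1]); se <- unname(est[, 2]); converged <- unname(est[, 3] == 1)
  stat <- beta / se
  p <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  fdr <- rep(NA_real_, length(p))
  fdr[converged] <- stats::p.adjust(p[converged], "BH")
  direction <- dplyr::case_when(
    !is.na(fdr) & fdr <= fdr_cut & beta > 0 ~ "up",
    !is.na(fdr) & fdr <= fdr_cut & beta < 0 ~ "down",
    .default = "ns"
  )
  out <- tibble::tibble(peak = rownames(pb$counts),
                        log2fc = beta / log(2), se = se / log(2),
                        stat = stat, p = p, fdr = fdr,
                        direction = direction, converged = converged)
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "contrast") <- coef_name
  class(out) <- c("diff_peak_result", class(out))
  out
}

#' Wilcoxon differential DORC testing per cell type
#'
#' Within each cell type containing both genotypes, compares each DORC's
#' per-cell score between genotypes with a two-sided Wilcoxon rank-sum test;
#' p-values are Benjamini-Hochberg adjusted across all (DORC, cell type)
#' tests. The effect is the difference in mean score (alt minus reference).
#'
#' @param scores A `dorc_scores` object or dorc x cells matrix.
#' @param cells Cell metadata with `cell_id`, `genotype`, `celltype`.
#' @param ref_genotype Reference genotype (default `"WT"`).
#' @return Tibble: `dorc`, `celltype`, `effect`, `p`, `fdr`. Cell types with
#'   a single genotype, and degenerate all-tied score vectors, are skipped.
#' @export
wilcoxon_dorc_diff <- function(scores, cells, ref_genotype = "WT") {
  sc <- if (inherits(scores, "dorc_scores")) scores$scores else as.matrix(scores)
  stopifnot(identical(cells$cell_id, colnames(sc)),
            all(c("genotype", "celltype") %in% names(cells)))
  res <- purrr::map_dfr(unique(cells$celltype), function(ct) {
    in_ct <- cells$celltype == ct
    gt <- cells$genotype[in_ct]
    if (length(unique(gt)) < 2L) {
      message("skipping celltype '", ct, "': only one genotype present")
      return(NULL)
    }
    is_ref <- gt == ref_genotype
    purrr::map_dfr(rownames(sc), function(d) {
      x <- sc[d, in_ct][!is_ref]; y <- sc[d, in_ct][is_ref]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(unique(c(x, y))) < 2L) return(NULL) # all tied: undefined
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      tibble::tibble(dorc = d, celltype = ct,
                     effect = mean(x) - mean(y), p = p)
    })
  })
  if (nrow(res)) res$fdr <- stats::p.adjust(res$p, "BH")
  res
}

#' Fraction of a cell's neighbourhood carrying a query label
#'
#' For each cell, finds its `k` nearest neighbours in the embedding
#' (Euclidean, self excluded, distance ties broken by cell index) and reports
#' the fraction of neighbours whose label equals `query_label`.
#'
#' @param embedding Cells x dims numeric matrix.
#' @param labels Character/factor vector, one label per cell.
#' @param query_label The label whose local density is measured.
#' @param k Neighbourhood size (default 50).
#' @return Tibble: `cell`, `fraction` in `[0, 1]`.
#' @export
neighborhood_fraction <- function(embedding, labels, query_label, k = 50L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(length(labels) == n, k < n)
  nn <- knn_brute(embedding, k)
  is_q <- labels == query_label
  frac <- rowMeans(matrix(is_q[nn], nrow = n))
  tibble::tibble(cell = rownames(embedding) %||% seq_len(n), fraction = frac)
}

#' PCA cell embedding from normalised counts
#'
#' Depth-normalises (per-cell total, median-scaled), log1p-transforms and
#' runs PCA over cells. Component signs follow a deterministic convention:
#' the loading with the largest absolute value is made positive, so the
#' embedding does not depend on LAPACK sign whims.
#'
#' @param counts Sparse features x cells counts.
#' @param n_pcs Number of components (default 30; must not exceed either
#'   dimension).
#' @return Cells x n_pcs score matrix with the rotation in
#'   `attr(, "rotation")` and component variances in `attr(, "sdev")`.
#' @export
pca_embedding <- function(counts, n_pcs = 30L) {
  if (n_pcs > min(dim(counts))) {
    stop("n_pcs exceeds the matrix dimensions", call. = FALSE)
  }
  x <- t(log1p(as.matrix(depth_normalize(counts))))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  out <- pc$x
  rownames(out) <- colnames(counts)
  attr(out, "rotation") <- pc$rotation
  attr(out, "sdev") <- pc$sdev[seq_len(n_pcs)]
  out
}
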