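#' Functional Perturbation Score for paired WT/KO clones
#'
#' Each assay column is z-standardised across all rows (WT and KO pooled);
#' the score of a clone is the Euclidean distance between its standardised
#' WT and KO rows, summarising the magnitude of mutation-induced functional
#' change. Constant assay columns are dropped with a warning (their sd is
#' zero). The score is invariant to any affine rescaling of an assay column.
#'
#' @param table Tibble with `clone`, `genotype` (exactly one `"WT"` and one
#'   `"KO"` row per clone) and numeric assay columns; extra non-numeric
#'   columns (e.g. `cytokine_group`) are carried through.
#' @param standardize `"pooled"` (default: one standardisation over all rows)
#'   or `"by_genotype"` (each genotype standardised separately).
#' @return A `fps_result` tibble: `clone`, any carried grouping columns,
#'   `score` (>= 0) and `rank` (dense, 1 = most perturbed).
#' @export
#' @examples
#' toy <- tibble::tibble(clone = rep(c("a", "b"), 2),
#'                       genotype = rep(c("WT", "KO"), each = 2),
#'                       A = c(0, 0, 3, 0), B = c(0, 0, 4, 0))
#' functional_perturbation_score(toy)
functional_perturbation_score <- function(table,
                                          standardize = c("pooled", "by_genotype")) {
  standardize <- match.arg(standardize)
  stopifnot(all(c("clone", "genotype") %in% names(table)))
  assay_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  assay_cols <- setdiff(assay_cols, c("clone", "genotype"))
  if (length(assay_cols) == 0L) stop("no numeric assay columns", call. = FALSE)
  if (anyNA(table[assay_cols])) stop("missing assay values", call. = FALSE)
  tab_wt <- table[table$genotype == "WT", ]
  tab_ko <- table[table$genotype == "KO", ]
  clones <- unique(table$clone)
  if (!identical(sort(tab_wt$clone), sort(clones)) ||
      !identical(sort(tab_ko$clone), sort(clones)) ||
      nrow(table) != 2L * length(clones)) {
    stop("every clone needs exactly one WT and one KO row", call. = FALSE)
  }

  m <- as.matrix(table[assay_cols])
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant assay column(s): ",
            paste(assay_cols[sds == 0], collapse = ", "), call. = FALSE)
    assay_cols <- assay_cols[sds > 0]
    m <- m[, assay_cols, drop = FALSE]
  }
  if (standardize == "pooled") {
    z <- scale(m)
  } else {
    z <- m
    for (g in c("WT", "KO")) {
      ix <- table$genotype == g
      z[ix, ] <- scale(m[ix, , drop = FALSE])
    }
  }
  wt <- z[table$genotype == "WT", , drop = FALSE][match(clones, tab_wt$clone), , drop = FALSE]
  ko <- z[table$genotype == "KO", , drop = FALSE][match(clones, tab_ko$clone), , drop = FALSE]
  score <- sqrt(rowSums((wt - ko)^2))

  carry <- setdiff(names(table), c(assay_cols, "genotype", "clone"))
  carry <- carry[!vapply(table[carry], is.numeric, logical(1))]
  out <- tibble::tibble(clone = clones, score = score,
                        rank = dplyr::dense_rank(dplyr::desc(score)))
  if (length(carry)) {
    out <- dplyr::left_join(out,
                            dplyr::distinct(table[c("clone", carry)]),
                            by = "clone")
    out <- dplyr::relocate(out, dplyr::all_of(carry), .after = "clone")
  }
  class(out) <- c("fps_result", class(out))
  attr(out, "assays") <- assay_cols
  out
}

#' Correlate clone functional assays with clone TF activity
#'
#' Pairwise Pearson correlation across clones between each assay readout and
#' each TF's aggregated motif deviation Z.
#'
#' @param clone_assays Clones x assays numeric matrix (rownames = clones) or
#'   tibble with a `clone` column.
#' @param clone_tf_z Clones x TFs matrix, same clone set.
#' @return Assays x TFs correlation matrix.
#' @export
correlate_function_with_tf <- function(clone_assays, clone_tf_z) {
  a <- as_clone_matrix(clone_assays)
  z <- as_clone_matrix(clone_tf_z)
  shared <- intersect(rownames(a), rownames(z))
  if (length(shared) < 3L) stop("need at least 3 aligned clones", call. = FALSE)
  stats::cor(a[shared, , drop = FALSE], z[shared, , drop = FALSE],
             use = "pairwise.complete.obs")
}

as_clone_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("clone" %in% names(x))
    m <- as.matrix(x[vapply(x, is.numeric, logical(1))])
    rownames(m) <- x$clone
    m
  } else {
    stopifnot(!is.null(rownames(x)))
    as.matrix(x)
  }
}

#' Rank chromatin features by correlation with the perturbation score
#'
#' Spearman-correlates every clone-level chromatin feature (DORC
#' accessibility, signature deviation, ...) with the Functional Perturbation
#' Score across clones; p-values come from [stats::cor.test()] and are
#' Benjamini-Hochberg adjusted. The strongest positive correlates mark a
#' sensitised chromatin state, the strongest negative a de-sensitised one.
#'
#' @param scores `fps_result` (or tibble with `clone` and `score`).
#' @param clone_features Clones x features matrix (rownames = clones) or
#'   tibble with a `clone` column.
#' @param method Correlation method (default `"spearman"`).
#' @return Tibble ranked by descending `r`: `feature`, `r`, `p`, `fdr`,
#'   `rank`. Features with all-tied values are reported with `NA` r.
#' @export
correlate_score_with_features <- function(scores, clone_features,
                                          method = "spearman") {
  stopifnot(all(c("clone", "score") %in% names(scores)))
  f <- as_clone_matrix(clone_features)
  shared <- intersect(scores$clone, rownames(f))
  if (length(shared) < 3L) stop("need at least 3 aligned clones", call. = FALSE)
  s <- scores$score[match(shared, scores$clone)]
  res <- purrr::map_dfr(colnames(f), function(ft) {
    x <- f[shared, ft]
    if (length(unique(x)) < 2L) {
      return(tibble::tibble(feature = ft, r = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, s, method = method))
    tibble::tibble(feature = ft, r = unname(ct$estimate), p = ct$p.value)
  })
  res$fdr <- stats::p.adjust(res$p, "BH")
  res <- dplyr::arrange(res, dplyr::desc(.data$r))
  res$rank <- seq_len(nrow(res))
  res
}

#' Extract lineage barcodes from reads
#'
#' Locates the first occurrence of `flank5` in each read, takes the next
#' `bc_len` bases as the candidate barcode and requires `flank3` to follow
#' immediately and the barcode to match the constant-base template exactly.
#' Reads failing any step are discarded.
#'
#' @param reads A [Biostrings::DNAStringSet], character vector of read
#'   sequences, or path to a FASTQ file.
#' @param flank5,flank3 Flanking constant sequences.
#' @param constant_positions Named vector `position -> base` within the
#'   barcode (default [larry_constant_bases()]).
#' @param bc_len Barcode length (default 28).
#' @return A `barcode_counts` tibble (`barcode`, `count`), stage `"raw"`
#'   (attribute), with `n_reads`, `n_assigned` and `n_multi_flank` attributes.
#' @export
extract_barcodes <- function(reads, flank5 = "GTCGACGGT", flank3 = "ACCGGTAGA",
                             constant_positions = larry_constant_bases(),
                             bc_len = 28L) {
  stopifnot(nchar(flank5) > 0L, nchar(flank3) > 0L)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  seqs <- as.character(reads)
  n_reads <- length(seqs)

  pos5 <- regexpr(flank5, seqs, fixed = TRUE)
  has5 <- pos5 > 0L
  bc_start <- pos5 + nchar(flank5)
  bc <- substr(seqs, bc_start, bc_start + bc_len - 1L)
  after <- substr(seqs, bc_start + bc_len, bc_start + bc_len + nchar(flank3) - 1L)
  ok <- has5 & nchar(bc) == bc_len & after == flank3

  cpos <- as.integer(names(constant_positions))
  for (j in seq_along(cpos)) {
    ok <- ok & substr(bc, cpos[j], cpos[j]) == constant_positions[[j]]
  }
  n_multi <- sum(has5 &
                   regexpr(flank5, substr(seqs, pos5 + 1L, nchar(seqs)),
                           fixed = TRUE) > 0L)

  tab <- table(bc[ok])
  out <- tibble::tibble(barcode = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$barcode)
  class(out) <- c("barcode_counts", class(out))
  attr(out, "stage") <- "raw"
  attr(out, "n_reads") <- n_reads
  attr(out, "n_assigned") <- sum(ok)
  attr(out, "n_multi_flank") <- n_multi
  out
}

#' Error-correct and filter barcode counts
#'
#' Message-passing-style merge in the spirit of sequencing-error clustering:
#' barcodes are visited in order of descending count (ties lexicographic);
#' each barcode is merged into the most abundant earlier *surviving* barcode
#' within Levenshtein distance `radius` whose original count is at least
#' `merge_ratio` times its own, transferring its count. Total assigned reads
#' are conserved by merging; survivors with fewer than `min_count` reads are
#' then removed.
#'
#' @param raw A `barcode_counts` tibble at stage `"raw"`.
#' @param radius Maximum Levenshtein distance for a merge (default 2).
#' @param merge_ratio Minimum abundance ratio parent/child (default 5).
#' @param min_count Low-frequency cutoff; barcodes with `count < min_count`
#'   are removed (default 10).
#' @return A `barcode_counts` tibble at stage `"filtered"`.
#' @export
correct_and_filter <- function(raw, radius = 2L, merge_ratio = 5,
                               min_count = 10L) {
  stopifnot(is.data.frame(raw), all(c("barcode", "count") %in% names(raw)))
  if (nrow(raw) == 0L) {
    out <- raw
    attr(out, "stage") <- "filtered"
    return(out)
  }
  o <- order(-raw$count, raw$barcode)
  bc <- raw$barcode[o]
  orig <- raw$count[o]
  cur <- orig
  alive <- rep(TRUE, length(bc))
  if (length(bc) > 1L) {
    d <- utils::adist(bc) # full Levenshtein matrix
    for (i in seq_along(bc)[-1L]) {
      parents <- which(alive[seq_len(i - 1L)] &
                         d[i, seq_len(i - 1L)] <= radius &
                         orig[seq_len(i - 1L)] >= merge_ratio * orig[i])
      if (length(parents)) {
        p <- parents[1L] # earlier order = higher original count
        cur[p] <- cur[p] + cur[i]
        cur[i] <- 0L
        alive[i] <- FALSE
      }
    }
  }
  keep <- alive & cur >= min_count
  out <- tibble::tibble(barcode = bc[keep], count = as.integer(cur[keep])) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$barcode)
  class(out) <- c("barcode_counts", class(out))
  attr(out, "stage") <- "filtered"
  attr(out, "merged_total") <- sum(cur[alive])
  out
}

#' Compare clone sizes between paired sister samples
#'
#' Converts each sample's barcode counts to fractional abundances, joins on
#' barcode, and fits ordinary least squares of sample B's fraction on sample
#' A's. Barcodes present in only one sample are listed separately.
#'
#' @param sample_a,sample_b `barcode_counts` tibbles (filtered stage).
#' @return A `clone_pair_comparison` list: `table` (tibble `barcode`,
#'   `frac_a`, `frac_b`, `residual`, `above_line`), `slope`, `intercept`,
#'   `unmatched_a`, `unmatched_b`.
#' @export
paired_clone_sizes <- function(sample_a, sample_b) {
  fa <- tibble::tibble(barcode = sample_a$barcode,
                       frac_a = sample_a$count / sum(sample_a$count))
  fb <- tibble::tibble(barcode = sample_b$barcode,
                       frac_b = sample_b$count / sum(sample_b$count))
  j <- dplyr::inner_join(fa, fb, by = "barcode")
  if (nrow(j) == 0L) stop("no shared barcodes between samples", call. = FALSE)
  fit <- stats::lm(frac_b ~ frac_a, data = j)
  co <- stats::coef(fit)
  j$residual <- stats::resid(fit)
  j$above_line <- j$residual > 0
  structure(list(table = j,
                 slope = unname(co["frac_a"]), intercept = unname(co["(Intercept)"]),
                 unmatched_a = setdiff(fa$barcode, j$barcode),
                 unmatched_b = setdiff(fb$barcode, j$barcode)),
            class = "clone_pair_comparison")
}

#' @export
print.clone_pair_comparison <- function(x, ...) {
  cat("<clone_pair_comparison> ", nrow(x$table), " shared barcodes | slope ",
      signif(x$slope, 4), " | intercept ", signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}
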