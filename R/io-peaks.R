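#' Write a sparse count matrix as MTX triplet plus annotation tables
#'
#' Serialises a features x cells sparse matrix the way single-cell pipelines
#' exchange counts: `matrix.mtx` (MatrixMarket triplet), `features.tsv` (one
#' feature id per line) and `barcodes.tsv` (cell ids; if `cell_meta` is given
#' its columns are written alongside, with a header).
#'
#' @param counts Sparse (or dense) features x cells matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param cell_meta Optional tibble of per-cell annotations; must contain a
#'   `cell_id` column matching `colnames(counts)`.
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry feature and cell ids as dimnames", call. = FALSE)
  }
  check_ids(rownames(counts), colnames(counts))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  if (is.null(cell_meta)) {
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  } else {
    stopifnot("cell_id" %in% names(cell_meta))
    if (!identical(cell_meta$cell_id, colnames(counts))) {
      stop("cell_meta$cell_id must match colnames(counts) in order", call. = FALSE)
    }
    readr::write_tsv(cell_meta, file.path(dir, "barcodes.tsv"))
  }
  invisible(dir)
}

#' Read a sparse count matrix written by [write_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return List with `counts` (sparse dgCMatrix with dimnames) and
#'   `cell_meta` (tibble with at least `cell_id`).
#' @export
read_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feats <- readLines(file.path(dir, "features.tsv"))
  bc_path <- file.path(dir, "barcodes.tsv")
  first <- readLines(bc_path, n = 1L)
  if (grepl("\t", first) || identical(first, "cell_id")) {
    cell_meta <- readr::read_tsv(bc_path, show_col_types = FALSE, progress = FALSE)
  } else {
    cell_meta <- tibble::tibble(cell_id = readLines(bc_path))
  }
  if (nrow(m) != length(feats) || ncol(m) != nrow(cell_meta)) {
    stop("MTX header dimensions do not match annotation tables", call. = FALSE)
  }
  check_ids(feats, cell_meta$cell_id)
  dimnames(m) <- list(feats, cell_meta$cell_id)
  list(counts = m, cell_meta = cell_meta)
}

check_ids <- function(features, cells) {
  if (anyDuplicated(features)) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell ids", call. = FALSE)
  invisible(TRUE)
}

#' Quality-control filter for RNA counts
#'
#' Retains cells with at least `min_features` detected genes AND at least
#' `min_umi` total UMIs AND mitochondrial fraction strictly below `max_mito`;
#' then drops genes with zero UMIs across the surviving cells. Input order is
#' preserved.
#'
#' @param rna Sparse genes x cells count matrix.
#' @param cells Tibble of cell metadata with `cell_id` and `mito_frac`.
#' @param min_features Minimum number of genes with >= 1 UMI (inclusive).
#' @param min_umi Minimum total UMIs (inclusive).
#' @param max_mito Mitochondrial-fraction ceiling (exclusive).
#' @return List with filtered `counts` and `cells`.
#' @export
qc_filter_rna <- function(rna, cells, min_features = 200L, min_umi = 5000L,
                          max_mito = 0.05) {
  stopifnot("mito_frac" %in% names(cells), "cell_id" %in% names(cells),
            identical(cells$cell_id, colnames(rna)))
  detected <- Matrix::colSums(rna > 0)
  umis <- Matrix::colSums(rna)
  keep <- detected >= min_features & umis >= min_umi & cells$mito_frac < max_mito
  if (!any(keep)) warning("QC removed every cell", call. = FALSE)
  out <- rna[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(out) > 0
  list(counts = out[gene_keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE])
}

#' Build a disjoint fixed-width reference peak set from summit calls
#'
#' Reproduces the standard summit-ranked greedy construction: per-condition
#' summits are extended to 800 bp windows (`pos - extend`, `pos + extend`,
#' half-open width `2 * extend + 1`), pooled and sorted by descending summit
#' significance (ties broken by chromosome then position so the result is
#' invariant to input order), and a window is kept iff it overlaps no
#' previously kept window. Optional atlas peaks, also as 800 bp windows around
#' their midpoints, are appended afterwards iff they do not overlap the kept
#' set. Finally every kept window is resized to `summit +/- final_halfwidth`
#' (301 bp under defaults); disjointness at 800 bp implies disjointness after
#' shrinking.
#'
#' @param summits Data frame (or list of data frames, one per condition) with
#'   columns `chrom`, `pos`, `score`. Coordinates are 0-based.
#' @param atlas Optional data frame of atlas peaks with `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `score` (defaults to 0).
#' @param extend Half-width of the ranking windows in bp (default 400).
#' @param final_halfwidth Half-width of the emitted peaks in bp (default 150).
#' @return Tibble peak set: `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open, width `2 * final_halfwidth + 1`), `summit`, `score`, `source`
#'   (`"summit"` or `"atlas"`), `gc`, `mean_access` (both `NA`, filled later).
#' @export
#' @examples
#' build_disjoint_peakset(data.frame(chrom = "chr1", pos = 10000, score = 5))
build_disjoint_peakset <- function(summits, atlas = NULL, extend = 400L,
                                   final_halfwidth = 150L) {
  if (is.data.frame(summits)) summits <- list(summits)
  s <- dplyr::bind_rows(lapply(summits, function(d) {
    stopifnot(all(c("chrom", "pos", "score") %in% names(d)))
    tibble::tibble(chrom = as.character(d$chrom), pos = as.integer(d$pos),
                   score = as.numeric(d$score))
  }))
  if (any(s$pos < extend)) {
    stop("summit extension produces negative coordinates", call. = FALSE)
  }
  s <- dplyr::arrange(s, dplyr::desc(.data$score), .data$chrom, .data$pos)
  kept <- greedy_nonoverlap(s$chrom, s$pos - extend, s$pos + extend, seq_len(nrow(s)))
  out <- s[kept, ]
  out$source <- "summit"

  if (!is.null(atlas) && nrow(atlas) > 0L) {
    a <- tibble::tibble(chrom = as.character(atlas$chrom),
                        pos = as.integer(floor((atlas$start + atlas$end) / 2)),
                        score = if ("score" %in% names(atlas)) as.numeric(atlas$score) else 0)
    if (any(a$pos < extend)) {
      stop("atlas extension produces negative coordinates", call. = FALSE)
    }
    a <- dplyr::arrange(a, dplyr::desc(.data$score), .data$chrom, .data$pos)
    a$source <- "atlas"
    comb <- dplyr::bind_rows(out, a)
    # kept summit windows are fixed; atlas windows accepted greedily after
    kept2 <- greedy_nonoverlap(comb$chrom, comb$pos - extend, comb$pos + extend,
                               seq_len(nrow(comb)), frozen = seq_len(nrow(out)))
    out <- comb[kept2, ]
  }

  tibble::tibble(
    peak_id = sprintf("peak%05d", seq_len(nrow(out))),
    chrom = out$chrom,
    start = as.integer(out$pos - final_halfwidth),
    end = as.integer(out$pos + final_halfwidth + 1L),
    summit = out$pos, score = out$score, source = out$source,
    gc = NA_real_, mean_access = NA_real_
  )
}

# Greedy acceptance of half-open windows [s, e+1) in the given row order:
# a window is accepted iff it overlaps no previously accepted window.
# `frozen` rows are accepted unconditionally (already vetted).
greedy_nonoverlap <- function(chrom, s, e, order_ix, frozen = integer(0)) {
  n <- length(s)
  gr <- IRanges::IRanges(start = s + 1L, end = e + 1L) # 1-based closed, same widths
  accepted <- logical(n)
  accepted[frozen] <- TRUE
  for (i in order_ix) {
    if (accepted[i]) next
    acc <- which(accepted & chrom == chrom[i])
    if (length(acc) == 0L ||
        !any(IRanges::overlapsAny(gr[i], gr[acc]))) {
      accepted[i] <- TRUE
    }
  }
  which(accepted)
}

#' Read / write a peak set as BED6 + GC
#'
#' Column layout: chrom, start, end, name, score, strand (always `.`), GC
#' fraction in column 7. Coordinates are 0-based half-open as in BED.
#'
#' @param peaks Peak tibble as produced by [build_disjoint_peakset()] or
#'   [simulate_multiome()].
#' @param path File path.
#' @return `write_peaks_bed` returns `path` invisibly; `read_peaks_bed`
#'   returns a peak tibble.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- tibble::tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                        name = peaks$peak_id, score = peaks$score, strand = ".",
                        gc = peaks$gc)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand", "gc"),
                         show_col_types = FALSE, progress = FALSE)
  tibble::tibble(peak_id = bed$name, chrom = bed$chrom,
                 start = as.integer(bed$start), end = as.integer(bed$end),
                 summit = as.integer(floor((bed$start + bed$end) / 2)),
                 score = bed$score, gc = bed$gc, mean_access = NA_real_)
}

#' Write every artefact of a simulated multiome to disk
#'
#' Emits MTX + annotation tables per modality, the peak BED, the motif match
#' matrix, the cell table, the TSS table and a ground-truth TSV bundle.
#'
#' @param sim A `multiome_sim` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_multiome <- function(sim, dir) {
  stopifnot(inherits(sim, "multiome_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx(sim$atac, file.path(dir, "atac"), cell_meta = sim$cells)
  write_mtx(sim$rna, file.path(dir, "rna"), cell_meta = sim$cells)
  write_peaks_bed(sim$peaks, file.path(dir, "peaks.bed"))
  Matrix::writeMM(methods::as(sim$motifs$match, "generalMatrix"),
                  file.path(dir, "motifs.mtx"))
  readr::write_tsv(sim$motifs$meta, file.path(dir, "motifs.tsv"))
  readr::write_tsv(sim$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(sim$tss, file.path(dir, "tss.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = names(sim$truth$cell_pseudotime),
                                  pseudotime = sim$truth$cell_pseudotime,
                                  branch = sim$truth$cell_branch,
                                  clone = sim$truth$clone_of_cell),
                   file.path(tdir, "cells.tsv"))
  readr::write_tsv(sim$truth$dorc_links, file.path(tdir, "dorc_links.tsv"))
  writeLines(sim$truth$ko_peaks, file.path(tdir, "ko_peaks.txt"))
  invisible(dir)
}
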