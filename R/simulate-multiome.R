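#' Simulate a paired single-cell multiome with planted ground truth
#'
#' Generates ATAC peak counts and RNA gene counts for the same cells under a
#' negative-binomial (Gamma-Poisson) observation model. The planted structure
#' mirrors a bifurcating myeloid differentiation experiment:
#'
#' * cells sit on a pseudotime in `[0, 1]` and commit to one of
#'   `traj_branches` fates past pseudotime 0.5;
#' * TF activity programs (stemness, one per branch, plus background motifs)
#'   load onto motif-bearing peak sets and drive accessibility;
#' * a subset of genes ("DORC genes") carries `peaks_per_dorc` cis peaks
#'   within 10 kb of the TSS whose accessibility shares a latent activity with
#'   the gene's expression, the chromatin side evaluated `lead_lag` ahead in
#'   pseudotime so accessibility can foreshadow expression;
#' * KO cells receive `ko_log_fc` log2 units of extra accessibility on a
#'   designated peak subset;
#' * each clone inherits a peak-wise log-accessibility offset.
#'
#' The per-cell log-rate for a peak is
#' `baseline + sum_m loading(peak, m) * activity(m, cell) + clone offset +
#'  genotype effect`, exponentiated, rescaled so each cell's expected total
#' equals its drawn sequencing depth, and observed through
#' `rnbinom(mu, size = nb_dispersion)`.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `multiome_sim` with elements `atac` and `rna`
#'   (sparse features x cells counts), `peaks` (tibble: `peak_id`, `chrom`,
#'   `start`, `end` 0-based half-open, `summit`, `score`, `gc`,
#'   `mean_access`), `motifs` (list: binary `match` matrix peaks x motifs and
#'   a `meta` tibble), `cells` (tibble with `cell_id`, `sample`, `celltype`,
#'   `genotype`, `clone`, `mito_frac`), `tss` (tibble gene/chrom/tss/strand),
#'   and `truth` (planted ground truth: pseudotime, branch, TF activities,
#'   DORC links, KO peaks, clone offsets).
#' @export
#' @examples
#' sim <- simulate_multiome(sim_config(n_cells = 120, n_peaks = 160,
#'                                     n_genes = 30, n_motifs = 10,
#'                                     dorc_genes = 5, peaks_per_dorc = 4,
#'                                     ko_effect_peaks = 20, seed = 7))
#' dim(sim$atac)
simulate_multiome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  ## ---- cells -------------------------------------------------------------
  n <- cf$n_cells
  cell_id <- sprintf("cell%05d", seq_len(n))
  u <- stats::runif(n)
  branch <- ifelse(u > 0.5, sample.int(cf$traj_branches, n, replace = TRUE), 0L)
  branch_names <- if (cf$traj_branches == 2L) c("mono", "neutro") else
    paste0("branch", seq_len(cf$traj_branches))
  celltype <- ifelse(branch == 0L, "stem", branch_names[pmax(branch, 1L)])

  n_ko_samples <- round(cf$frac_ko * cf$n_samples)
  if (cf$frac_ko > 0) n_ko_samples <- max(1L, n_ko_samples)
  if (cf$frac_ko < 1) n_ko_samples <- min(cf$n_samples - 1L, n_ko_samples)
  if (cf$frac_ko == 0) n_ko_samples <- 0L
  if (cf$frac_ko == 1) n_ko_samples <- cf$n_samples
  sample_ix <- sample.int(cf$n_samples, n, replace = TRUE)
  genotype <- ifelse(sample_ix <= n_ko_samples, "KO", "WT")
  sample_id <- sprintf("%s_m%02d", genotype, sample_ix)
  clone_ix <- sample.int(cf$n_clones, n, replace = TRUE)
  mito_frac <- stats::rbeta(n, 2, 80)

  ## ---- genome layout -----------------------------------------------------
  gene_id <- sprintf("gene%04d", seq_len(cf$n_genes))
  tss_pos <- 100000L + (seq_len(cf$n_genes) - 1L) * 50000L
  tss <- tibble::tibble(gene = gene_id, chrom = "chr1", tss = tss_pos, strand = "+")

  # linked (DORC) peaks, then 2 uncorrelated proximal peaks per gene, then
  # distal filler peaks on chr2
  link_offsets <- seq(-9000L, 9000L, by = 600L)
  dorc_gene_ix <- seq_len(cf$dorc_genes)
  centers <- integer(0); chroms <- character(0)
  link_gene <- integer(0)
  for (d in dorc_gene_ix) {
    off <- sample(link_offsets, cf$peaks_per_dorc)
    centers <- c(centers, tss_pos[d] + off)
    chroms <- c(chroms, rep("chr1", cf$peaks_per_dorc))
    link_gene <- c(link_gene, rep(d, cf$peaks_per_dorc))
  }
  n_link <- length(centers)
  prox_off <- sample(c(-1, 1), cf$n_genes, replace = TRUE) *
    sample(4000:9500, cf$n_genes, replace = TRUE)
  centers <- c(centers, as.integer(tss_pos + prox_off))
  chroms <- c(chroms, rep("chr1", cf$n_genes))
  n_distal <- cf$n_peaks - length(centers)
  centers <- c(centers, 50000L + seq_len(n_distal) * 5000L)
  chroms <- c(chroms, rep("chr2", n_distal))
  peak_id <- sprintf("peak%05d", seq_len(cf$n_peaks))
  distal_ix <- which(chroms == "chr2")

  ## ---- latent activities -------------------------------------------------
  n_prog <- 1L + cf$traj_branches
  n_cog <- min(cf$dorc_genes, max(cf$n_motifs - n_prog, 0L))
  n_noise <- cf$n_motifs - n_prog - n_cog
  if (n_noise < 0L) stop("n_motifs too small for trajectory programs", call. = FALSE)

  act <- matrix(0, cf$n_motifs, n)           # motifs x cells true activity
  act[1L, ] <- 1.5 * (1 - u)                 # stemness program
  for (b in seq_len(cf$traj_branches)) {
    act[1L + b, ] <- 1.5 * u * (branch == b)
  }
  # DORC latent activities: a smooth phase-shifted trajectory wave plus a
  # gene-specific per-cell co-fluctuation shared by the linked peaks and the
  # gene's expression (cis covariation beyond the trajectory mode, as clone
  # and stochastic regulatory state produce in real data); only the
  # trajectory part is subject to the accessibility lead
  phase <- 2 * pi * seq_len(max(cf$dorc_genes, 1L)) / max(cf$dorc_genes, 1L)
  dorc_wave <- function(uu) {
    if (cf$dorc_genes == 0L) return(matrix(0, 0, length(uu)))
    t(vapply(seq_len(cf$dorc_genes),
             function(d) 0.8 * sin(pi * uu + phase[d]),
             numeric(length(uu))))
  }
  dorc_cofluct <- matrix(stats::rnorm(cf$dorc_genes * n, 0, 0.8),
                         max(cf$dorc_genes, 0L), n)
  D_atac <- dorc_wave(u) + dorc_cofluct
  D_rna <- dorc_wave(pmax(u - cf$lead_lag, 0)) + dorc_cofluct
  if (n_cog > 0L) act[n_prog + seq_len(n_cog), ] <- D_atac[seq_len(n_cog), , drop = FALSE]
  if (n_noise > 0L) {
    freq <- sample(1:2, n_noise, replace = TRUE)
    ph2 <- stats::runif(n_noise, 0, 2 * pi)
    for (j in seq_len(n_noise)) {
      act[n_prog + n_cog + j, ] <- 0.8 * sin(pi * u * freq[j] + ph2[j])
    }
  }

  ## ---- loadings / motif matches ------------------------------------------
  loading <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(cf$n_peaks, cf$n_motifs))
  peaks_per_set <- max(10L, round(0.05 * cf$n_peaks))
  motif_peaks <- vector("list", cf$n_motifs)
  for (m in seq_len(n_prog)) {
    motif_peaks[[m]] <- sample(distal_ix, min(peaks_per_set, length(distal_ix)))
    loading[motif_peaks[[m]], m] <- 0.8
  }
  for (d in seq_len(n_cog)) {
    ix <- which(link_gene == d)
    motif_peaks[[n_prog + d]] <- ix
    loading[ix, n_prog + d] <- 1
  }
  if (n_noise > 0L) {
    for (j in seq_len(n_noise)) {
      m <- n_prog + n_cog + j
      motif_peaks[[m]] <- sample(distal_ix, min(peaks_per_set, length(distal_ix)))
      loading[motif_peaks[[m]], m] <- 0.6
    }
  }
  # binary motif matches = loaded peaks plus sparse background matches
  match_bg <- Matrix::rsparsematrix(cf$n_peaks, cf$n_motifs, density = 0.02,
                                    rand.x = function(k) rep(1, k))
  match <- (abs(loading) > 0) + match_bg
  match <- methods::as(match > 0, "CsparseMatrix") * 1
  dimnames(match) <- list(peak_id, sprintf("motif%03d", seq_len(cf$n_motifs)))

  ## ---- knockout peaks ----------------------------------------------------
  loaded <- which(Matrix::rowSums(abs(loading)) > 0)
  ko_pool <- setdiff(distal_ix, loaded)
  if (length(ko_pool) < cf$ko_effect_peaks) ko_pool <- distal_ix
  ko_peaks_ix <- sort(sample(ko_pool, min(cf$ko_effect_peaks, length(ko_pool))))

  ## ---- ATAC rates and counts ---------------------------------------------
  baseline <- stats::rnorm(cf$n_peaks, 0, 0.3)
  clone_off <- matrix(stats::rnorm(cf$n_clones * cf$n_peaks, 0, cf$clone_offset_sd),
                      cf$n_clones, cf$n_peaks)
  B <- as.matrix(loading %*% act) + baseline
  # DORC latent on linked peaks beyond the cognate-motif set enters directly
  if (cf$dorc_genes > n_cog) {
    for (d in seq(n_cog + 1L, cf$dorc_genes)) {
      ix <- which(link_gene == d)
      B[ix, ] <- B[ix, ] + rep(D_atac[d, ], each = length(ix))
    }
  }
  B <- B + t(clone_off)[, clone_ix, drop = FALSE]
  # stochastic per-peak, per-cell accessibility noise: every peak carries
  # log-normal fluctuation beyond the NB observation model, so planted peaks
  # are not marginal-variance outliers relative to the background pool
  B <- B + matrix(stats::rnorm(cf$n_peaks * n, 0, 0.6), cf$n_peaks, n)
  is_ko <- genotype == "KO"
  if (length(ko_peaks_ix) && any(is_ko) && cf$ko_log_fc != 0) {
    B[ko_peaks_ix, is_ko] <- B[ko_peaks_ix, is_ko] + cf$ko_log_fc * log(2)
  }
  depth_atac <- stats::rlnorm(n, log(cf$depth_mean) - 0.3^2 / 2, 0.3)
  lam <- exp(B)
  lam <- sweep(lam, 2L, depth_atac / colSums(lam), "*")
  atac <- matrix(stats::rnbinom(length(lam), mu = lam, size = cf$nb_dispersion),
                 cf$n_peaks, n)
  dimnames(atac) <- list(peak_id, cell_id)
  atac <- methods::as(atac, "CsparseMatrix")

  ## ---- RNA rates and counts ----------------------------------------------
  g_base <- stats::rnorm(cf$n_genes, 0, 0.3)
  G <- matrix(g_base, cf$n_genes, n)
  if (cf$dorc_genes > 0L) {
    G[dorc_gene_ix, ] <- G[dorc_gene_ix, ] + D_rna
  }
  depth_rna <- stats::rlnorm(n, log(cf$depth_mean) - 0.3^2 / 2, 0.3)
  lam_g <- exp(G)
  lam_g <- sweep(lam_g, 2L, depth_rna / colSums(lam_g), "*")
  rna <- matrix(stats::rnbinom(length(lam_g), mu = lam_g, size = cf$nb_dispersion),
                cf$n_genes, n)
  dimnames(rna) <- list(gene_id, cell_id)
  rna <- methods::as(rna, "CsparseMatrix")

  ## ---- assembled tables --------------------------------------------------
  peaks <- tibble::tibble(
    peak_id = peak_id, chrom = chroms,
    start = as.integer(centers - 150L), end = as.integer(centers + 151L),
    summit = as.integer(centers),
    score = stats::runif(cf$n_peaks, 2, 10),
    gc = stats::runif(cf$n_peaks, 0.3, 0.7),
    mean_access = Matrix::rowMeans(atac)
  )
  cells <- tibble::tibble(
    cell_id = cell_id, sample = sample_id, celltype = celltype,
    genotype = genotype, clone = sprintf("clone%02d", clone_ix),
    mito_frac = mito_frac
  )
  motif_meta <- tibble::tibble(
    motif = colnames(match),
    kind = c(rep("program", n_prog), rep("cognate", n_cog), rep("background", n_noise)),
    cognate_gene = c(rep(NA_character_, n_prog), gene_id[seq_len(n_cog)],
                     rep(NA_character_, n_noise))
  )
  dorc_links <- tibble::tibble(
    gene = gene_id[link_gene],
    peak = peak_id[seq_len(n_link)],
    distance = as.integer(centers[seq_len(n_link)] - tss_pos[link_gene])
  )
  dimnames(act) <- list(colnames(match), cell_id)
  truth <- list(
    cell_pseudotime = stats::setNames(u, cell_id),
    cell_branch = stats::setNames(branch, cell_id),
    tf_activity = act,
    dorc_links = dorc_links,
    ko_peaks = peak_id[ko_peaks_ix],
    clone_of_cell = stats::setNames(cells$clone, cell_id),
    clone_chromatin_offset = `dimnames<-`(clone_off,
      list(sprintf("clone%02d", seq_len(cf$n_clones)), peak_id)),
    program_motifs = motif_meta$motif[motif_meta$kind != "background"]
  )
  structure(list(atac = atac, rna = rna, peaks = peaks,
                 motifs = list(match = match, meta = motif_meta),
                 cells = cells, tss = tss, truth = truth, config = cf),
            class = "multiome_sim")
}

#' @export
print.multiome_sim <- function(x, ...) {
  cat("<multiome_sim> ", ncol(x$atac), " cells | ", nrow(x$atac), " peaks | ",
      nrow(x$rna), " genes | ", ncol(x$motifs$match), " motifs\n", sep = "")
  invisible(x)
}
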