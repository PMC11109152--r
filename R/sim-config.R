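#' Configuration for the synthetic paired-multiome generator
#'
#' Bundles every knob of [simulate_multiome()] and [simulate_clone_function()]
#' into a validated list. Defaults describe a modest bifurcating myeloid
#' differentiation experiment: stem cells branching into monocytic and
#' neutrophilic fates, a knockout genotype acting on a designated peak subset,
#' and heritable clone-specific chromatin offsets.
#'
#' @param n_cells Number of cells (paired across ATAC and RNA).
#' @param n_peaks Number of accessibility peaks.
#' @param n_genes Number of genes.
#' @param n_motifs Number of TF motifs.
#' @param n_clones Number of clones cells are drawn from.
#' @param frac_ko Fraction of cells carrying the knockout genotype, in `[0, 1]`.
#' @param n_samples Number of (mouse) samples; samples are nested in genotype.
#' @param traj_branches Number of post-commitment branches (default 2:
#'   monocytic / neutrophilic).
#' @param dorc_genes Number of genes planted with >= 3 correlated cis peaks
#'   within 10 kb of their TSS.
#' @param peaks_per_dorc Planted linked peaks per DORC gene (must be >= 3).
#' @param ko_effect_peaks Number of peaks carrying the genotype effect.
#' @param ko_log_fc Planted log2 fold change on knockout peaks in KO cells.
#' @param clone_offset_sd Standard deviation of the heritable clone-specific
#'   log-accessibility offsets (0 disables clone structure).
#' @param depth_mean Expected fragments (ATAC) / UMIs (RNA) per cell.
#' @param nb_dispersion Negative-binomial size parameter shared across
#'   features; larger values approach the Poisson limit.
#' @param lead_lag Pseudotime lead of DORC accessibility over expression
#'   (positive values make chromatin foreshadow expression).
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 200, n_peaks = 150, n_genes = 40, seed = 1)
sim_config <- function(n_cells = 2000L, n_peaks = 1000L, n_genes = 200L,
                       n_motifs = 50L, n_clones = 8L, frac_ko = 0.5,
                       n_samples = 8L, traj_branches = 2L,
                       dorc_genes = 20L, peaks_per_dorc = 4L,
                       ko_effect_peaks = 100L, ko_log_fc = 1,
                       clone_offset_sd = 0.2, depth_mean = 5000,
                       nb_dispersion = 10, lead_lag = 0.1, seed = 1L) {
  for (nm in c("n_cells", "n_peaks", "n_genes", "n_motifs", "n_clones",
               "n_samples", "traj_branches", "dorc_genes", "ko_effect_peaks")) {
    assert_count(get(nm), nm, min = if (nm %in% c("dorc_genes", "ko_effect_peaks")) 0L else 1L)
  }
  assert_count(peaks_per_dorc, "peaks_per_dorc", min = 3L)
  if (!is.numeric(frac_ko) || frac_ko < 0 || frac_ko > 1) {
    stop("`frac_ko` must lie in [0, 1]", call. = FALSE)
  }
  if (depth_mean <= 0) stop("`depth_mean` must be positive", call. = FALSE)
  if (nb_dispersion <= 0) stop("`nb_dispersion` must be positive", call. = FALSE)
  if (clone_offset_sd < 0) stop("`clone_offset_sd` must be >= 0", call. = FALSE)
  if (dorc_genes * peaks_per_dorc > n_peaks) {
    stop("dorc_genes * peaks_per_dorc must not exceed n_peaks", call. = FALSE)
  }
  if (dorc_genes > n_genes) stop("dorc_genes must not exceed n_genes", call. = FALSE)
  # every gene gets 1 uncorrelated proximal peak; DORC genes add linked peaks
  min_peaks <- n_genes + dorc_genes * peaks_per_dorc
  if (n_peaks < min_peaks) {
    stop(sprintf("n_peaks must be >= n_genes + dorc_genes*peaks_per_dorc (= %d)",
                 min_peaks), call. = FALSE)
  }
  structure(list(
    n_cells = as.integer(n_cells), n_peaks = as.integer(n_peaks),
    n_genes = as.integer(n_genes), n_motifs = as.integer(n_motifs),
    n_clones = as.integer(n_clones), frac_ko = frac_ko,
    n_samples = as.integer(n_samples), traj_branches = as.integer(traj_branches),
    dorc_genes = as.integer(dorc_genes), peaks_per_dorc = as.integer(peaks_per_dorc),
    ko_effect_peaks = as.integer(ko_effect_peaks), ko_log_fc = ko_log_fc,
    clone_offset_sd = clone_offset_sd, depth_mean = depth_mean,
    nb_dispersion = nb_dispersion, lead_lag = lead_lag,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cells, " cells, ", x$n_peaks, " peaks, ",
      x$n_genes, " genes, ", x$n_motifs, " motifs, ", x$n_clones,
      " clones, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
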