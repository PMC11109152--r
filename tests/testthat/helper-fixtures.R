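# Shared fixtures: all synthetic, generated in code at test time.

small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_cells = 300L, n_peaks = 260L, n_genes = 40L, n_motifs = 10L,
         n_clones = 4L, frac_ko = 0.5, n_samples = 6L, dorc_genes = 8L,
         peaks_per_dorc = 4L, ko_effect_peaks = 30L, ko_log_fc = 1,
         clone_offset_sd = 0.15, depth_mean = 2000, nb_dispersion = 10,
         lead_lag = 0.05, seed = seed),
    list(...))
  do.call(sim_config, args)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_multiome(small_config())
    cache
  }
})

# tiny sparse matrix with dimnames for I/O round trips
toy_counts <- function(nr = 3, nc = 2, vals = NULL) {
  m <- matrix(vals %||% (seq_len(nr * nc) %% 4), nr, nc,
              dimnames = list(sprintf("f%d", seq_len(nr)),
                              sprintf("c%d", seq_len(nc))))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle for the summit-ranked greedy peak selection: test every
# kept/dropped decision by exhaustive pairwise overlap
brute_greedy <- function(df, extend = 400) {
  df <- df[order(-df$score, df$chrom, df$pos), ]
  kept <- list()
  for (i in seq_len(nrow(df))) {
    w <- c(df$pos[i] - extend, df$pos[i] + extend + 1) # half-open
    clash <- FALSE
    for (k in kept) {
      if (k$chrom == df$chrom[i] && w[1] < k$e && k$s < w[2]) clash <- TRUE
    }
    if (!clash) kept[[length(kept) + 1]] <- list(chrom = df$chrom[i],
                                                 s = w[1], e = w[2],
                                                 pos = df$pos[i])
  }
  sort(vapply(kept, function(k) k$pos, numeric(1)))
}

# paired WT/KO assay table whose columns have pooled sd exactly 1, so clone
# k1's standardized WT-KO difference is (3, 4) and its FPS is 5
fps_345_toy <- function() {
  tibble::tibble(
    clone = rep(paste0("k", 1:5), 2),
    genotype = rep(c("WT", "KO"), each = 5),
    A = c(3, 3, 1.5, 1.5, 1.5, 0, 0, 1.5, 1.5, 1.5),
    B = c(4, 2.5, 2.5, 2, 2, 0, 1.5, 1.5, 2, 2))
}

# uniform background sets over all other peaks (for toys where matching
# structure is irrelevant)
uniform_bg <- function(n_peaks, n_background = 50, seed = 1) {
  set.seed(seed)
  draws <- matrix(0L, n_peaks, n_background)
  for (i in seq_len(n_peaks)) {
    draws[i, ] <- sample(setdiff(seq_len(n_peaks), i), n_background,
                         replace = TRUE)
  }
  structure(list(draws = draws, pools = NULL,
                 peak_id = sprintf("p%d", seq_len(n_peaks)),
                 n_background = as.integer(n_background)),
            class = "background_sets")
}
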