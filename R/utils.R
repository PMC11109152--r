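# Internal helpers shared across modules.

#' @importFrom Matrix colSums rowSums t crossprod sparseMatrix Diagonal
#' @importFrom methods as is
#' @importFrom rlang .data %||%
#' @importFrom utils head adist
#' @import tibble
#' @keywords internal
"_PACKAGE"

# Depth-normalize a features x cells sparse matrix: counts / cell total,
# rescaled by the median cell total so values stay on a count-like scale.
depth_normalize <- function(counts, median_scale = TRUE) {
  tot <- Matrix::colSums(counts)
  bad <- tot == 0
  tot[bad] <- 1 # masked below by caller where relevant
  sf <- if (median_scale) stats::median(Matrix::colSums(counts)[!bad]) / tot else 1 / tot
  out <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(counts)
  out
}

# Row-wise rank transform (ties = average), returned centered and scaled to
# unit sample sd so that tcrossprod / (n-1) gives Spearman correlations.
row_rank_scale <- function(m) {
  m <- as.matrix(m)
  r <- t(apply(m, 1L, rank))
  r <- r - rowMeans(r)
  s <- sqrt(rowSums(r^2) / (ncol(r) - 1L))
  s[s == 0] <- NA_real_
  r / s
}

# Row z-score (population of cells), constant rows -> 0 with NA flagged off.
row_zscore <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0] <- NA_real_
  sweep(sweep(m, 1L, mu, "-"), 1L, sd, "/")
}

# Deterministic child seeds below 2^31 derived from one user seed.
child_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k)) %% 2147483647L
}

# Brute-force k nearest neighbours (self excluded), ties broken by index.
# Returns an n x k integer matrix of neighbour indices.
knn_brute <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
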