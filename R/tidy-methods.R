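#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.diff_peak_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("peak", "log2fc", "se", "stat", "p", "fdr",
                                 "direction", "converged")])
}

#' @export
glance.diff_peak_result <- function(x, ...) {
  tibble::tibble(n_peaks = nrow(x),
                 n_converged = sum(x$converged),
                 n_up = sum(x$direction == "up"),
                 n_down = sum(x$direction == "down"),
                 fdr_cut = attr(x, "fdr_cut"),
                 contrast = attr(x, "contrast"))
}

#' @export
tidy.fps_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.fps_result <- function(x, ...) {
  tibble::tibble(n_clones = nrow(x), n_assays = length(attr(x, "assays")),
                 median_score = stats::median(x$score),
                 max_score = max(x$score))
}

#' @export
tidy.dorc_table <- function(x, ...) {
  links <- attr(x, "links")
  dplyr::left_join(tibble::as_tibble(unclass(x)[c("gene", "n_peaks")]),
                   links, by = "gene")
}

#' @export
glance.dorc_table <- function(x, ...) {
  tibble::tibble(n_dorcs = nrow(x),
                 n_links = nrow(attr(x, "links")),
                 max_peaks = if (nrow(x)) max(x$n_peaks) else NA_integer_)
}

#' @export
tidy.clone_pair_comparison <- function(x, ...) x$table

#' @export
glance.clone_pair_comparison <- function(x, ...) {
  tibble::tibble(n_shared = nrow(x$table), slope = x$slope,
                 intercept = x$intercept,
                 n_unmatched_a = length(x$unmatched_a),
                 n_unmatched_b = length(x$unmatched_b))
}

#' @export
tidy.deviation_result <- function(x, ...) {
  tibble::tibble(
    annotation = rep(rownames(x$z), times = ncol(x$z)),
    cell = rep(colnames(x$z), each = nrow(x$z)),
    raw_dev = as.vector(x$raw_dev),
    dev = as.vector(x$dev),
    z = as.vector(x$z)
  )
}
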