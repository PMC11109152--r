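#' Simulate paired WT/KO clone functional assay readouts
#'
#' Emulates a panel of in vitro myeloid functional assays (marker expression,
#' cytokine production, ROS, phagocytosis, ...) measured on paired wild-type
#' and knockout sister clones. Each clone's KO row equals its WT row plus a
#' clone-specific perturbation magnitude along a shared unit direction, plus
#' measurement noise, so the planted perturbation is exactly the quantity the
#' Functional Perturbation Score should recover.
#'
#' @param config A [sim_config()] object (uses `n_clones` and `seed`).
#' @param n_assays Number of assay columns (>= 2).
#' @param perturbation Optional numeric vector of length `n_clones` giving the
#'   planted perturbation magnitude per clone; defaults to `|N(0, 2)|` draws.
#' @param noise_sd Standard deviation of iid assay noise added to both rows.
#' @param frac_gmcsf Fraction of clones grown in GM-CSF (the remainder in
#'   SCF), recorded in the `cytokine_group` column.
#'
#' @return A list with `table` (tibble: `clone`, `genotype`, `cytokine_group`,
#'   assay columns; exactly `2 * n_clones` rows) and `truth` (tibble: `clone`,
#'   `assay_perturbation`).
#' @export
#' @examples
#' cf <- sim_config(n_cells = 50, n_peaks = 150, n_genes = 30, n_clones = 6, seed = 3)
#' simulate_clone_function(cf, n_assays = 4)$table
simulate_clone_function <- function(config, n_assays = 8L, perturbation = NULL,
                                    noise_sd = 0.1, frac_gmcsf = 1 / 7) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_clones < 2L) stop("need at least 2 clones", call. = FALSE)
  assert_count(n_assays, "n_assays", min = 2L)
  n_assays <- as.integer(n_assays)
  set.seed(child_seed(config$seed, 101L))

  k <- config$n_clones
  clone <- sprintf("clone%02d", seq_len(k))
  if (is.null(perturbation)) perturbation <- abs(stats::rnorm(k, 0, 2))
  stopifnot(length(perturbation) == k)

  assay_names <- c("Ly6G", "CD115", "CD11b", "IL6", "ROS",
                   "phago_ecoli", "phago_saureus", "proliferation")
  assay_names <- if (n_assays <= length(assay_names)) assay_names[seq_len(n_assays)]
                 else c(assay_names, sprintf("assay%02d", seq_len(n_assays - length(assay_names))))

  # assay-specific scale/center so standardization has real work to do
  scale_a <- stats::runif(n_assays, 0.5, 3)
  center_a <- stats::rnorm(n_assays, 10, 3)
  direction <- stats::rnorm(n_assays)
  direction <- direction / sqrt(sum(direction^2))

  wt <- sweep(sweep(matrix(stats::rnorm(k * n_assays), k, n_assays),
                    2L, scale_a, "*"), 2L, center_a, "+")
  shift <- outer(perturbation, direction * scale_a)
  noise <- function() sweep(matrix(stats::rnorm(k * n_assays, 0, noise_sd), k, n_assays),
                            2L, scale_a, "*")
  ko <- wt + shift + noise()
  wt <- wt + noise()

  n_gm <- max(0L, min(k, round(frac_gmcsf * k)))
  group <- c(rep("GM-CSF", n_gm), rep("SCF", k - n_gm))

  tab <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(clone = clone, genotype = "WT",
                                    cytokine_group = group),
                     tibble::as_tibble(`colnames<-`(wt, assay_names))),
    dplyr::bind_cols(tibble::tibble(clone = clone, genotype = "KO",
                                    cytokine_group = group),
                     tibble::as_tibble(`colnames<-`(ko, assay_names)))
  )
  list(table = tab,
       truth = tibble::tibble(clone = clone, assay_perturbation = perturbation))
}

# Default LARRY-style constant-base template: 4 random bases then a fixed
# dinucleotide, repeated (…NNNNTG NNNNCA NNNNAC NNNNGA NNNN…), 28 bases total.
#' Constant-base template for lineage barcodes
#'
#' Positions (1-based) within the 28-mer barcode that carry fixed bases, as a
#' named character vector `position -> base`.
#' @return Named character vector.
#' @export
larry_constant_bases <- function() {
  c(`5` = "T", `6` = "G", `11` = "C", `12` = "A",
    `17` = "A", `18` = "C", `23` = "G", `24` = "A")
}

#' Simulate lineage-barcode sequencing reads
#'
#' Draws one 28-mer barcode per clone honouring the constant-base template,
#' then emits reads of the form `prefix + flank5 + barcode + flank3 + suffix`
#' with iid substitution errors applied to the barcode bases (constant
#' positions included, so error-bearing reads can fail the downstream
#' constant-base filter, as in real data).
#'
#' @param abundance Named or unnamed integer vector of reads per true barcode;
#'   names, if given, are used as clone labels.
#' @param flank5,flank3 Constant sequences bracketing the barcode in the read.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param bc_len Barcode length (default 28).
#' @param constant_positions Named vector `position -> base` of fixed bases
#'   (default [larry_constant_bases()]).
#' @param read_length Total read length; reads are padded with random sequence.
#'
#' @return List with `reads` (a named [Biostrings::DNAStringSet]) and `truth`
#'   (tibble: `barcode`, `count`).
#' @export
#' @examples
#' bc <- simulate_barcode_reads(c(a = 20, b = 5), error_rate = 0, seed = 1)
#' length(bc$reads)
simulate_barcode_reads <- function(abundance,
                                   flank5 = "GTCGACGGT", flank3 = "ACCGGTAGA",
                                   error_rate = 0.005, seed = 1L,
                                   bc_len = 28L,
                                   constant_positions = larry_constant_bases(),
                                   read_length = 100L) {
  if (!all(strsplit(paste0(flank5, flank3), "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("flanks must be DNA over the A/C/G/T alphabet", call. = FALSE)
  }
  stopifnot(is.numeric(abundance), all(abundance >= 0),
            error_rate >= 0, error_rate < 1)
  set.seed(as.integer(seed))
  alph <- c("A", "C", "G", "T")
  n_bc <- length(abundance)
  cpos <- as.integer(names(constant_positions))
  stopifnot(all(cpos >= 1L), all(cpos <= bc_len))

  draw_barcode <- function() {
    b <- sample(alph, bc_len, replace = TRUE)
    b[cpos] <- constant_positions
    paste(b, collapse = "")
  }
  barcodes <- character(n_bc)
  repeat {                                   # ensure distinct true barcodes
    barcodes <- vapply(seq_len(n_bc), function(i) draw_barcode(), character(1))
    if (!anyDuplicated(barcodes)) break
  }

  total <- sum(abundance)
  bc_of_read <- rep(seq_len(n_bc), times = abundance)
  bc_mat <- matrix(unlist(strsplit(barcodes[bc_of_read], "")), ncol = bc_len,
                   byrow = TRUE)
  if (error_rate > 0 && total > 0) {
    err <- which(matrix(stats::runif(total * bc_len) < error_rate,
                        nrow = total))
    if (length(err)) {
      # substitute with a uniformly drawn *different* base
      cur <- bc_mat[err]
      sub <- vapply(cur, function(b) sample(setdiff(alph, b), 1L), character(1))
      bc_mat[err] <- sub
    }
  }
  obs_bc <- apply(bc_mat, 1L, paste, collapse = "")

  pre_len <- pmax(0L, sample(8:15, total, replace = TRUE))
  core_len <- nchar(flank5) + bc_len + nchar(flank3)
  reads <- vapply(seq_len(total), function(i) {
    pre <- paste(sample(alph, pre_len[i], replace = TRUE), collapse = "")
    suf_len <- max(0L, read_length - pre_len[i] - core_len)
    suf <- paste(sample(alph, suf_len, replace = TRUE), collapse = "")
    paste0(pre, flank5, obs_bc[i], flank3, suf)
  }, character(1))
  names(reads) <- sprintf("read%06d", seq_len(total))

  cl <- names(abundance) %||% sprintf("clone%02d", seq_len(n_bc))
  list(reads = Biostrings::DNAStringSet(reads),
       truth = tibble::tibble(clone = cl, barcode = barcodes,
                              count = as.integer(abundance)))
}
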