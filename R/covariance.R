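#' Pairwise copy-number correlation across samples
#'
#' If two genes lie on the same copy-number variable segment, loss or gain
#' of depth affects both, so their copy-number estimates correlate strongly
#' across individuals. This computes the correlation matrix over assay
#' groups; groups with zero variance across the cohort have undefined
#' correlation and are reported as `NA`.
#'
#' @param cn A `copy_number_matrix` with at least 3 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric numeric matrix (groups x groups) with unit diagonal for
#'   groups of nonzero variance and `NA` rows/columns for degenerate groups.
#' @export
cn_correlation <- function(cn, method = c("pearson", "spearman")) {
  stopifnot(inherits(cn, "copy_number_matrix"))
  method <- match.arg(method)
  est <- cn$estimates
  if (nrow(est) < 3L) {
    stop("correlation needs >= 3 samples", call. = FALSE)
  }
  sds <- apply(est, 2L, stats::sd, na.rm = TRUE)
  corr <- suppressWarnings(stats::cor(est, method = method,
                                      use = "pairwise.complete.obs"))
  degenerate <- !is.finite(sds) | sds == 0
  corr[degenerate, ] <- NA_real_
  corr[, degenerate] <- NA_real_
  diag(corr)[!degenerate] <- 1
  corr
}

#' Find pairs of genes whose copy numbers covary
#'
#' @param corr Correlation matrix from [cn_correlation()].
#' @param threshold Signed correlation threshold in (0, 1]; pairs whose
#'   correlation is at or above it are reported (inclusive). Missing
#'   (zero-variance) entries never satisfy the threshold.
#' @return Data.frame `gene_a`, `gene_b`, `r`, sorted by descending `r`,
#'   each unordered pair once; the threshold is attached as an attribute.
#' @export
find_covarying_pairs <- function(corr, threshold = 0.9) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (is.null(rownames(corr))) {
    dimnames(corr) <- list(paste0("V", seq_len(nrow(corr))),
                           paste0("V", seq_len(ncol(corr))))
  }
  keep <- which(upper.tri(corr) & !is.na(corr) & corr >= threshold,
                arr.ind = TRUE)
  out <- data.frame(
    gene_a = rownames(corr)[keep[, 1L]],
    gene_b = colnames(corr)[keep[, 2L]],
    r = corr[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    out <- out[order(-out$r, out$gene_a, out$gene_b), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Group covarying pairs into copy-number covariation blocks
#'
#' Blocks are the connected components of the thresholded correlation
#' graph: pairwise evidence is chained, so genes A and C join one block
#' when both correlate with B even if their direct correlation is below
#' threshold. Each block is annotated with the minimum pairwise correlation
#' among its members, taken from the full matrix.
#'
#' @param pairs Pair table from [find_covarying_pairs()].
#' @param corr The correlation matrix the pairs were derived from.
#' @return Data.frame with one row per block: `block`, `n_members`,
#'   `members` (comma-separated, catalogue order preserved as in `corr`),
#'   `min_r`, `threshold`.
#' @export
find_blocks <- function(pairs, corr) {
  stopifnot(is.data.frame(pairs), is.matrix(corr))
  threshold <- attr(pairs, "threshold")
  if (is.null(threshold)) threshold <- NA_real_
  if (nrow(pairs) == 0L) {
    return(data.frame(block = integer(), n_members = integer(),
                      members = character(), min_r = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  blocks <- lapply(seq_len(comp$no), function(k) {
    members <- names(membership)[membership == k]
    # preserve the matrix (catalogue) ordering of members
    members <- intersect(rownames(corr), members)
    sub <- corr[members, members, drop = FALSE]
    min_r <- min(sub[upper.tri(sub)], na.rm = TRUE)
    data.frame(block = k, n_members = length(members),
               members = paste(members, collapse = ","),
               min_r = min_r, threshold = threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[order(-out$n_members, out$members), , drop = FALSE]
  out$block <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag blocks whose members overlap genomically
#'
#' Genes in one block whose genomic intervals overlap share sequencing
#' reads, so their covariation is expected as a counting artifact (e.g.
#' alternative transcripts annotated over the same locus) rather than
#' evidence of a shared copy-number variable segment.
#'
#' @param blocks Block table from [find_blocks()].
#' @param catalogue A `gene_catalogue` covering all block members (block
#'   members are assay groups; a member matches a catalogue region via its
#'   assay group).
#' @return `blocks` with added columns `overlap_artifact` (logical) and
#'   `overlapping_pairs` (comma-separated `a|b` region pairs, `""` if none).
#' @export
flag_overlap_artifacts <- function(blocks, catalogue) {
  stopifnot(is.data.frame(blocks), inherits(catalogue, "gene_catalogue"))
  ov <- find_overlapping_pairs(catalogue)
  grp <- stats::setNames(catalogue$assay_group, catalogue$symbol)
  blocks$overlap_artifact <- rep(FALSE, nrow(blocks))
  blocks$overlapping_pairs <- rep("", nrow(blocks))
  if (nrow(blocks) == 0L || nrow(ov) == 0L) return(blocks)
  for (i in seq_len(nrow(blocks))) {
    members <- strsplit(blocks$members[i], ",", fixed = TRUE)[[1L]]
    hit <- grp[ov$symbol_a] %in% members & grp[ov$symbol_b] %in% members
    if (any(hit)) {
      blocks$overlap_artifact[i] <- TRUE
      blocks$overlapping_pairs[i] <- paste(
        paste(ov$symbol_a[hit], ov$symbol_b[hit], sep = "|"),
        collapse = ",")
    }
  }
  blocks
}
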