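#' Transcripts per million from a count matrix
#'
#' Standard within-sample normalization: per sample,
#' `TPM(g) = 1e6 * (count_g / length_g) / sum_g (count_g / length_g)`.
#' Rows sum to one million except for samples with all-zero counts, which
#' are returned as zero rows with a warning.
#'
#' @param counts Integer matrix (samples x genes) of read counts.
#' @param lengths Named numeric vector of per-gene effective lengths (bp),
#'   all > 0, covering every column of `counts`.
#' @return Numeric matrix (samples x genes) of TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("counts must have gene colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!is.null(names(lengths))) lengths <- lengths[colnames(counts)]
  if (length(lengths) != ncol(counts) || any(is.na(lengths))) {
    stop("lengths must cover every gene column", call. = FALSE)
  }
  if (any(lengths <= 0)) {
    stop("gene lengths must be > 0", call. = FALSE)
  }
  rate <- sweep(counts, 2L, lengths, "/")
  denom <- rowSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts returned as zero TPM rows: ",
            paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
    denom[zero] <- 1
  }
  1e6 * rate / denom
}

#' Read / write an expression (TPM) matrix as TSV
#'
#' Layout: one row per sample, `sample` column, optional `group` column,
#' then one numeric column per gene.
#'
#' @param path TSV file path.
#' @return `read_expression_tsv()` returns a list with `tpm` (matrix) and
#'   `group` (named vector or NULL); `write_expression_tsv()` returns
#'   `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("expression TSV must have a 'sample' column", call. = FALSE)
  }
  meta <- intersect(c("sample", "group"), names(df))
  genes <- setdiff(names(df), meta)
  tpm <- as.matrix(df[, genes, drop = FALSE])
  rownames(tpm) <- df$sample
  list(tpm = tpm,
       group = if ("group" %in% meta) stats::setNames(df$group, df$sample))
}

#' @rdname read_expression_tsv
#' @param tpm Numeric matrix (samples x genes).
#' @param group Optional named character vector of per-sample group labels.
#' @export
write_expression_tsv <- function(tpm, path, group = NULL) {
  df <- data.frame(sample = rownames(tpm), stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- unname(group[rownames(tpm)])
  df <- cbind(df, as.data.frame(tpm, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group differential expression on TPM
#'
#' A deliberately simple screening stage: per gene, log2 fold change of
#' group means with a 1-TPM pseudo-count, Welch's unequal-variance t-test
#' on `log2(TPM + 1)`, and Benjamini-Hochberg FDR. It is a screen for
#' group-shifted genes in TPM space, not a count-model DE method; for
#' count-level inference use a negative-binomial framework.
#'
#' @param tpm Numeric matrix (samples x genes).
#' @param group Named character/factor vector with exactly two levels
#'   covering the samples; fold changes are `level2 / level1` in the sorted
#'   level order.
#' @param fdr_cutoff FDR flag threshold (default 0.1).
#' @param pseudo Pseudo-count in TPM units (default 1).
#' @return Data.frame per gene: `gene`, `mean_<level1>`, `mean_<level2>`,
#'   `log2_fold_change`, `p_value`, `fdr`, `significant`.
#' @export
group_differential_expression <- function(tpm, group, fdr_cutoff = 0.1,
                                          pseudo = 1) {
  tpm <- as.matrix(tpm)
  group <- group[rownames(tpm)]
  if (any(is.na(group))) {
    stop("group label missing for some samples", call. = FALSE)
  }
  levels <- sort(unique(as.character(group)))
  if (length(levels) != 2L) {
    stop("exactly two group labels required, got: ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  idx1 <- group == levels[1L]
  idx2 <- group == levels[2L]
  if (sum(idx1) < 2L || sum(idx2) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  logx <- log2(tpm + pseudo)
  m1 <- colMeans(tpm[idx1, , drop = FALSE])
  m2 <- colMeans(tpm[idx2, , drop = FALSE])
  lfc <- log2((m2 + pseudo) / (m1 + pseudo))
  pvals <- vapply(seq_len(ncol(tpm)), function(j) {
    x1 <- logx[idx1, j]
    x2 <- logx[idx2, j]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      # degenerate: constant within both groups; identical means carry no
      # evidence, differing constant means are off the t-scale
      return(if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else NA_real_)
    }
    stats::t.test(x2, x1)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(pvals, method = "BH")
  out <- data.frame(
    gene = colnames(tpm),
    mean1 = unname(m1),
    mean2 = unname(m2),
    log2_fold_change = unname(lfc),
    p_value = pvals,
    fdr = fdr,
    significant = !is.na(fdr) & fdr < fdr_cutoff,
    stringsAsFactors = FALSE
  )
  names(out)[2:3] <- paste0("mean_", levels)
  out[order(out$fdr, out$p_value), , drop = FALSE]
}

#' Correlate gene copy number with expression (dosage analysis)
#'
#' Under a gene dosage effect, transcript abundance scales with genomic
#' copy number. For each gene present in both matrices, the copy-number
#' estimate is correlated with expression across matched samples; the
#' nominal two-sided p-value, variance explained (r squared) and slope sign
#' are reported, with a BH-adjusted column alongside for transparency.
#'
#' @param cn A `copy_number_matrix` (columns are assay groups; genes are
#'   matched to expression columns by name).
#' @param tpm Numeric expression matrix (samples x genes).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"none"` (default; correlate raw TPM) or `"log1p"`.
#' @return Data.frame per matched gene: `gene`, `n`, `r`, `r_squared`,
#'   `slope_sign`, `p_value`, `fdr`, `degenerate` (TRUE where either
#'   variable has zero variance; statistics are `NA` there).
#' @export
dosage_correlation <- function(cn, tpm,
                               method = c("pearson", "spearman"),
                               transform = c("none", "log1p")) {
  stopifnot(inherits(cn, "copy_number_matrix"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  tpm <- as.matrix(tpm)
  samples <- intersect(rownames(cn$estimates), rownames(tpm))
  if (length(samples) < 3L) {
    stop("dosage correlation needs >= 3 matched samples", call. = FALSE)
  }
  genes <- intersect(colnames(cn$estimates), colnames(tpm))
  if (length(genes) == 0L) {
    stop("no genes shared between copy-number and expression matrices",
         call. = FALSE)
  }
  expr <- tpm[samples, genes, drop = FALSE]
  if (transform == "log1p") expr <- log1p(expr)
  est <- cn$estimates[samples, genes, drop = FALSE]
  rows <- lapply(genes, function(g) {
    x <- est[, g]
    y <- expr[, g]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(gene = g, n = sum(ok), r = NA_real_,
                        r_squared = NA_real_, slope_sign = NA_real_,
                        p_value = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
    r <- unname(ct$estimate)
    data.frame(gene = g, n = sum(ok), r = r, r_squared = r^2,
               slope_sign = sign(r), p_value = ct$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("gene", "n", "r", "r_squared", "slope_sign", "p_value",
                 "fdr", "degenerate")]
  out[order(out$p_value), , drop = FALSE]
}

#' Per-gene zero-expression report
#'
#' @param tpm Numeric expression matrix (samples x genes).
#' @return Data.frame per gene: `gene`, `n_zero`, `fraction_zero`.
#' @export
zero_expression_report <- function(tpm) {
  tpm <- as.matrix(tpm)
  n_zero <- colSums(tpm == 0)
  data.frame(gene = colnames(tpm),
             n_zero = unname(n_zero),
             fraction_zero = unname(n_zero) / nrow(tpm),
             stringsAsFactors = FALSE)
}
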