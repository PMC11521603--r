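#' Construct a read-count matrix
#'
#' Container for per-sample, per-region mapped read counts, the input to
#' reference-gene copy-number estimation. Columns are assay-group keys plus
#' the reference-gene key; rows are samples.
#'
#' @param counts Integer matrix (samples x regions) of non-negative mapped
#'   read counts, with rownames (sample IDs) and colnames (assay group /
#'   reference keys).
#' @param mean_coverage Optional named numeric vector of per-sample mean
#'   genome coverage (x units), used by QC filtering.
#' @param reference_gene Column name of the two-copy reference gene
#'   (default `"TP53"`).
#' @param breed Optional named character vector of per-sample breed labels.
#' @return A `read_count_matrix` object (list with elements `counts`,
#'   `mean_coverage`, `reference_gene`, `breed`).
#' @export
read_count_matrix <- function(counts, mean_coverage = NULL,
                              reference_gene = "TP53", breed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and region colnames",
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(mean_coverage)) {
    mean_coverage <- mean_coverage[rownames(counts)]
    if (any(is.na(mean_coverage))) {
      stop("mean_coverage missing for sample(s): ",
           paste(rownames(counts)[is.na(mean_coverage)], collapse = ", "),
           call. = FALSE)
    }
    names(mean_coverage) <- rownames(counts)
  }
  if (!is.null(breed)) {
    breed <- breed[rownames(counts)]
    names(breed) <- rownames(counts)
  }
  structure(list(counts = counts, mean_coverage = mean_coverage,
                 reference_gene = reference_gene, breed = breed),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat(sprintf(
    "read_count_matrix: %d samples x %d regions (reference gene %s)\n",
    nrow(x$counts), ncol(x$counts), x$reference_gene))
  if (!is.null(x$mean_coverage)) {
    cat(sprintf("  mean coverage: %.1fx-%.1fx\n",
                min(x$mean_coverage), max(x$mean_coverage)))
  }
  invisible(x)
}

#' Read / write a read-count matrix as TSV
#'
#' The TSV layout is one row per sample: a `sample` column, optional
#' `mean_coverage` and `breed` columns, then one integer column per region.
#'
#' @param path TSV file path.
#' @param reference_gene Reference-gene column name expected in the file.
#' @return `read_counts_tsv()` returns a `read_count_matrix`;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path, reference_gene = "TP53") {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("count TSV must have a 'sample' column", call. = FALSE)
  }
  meta <- intersect(c("sample", "mean_coverage", "breed"), names(df))
  region_cols <- setdiff(names(df), meta)
  counts <- as.matrix(df[, region_cols, drop = FALSE])
  rownames(counts) <- df$sample
  mc <- if ("mean_coverage" %in% meta) {
    stats::setNames(as.numeric(df$mean_coverage), df$sample)
  }
  br <- if ("breed" %in% meta) stats::setNames(df$breed, df$sample)
  read_count_matrix(counts, mean_coverage = mc,
                    reference_gene = reference_gene, breed = br)
}

#' @rdname read_counts_tsv
#' @param x A `read_count_matrix`.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "read_count_matrix"))
  df <- data.frame(sample = rownames(x$counts), stringsAsFactors = FALSE)
  if (!is.null(x$mean_coverage)) df$mean_coverage <- x$mean_coverage
  if (!is.null(x$breed)) df$breed <- x$breed
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count mapped reads per catalogue region from a BAM file
#'
#' Counts, for each region, the mapped reads whose alignment start position
#' lies inside the region (1-based inclusive). Unmapped and duplicate-flagged
#' reads are excluded. No mapping-quality filter is applied: paralogous
#' regions legitimately attract MAPQ-0 multi-mapping reads, and discarding
#' them would systematically deflate multi-copy estimates. When `regions` is
#' a `gene_catalogue`, counts of regions sharing an assay group are summed.
#'
#' @param bam_file Path to a coordinate-sorted, indexed BAM file.
#' @param regions A `gene_catalogue`, a [GenomicRanges::GRanges] with a
#'   `name`/`symbol` metadata column, or a path to a BED file.
#' @return Named integer vector of counts, one entry per assay group (or per
#'   BED region name).
#' @export
count_reads <- function(bam_file, regions) {
  if (!file.exists(bam_file)) {
    stop("BAM file not found: ", bam_file, call. = FALSE)
  }
  group <- NULL
  if (inherits(regions, "gene_catalogue")) {
    gr <- catalogue_granges(regions)
    group <- regions$assay_group
  } else if (methods::is(regions, "GRanges")) {
    gr <- regions
  } else if (is.character(regions) && length(regions) == 1L) {
    gr <- rtracklayer::import(regions, format = "bed")
  } else {
    stop("regions must be a gene_catalogue, GRanges or BED path",
         call. = FALSE)
  }
  nm <- names(gr)
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$symbol
  if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
  if (is.null(group)) group <- nm

  hdr <- Rsamtools::scanBamHeader(bam_file)[[1L]]$targets
  absent <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                    names(hdr))
  if (length(absent) > 0L) {
    stop("region contig(s) absent from BAM header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  bai <- paste0(bam_file, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_file))) {
    stop("BAM index (.bai) not found; input must be coordinate-sorted ",
         "and indexed: ", bam_file, call. = FALSE)
  }

  param <- Rsamtools::ScanBamParam(
    what = "pos",
    which = gr,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE)
  )
  res <- Rsamtools::scanBam(bam_file, param = param)
  # scanBam's `which` returns reads overlapping the region; restrict to
  # alignment start within it so overlapping regions count each read once
  # per region containing its start.
  per_region <- vapply(seq_along(gr), function(i) {
    pos <- res[[i]]$pos
    sum(!is.na(pos) &
          pos >= GenomicRanges::start(gr)[i] &
          pos <= GenomicRanges::end(gr)[i])
  }, integer(1))
  out <- tapply(per_region, group, sum)
  stats::setNames(as.integer(out), names(out))[unique(group)]
}

#' Remove samples failing a mean-coverage threshold
#'
#' Samples whose mean genome coverage fell below the threshold are removed
#' before copy-number estimation; read-depth ratios from very shallow
#' genomes are too noisy to genotype. The boundary is strict: a sample at
#' exactly the threshold is retained.
#'
#' @param x A `read_count_matrix` with `mean_coverage` metadata.
#' @param min_mean_coverage Coverage threshold in x units (default 10).
#' @return List with `retained` (filtered `read_count_matrix`, original
#'   sample order preserved) and `excluded` (data.frame of dropped samples
#'   and their coverage).
#' @export
qc_filter_samples <- function(x, min_mean_coverage = 10) {
  stopifnot(inherits(x, "read_count_matrix"))
  if (is.null(x$mean_coverage) || any(is.na(x$mean_coverage))) {
    stop("mean_coverage metadata is required for QC filtering; ",
         "refusing to retain samples of unknown coverage", call. = FALSE)
  }
  drop <- x$mean_coverage < min_mean_coverage
  excluded <- data.frame(
    sample = rownames(x$counts)[drop],
    mean_coverage = unname(x$mean_coverage[drop]),
    stringsAsFactors = FALSE
  )
  keep <- !drop
  retained <- read_count_matrix(
    x$counts[keep, , drop = FALSE],
    mean_coverage = x$mean_coverage[keep],
    reference_gene = x$reference_gene,
    breed = if (!is.null(x$breed)) x$breed[keep]
  )
  list(retained = retained, excluded = excluded)
}
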