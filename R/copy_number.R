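#' Estimate diploid copy numbers by reference-gene normalization
#'
#' For sample `s` and assay group `g`, the count ratio
#' `r(s,g) = count(s,g) / count(s, reference)` removes per-sample depth;
#' dividing by the cohort centre of `r(.,g)` removes per-region constants
#' (length, mappability); scaling by the group's expected diploid copy
#' number (`2 * reference_copies`) yields the estimate
#' \deqn{\hat{CN}(s,g) = E_g \; r(s,g) / \mathrm{centre}_s\, r(s,g).}
#' With the default mean centre, each group's cohort mean estimate equals
#' its expected copy number exactly, by construction. This anchors the
#' cohort to the expected state and therefore biases estimates when a
#' deletion or duplication allele is common; the `"median"` centre is more
#' robust in that regime (see the methods vignette).
#'
#' @param x A `read_count_matrix` containing the reference-gene column.
#' @param catalogue A `gene_catalogue` providing `expected_copy_number()`
#'   for every assay-group column of `x`.
#' @param reference_gene Reference column name; defaults to the one recorded
#'   on `x`.
#' @param centre Cohort centring statistic, `"mean"` (default) or
#'   `"median"`.
#' @return A `copy_number_matrix`: list with `estimates` (samples x groups
#'   numeric matrix), `expected_cn` (named vector), `centre`, and `breed`
#'   carried over from `x`.
#' @examples
#' counts <- matrix(c(100, 50, 100, 100, 1000, 1000), nrow = 2,
#'                  dimnames = list(c("s1", "s2"), c("A", "B", "TP53")))
#' ctl <- new_gene_catalogue(data.frame(
#'   symbol = c("A", "B"), chromosome = "chr1",
#'   start = c(1L, 5001L), end = c(2000L, 7000L),
#'   reference_copies = 1L, assay_group = c("A", "B")))
#' cn <- estimate_copy_number(read_count_matrix(counts), ctl)
#' cn$estimates
#' @export
estimate_copy_number <- function(x, catalogue,
                                 reference_gene = x$reference_gene,
                                 centre = c("mean", "median")) {
  stopifnot(inherits(x, "read_count_matrix"),
            inherits(catalogue, "gene_catalogue"))
  centre <- match.arg(centre)
  counts <- x$counts
  if (nrow(counts) < 2L) {
    stop("copy-number estimation needs >= 2 samples (the cohort centre ",
         "is undefined otherwise)", call. = FALSE)
  }
  if (!reference_gene %in% colnames(counts)) {
    stop("reference gene '", reference_gene, "' not present in counts",
         call. = FALSE)
  }
  ref <- counts[, reference_gene]
  if (any(ref == 0L)) {
    stop("zero reference-gene count for sample(s): ",
         paste(rownames(counts)[ref == 0L], collapse = ", "), call. = FALSE)
  }
  groups <- setdiff(colnames(counts), reference_gene)
  ecn <- expected_copy_number(catalogue)
  unknown <- setdiff(groups, names(ecn))
  if (length(unknown) > 0L) {
    stop("assay group(s) absent from catalogue: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ratio <- counts[, groups, drop = FALSE] / ref
  centre_fun <- if (centre == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  ctr <- centre_fun(ratio)
  est <- sweep(ratio, 2L, ctr, "/")
  est <- sweep(est, 2L, ecn[groups], "*")
  if (any(ctr == 0)) {
    zg <- groups[ctr == 0]
    warning("assay group(s) with zero cohort-centre ratio reported as ",
            "missing: ", paste(zg, collapse = ", "), call. = FALSE)
    est[, zg] <- NA_real_
  }
  structure(list(estimates = est,
                 expected_cn = ecn[groups],
                 centre = centre,
                 breed = x$breed),
            class = "copy_number_matrix")
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat(sprintf(
    "copy_number_matrix: %d samples x %d assay groups (%s-centred)\n",
    nrow(x$estimates), ncol(x$estimates), x$centre))
  invisible(x)
}

#' Read / write a copy-number matrix as TSV
#'
#' Layout: one row per sample (`sample` column, optional `breed`, then one
#' numeric column per assay group); expected copy numbers are stored in a
#' `#expected_cn:` comment line so the file round-trips.
#'
#' @param x A `copy_number_matrix`.
#' @param path TSV file path.
#' @return `write_cn_tsv()` returns `path` invisibly; `read_cn_tsv()`
#'   returns a `copy_number_matrix`.
#' @export
write_cn_tsv <- function(x, path) {
  stopifnot(inherits(x, "copy_number_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#expected_cn: ",
                    paste(names(x$expected_cn), unname(x$expected_cn),
                          sep = "=", collapse = ",")), con)
  df <- data.frame(sample = rownames(x$estimates), stringsAsFactors = FALSE)
  if (!is.null(x$breed)) df$breed <- x$breed
  df <- cbind(df, as.data.frame(x$estimates, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_tsv
#' @export
read_cn_tsv <- function(path) {
  if (!file.exists(path)) stop("CN file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  ecn <- NULL
  if (startsWith(first, "#expected_cn:")) {
    kv <- strsplit(trimws(sub("#expected_cn:", "", first)), ",")[[1L]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    ecn <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                           vapply(parts, `[`, "", 1L))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  meta <- intersect(c("sample", "breed"), names(df))
  groups <- setdiff(names(df), meta)
  est <- as.matrix(df[, groups, drop = FALSE])
  rownames(est) <- df$sample
  if (is.null(ecn)) ecn <- stats::setNames(rep(2, length(groups)), groups)
  structure(list(estimates = est, expected_cn = ecn[groups],
                 centre = "mean",
                 breed = if ("breed" %in% meta)
                   stats::setNames(df$breed, df$sample)),
            class = "copy_number_matrix")
}

#' Threshold rule for deletion / duplication calls
#'
#' Call bands are scaled from each group's expected diploid copy number:
#' `lower = expected * (1 - fraction)`, `upper = expected * (1 + fraction)`.
#' The default `fraction = 0.25` reproduces the conventional 1.5/2.5 bounds
#' for a two-copy gene and 4.5/7.5 for a six-copy group.
#'
#' @param fraction Proportion of the expected copy number defining the band
#'   (0 < fraction < 1; default 0.25).
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(fraction = 0.25) {
  stopifnot(length(fraction) == 1L, is.finite(fraction))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(fraction = fraction), class = "threshold_rule")
}

# Shared classifier: strict inequalities ("less than" / "greater than"),
# so an estimate exactly at a bound is normal. NA estimates stay NA.
.classify_cn <- function(estimate, expected_cn, rule) {
  lower <- expected_cn * (1 - rule$fraction)
  upper <- expected_cn * (1 + rule$fraction)
  out <- rep(NA_character_, length(estimate))
  ok <- !is.na(estimate)
  out[ok] <- "normal"
  out[ok & estimate < lower] <- "deletion"
  out[ok & estimate > upper] <- "duplication"
  out
}

#' Call deletions and duplications from copy-number estimates
#'
#' Applies the expected-copy-scaled [threshold_rule()] to every
#' sample-by-group estimate. Inequalities are strict; for a multi-copy
#' group, `"deletion"`/`"duplication"` read as low/high copy number
#' relative to the expected state.
#'
#' @param cn A `copy_number_matrix`.
#' @param rule A [threshold_rule()] (default fraction 0.25).
#' @return A data.frame of calls: `sample`, `assay_group`, `expected_cn`,
#'   `estimate`, `call`.
#' @export
call_cnv <- function(cn, rule = threshold_rule()) {
  stopifnot(inherits(cn, "copy_number_matrix"),
            inherits(rule, "threshold_rule"))
  est <- cn$estimates
  long <- data.frame(
    sample = rep(rownames(est), times = ncol(est)),
    assay_group = rep(colnames(est), each = nrow(est)),
    expected_cn = rep(unname(cn$expected_cn[colnames(est)]),
                      each = nrow(est)),
    estimate = as.vector(est),
    stringsAsFactors = FALSE
  )
  long$call <- .classify_cn(long$estimate, long$expected_cn, rule)
  long
}

#' Summarize CNV calls per breed and per gene
#'
#' @param calls Call table from [call_cnv()], covering every sample x group.
#' @param breed Named character vector mapping every sample in `calls` to a
#'   breed label; defaults to one pooled cohort.
#' @return List with `breed_summary` (per breed: samples, assay groups with
#'   no non-normal call, groups with CNV) and `gene_ranges` (per assay
#'   group: min/max estimate and deletion/duplication call counts across
#'   the whole cohort).
#' @export
summarize_cohort <- function(calls, breed = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("sample", "assay_group", "estimate", "call") %in%
                  names(calls)))
  samples <- unique(calls$sample)
  if (is.null(breed)) {
    breed <- stats::setNames(rep("cohort", length(samples)), samples)
  }
  unknown <- setdiff(samples, names(breed))
  if (length(unknown) > 0L) {
    stop("sample(s) missing from breed map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  calls$breed <- unname(breed[calls$sample])
  breed_summary <- do.call(rbind, lapply(split(calls, calls$breed),
    function(d) {
      nonnormal <- tapply(d$call != "normal", d$assay_group,
                          function(v) any(v, na.rm = TRUE))
      data.frame(breed = d$breed[1L],
                 n_samples = length(unique(d$sample)),
                 n_groups = length(nonnormal),
                 n_groups_no_cnv = sum(!nonnormal),
                 n_groups_cnv = sum(nonnormal),
                 stringsAsFactors = FALSE)
    }))
  rownames(breed_summary) <- NULL
  gene_ranges <- do.call(rbind, lapply(split(calls, calls$assay_group),
    function(d) {
      data.frame(assay_group = d$assay_group[1L],
                 min_estimate = suppressWarnings(min(d$estimate,
                                                     na.rm = TRUE)),
                 max_estimate = suppressWarnings(max(d$estimate,
                                                     na.rm = TRUE)),
                 n_deletion = sum(d$call == "deletion", na.rm = TRUE),
                 n_duplication = sum(d$call == "duplication", na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  rownames(gene_ranges) <- NULL
  list(breed_summary = breed_summary, gene_ranges = gene_ranges)
}
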