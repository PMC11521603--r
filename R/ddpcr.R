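#' Mean template copies per droplet from droplet counts
#'
#' In droplet digital PCR the sample is partitioned into ~20000 droplets;
#' template molecules distribute across droplets as Poisson, so the mean
#' copies per droplet is recovered from the fraction of positive droplets:
#' \deqn{\hat\lambda = -\ln(1 - k/n).}
#' A well with every droplet positive is saturated — lambda is unbounded —
#' and is an error, not a value.
#'
#' @param positives Integer vector, positive-droplet counts (`0 <= k < n`).
#' @param total Integer vector, accepted droplets per well (`n > 0`).
#' @return Numeric vector of lambda estimates (copies per droplet).
#' @examples
#' poisson_lambda(10000, 20000)  # log(2)
#' @export
poisson_lambda <- function(positives, total) {
  if (any(total <= 0)) stop("droplets_total must be > 0", call. = FALSE)
  if (any(positives < 0) || any(positives > total)) {
    stop("positives must satisfy 0 <= positives <= total", call. = FALSE)
  }
  if (any(positives == total)) {
    stop("saturated well (all droplets positive): lambda is undefined; ",
         "dilute the sample", call. = FALSE)
  }
  -log1p(-(positives / total))
}

#' Normalized copy number from target and reference lambdas
#'
#' The reference assay targets a stable two-copy gene, so
#' `CN = reference_diploid_cn * lambda_target / lambda_reference`.
#' Droplet volume cancels in the ratio; it only matters for absolute
#' concentration reporting.
#'
#' @param lambda_target,lambda_reference Mean copies per droplet for the
#'   target and reference assays (`lambda_reference > 0`).
#' @param reference_diploid_cn Diploid copy number of the reference gene
#'   (default 2).
#' @return Numeric vector of diploid copy-number estimates.
#' @export
normalized_copy_number <- function(lambda_target, lambda_reference,
                                   reference_diploid_cn = 2) {
  if (any(lambda_reference <= 0)) {
    stop("lambda_reference must be > 0", call. = FALSE)
  }
  if (any(lambda_target < 0)) {
    stop("lambda_target must be >= 0", call. = FALSE)
  }
  reference_diploid_cn * lambda_target / lambda_reference
}

#' Read a ddPCR well table from TSV
#'
#' Expected columns: `sample`, `gene` (assay group; the reference gene for
#' reference wells), `role` (`target` or `reference`), `droplets_total`,
#' `droplets_positive`.
#'
#' @param path TSV file path.
#' @return Validated data.frame of wells.
#' @export
read_ddpcr_wells <- function(path) {
  if (!file.exists(path)) stop("well file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample", "gene", "role", "droplets_total",
                "droplets_positive")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("well TSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$role %in% c("target", "reference"))) {
    stop("role must be 'target' or 'reference'", call. = FALSE)
  }
  if (any(df$droplets_total <= 0) || any(df$droplets_positive < 0) ||
      any(df$droplets_positive > df$droplets_total)) {
    stop("droplet counts must satisfy 0 <= positive <= total, total > 0",
         call. = FALSE)
  }
  df
}

#' Copy-number estimates from ddPCR wells
#'
#' Replicate wells for one sample/gene/role are merged by pooling droplets
#' before lambda estimation (the maximum-likelihood combination for Poisson
#' partitions). Each sample needs at least one reference-role well; target
#' copy number is `2 * lambda_target / lambda_reference` per sample and
#' gene. Absolute concentrations (copies/µL) are reported for audit using
#' the droplet volume, which cancels in the copy-number ratio.
#'
#' @param wells Well table as from [read_ddpcr_wells()].
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @param reference_diploid_cn Diploid CN of the reference gene (default 2).
#' @return Data.frame with one row per sample x target gene: `sample`,
#'   `gene`, `lambda_target`, `lambda_reference`, `concentration_target`
#'   (copies/µL), `cn`.
#' @export
ddpcr_copy_number <- function(wells, droplet_volume = 0.85,
                              reference_diploid_cn = 2) {
  stopifnot(is.data.frame(wells), droplet_volume > 0)
  pool <- function(d) {
    data.frame(sample = d$sample[1L], gene = d$gene[1L],
               positives = sum(d$droplets_positive),
               total = sum(d$droplets_total), stringsAsFactors = FALSE)
  }
  ref <- wells[wells$role == "reference", , drop = FALSE]
  tgt <- wells[wells$role == "target", , drop = FALSE]
  if (nrow(ref) == 0L || nrow(tgt) == 0L) {
    stop("wells must include both target and reference roles",
         call. = FALSE)
  }
  ref_pool <- do.call(rbind, lapply(split(ref, ref$sample), pool))
  no_ref <- setdiff(unique(tgt$sample), ref_pool$sample)
  if (length(no_ref) > 0L) {
    stop("no reference well for sample(s): ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  }
  lambda_ref <- stats::setNames(
    poisson_lambda(ref_pool$positives, ref_pool$total), ref_pool$sample)
  if (any(lambda_ref == 0)) {
    stop("reference well with zero positive droplets for sample(s): ",
         paste(names(lambda_ref)[lambda_ref == 0], collapse = ", "),
         call. = FALSE)
  }
  tgt_pool <- do.call(rbind, lapply(
    split(tgt, paste(tgt$sample, tgt$gene, sep = "\r")), pool))
  lt <- poisson_lambda(tgt_pool$positives, tgt_pool$total)
  lr <- unname(lambda_ref[tgt_pool$sample])
  out <- data.frame(
    sample = tgt_pool$sample,
    gene = tgt_pool$gene,
    lambda_target = lt,
    lambda_reference = lr,
    # copies/µL = (copies/droplet) / (droplet volume in nL) * 1000 nL/µL
    concentration_target = lt / droplet_volume * 1000,
    cn = normalized_copy_number(lt, lr, reference_diploid_cn),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify ddPCR copy-number estimates
#'
#' Applies the same expected-copy-scaled threshold rule used for
#' sequencing-based calls ([call_cnv()]): for a two-copy gene the default
#' bands are <1.5 / >2.5, for a six-copy group <4.5 / >7.5.
#'
#' @param results Result table from [ddpcr_copy_number()].
#' @param catalogue A `gene_catalogue` supplying expected copy numbers for
#'   the assayed genes.
#' @param rule A [threshold_rule()] (default fraction 0.25).
#' @return `results` with added `expected_cn` and `call` columns.
#' @export
classify_ddpcr <- function(results, catalogue, rule = threshold_rule()) {
  stopifnot(is.data.frame(results), inherits(catalogue, "gene_catalogue"),
            inherits(rule, "threshold_rule"))
  ecn <- expected_copy_number(catalogue)
  unknown <- setdiff(unique(results$gene), names(ecn))
  if (length(unknown) > 0L) {
    stop("gene(s) absent from catalogue: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  results$expected_cn <- unname(ecn[results$gene])
  results$call <- .classify_cn(results$cn, results$expected_cn, rule)
  results
}

#' Concordance between sequencing and ddPCR copy numbers
#'
#' Cross-platform validation on individuals measured by both assays:
#' correlation of the matched estimates, mean bias (ddPCR minus
#' sequencing), and the fraction of identical categorical calls under a
#' shared threshold rule.
#'
#' @param cn A `copy_number_matrix` of sequencing-based estimates.
#' @param ddpcr Classified ddPCR results (from [classify_ddpcr()], or
#'   [ddpcr_copy_number()] output if `catalogue` is given).
#' @param catalogue Optional `gene_catalogue` used to (re)classify both
#'   platforms; required if `ddpcr` lacks a `call` column.
#' @param rule A [threshold_rule()] applied to both platforms.
#' @return List with `n_matched`, `r`, `bias`, `call_agreement`, and the
#'   matched observation table `matched`.
#' @export
ddpcr_concordance <- function(cn, ddpcr, catalogue = NULL,
                              rule = threshold_rule()) {
  stopifnot(inherits(cn, "copy_number_matrix"), is.data.frame(ddpcr))
  if (!"call" %in% names(ddpcr)) {
    if (is.null(catalogue)) {
      stop("catalogue required to classify ddPCR results", call. = FALSE)
    }
    ddpcr <- classify_ddpcr(ddpcr, catalogue, rule)
  }
  est <- cn$estimates
  keep <- ddpcr$sample %in% rownames(est) &
    ddpcr$gene %in% colnames(est)
  matched <- ddpcr[keep, , drop = FALSE]
  if (nrow(matched) < 3L) {
    stop("concordance needs >= 3 matched sample x gene observations",
         call. = FALSE)
  }
  wgs_cn <- est[cbind(matched$sample, matched$gene)]
  wgs_call <- .classify_cn(wgs_cn,
                           unname(cn$expected_cn[matched$gene]), rule)
  ok <- !is.na(wgs_cn) & !is.na(matched$cn)
  matched$wgs_cn <- wgs_cn
  matched$wgs_call <- wgs_call
  list(
    n_matched = sum(ok),
    r = stats::cor(matched$cn[ok], wgs_cn[ok]),
    bias = mean(matched$cn[ok] - wgs_cn[ok]),
    call_agreement = mean(matched$call[ok] == wgs_call[ok]),
    matched = matched
  )
}
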