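#' Configuration for a synthetic CNV cohort
#'
#' Builds the full parameter set for [simulate_cohort()]. The defaults
#' emulate the data structure of a gene-family CNV study on a diploid
#' cohort: bi-allelic deletion/duplication alleles at Hardy-Weinberg
#' proportions for single-copy genes, one extensively multi-allelic
#' assay group (wide diploid copy-number range), a genomic segment on
#' which several genes share one CNV event, depth-proportional Poisson
#' read counts against a two-copy reference gene, dosage-coupled
#' expression with noise, and Poisson-partitioned ddPCR droplet counts.
#'
#' @param n_samples Number of diploid individuals (default 100).
#' @param catalogue A `gene_catalogue` defining assay groups, expected
#'   copy numbers and region lengths; defaults to the packaged
#'   beta-defensin catalogue.
#' @param genes Optional data.frame overriding the per-gene allele model:
#'   columns `assay_group`, `expected_cn`, `del_freq`, `dup_freq`,
#'   `region_length`. Derived from `catalogue` when `NULL` (singleton
#'   groups get `del_freq = dup_freq = 0.05`).
#' @param multiallelic List describing the multi-allelic group:
#'   `assay_group`, `hap_probs` (distribution over haploid copy counts
#'   starting at 0; must sum to 1), `region_length`. Default: the
#'   six-copy group in the catalogue with a Poisson(3) haploid
#'   distribution truncated to 0-15 copies (diploid totals 0-30).
#'   Set to `NULL` for no multi-allelic gene.
#' @param segments List of shared-segment events, each a list with
#'   `members` (assay groups), `del_freq`, `dup_freq`; member genes take
#'   CN `2 + delta` with one shared diploid delta per sample. Default: one
#'   four-gene segment (`DEFB110-1`, `DEFB110-2`, `DEFB112`, `DEFB113`)
#'   with allele frequencies 0.15/0.15 when those groups are present.
#' @param depth_mean,depth_sd,depth_min Per-sample mean coverage is drawn
#'   from Normal(`depth_mean`, `depth_sd`) truncated below at `depth_min`
#'   (defaults 30x, 5x, 5x).
#' @param read_length Read length in bp (default 150).
#' @param reference_gene,reference_length Reference gene key and region
#'   length (defaults `"TP53"`, 20000 bp); its true CN is 2 everywhere.
#' @param dispersion Negative-binomial size parameter for counts;
#'   `Inf` (default) gives pure Poisson.
#' @param dosage Optional data.frame of expression coupling: columns
#'   `assay_group`, `beta0`, `beta`, `sd` (TPM units; `beta` may be
#'   negative, 0 = null gene). A default with mostly-null genes, two
#'   positive and two negative dosage genes is built when `NULL`.
#' @param droplets_total Accepted droplets per ddPCR well (default 20000).
#' @param lambda_ref Reference-assay mean copies per droplet
#'   (default 0.2).
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @param ddpcr_panel Assay groups with ddPCR target wells; default all.
#' @param breed_probs Named probability vector for breed labels.
#' @param seed Integer RNG seed; mandatory before simulation.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 100,
                          catalogue = NULL,
                          genes = NULL,
                          multiallelic = "auto",
                          segments = "auto",
                          depth_mean = 30, depth_sd = 5, depth_min = 5,
                          read_length = 150,
                          reference_gene = "TP53",
                          reference_length = 20000,
                          dispersion = Inf,
                          dosage = NULL,
                          droplets_total = 20000,
                          lambda_ref = 0.2,
                          droplet_volume = 0.85,
                          ddpcr_panel = NULL,
                          breed_probs = c(Holstein = 0.30, Braunvieh = 0.30,
                                          Charolais = 0.15, Limousin = 0.10,
                                          Angus = 0.05, Simmental = 0.05,
                                          Hereford = 0.05),
                          seed = NULL) {
  if (is.null(catalogue) && is.null(genes)) {
    catalogue <- load_catalogue(system.file(
      "extdata", "bdefensin_catalogue.tsv", package = "defcnv"))
  }
  if (is.null(genes)) {
    ecn <- expected_copy_number(catalogue)
    span <- tapply(catalogue$end - catalogue$start + 1L,
                   catalogue$assay_group, sum)[names(ecn)]
    genes <- data.frame(assay_group = names(ecn),
                        expected_cn = unname(ecn),
                        del_freq = 0.05, dup_freq = 0.05,
                        region_length = as.numeric(span),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("assay_group", "expected_cn", "del_freq", "dup_freq",
                  "region_length") %in% names(genes)))
  if (any(genes$del_freq < 0 | genes$del_freq > 1 |
            genes$dup_freq < 0 | genes$dup_freq > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (identical(multiallelic, "auto")) {
    multi_grp <- genes$assay_group[genes$expected_cn > 2]
    multiallelic <- if (length(multi_grp) > 0L) {
      p <- stats::dpois(0:15, lambda = 3)
      list(assay_group = multi_grp[1L],
           hap_probs = p / sum(p),
           region_length = genes$region_length[
             match(multi_grp[1L], genes$assay_group)])
    }
  }
  if (!is.null(multiallelic)) {
    if (abs(sum(multiallelic$hap_probs) - 1) > 1e-8) {
      stop("multiallelic hap_probs must sum to 1", call. = FALSE)
    }
    genes <- genes[genes$assay_group != multiallelic$assay_group, ,
                   drop = FALSE]
  }
  if (identical(segments, "auto")) {
    default_members <- c("DEFB110-1", "DEFB110-2", "DEFB112", "DEFB113")
    segments <- if (all(default_members %in% genes$assay_group)) {
      list(list(members = default_members, del_freq = 0.15,
                dup_freq = 0.15))
    } else {
      list()
    }
  }
  for (seg in segments) {
    miss <- setdiff(seg$members, genes$assay_group)
    if (length(miss) > 0L) {
      stop("segment member(s) not in gene table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(dosage)) {
    all_groups <- c(genes$assay_group,
                    if (!is.null(multiallelic)) multiallelic$assay_group)
    dosage <- data.frame(assay_group = all_groups, beta0 = 50, beta = 0,
                         sd = 15, stringsAsFactors = FALSE)
    plant <- function(group, beta, sd) {
      i <- match(group, dosage$assay_group)
      if (!is.na(i)) dosage[i, c("beta", "sd")] <<- list(beta, sd)
    }
    # two positive and two negative dosage genes; effect sizes chosen for
    # a planted variance-explained around 10% (small, as dosage effects
    # on expression typically are)
    plant("DEFB10", 10, 15)
    plant("DEFB1-1", 8, 15)
    plant("DEFB127", -10, 15)
    if (!is.null(multiallelic)) plant(multiallelic$assay_group, -5, 35)
  }
  if (is.null(ddpcr_panel)) {
    ddpcr_panel <- c(genes$assay_group,
                     if (!is.null(multiallelic)) multiallelic$assay_group)
  }
  structure(list(
    n_samples = as.integer(n_samples), genes = genes,
    multiallelic = multiallelic, segments = segments,
    depth_mean = depth_mean, depth_sd = depth_sd, depth_min = depth_min,
    read_length = read_length, reference_gene = reference_gene,
    reference_length = reference_length, dispersion = dispersion,
    dosage = dosage, droplets_total = as.integer(droplets_total),
    lambda_ref = lambda_ref, droplet_volume = droplet_volume,
    ddpcr_panel = ddpcr_panel,
    breed_probs = breed_probs / sum(breed_probs), seed = seed
  ), class = "cohort_config")
}

# Two haploid draws per individual; allele carries 0 (deletion), 1
# (normal) or 2 (duplication) copies, so diploid CN in 0..4 and
# heterozygote/homozygote structure follows Hardy-Weinberg.
.draw_biallelic <- function(n, del_freq, dup_freq) {
  probs <- c(del_freq, 1 - del_freq - dup_freq, dup_freq)
  a1 <- sample(0:2, n, replace = TRUE, prob = probs)
  a2 <- sample(0:2, n, replace = TRUE, prob = probs)
  as.integer(a1 + a2)
}

#' Simulate true diploid copy numbers
#'
#' Per sample and assay group, diploid CN is the sum of two independently
#' drawn haploid allele copy counts. Genes in a shared segment receive one
#' identical diploid perturbation (`2 + delta`) per sample; the
#' multi-allelic group draws haploid counts from its configured
#' distribution.
#'
#' @param config A [cohort_config()].
#' @return Integer matrix (samples x assay groups) of true copy numbers.
#' @export
simulate_true_cn <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  genes <- config$genes
  seg_members <- unlist(lapply(config$segments, `[[`, "members"))
  groups <- c(genes$assay_group,
              if (!is.null(config$multiallelic))
                config$multiallelic$assay_group)
  cn <- matrix(NA_integer_, nrow = n, ncol = length(groups),
               dimnames = list(sprintf("S%03d", seq_len(n)), groups))
  for (i in seq_len(nrow(genes))) {
    g <- genes$assay_group[i]
    if (g %in% seg_members) next
    cn[, g] <- .draw_biallelic(n, genes$del_freq[i], genes$dup_freq[i])
  }
  for (seg in config$segments) {
    delta <- .draw_biallelic(n, seg$del_freq, seg$dup_freq) - 2L
    for (g in seg$members) cn[, g] <- 2L + delta
  }
  ma <- config$multiallelic
  if (!is.null(ma)) {
    counts <- seq_along(ma$hap_probs) - 1L
    h1 <- sample(counts, n, replace = TRUE, prob = ma$hap_probs)
    h2 <- sample(counts, n, replace = TRUE, prob = ma$hap_probs)
    cn[, ma$assay_group] <- as.integer(h1 + h2)
  }
  cn
}

#' Simulate per-region read counts from true copy numbers
#'
#' Counts follow `Poisson(depth_s * length_g * CN(s,g) / (2 * read_length))`
#' (or negative binomial around the same mean when `dispersion` is
#' finite); the reference gene is simulated at CN 2 for every sample, and
#' the drawn per-sample depth is stored as `mean_coverage` metadata.
#'
#' @param true_cn Integer matrix from [simulate_true_cn()].
#' @param config The same [cohort_config()].
#' @return A `read_count_matrix` including the reference-gene column.
#' @export
simulate_read_counts <- function(true_cn, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(true_cn)
  depth <- pmax(config$depth_min,
                stats::rnorm(n, config$depth_mean, config$depth_sd))
  lens <- c(stats::setNames(config$genes$region_length,
                            config$genes$assay_group),
            if (!is.null(config$multiallelic))
              stats::setNames(config$multiallelic$region_length,
                              config$multiallelic$assay_group))
  lens <- lens[colnames(true_cn)]
  mu <- (depth * t(t(true_cn) * lens)) / (2 * config$read_length)
  mu_ref <- depth * config$reference_length * 2 / (2 * config$read_length)
  draw <- function(m) {
    if (is.finite(config$dispersion)) {
      stats::rnbinom(length(m), mu = m, size = config$dispersion)
    } else {
      stats::rpois(length(m), m)
    }
  }
  counts <- matrix(draw(mu), nrow = n, dimnames = dimnames(true_cn))
  counts <- cbind(counts,
                  matrix(draw(mu_ref), ncol = 1,
                         dimnames = list(rownames(true_cn),
                                         config$reference_gene)))
  read_count_matrix(counts,
                    mean_coverage = stats::setNames(depth,
                                                    rownames(true_cn)),
                    reference_gene = config$reference_gene)
}

#' Simulate dosage-coupled expression
#'
#' `TPM(s,g) = max(0, beta0_g + beta_g * CN(s,g) + Normal(0, sd_g))`.
#' Values are on the TPM scale but are not re-closed to a row sum of one
#' million: compositional re-normalization would couple all genes and
#' distort the planted per-gene dosage correlations.
#'
#' @inheritParams simulate_read_counts
#' @return Numeric matrix (samples x assay groups) of expression values.
#' @export
simulate_expression <- function(true_cn, config) {
  stopifnot(inherits(config, "cohort_config"))
  dosage <- config$dosage
  groups <- intersect(colnames(true_cn), dosage$assay_group)
  expr <- sapply(groups, function(g) {
    i <- match(g, dosage$assay_group)
    pmax(0, dosage$beta0[i] + dosage$beta[i] * true_cn[, g] +
           stats::rnorm(nrow(true_cn), 0, dosage$sd[i]))
  })
  rownames(expr) <- rownames(true_cn)
  expr
}

#' Simulate ddPCR droplet wells
#'
#' Target wells receive `lambda = lambda_ref * CN / 2`; positives are
#' binomial with success probability `1 - exp(-lambda)`. One reference
#' well per sample is simulated at `lambda_ref` (reference true CN 2).
#'
#' @inheritParams simulate_read_counts
#' @return Well table in the layout of [read_ddpcr_wells()].
#' @export
simulate_ddpcr_wells <- function(true_cn, config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- intersect(config$ddpcr_panel, colnames(true_cn))
  samples <- rownames(true_cn)
  n <- length(samples)
  total <- config$droplets_total
  lam_t <- config$lambda_ref * true_cn[, panel, drop = FALSE] / 2
  if (any(1 - exp(-lam_t) > 0.999)) {
    warning("ddPCR wells near saturation (positive fraction > 0.999): ",
            "assay outside dynamic range", call. = FALSE)
  }
  tgt <- data.frame(
    sample = rep(samples, times = length(panel)),
    gene = rep(panel, each = n),
    role = "target",
    droplets_total = total,
    droplets_positive = stats::rbinom(n * length(panel), total,
                                      1 - exp(-as.vector(lam_t))),
    stringsAsFactors = FALSE
  )
  ref <- data.frame(
    sample = samples,
    gene = config$reference_gene,
    role = "reference",
    droplets_total = total,
    droplets_positive = stats::rbinom(n, total,
                                      1 - exp(-config$lambda_ref)),
    stringsAsFactors = FALSE
  )
  out <- rbind(tgt, ref)
  out[order(out$sample, out$role, out$gene), , drop = FALSE]
}

#' Simulate a complete cohort with ground truth
#'
#' Runs all generators under one seed and returns every layer the
#' downstream analysis consumes, plus the truth it is judged against.
#' A seed is mandatory: simulated cohorts must be reproducible.
#'
#' @param config A [cohort_config()] with a non-`NULL` `seed`.
#' @return A `synthetic_cohort` list: `true_cn`, `counts`
#'   (`read_count_matrix`), `expression`, `wells`, `breed`, `config`.
#' @examples
#' cfg <- cohort_config(n_samples = 20, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$true_cn)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$seed)) {
    stop("config$seed must be set: simulated cohorts are seeded, never ",
         "drawn from ambient entropy", call. = FALSE)
  }
  set.seed(config$seed)
  true_cn <- simulate_true_cn(config)
  counts <- simulate_read_counts(true_cn, config)
  expression <- simulate_expression(true_cn, config)
  wells <- simulate_ddpcr_wells(true_cn, config)
  breed <- stats::setNames(
    sample(names(config$breed_probs), config$n_samples, replace = TRUE,
           prob = config$breed_probs),
    rownames(true_cn))
  counts$breed <- breed
  structure(list(true_cn = true_cn, counts = counts,
                 expression = expression, wells = wells, breed = breed,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples x %d assay groups (seed %s)\n",
    nrow(x$true_cn), ncol(x$true_cn),
    format(x$config$seed)))
  invisible(x)
}

#' Dosage slope for a target variance explained
#'
#' Utility for planting expression-dosage effects: returns the slope
#' `beta` such that a linear dosage model with noise standard deviation
#' `sd_noise` on a copy-number variable of standard deviation `sd_cn`
#' has population variance explained `r2`
#' (`beta = sd_noise / sd_cn * sqrt(r2 / (1 - r2))`).
#'
#' @param r2 Target population r squared in (0, 1).
#' @param sd_cn Standard deviation of the copy-number variable.
#' @param sd_noise Expression noise standard deviation.
#' @return Positive slope; negate for a negative dosage effect.
#' @export
dosage_slope_for_r2 <- function(r2, sd_cn, sd_noise) {
  stopifnot(r2 > 0, r2 < 1, sd_cn > 0, sd_noise > 0)
  sd_noise / sd_cn * sqrt(r2 / (1 - r2))
}
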