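#' Run the full copy-number analysis pipeline
#'
#' Composes the stages — cohort input (simulated or from files), coverage
#' QC, reference-gene copy-number estimation, threshold calling, cohort
#' summary, covariance-block detection, ddPCR quantification and
#' concordance, and dosage correlation — into one reproducible run that
#' writes every stage output as TSV plus a JSON run manifest.
#'
#' The configuration is a named list (or a YAML file with the same keys):
#' \describe{
#'   \item{simulate}{Named list of [cohort_config()] arguments (must
#'     include `seed`); mutually exclusive with `counts_tsv`.}
#'   \item{counts_tsv, expression_tsv, wells_tsv, catalogue_tsv}{Input
#'     file paths for real-data mode; `catalogue_tsv` defaults to the
#'     packaged beta-defensin catalogue.}
#'   \item{min_coverage}{QC threshold in x units (default 10; `NULL`
#'     skips QC).}
#'   \item{threshold_fraction}{Call-band fraction (default 0.25).}
#'   \item{correlation_threshold, correlation_method}{Covariation pair
#'     threshold (default 0.9) and method (default `"pearson"`).}
#'   \item{dosage_method, dosage_transform}{Dosage-correlation options
#'     (defaults `"pearson"`, `"none"`).}
#' }
#'
#' The manifest records the package version, the thresholds actually
#' used, the seed, per-stage timings and an MD5 digest of every output
#' file; it is written last, so its presence marks a complete run.
#'
#' @param config Named list or path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(min_coverage = 10, threshold_fraction = 0.25,
                   correlation_threshold = 0.9,
                   correlation_method = "pearson",
                   dosage_method = "pearson", dosage_transform = "none")
  for (nm in names(defaults)) {
    if (!nm %in% names(config)) config[[nm]] <- defaults[[nm]]
  }
  simulate_mode <- !is.null(config$simulate)
  if (!simulate_mode && is.null(config$counts_tsv)) {
    stop("config must provide either 'simulate' or 'counts_tsv'",
         call. = FALSE)
  }
  # pre-flight: every named input must exist before any stage runs
  for (key in c("counts_tsv", "expression_tsv", "wells_tsv",
                "catalogue_tsv")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for '", key, "' not found: ", p, call. = FALSE)
    }
  }
  if (simulate_mode && is.null(config$simulate$seed)) {
    stop("simulate mode requires an explicit seed", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package = "defcnv",
    version = as.character(utils::packageVersion("defcnv")),
    mode = if (simulate_mode) "simulate" else "files",
    seed = if (simulate_mode) config$simulate$seed,
    parameters = config[names(defaults)],
    status = "failed", stages = list(), outputs = list()
  )
  outputs <- character()
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      .write_manifest(manifest, outdir, outputs)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }
  emit <- function(file) outputs <<- c(outputs, file.path(outdir, file))

  catalogue <- stage("catalogue", {
    path <- config$catalogue_tsv
    if (is.null(path)) {
      path <- system.file("extdata", "bdefensin_catalogue.tsv",
                          package = "defcnv")
    }
    load_catalogue(path)
  })

  input <- stage("input", {
    if (simulate_mode) {
      cfg <- do.call(cohort_config, config$simulate)
      ch <- simulate_cohort(cfg)
      write_counts_tsv(ch$counts, file.path(outdir, "counts.tsv"))
      emit("counts.tsv")
      list(counts = ch$counts, cohort = ch)
    } else {
      list(counts = read_counts_tsv(config$counts_tsv), cohort = NULL)
    }
  })
  cohort <- input$cohort
  counts <- input$counts

  counts <- stage("qc", {
    if (is.null(config$min_coverage) || is.null(counts$mean_coverage)) {
      counts
    } else {
      qc <- qc_filter_samples(counts, config$min_coverage)
      utils::write.table(qc$excluded,
                         file.path(outdir, "qc_excluded.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("qc_excluded.tsv")
      qc$retained
    }
  })

  cn <- stage("copy_number", {
    cn <- estimate_copy_number(counts, catalogue)
    write_cn_tsv(cn, file.path(outdir, "cn_matrix.tsv"))
    emit("cn_matrix.tsv")
    cn
  })

  rule <- threshold_rule(config$threshold_fraction)
  calls <- stage("calls", {
    calls <- call_cnv(cn, rule)
    utils::write.table(calls, file.path(outdir, "cnv_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("cnv_calls.tsv")
    calls
  })

  stage("summary", {
    summ <- summarize_cohort(calls, breed = counts$breed)
    utils::write.table(summ$breed_summary,
                       file.path(outdir, "breed_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$gene_ranges,
                       file.path(outdir, "gene_ranges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("breed_summary.tsv"); emit("gene_ranges.tsv")
    summ
  })

  stage("covariance", {
    corr <- cn_correlation(cn, method = config$correlation_method)
    pairs <- find_covarying_pairs(corr, config$correlation_threshold)
    blocks <- flag_overlap_artifacts(find_blocks(pairs, corr), catalogue)
    utils::write.table(pairs, file.path(outdir, "covariance_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(blocks, file.path(outdir, "covariance_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("covariance_pairs.tsv"); emit("covariance_blocks.tsv")
    blocks
  })

  wells <- if (simulate_mode) cohort$wells
           else if (!is.null(config$wells_tsv))
             read_ddpcr_wells(config$wells_tsv)
  if (!is.null(wells)) {
    stage("ddpcr", {
      res <- classify_ddpcr(
        ddpcr_copy_number(wells, droplet_volume =
                            if (simulate_mode)
                              cohort$config$droplet_volume else 0.85),
        catalogue, rule)
      utils::write.table(res, file.path(outdir, "ddpcr_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("ddpcr_results.tsv")
      conc <- ddpcr_concordance(cn, res, rule = rule)
      utils::write.table(
        data.frame(n_matched = conc$n_matched, r = conc$r,
                   bias = conc$bias,
                   call_agreement = conc$call_agreement),
        file.path(outdir, "ddpcr_concordance.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      emit("ddpcr_concordance.tsv")
      conc
    })
  }

  expr <- if (simulate_mode) list(tpm = cohort$expression, group = NULL)
          else if (!is.null(config$expression_tsv))
            read_expression_tsv(config$expression_tsv)
  if (!is.null(expr)) {
    stage("expression", {
      dc <- dosage_correlation(cn, expr$tpm,
                               method = config$dosage_method,
                               transform = config$dosage_transform)
      utils::write.table(dc, file.path(outdir, "dosage_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("dosage_correlation.tsv")
      zr <- zero_expression_report(expr$tpm)
      utils::write.table(zr, file.path(outdir, "zero_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("zero_expression.tsv")
      if (!is.null(expr$group)) {
        de <- group_differential_expression(expr$tpm, expr$group)
        utils::write.table(de,
                           file.path(outdir,
                                     "differential_expression.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("differential_expression.tsv")
      }
      dc
    })
  }

  manifest$status <- "ok"
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  .write_manifest(manifest, outdir, outputs)
  invisible(manifest)
}

.write_manifest <- function(manifest, outdir, outputs) {
  existing <- outputs[file.exists(outputs)]
  manifest$outputs <- as.list(
    stats::setNames(unname(tools::md5sum(existing)), basename(existing)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
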