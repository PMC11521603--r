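# Shared fixture builders: everything is generated in code at test time.

# Minimal catalogue from parallel vectors.
make_catalogue <- function(symbol, chromosome, start, end,
                           reference_copies = 1L, assay_group = symbol) {
  new_gene_catalogue(data.frame(
    symbol = symbol, chromosome = chromosome,
    start = as.integer(start), end = as.integer(end),
    reference_copies = as.integer(reference_copies),
    assay_group = assay_group, stringsAsFactors = FALSE))
}

packaged_catalogue <- function() {
  load_catalogue(system.file("extdata", "bdefensin_catalogue.tsv",
                             package = "defcnv"))
}

# Random catalogue for property tests (possibly overlapping intervals).
random_catalogue <- function(n, n_chrom = 3L) {
  start <- sample.int(5000L, n, replace = TRUE)
  make_catalogue(
    symbol = sprintf("G%03d", seq_len(n)),
    chromosome = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(500L, n, replace = TRUE) - 1L
  )
}

# Brute-force all-pairs closed-interval overlap oracle.
brute_force_overlaps <- function(catalogue) {
  out <- list()
  n <- nrow(catalogue)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (catalogue$chromosome[i] == catalogue$chromosome[j] &&
            max(catalogue$start[i], catalogue$start[j]) <=
              min(catalogue$end[i], catalogue$end[j])) {
        out[[length(out) + 1L]] <- c(catalogue$symbol[i],
                                     catalogue$symbol[j])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(symbol_a = character(), symbol_b = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(symbol_a = m[, 1L], symbol_b = m[, 2L],
             stringsAsFactors = FALSE)
}

pair_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(pmin(df[[1L]], df[[2L]]), pmax(df[[1L]], df[[2L]]),
             sep = "|"))
}

# Write a SAM file and convert it to a sorted, indexed BAM.
# reads: data.frame(chrom, pos, flag); contigs: named lengths.
make_test_bam <- function(reads, contigs = c(chrT = 100000L),
                          dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  reads <- reads[order(match(reads$chrom, names(contigs)), reads$pos), ,
                 drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  body <- sprintf(
    "r%03d\t%d\t%s\t%d\t30\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    seq_len(nrow(reads)), reads$flag, reads$chrom, reads$pos)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# Small simulation panel: n_single singleton genes (2 kb), optionally a
# 3-gene shared segment and a multi-allelic gene, for fast replicates.
small_panel_config <- function(n_samples, seed, n_single = 6L,
                               del_freq = 0.05, dup_freq = 0.05,
                               segment = FALSE, seg_freq = 0.15,
                               multiallelic = FALSE, ...) {
  genes <- data.frame(
    assay_group = sprintf("GEN%02d", seq_len(n_single)),
    expected_cn = 2, del_freq = del_freq, dup_freq = dup_freq,
    region_length = 2000, stringsAsFactors = FALSE)
  segs <- list()
  if (segment) {
    seg_genes <- data.frame(
      assay_group = c("SEGA", "SEGB", "SEGC"), expected_cn = 2,
      del_freq = 0, dup_freq = 0, region_length = 2000,
      stringsAsFactors = FALSE)
    genes <- rbind(genes, seg_genes)
    segs <- list(list(members = seg_genes$assay_group,
                      del_freq = seg_freq, dup_freq = seg_freq))
  }
  ma <- NULL
  if (multiallelic) {
    p <- stats::dpois(0:15, 3)
    ma <- list(assay_group = "MULTI", hap_probs = p / sum(p),
               region_length = 2500)
  }
  cohort_config(n_samples = n_samples, genes = genes, multiallelic = ma,
                segments = segs, seed = seed, ...)
}

# Catalogue matching small_panel_config groups (disjoint 2 kb intervals),
# so estimate_copy_number / classify can look up expected copy numbers.
small_panel_catalogue <- function(config) {
  groups <- c(config$genes$assay_group,
              if (!is.null(config$multiallelic))
                config$multiallelic$assay_group)
  rc <- rep(1L, length(groups))
  if (!is.null(config$multiallelic)) {
    rc[groups == config$multiallelic$assay_group] <- 3L
  }
  start <- seq_along(groups) * 10000L
  make_catalogue(symbol = groups, chromosome = "chr1", start = start,
                 end = start + 1999L, reference_copies = rc,
                 assay_group = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
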