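#' Load a gene catalogue from TSV
#'
#' Reads an annotated gene catalogue describing the regions quantified by the
#' copy-number pipeline. Coordinates are 1-based inclusive on the named
#' assembly; thousands separators (commas) are accepted, as gene locations are
#' commonly printed that way. Near-identical paralogous regions that short
#' reads cannot distinguish are grouped into a single *assay group* and
#' quantified jointly; `reference_copies` is the number of assembly copies the
#' group represents, so its expected diploid copy number is
#' `2 * reference_copies`.
#'
#' @param path Path to a tab-separated file with header columns `symbol`,
#'   `chromosome`, `start`, `end`, `reference_copies`, `assay_group`, and
#'   optionally `orthologue` and `protein_sequence`.
#' @param assembly Assembly label stored on the catalogue
#'   (default `"ARS-UCD1.2"`).
#' @return A `gene_catalogue`: a `data.frame` with one row per region and an
#'   `assembly` attribute.
#' @examples
#' cat_path <- system.file("extdata", "bdefensin_catalogue.tsv",
#'                         package = "defcnv")
#' ctl <- load_catalogue(cat_path)
#' nrow(ctl)
#' head(expected_copy_number(ctl))
#' @export
load_catalogue <- function(path, assembly = "ARS-UCD1.2") {
  if (!file.exists(path)) {
    stop("catalogue file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  required <- c("symbol", "chromosome", "start", "end",
                "reference_copies", "assay_group")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("catalogue is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    symbol           = raw$symbol,
    chromosome       = raw$chromosome,
    start            = .parse_coord(raw$start, "start"),
    end              = .parse_coord(raw$end, "end"),
    reference_copies = .parse_coord(raw$reference_copies, "reference_copies"),
    assay_group      = raw$assay_group,
    orthologue       = if ("orthologue" %in% names(raw)) raw$orthologue
                       else rep(NA_character_, nrow(raw)),
    protein_sequence = if ("protein_sequence" %in% names(raw))
                         raw$protein_sequence
                       else rep(NA_character_, nrow(raw)),
    stringsAsFactors = FALSE
  )
  new_gene_catalogue(df, assembly = assembly)
}

# Integer coordinates with optional comma thousands separators; errors name
# the first offending data line (header is line 1).
.parse_coord <- function(x, col) {
  y <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- is.na(y) | y != round(y)
  if (any(bad)) {
    stop(sprintf("malformed value '%s' in column '%s' at line %d",
                 x[which(bad)[1L]], col, which(bad)[1L] + 1L), call. = FALSE)
  }
  as.integer(y)
}

#' Construct and validate a gene catalogue
#'
#' @param df A data.frame with at least `symbol`, `chromosome`, `start`,
#'   `end`, `reference_copies`, `assay_group` columns.
#' @param assembly Assembly label.
#' @return A validated `gene_catalogue`.
#' @export
new_gene_catalogue <- function(df, assembly = "ARS-UCD1.2") {
  stopifnot(is.data.frame(df))
  if (!"orthologue" %in% names(df)) {
    df$orthologue <- rep(NA_character_, nrow(df))
  }
  if (!"protein_sequence" %in% names(df)) {
    df$protein_sequence <- rep(NA_character_, nrow(df))
  }
  rownames(df) <- NULL
  obj <- structure(df, assembly = assembly,
                   class = c("gene_catalogue", "data.frame"))
  validate_gene_catalogue(obj)
}

#' @rdname new_gene_catalogue
#' @param x A `gene_catalogue`.
#' @export
validate_gene_catalogue <- function(x) {
  if (nrow(x) == 0L) return(x)
  dup <- x$symbol[duplicated(x$symbol)]
  if (length(dup) > 0L) {
    stop("duplicate symbol(s) in catalogue: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(x$start < 1L)) {
    stop("start must be >= 1 (1-based coordinates); offending symbol(s): ",
         paste(x$symbol[x$start < 1L], collapse = ", "), call. = FALSE)
  }
  bad_span <- x$end < x$start
  if (any(bad_span)) {
    stop("end < start for symbol(s): ",
         paste(x$symbol[bad_span], collapse = ", "), call. = FALSE)
  }
  if (any(x$reference_copies < 1L)) {
    stop("reference_copies must be >= 1", call. = FALSE)
  }
  rc <- tapply(x$reference_copies, x$assay_group,
               function(v) length(unique(v)))
  if (any(rc > 1L)) {
    stop("assay_group(s) with inconsistent reference_copies: ",
         paste(names(rc)[rc > 1L], collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.gene_catalogue <- function(x, ...) {
  cat(sprintf("gene_catalogue: %d regions, %d assay groups, assembly %s\n",
              nrow(x), length(unique(x$assay_group)),
              attr(x, "assembly")))
  NextMethod()
}

#' Expected diploid copy number per assay group
#'
#' The unvaried diploid state of an assay group carries two copies of each
#' assembly copy it represents, so the expected diploid copy number is
#' `2 * reference_copies` (2 for single-copy genes; 6 for a group of three
#' assembled paralogues).
#'
#' @param catalogue A `gene_catalogue`.
#' @return Named numeric vector, one entry per assay group.
#' @export
expected_copy_number <- function(catalogue) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  grp <- !duplicated(catalogue$assay_group)
  stats::setNames(2 * as.numeric(catalogue$reference_copies[grp]),
                  catalogue$assay_group[grp])
}

#' Convert a catalogue to GRanges
#'
#' @param catalogue A `gene_catalogue`.
#' @return A [GenomicRanges::GRanges] with `symbol` and `assay_group`
#'   metadata columns and the region symbol as names.
#' @export
catalogue_granges <- function(catalogue) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  gr <- GenomicRanges::GRanges(
    seqnames = catalogue$chromosome,
    ranges = IRanges::IRanges(start = catalogue$start, end = catalogue$end)
  )
  S4Vectors::mcols(gr)$symbol <- catalogue$symbol
  S4Vectors::mcols(gr)$assay_group <- catalogue$assay_group
  names(gr) <- catalogue$symbol
  gr
}

#' Write catalogue regions as a BED file
#'
#' Emits one 4-column BED line per region (0-based half-open coordinates,
#' name column = symbol), the region format consumed by read counters.
#'
#' @param catalogue A `gene_catalogue`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [catalogue_from_bed()] for the lossless coordinate round-trip.
#' @export
write_catalogue_bed <- function(catalogue, path) {
  gr <- catalogue_granges(catalogue)
  S4Vectors::mcols(gr)$name <- catalogue$symbol
  S4Vectors::mcols(gr)$symbol <- NULL
  S4Vectors::mcols(gr)$assay_group <- NULL
  names(gr) <- NULL
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file back into a minimal catalogue
#'
#' Reconstructs 1-based inclusive coordinates from 0-based half-open BED.
#' Assay grouping and reference copies are not representable in BED, so each
#' region becomes a singleton assay group with `reference_copies = 1`.
#'
#' @param path BED file path.
#' @param assembly Assembly label for the resulting catalogue.
#' @return A `gene_catalogue`.
#' @export
catalogue_from_bed <- function(path, assembly = "ARS-UCD1.2") {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
  df <- data.frame(
    symbol = nm,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    reference_copies = 1L,
    assay_group = nm,
    stringsAsFactors = FALSE
  )
  new_gene_catalogue(df, assembly = assembly)
}

#' Find pairs of catalogue regions with overlapping intervals
#'
#' Reports each unordered pair of regions on the same chromosome whose
#' closed intervals intersect (touching endpoints count). Overlapping regions
#' double-count sequencing reads, so copy-number covariation between them is
#' expected as a counting artifact rather than evidence of a shared
#' copy-number variable segment.
#'
#' @param catalogue A `gene_catalogue`.
#' @return A data.frame with columns `symbol_a`, `symbol_b`, one row per
#'   overlapping pair (each pair reported once, `symbol_a` first in catalogue
#'   order).
#' @export
find_overlapping_pairs <- function(catalogue) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  empty <- data.frame(symbol_a = character(), symbol_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(catalogue) < 2L) return(empty)
  gr <- catalogue_granges(catalogue)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits) == 0L) return(empty)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  a <- pmin(i, j)
  b <- pmax(i, j)
  ord <- order(a, b)
  data.frame(symbol_a = catalogue$symbol[a[ord]],
             symbol_b = catalogue$symbol[b[ord]],
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}
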