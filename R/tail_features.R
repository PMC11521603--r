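#' C-terminal tail length after the last cysteine
#'
#' Mature defensin-fold peptides carry six conserved cysteines; residues
#' after the final cysteine form the C-terminal tail, which in several
#' fertility-associated family members is long and heavily O-glycosylated.
#' The tail length is the number of residues strictly after the last `C`.
#'
#' A sequence containing no cysteine has no defensin tail at all; this is
#' signalled explicitly as `NA_integer_` (never `0`, which means a sequence
#' ending in cysteine).
#'
#' @param protein_sequence Character vector of non-empty uppercase
#'   one-letter amino-acid sequences.
#' @return Integer vector of tail lengths; `NA` where no cysteine occurs.
#' @examples
#' c_terminal_tail_length(c("GICAKKC", "GICAKKCSTNA", "GGGGG"))
#' @export
c_terminal_tail_length <- function(protein_sequence) {
  .check_protein(protein_sequence)
  vapply(protein_sequence, function(s) {
    pos <- .last_cys(s)
    if (is.na(pos)) NA_integer_ else nchar(s) - pos
  }, integer(1), USE.NAMES = FALSE)
}

#' Count serine and threonine residues in the C-terminal tail
#'
#' A coarse proxy for O-glycosylation potential: O-linked glycans attach to
#' Ser/Thr hydroxyls, so a tail without any S or T cannot be O-glycosylated.
#' This deliberately does not emulate a trained glycosylation-site predictor.
#'
#' @inheritParams c_terminal_tail_length
#' @return Integer vector of S+T counts in the tail; `NA` where the sequence
#'   has no cysteine.
#' @examples
#' count_ser_thr_in_tail("GICAKKCSTNA")
#' @export
count_ser_thr_in_tail <- function(protein_sequence) {
  .check_protein(protein_sequence)
  vapply(protein_sequence, function(s) {
    pos <- .last_cys(s)
    if (is.na(pos)) return(NA_integer_)
    if (pos == nchar(s)) return(0L)
    tail_seq <- substr(s, pos + 1L, nchar(s))
    nchar(gsub("[^ST]", "", tail_seq))
  }, integer(1), USE.NAMES = FALSE)
}

#' Tabulate C-terminal tail features for a set of proteins
#'
#' @inheritParams c_terminal_tail_length
#' @param long_tail_cutoff Tail length (residues) above which a tail is
#'   flagged as "long" (default 20; long fertility-associated tails run to
#'   about 45 residues while typical tails are well under 20).
#' @return A data.frame with columns `protein`, `tail_length`,
#'   `no_cysteine`, `long_tail`, `ser_thr_in_tail`.
#' @export
tail_features <- function(protein_sequence, long_tail_cutoff = 20L) {
  stopifnot(length(long_tail_cutoff) == 1L, long_tail_cutoff >= 0)
  len <- c_terminal_tail_length(protein_sequence)
  st <- count_ser_thr_in_tail(protein_sequence)
  nm <- names(protein_sequence)
  if (is.null(nm)) nm <- paste0("seq_", seq_along(protein_sequence))
  data.frame(
    protein = nm,
    tail_length = len,
    no_cysteine = is.na(len),
    long_tail = !is.na(len) & len > long_tail_cutoff,
    ser_thr_in_tail = st,
    stringsAsFactors = FALSE
  )
}

.last_cys <- function(s) {
  m <- gregexpr("C", s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) NA_integer_ else as.integer(m[length(m)])
}

.check_protein <- function(x) {
  if (length(x) == 0L) return(invisible(x))
  if (!is.character(x) || any(is.na(x)) || any(nchar(x) == 0L)) {
    stop("protein sequences must be non-empty character strings",
         call. = FALSE)
  }
  if (any(grepl("[^A-Z*]", x))) {
    stop("protein sequences must be uppercase one-letter amino-acid codes",
         call. = FALSE)
  }
  invisible(x)
}
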