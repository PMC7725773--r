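#' @importFrom methods is
#' @importFrom stats setNames
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# complement map; N stays N
comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors (the package's internal representation).
#'
#' @param x character vector of DNA strings over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_chars <- function(chars) unname(comp_map[chars])

#' Convert internal 0-based half-open coordinates to 1-based inclusive
#'
#' The single place in the package where coordinate offsets are adjusted.
#' Internally every interval is 0-based half-open (like BED/bedGraph); every
#' human-readable report is 1-based inclusive (like GenBank). Keeping the
#' conversion in one routine eliminates off-by-one drift.
#'
#' @param start0,end0 integer vectors, 0-based half-open.
#' @return data.frame with columns `start1`, `end1` (1-based inclusive).
#' @export
coords_to_report <- function(start0, end0) {
  stopifnot(all(end0 > start0))
  data.frame(start1 = as.integer(start0 + 1L), end1 = as.integer(end0))
}

#' @rdname coords_to_report
#' @param start1,end1 integer vectors, 1-based inclusive.
#' @return for `coords_from_report`, data.frame with `start0`, `end0`.
#' @export
coords_from_report <- function(start1, end1) {
  stopifnot(all(end1 >= start1), all(start1 >= 1))
  data.frame(start0 = as.integer(start1 - 1L), end0 = as.integer(end1))
}

# split a DNA string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# all start positions (0-based) of fixed `motif` in `subject`, overlapping
motif_starts0 <- function(subject, motif) {
  if (nchar(motif) == 0 || nchar(motif) > nchar(subject)) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(subject))
  as.integer(BiocGenerics::start(m)) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
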