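# Codon adaptation machinery: usage tables, CDS objects, CAI.

CODONS64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0), c("T", "C", "A", "G"), paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Codon usage weight table
#'
#' Relative-adaptiveness weights in (0, 1]: within every synonymous family
#' the preferred codon has weight exactly 1 and alternatives are scaled
#' against it. Stop codons may be present but are excluded from CAI.
#'
#' @param x a data.frame with columns `codon`, `weight`, or the path of a TSV
#'   with those columns (`#` comment lines allowed).
#' @param provenance free-text note on where the weights come from.
#' @return object of class `codon_table`: named numeric `weights` (one per
#'   codon, T alphabet) plus `provenance`.
#' @seealso [celegans_codon_table()] for the shipped default.
#' @export
codon_usage_table <- function(x, provenance = "user-supplied") {
  if (is.character(x) && length(x) == 1L) {
    df <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
    provenance <- paste0("file: ", x)
  } else df <- as.data.frame(x)
  abort_if(!all(c("codon", "weight") %in% names(df)),
           "need columns 'codon' and 'weight'")
  codon <- toupper(chartr("U", "T", df$codon))
  abort_if(anyDuplicated(codon) > 0, "duplicated codons in table")
  abort_if(!all(codon %in% CODONS64), "invalid codon in table")
  w <- stats::setNames(as.numeric(df$weight), codon)
  abort_if(any(w <= 0) || any(w > 1), "weights must lie in (0, 1]")
  sense <- setdiff(CODONS64, STOP_CODONS)
  missing <- setdiff(sense, codon)
  abort_if(length(missing) > 0,
           "table missing sense codons: ", paste(missing, collapse = ", "))
  aa <- Biostrings::GENETIC_CODE[sense]
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    abort_if(abs(max(w[fam]) - 1) > 1e-9,
             "synonymous family for ", a, " has no weight-1 codon")
  }
  structure(list(weights = w, provenance = provenance),
            class = "codon_table")
}

#' The shipped C. elegans-flavoured codon weight table
#'
#' A synthetic stand-in for the community codon-adaptation weights: the
#' preferred codon of each family follows published C. elegans optimal-codon
#' assignments and alternatives are ranked with a fixed geometric-like decay.
#' CAI values are table-relative, so substitute your own table (TSV with
#' `codon`, `weight`) to reproduce an external tool's numbers.
#'
#' @return a [codon_usage_table()].
#' @export
celegans_codon_table <- function() {
  path <- system.file("extdata", "codon_weights_celegans_synthetic.tsv",
                      package = "patcraft", mustWork = TRUE)
  tab <- codon_usage_table(path)
  tab$provenance <- "patcraft synthetic C. elegans-flavoured defaults"
  tab
}

translate_dna <- function(dna) {
  abort_if(nchar(dna) %% 3L != 0L, "length not divisible by 3")
  codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
  abort_if(any(!codons %in% CODONS64),
           "CDS contains a non-ACGT codon: ",
           codons[which(!codons %in% CODONS64)[1]])
  aa <- Biostrings::GENETIC_CODE[codons]
  paste(ifelse(aa == "*", "*", aa), collapse = "")
}

split_codons <- function(dna) {
  substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
}

#' Protein-coding sequence
#'
#' @param dna DNA string, length divisible by 3, frame 0.
#' @param id label.
#' @param allow_internal_stops keep internal stop codons instead of erroring.
#' @return object of class `coding_sequence` with fields `dna`, `protein`
#'   (derived; trailing stop shown as `*`), `id`.
#' @export
coding_sequence <- function(dna, id = "cds", allow_internal_stops = FALSE) {
  if (is(dna, "nt_seq")) { id <- dna$id; dna <- dna$residues }
  dna <- toupper(dna)
  abort_if(nchar(dna) %% 3L != 0L, "CDS length not divisible by 3")
  protein <- translate_dna(dna)
  internal <- grepl("\\*", substr(protein, 1L, nchar(protein) - 1L))
  abort_if(internal && !allow_internal_stops,
           "internal stop codon in CDS '", id, "'")
  structure(list(dna = dna, protein = protein, id = id), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d bp, %d aa\n", x$id, nchar(x$dna),
              nchar(sub("\\*$", "", x$protein))))
  invisible(x)
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over all non-stop codons.
#' Single-codon families (Met, Trp) carry weight 1 and are included (no
#' effect on the mean).
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @param table a [codon_usage_table()]; default [celegans_codon_table()].
#' @param allow_internal_stops passed to [coding_sequence()].
#' @return CAI in (0, 1].
#' @examples
#' toy <- codon_usage_table(data.frame(
#'   codon = setdiff(patcraft:::CODONS64, patcraft:::STOP_CODONS),
#'   weight = 1))
#' cai("ATGTGG", toy)  # 1
#' @export
cai <- function(cds, table = celegans_codon_table(),
                allow_internal_stops = FALSE) {
  if (!is(cds, "coding_sequence"))
    cds <- coding_sequence(cds, allow_internal_stops = allow_internal_stops)
  codons <- split_codons(cds$dna)
  codons <- codons[!codons %in% STOP_CODONS]
  abort_if(length(codons) == 0L, "no non-stop codons")
  exp(mean(log(table$weights[codons])))
}

# synonymous codons encoding amino acid `aa` (single letter), T alphabet
synonymous_codons <- function(aa) {
  sense <- setdiff(CODONS64, STOP_CODONS)
  sort(sense[Biostrings::GENETIC_CODE[sense] == aa])
}

# highest-weight codon for each residue; alphabetical tie-break
optimal_codon <- function(aa, table) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    if (a == "*") return("TAA")
    syn <- synonymous_codons(a)
    abort_if(length(syn) == 0L, "cannot encode residue '", a, "'")
    w <- table$weights[syn]
    syn[order(-w, syn)][1L]     # max weight, then alphabetical
  }, "")
}
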