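# piRNA (21U-RNA) target-site scanning.
#
# C. elegans piRNAs are 21-nt germline small RNAs that silence transcripts
# with sufficient antisense complementarity. The site model requires perfect
# Watson-Crick pairing of the piRNA seed (positions 2-8) and tolerates a
# budget of imperfections elsewhere, with G:U wobbles charged a reduced
# cost. A piRNA pairs antiparallel to the mRNA, so piRNA position i faces
# position 22-i of a 21-nt sense window.

#' piRNA database
#'
#' @param x FASTA path, or a named/unnamed character vector of 21-nt piRNA
#'   sequences (U is mapped to T).
#' @return object of class `pirna_db`: `entries` data.frame (`id`, `seq`) and
#'   a `seed_index` environment mapping the sense-strand 7-mer complementary
#'   to piRNA positions 2-8 onto entry indices.
#' @export
pirna_db <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    seqs <- as.character(set)
    ids <- sub("\\s.*$", "", names(set))
  } else {
    seqs <- as.character(x)
    ids <- names(seqs) %||% sprintf("21ur-%d", seq_along(seqs))
    if (is.null(names(seqs))) names(seqs) <- ids else ids <- names(seqs)
  }
  seqs <- toupper(chartr("U", "T", seqs))
  ok <- !grepl("[^ACGT]", seqs) & nchar(seqs) == 21L
  abort_if(length(seqs) > 0 && !all(ok),
           "piRNA entries must be 21 nt over ACGT/U; offending: ",
           paste(ids[!ok], collapse = ", "))
  idx <- new.env(parent = emptyenv())
  if (length(seqs)) {
    # sense-strand 7-mer a perfect target shows opposite the seed:
    # positions 14..20 of revcomp(piRNA)
    keys <- substr(revcomp(seqs), 14L, 20L)
    for (i in seq_along(keys)) {
      idx[[keys[i]]] <- c(idx[[keys[i]]], i)
    }
  }
  structure(list(entries = data.frame(id = ids, seq = unname(seqs),
                                      stringsAsFactors = FALSE),
                 seed_index = idx),
            class = "pirna_db")
}

#' @export
print.pirna_db <- function(x, ...) {
  cat(sprintf("<pirna_db> %d piRNAs (21 nt)\n", nrow(x$entries)))
  invisible(x)
}

#' piRNA targeting-rule parameters
#'
#' @param max_nonseed_mismatches mismatch budget outside the seed.
#' @param gu_wobble_cost cost of a G:U pair, counted toward the budget.
#' @param site_weight weight contributed by each accepted site to the piRNA
#'   score.
#' @return object of class `pirna_model`.
#' @export
pirna_model <- function(max_nonseed_mismatches = 3.0, gu_wobble_cost = 0.5,
                        site_weight = 1.0) {
  abort_if(max_nonseed_mismatches < 0 || gu_wobble_cost < 0 || site_weight < 0,
           "costs and weights must be >= 0")
  structure(list(seed_from = 2L, seed_to = 8L,
                 max_nonseed_mismatches = as.numeric(max_nonseed_mismatches),
                 gu_wobble_cost = as.numeric(gu_wobble_cost),
                 site_weight = as.numeric(site_weight)),
            class = "pirna_model")
}

# pairing cost of piRNA base p (DNA alphabet) against sense-strand target
# base b: 0 Watson-Crick, gu wobble cost, else 1. N is a universal mismatch.
pair_cost <- function(p, b, model) {
  wc <- p == comp_map[b] & b %in% c("A", "C", "G", "T")
  wobble <- (p == "G" & b == "T") | (p == "T" & b == "G")
  ifelse(wc, 0, ifelse(wobble, model$gu_wobble_cost, 1))
}

#' Scan a sequence for piRNA target sites
#'
#' For every 21-nt sense window, entries whose seed (piRNA positions 2-8) is
#' perfectly complementary to window positions 14-20 (via the 7-mer index)
#' are extended over the remaining positions; a site is accepted when the
#' accumulated non-seed cost stays within the budget.
#'
#' @param seq an [nt_seq()], [coding_sequence()] or character string
#'   (sense/mRNA strand, DNA alphabet).
#' @param db a [pirna_db()].
#' @param model a [pirna_model()].
#' @return data.frame with one row per accepted (entry, window) pair:
#'   `pirna_id`, `target_start` (0-based window start), `mismatch_cost`,
#'   `weight`.
#' @export
scan_pirna_sites <- function(seq, db, model = pirna_model()) {
  if (is(seq, "coding_sequence")) seq <- seq$dna
  if (is(seq, "nt_seq")) seq <- seq$residues
  seq <- toupper(seq)
  out <- data.frame(pirna_id = character(0), target_start = integer(0),
                    mismatch_cost = numeric(0), weight = numeric(0))
  if (nrow(db$entries) == 0L || nchar(seq) < 21L) return(out)
  n <- nchar(seq)
  chars <- seq_chars(seq)
  pir_chars <- lapply(db$entries$seq, seq_chars)
  nonseed <- setdiff(1:21, model$seed_from:model$seed_to)  # piRNA positions
  rows <- list()
  for (s in 0:(n - 21L)) {                       # 0-based window start
    key <- substr(seq, s + 14L, s + 20L)
    hits <- db$seed_index[[key]]
    if (is.null(hits)) next
    win <- chars[(s + 1L):(s + 21L)]
    for (i in hits) {
      p <- pir_chars[[i]]
      cost <- sum(pair_cost(p[nonseed], win[22L - nonseed], model))
      if (cost <= model$max_nonseed_mismatches) {
        rows[[length(rows) + 1L]] <- data.frame(
          pirna_id = db$entries$id[i], target_start = s,
          mismatch_cost = cost, weight = model$site_weight,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' piRNA score of a site list
#'
#' The "piRNA score" of a design: the sum of site weights over all predicted
#' target sites (0 for a clean sequence).
#'
#' @param sites data.frame from [scan_pirna_sites()].
#' @return numeric scalar.
#' @export
pirna_score <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) return(0)
  sum(sites$weight)
}
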