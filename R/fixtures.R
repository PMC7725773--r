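# Seeded synthetic-sequence generators. Every generator is a pure function
# of its arguments and seed (byte-identical output on repeat), so all
# modules are testable without downloads. The shipped default seed is
# 20201209.

DEFAULT_SEED <- 20201209L

#' Random DNA sequence at a target GC fraction
#'
#' @param length sequence length (>= 1).
#' @param gc_fraction target GC content in (0, 1); the C. elegans genome sits
#'   near 0.36.
#' @param seed RNG seed.
#' @param id sequence id.
#' @return an [nt_seq()].
#' @export
gen_random_seq <- function(length, gc_fraction = 0.36, seed = DEFAULT_SEED,
                           id = "random") {
  abort_if(length < 1L, "length must be >= 1")
  abort_if(gc_fraction <= 0 || gc_fraction >= 1, "gc_fraction must be in (0,1)")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  draw <- function()
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  # seed = NULL draws from the ambient RNG stream (used inside other
  # generators' with_seed blocks)
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  nt_seq(res, id = id)
}

#' Random sequence with a planted periodic A/T run cluster
#'
#' Emulates the PATC structure: `n_runs` mononucleotide runs of
#' `run_length` whose centers sit `period` bp apart (plus integer jitter),
#' embedded centrally in random background. Bases flanking each run are
#' forced to C/G so the planted runs stay maximal. The ground truth (run
#' table and cluster span) is returned alongside the sequence.
#'
#' @param length total sequence length.
#' @param gc_fraction background GC content.
#' @param n_runs,run_length,period planted cluster geometry (bp).
#' @param jitter_bp maximal absolute center jitter (< period / 2).
#' @param alternate alternate A and T runs instead of all-A.
#' @param seed RNG seed.
#' @return list with `seq` ([nt_seq()]), `runs` (0-based data.frame) and
#'   `span` (0-based half-open cluster extent).
#' @export
gen_patc_sequence <- function(length = 400L, gc_fraction = 0.5, n_runs = 10L,
                              run_length = 6L, period = 10, jitter_bp = 0L,
                              alternate = FALSE, seed = DEFAULT_SEED) {
  abort_if(jitter_bp >= period / 2, "jitter must be < period / 2")
  span_needed <- (n_runs - 1) * period + run_length + 2L
  abort_if(length < span_needed, "sequence too short for the planted cluster")
  withr::with_seed(seed, {
    chars <- seq_chars(gen_random_seq(length, gc_fraction, seed = NULL,
                                      id = "patc_fixture")$residues)
    c0 <- floor((length - (n_runs - 1) * period) / 2)
    jit <- if (jitter_bp > 0)
      sample(seq(-jitter_bp, jitter_bp), n_runs, replace = TRUE)
    else rep(0L, n_runs)
    centers <- round(c0 + (seq_len(n_runs) - 1L) * period + jit)
    starts <- as.integer(centers - (run_length - 1) / 2)   # 0-based
    abort_if(any(diff(starts) < run_length + 1L), "planted runs overlap")
    base <- if (alternate) rep(c("A", "T"), length.out = n_runs)
    else rep("A", n_runs)
    for (i in seq_len(n_runs)) {
      idx <- (starts[i] + 1L):(starts[i] + run_length)
      chars[idx] <- base[i]
      # C/G guards keep runs maximal
      if (starts[i] >= 1L) chars[starts[i]] <- "C"
      if (starts[i] + run_length < length) chars[starts[i] + run_length + 1L] <- "G"
    }
    runs <- data.frame(start = starts, length = run_length, base = base,
                       center = starts + (run_length - 1) / 2)
    list(seq = nt_seq(paste(chars, collapse = ""), id = "patc_fixture"),
         runs = runs,
         span = c(starts[1L], starts[n_runs] + run_length))
  })
}

#' Toy piRNA database
#'
#' @param n number of random 21-nt entries.
#' @param seed RNG seed.
#' @param gc_fraction base composition of the entries.
#' @return a [pirna_db()] with ids `21ur-synth-1..n`.
#' @export
gen_toy_pirna_db <- function(n, seed = DEFAULT_SEED, gc_fraction = 0.5) {
  seqs <- withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE,
                 prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                          gc_fraction / 2, (1 - gc_fraction) / 2)),
          collapse = ""), ""))
  names(seqs) <- sprintf("21ur-synth-%d", seq_len(n))
  pirna_db(seqs)
}

#' Plant a perfect piRNA target site into a CDS by synonymous recoding
#'
#' Searches 21-nt windows left to right for one whose codons can be
#' synonymously recoded to the exact reverse complement of the piRNA
#' (a mismatch-free site). Translation is preserved exactly.
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @param pirna 21-nt piRNA sequence (U allowed).
#' @param table optional [codon_usage_table()] used to rank compatible
#'   synonymous codons (otherwise alphabetical).
#' @return list with `cds` (recoded [coding_sequence()]) and `target_start`
#'   (0-based window start).
#' @export
plant_pirna_site <- function(cds, pirna, table = NULL) {
  if (!is(cds, "coding_sequence")) cds <- coding_sequence(cds)
  pirna <- toupper(chartr("U", "T", pirna))
  abort_if(nchar(pirna) != 21L || grepl("[^ACGT]", pirna),
           "pirna must be 21 nt over ACGT/U")
  target <- revcomp(pirna)
  dna <- cds$dna
  L <- nchar(dna)
  abort_if(L < 21L, "CDS shorter than a piRNA site")
  codons <- split_codons(dna)
  for (w in 0:(L - 21L)) {
    ci_from <- w %/% 3L
    ci_to <- (w + 20L) %/% 3L
    new_codons <- codons
    feasible <- TRUE
    for (ci in ci_from:ci_to) {
      cur <- codons[ci + 1L]
      if (cur %in% STOP_CODONS) { feasible <- FALSE; break }
      # required characters of this codon fixed by the target window
      need <- rep(NA_character_, 3L)
      for (k in 1:3) {
        pos <- ci * 3L + k - 1L                 # 0-based on dna
        if (pos >= w && pos < w + 21L)
          need[k] <- substr(target, pos - w + 1L, pos - w + 1L)
      }
      syn <- synonymous_codons(Biostrings::GENETIC_CODE[cur])
      ok <- syn[vapply(syn, function(s) {
        all(is.na(need) | seq_chars(s) == need)
      }, TRUE)]
      if (!length(ok)) { feasible <- FALSE; break }
      new_codons[ci + 1L] <- if (cur %in% ok) cur
      else if (!is.null(table)) ok[order(-table$weights[ok], ok)][1L]
      else ok[1L]
    }
    if (!feasible) next
    out <- coding_sequence(paste(new_codons, collapse = ""), id = cds$id)
    stopifnot(out$protein == cds$protein,
              substr(out$dna, w + 1L, w + 21L) == target)
    return(list(cds = out, target_start = w))
  }
  stop("no synonymous encoding achieves complementarity to this piRNA ",
       "anywhere in the CDS", call. = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: generates a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) counts, first and last base
#' as the input, via a random Eulerian path on the dinucleotide multigraph.
#' The standard null model for periodicity scores.
#'
#' @param seq an [nt_seq()] or character string.
#' @param seed RNG seed.
#' @return an [nt_seq()] of the same length.
#' @export
dinucleotide_shuffle <- function(seq, seed = DEFAULT_SEED) {
  seq <- as_nt_seq(seq)
  chars <- seq_chars(seq$residues)
  n <- length(chars)
  if (n < 3L) return(seq)
  first <- chars[1L]; last <- chars[n]
  verts <- unique(chars)
  edges <- split(chars[-1L], factor(chars[-n], levels = verts))
  shuffled <- withr::with_seed(seed, {
    repeat {
      # pick one candidate terminal edge per non-sink vertex
      last_edge <- lapply(verts, function(v) {
        if (v == last || length(edges[[v]]) == 0L) return(NA_character_)
        edges[[v]][sample.int(length(edges[[v]]), 1L)]
      })
      names(last_edge) <- verts
      # the chosen edges must form paths leading to `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(edges[[v]]) == 0L) next
        seen <- character(0); cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (!ok) next
      # shuffle the remaining edges; reserved terminal edge goes last
      lists <- lapply(verts, function(v) {
        e <- edges[[v]]
        if (v != last && length(e)) {
          drop <- match(last_edge[[v]], e)
          rest <- e[-drop]
          c(rest[sample.int(length(rest))], last_edge[[v]])
        } else if (length(e)) e[sample.int(length(e))] else character(0)
      })
      names(lists) <- verts
      out <- character(n)
      out[1L] <- first
      ptr <- stats::setNames(rep(1L, length(verts)), verts)
      good <- TRUE
      for (i in 2:n) {
        v <- out[i - 1L]
        if (ptr[[v]] > length(lists[[v]])) { good <- FALSE; break }
        out[i] <- lists[[v]][ptr[[v]]]
        ptr[[v]] <- ptr[[v]] + 1L
      }
      if (good) break
    }
    paste(out, collapse = "")
  })
  nt_seq(shuffled, id = paste0(seq$id, "_shuffled"))
}
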