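# Constrained synonymous recoding: codon optimization under forbidden-motif,
# homopolymer and piRNA-site constraints. Fully deterministic (no RNG).

#' Design constraints for synonymous recoding
#'
#' @param forbidden_motifs motifs scanned on both strands (each motif and its
#'   reverse complement); default the BsaI recognition site GGTCTC, whose
#'   reverse complement GAGACC is scanned automatically.
#' @param max_homopolymer longest tolerated mononucleotide run.
#' @param min_cai CAI the design should retain.
#' @param target_pirna_score piRNA score the design should reach.
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(forbidden_motifs = "GGTCTC",
                               max_homopolymer = 8L, min_cai = 0.9,
                               target_pirna_score = 0) {
  abort_if(length(forbidden_motifs) > 0 &&
             any(!nzchar(forbidden_motifs)), "motifs must be non-empty")
  structure(list(forbidden_motifs = toupper(forbidden_motifs),
                 max_homopolymer = as.integer(max_homopolymer),
                 min_cai = as.numeric(min_cai),
                 target_pirna_score = as.numeric(target_pirna_score)),
            class = "design_constraints")
}

# violation table: type in {motif, homopolymer, pirna}, 0-based half-open
# window, detail (motif string / base / piRNA id)
scan_violations <- function(dna, constraints, db = NULL,
                            model = pirna_model(),
                            types = c("motif", "homopolymer", "pirna")) {
  rows <- list()
  if ("motif" %in% types && length(constraints$forbidden_motifs)) {
    motifs <- unique(c(constraints$forbidden_motifs,
                       revcomp(constraints$forbidden_motifs)))
    for (m in motifs) {
      st <- motif_starts0(dna, m)
      if (length(st)) rows[[length(rows) + 1L]] <- data.frame(
        type = "motif", start = st, end = st + nchar(m), detail = m,
        stringsAsFactors = FALSE)
    }
  }
  if ("homopolymer" %in% types) {
    r <- rle(seq_chars(dna))
    ends <- cumsum(r$lengths)
    bad <- which(r$lengths > constraints$max_homopolymer &
                   r$values %in% c("A", "C", "G", "T"))
    if (length(bad)) rows[[length(rows) + 1L]] <- data.frame(
      type = "homopolymer", start = ends[bad] - r$lengths[bad],
      end = ends[bad], detail = r$values[bad], stringsAsFactors = FALSE)
  }
  if ("pirna" %in% types && !is.null(db)) {
    sites <- scan_pirna_sites(dna, db, model)
    if (nrow(sites)) rows[[length(rows) + 1L]] <- data.frame(
      type = "pirna", start = sites$target_start,
      end = sites$target_start + 21L, detail = sites$pirna_id,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(type = character(0),
                                       start = integer(0), end = integer(0),
                                       detail = character(0)))
  v <- do.call(rbind, rows)
  v <- v[order(v$start, match(v$type, c("motif", "homopolymer", "pirna")),
               v$detail), , drop = FALSE]
  rownames(v) <- NULL
  v
}

viol_key <- function(v) paste(v$type, v$start, v$detail, sep = "|")

# all synonymous single-codon substitutions whose codon overlaps [start,end)
candidate_substitutions <- function(dna, start, end, table) {
  codons <- split_codons(dna)
  ci_from <- max(0L, start %/% 3L)
  ci_to <- min(length(codons) - 1L, (end - 1L) %/% 3L)
  out <- list()
  for (ci in ci_from:ci_to) {
    cur <- codons[ci + 1L]
    if (cur %in% STOP_CODONS) next
    aa <- Biostrings::GENETIC_CODE[cur]
    for (alt in setdiff(synonymous_codons(aa), cur)) {
      out[[length(out) + 1L]] <- data.frame(
        codon_index = ci, from = cur, to = alt,
        cai_loss = log(table$weights[cur]) - log(table$weights[alt]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

apply_substitution <- function(dna, codon_index, to) {
  paste0(substr(dna, 1L, codon_index * 3L), to,
         substr(dna, codon_index * 3L + 4L, nchar(dna)))
}

# TRUE when `trial` no longer carries a violation of v's type overlapping
# v's window
violation_removed <- function(trial, v, constraints, db, model) {
  vt <- scan_violations(trial, constraints, db, model, types = v$type)
  !any(vt$start < v$end & vt$end > v$start & vt$detail == v$detail)
}

# The deterministic repair loop shared by optimize_codons() and
# deplete_pirna(). Each iteration targets the first outstanding violation
# (smallest start; type order motif < homopolymer < pirna) and applies the
# synonymous single-codon substitution that removes it at minimal CAI loss
# (ties: smallest codon position, then alphabetical codon). Violations no
# substitution can remove are parked and reported as residuals; the parked
# set is cleared whenever a substitution lands, since it may unlock them.
repair_loop <- function(dna, table, constraints, db, model, types,
                        prefer_seed = FALSE, monotone_pirna = FALSE) {
  subs <- list()
  stuck <- character(0)
  max_iter <- 10L * (nchar(dna) %/% 3L) + 50L
  base_pirna <- function(d) {
    if (is.null(db)) 0 else pirna_score(scan_pirna_sites(d, db, model))
  }
  for (iter in seq_len(max_iter)) {
    v <- scan_violations(dna, constraints, db, model, types)
    open <- v[!viol_key(v) %in% stuck, , drop = FALSE]
    if (!nrow(open)) break
    tgt <- open[1L, ]
    cand <- candidate_substitutions(dna, tgt$start, tgt$end, table)
    applied <- FALSE
    if (!is.null(cand)) {
      if (prefer_seed && tgt$type == "pirna") {
        # the seed-complementary 7-mer sits at window positions 14-20;
        # breaking it kills the site outright
        seed_lo <- tgt$start + 13L; seed_hi <- tgt$start + 20L
        in_seed <- cand$codon_index * 3L < seed_hi &
          (cand$codon_index + 1L) * 3L > seed_lo
        cand <- cand[order(!in_seed, cand$cai_loss, cand$codon_index,
                           cand$to), , drop = FALSE]
      } else {
        cand <- cand[order(cand$cai_loss, cand$codon_index, cand$to), ,
                     drop = FALSE]
      }
      score_now <- if (monotone_pirna) base_pirna(dna) else NULL
      for (r in seq_len(nrow(cand))) {
        trial <- apply_substitution(dna, cand$codon_index[r], cand$to[r])
        if (!violation_removed(trial, tgt, constraints, db, model)) next
        if (monotone_pirna && base_pirna(trial) > score_now) next
        dna <- trial
        subs[[length(subs) + 1L]] <- cand[r, ]
        stuck <- character(0)
        applied <- TRUE
        break
      }
    }
    if (!applied) stuck <- c(stuck, viol_key(tgt))
  }
  residual <- scan_violations(dna, constraints, db, model, types)
  list(dna = dna, residual = residual,
       substitutions = if (length(subs)) do.call(rbind, subs)
       else data.frame())
}

design_report <- function(cds, table, constraints, db, model, loop) {
  sites <- if (is.null(db)) NULL else scan_pirna_sites(cds$dna, db, model)
  structure(list(
    cds = cds,
    cai = cai(cds, table),
    pirna_score = pirna_score(sites),
    pirna_sites = sites,
    residual_violations = loop$residual,
    substitutions = loop$substitutions,
    profile = list(constraints = unclass(constraints),
                   pirna_model = if (is.null(db)) NULL else unclass(model),
                   codon_table = table$provenance)),
    class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s: CAI %.3f, piRNA score %g, %d residual violation(s)\n",
              x$cds$id, x$cai, x$pirna_score, nrow(x$residual_violations)))
  if (nrow(x$residual_violations)) {
    r <- x$residual_violations
    rep1 <- coords_to_report(r$start, r$end)
    print(cbind(r["type"], rep1, r["detail"]))
  }
  invisible(x)
}

#' Codon-optimize a protein under design constraints
#'
#' Two phases: a seed pass encodes every residue with its highest-weight
#' codon (alphabetical tie-break), then a deterministic repair loop removes
#' forbidden motifs (both strands), over-long homopolymers and piRNA sites by
#' synonymous single-codon substitutions at minimal CAI loss. Translation is
#' preserved exactly; unresolvable violations are reported, not fatal.
#'
#' @param x a protein string, a [coding_sequence()], or a DNA string with
#'   length divisible by 3 (recoded from its translation).
#' @param table a [codon_usage_table()].
#' @param constraints a [design_constraints()].
#' @param db optional [pirna_db()]; when supplied, piRNA sites count as
#'   violations.
#' @param model a [pirna_model()].
#' @param id label for the output CDS.
#' @return a `design_report` with fields `cds`, `cai`, `pirna_score`,
#'   `residual_violations`, `substitutions` and the resolved `profile`.
#' @export
optimize_codons <- function(x, table = celegans_codon_table(),
                            constraints = design_constraints(),
                            db = NULL, model = pirna_model(), id = "design") {
  protein <- if (is(x, "coding_sequence")) x$protein
  else if (grepl("[^ACGTUacgtu*]", x) || nchar(x) %% 3L != 0L) toupper(x)
  else coding_sequence(toupper(chartr("U", "T", x)), id = id)$protein
  abort_if(grepl("[^ACDEFGHIKLMNPQRSTVWY*]", protein),
           "not a translatable protein/CDS input")
  core <- sub("\\*$", "", protein)
  dna <- paste(optimal_codon(core, table), collapse = "")
  if (endsWith(protein, "*")) dna <- paste0(dna, "TAA")
  loop <- repair_loop(dna, table, constraints, db, model,
                      types = c("motif", "homopolymer", "pirna"))
  cds <- coding_sequence(loop$dna, id = id)
  abort_if(cds$protein != protein, "translation changed during repair")
  design_report(cds, table, constraints, db, model, loop)
}

#' Deplete piRNA homology from an existing coding sequence
#'
#' Convenience wrapper over the repair loop restricted to piRNA-site
#' violations: substitutions inside the seed-complementary 7-nt window are
#' preferred (breaking the seed kills the site) and no accepted move may
#' increase the piRNA score, so depletion is monotone. A CDS with no sites is
#' returned unchanged (fixed point).
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @param db a [pirna_db()].
#' @param model a [pirna_model()].
#' @param table a [codon_usage_table()] used to rank substitutions by CAI
#'   loss.
#' @param constraints a [design_constraints()] (only the piRNA target is
#'   relevant here).
#' @return a `design_report`.
#' @export
deplete_pirna <- function(cds, db, model = pirna_model(),
                          table = celegans_codon_table(),
                          constraints = design_constraints()) {
  if (!is(cds, "coding_sequence")) cds <- coding_sequence(cds)
  loop <- repair_loop(cds$dna, table, constraints, db, model,
                      types = "pirna", prefer_seed = TRUE,
                      monotone_pirna = TRUE)
  out <- coding_sequence(loop$dna, id = cds$id)
  abort_if(out$protein != cds$protein, "translation changed during depletion")
  design_report(out, table, constraints, db, model, loop)
}
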