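# Intron planning, insertion and in-silico splicing.
#
# C. elegans introns follow the GT-AG rule with a strong 5' donor consensus
# (GTAAGTTT) and a short pyrimidine-rich acceptor (TTTTCAG). Germline
# expression engineering favours >= 2 introns with the first exon kept short
# (< 350 bp, preferably < 150 bp), and intron insertion is ranked toward
# exonic AG|G junctions, the preferred exon/exon context around C. elegans
# splice sites.

#' Splice-site model
#'
#' @param donor_consensus intron 5' end, must begin `GT`.
#' @param acceptor_consensus intron 3' end, must end `AG`.
#' @return object of class `splice_model`.
#' @export
splice_model <- function(donor_consensus = "GTAAGTTT",
                         acceptor_consensus = "TTTTCAG") {
  donor_consensus <- toupper(donor_consensus)
  acceptor_consensus <- toupper(acceptor_consensus)
  abort_if(!startsWith(donor_consensus, "GT"),
           "donor consensus must begin GT")
  abort_if(!endsWith(acceptor_consensus, "AG"),
           "acceptor consensus must end AG")
  structure(list(donor_consensus = donor_consensus,
                 acceptor_consensus = acceptor_consensus),
            class = "splice_model")
}

#' Default synthetic intron
#'
#' Donor consensus + neutral spacer + acceptor consensus (~50 nt, echoing
#' community synthetic introns). The spacer is a fixed G-free repeat so no
#' BsaI site or spurious splice signal can arise; this is a package default,
#' not a published sequence.
#'
#' @param model a [splice_model()].
#' @param length_bp total intron length (>= donor + acceptor length + 1).
#' @return intron DNA string starting GT and ending AG.
#' @export
synthetic_intron <- function(model = splice_model(), length_bp = 50L) {
  fixed <- nchar(model$donor_consensus) + nchar(model$acceptor_consensus)
  abort_if(length_bp <= fixed, "length_bp must exceed the consensi (", fixed, ")")
  spacer <- substr(strrep("ATCTAC", ceiling(length_bp / 6)), 1L,
                   length_bp - fixed)
  paste0(model$donor_consensus, spacer, model$acceptor_consensus)
}

#' Registry of Golden-Gate-compatible C. elegans donor introns
#'
#' The packaged library of endogenous PATC-rich (and control) introns
#' available as Golden-Gate donor plasmids, keyed by plasmid id with the
#' registered length, PATC density and Addgene accession. Sequences are not
#' shipped (fetch by Addgene id) — attach them via [patc_calibrate()] to
#' recompute densities.
#'
#' @return data.frame with columns name, plasmid, site, length_bp,
#'   patc_density, addgene.
#' @export
intron_donor_registry <- function() {
  path <- system.file("extdata", "intron_donors.tsv", package = "patcraft",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Intron donor record
#'
#' @param name intron name; @param plasmid plasmid id; @param site Golden-Gate
#'   slot (1, 2 or 3); @param length_bp registered length;
#'   @param patc_density registered density; @param addgene accession;
#'   @param sequence optional DNA string (length must equal `length_bp`).
#' @return object of class `intron_donor`; when `sequence` is present the
#'   record also carries `recomputed_density` next to the registered value.
#' @export
intron_donor <- function(name, plasmid, site, length_bp, patc_density,
                         addgene = NA, sequence = NULL) {
  abort_if(!site %in% 1:3, "site must be 1, 2 or 3")
  rec <- list(name = name, plasmid = plasmid, site = as.integer(site),
              length_bp = as.integer(length_bp),
              patc_density = as.numeric(patc_density), addgene = addgene,
              sequence = NULL, recomputed_density = NA_real_)
  if (!is.null(sequence)) {
    s <- as_nt_seq(sequence, id = plasmid)
    abort_if(length(s) != rec$length_bp,
             "sequence length ", length(s), " != registered ", rec$length_bp)
    rec$sequence <- s$residues
    rec$recomputed_density <- mean(score_patc(s)$track$values)
  }
  structure(rec, class = "intron_donor")
}

#' Intron placement rules
#'
#' @param min_introns minimal intron count a design should carry.
#' @param first_exon_preferred_max_bp preferred upper bound on the first
#'   exon.
#' @param first_exon_hard_max_bp hard upper bound on the first exon.
#' @return object of class `placement_rules`.
#' @export
placement_rules <- function(min_introns = 2L,
                            first_exon_preferred_max_bp = 150L,
                            first_exon_hard_max_bp = 350L) {
  abort_if(first_exon_preferred_max_bp > first_exon_hard_max_bp,
           "preferred max must be <= hard max")
  structure(list(min_introns = as.integer(min_introns),
                 first_exon_preferred_max_bp =
                   as.integer(first_exon_preferred_max_bp),
                 first_exon_hard_max_bp = as.integer(first_exon_hard_max_bp)),
            class = "placement_rules")
}

# candidate insertion offsets: exonic AG|G junctions. Offsets are 0-based
# inter-nucleotide positions (= length of the exon prefix).
agg_junction_offsets <- function(dna) {
  n <- nchar(dna)
  if (n < 3L) return(integer(0))
  offs <- motif_starts0(dna, "AGG") + 2L   # insert between AG and G
  offs[offs >= 1L & offs <= n - 1L]
}

#' Plan intron insertion offsets for a CDS
#'
#' Candidates are exonic AG|G junctions (any inter-nucleotide offset as a
#' warned fallback). The first offset is kept within the preferred first-exon
#' bound when a candidate exists there (hard bound otherwise, error beyond
#' that); remaining offsets are chosen nearest to an even partition of the
#' residual CDS. Output is strictly increasing and deterministic.
#'
#' @param cds a [coding_sequence()] or DNA string (length >= 6).
#' @param n_introns number of introns to place (>= 1).
#' @param rules a [placement_rules()].
#' @return integer vector of 0-based insertion offsets.
#' @export
plan_intron_positions <- function(cds, n_introns, rules = placement_rules()) {
  if (!is(cds, "coding_sequence")) cds <- coding_sequence(cds)
  dna <- cds$dna
  L <- nchar(dna)
  abort_if(n_introns < 1L, "n_introns must be >= 1")
  abort_if(L < 6L, "CDS too short")
  cand <- agg_junction_offsets(dna)
  if (!length(cand)) {
    warning("no AG|G junction in CDS; falling back to arbitrary offsets")
    cand <- seq_len(L - 1L)
  }
  abort_if(n_introns > length(cand),
           "only ", length(cand), " candidate offsets for ", n_introns,
           " introns")
  limit <- if (any(cand <= rules$first_exon_preferred_max_bp))
    rules$first_exon_preferred_max_bp
  else if (any(cand <= rules$first_exon_hard_max_bp))
    rules$first_exon_hard_max_bp
  else abort_if(TRUE, "no candidate offset within the hard first-exon bound (",
                rules$first_exon_hard_max_bp, " bp)")
  ideal1 <- min(L / (n_introns + 1), limit)
  eligible <- cand[cand <= limit]
  first <- eligible[order(abs(eligible - ideal1), eligible)][1L]
  offsets <- first
  if (n_introns > 1L) {
    residual <- L - first
    for (j in seq_len(n_introns - 1L)) {
      ideal <- first + j * residual / n_introns
      pool <- cand[cand > offsets[length(offsets)]]
      abort_if(!length(pool), "not enough increasing candidates")
      offsets <- c(offsets, pool[order(abs(pool - ideal), pool)][1L])
    }
  }
  as.integer(offsets)
}

wrap_intron <- function(intron, model) {
  intron <- toupper(intron)
  if (!(startsWith(intron, "GT") && endsWith(intron, "AG")))
    intron <- paste0(model$donor_consensus, intron, model$acceptor_consensus)
  abort_if(!(startsWith(intron, "GT") && endsWith(intron, "AG")),
           "intron violates the GT-AG rule after wrapping")
  intron
}

#' Insert introns into a coding sequence
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @param offsets 0-based inter-nucleotide offsets (strictly increasing);
#'   introns may interrupt codons.
#' @param introns character vector of intron sequences, one per offset
#'   (recycled when length 1); introns not already GT..AG are wrapped with
#'   the model consensi.
#' @param model a [splice_model()].
#' @return a [construct()] whose sequence is the genomic-style product with
#'   exon and intron features annotated; every intron starts GT and ends AG.
#' @export
insert_introns <- function(cds, offsets, introns = synthetic_intron(model),
                           model = splice_model()) {
  if (!is(cds, "coding_sequence")) cds <- coding_sequence(cds)
  L <- nchar(cds$dna)
  offsets <- as.integer(offsets)
  if (length(offsets) == 0L) {
    return(construct(nt_seq(cds$dna, id = cds$id),
                     feature("exon", 0L, L, label = cds$id)))
  }
  abort_if(any(offsets <= 0L) || any(offsets >= L) ||
             any(diff(offsets) <= 0L),
           "offsets must be strictly increasing within (0, ", L, ")")
  introns <- vapply(rep_len(introns, length(offsets)), wrap_intron, "",
                    model = model, USE.NAMES = FALSE)
  bounds <- c(0L, offsets, L)
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    ex <- substr(cds$dna, bounds[i] + 1L, bounds[i + 1L])
    pieces <- c(pieces, ex)
    feats[[length(feats) + 1L]] <-
      feature("exon", pos, pos + nchar(ex), label = cds$id)
    pos <- pos + nchar(ex)
    if (i <= length(offsets)) {
      pieces <- c(pieces, introns[i])
      feats[[length(feats) + 1L]] <-
        feature("intron", pos, pos + nchar(introns[i]),
                label = sprintf("intron_%d", i))
      pos <- pos + nchar(introns[i])
    }
  }
  construct(nt_seq(paste(pieces, collapse = ""),
                   id = paste0(cds$id, "_genomic")),
            do.call(rbind, feats))
}

#' Splice a construct in silico
#'
#' Concatenates the exon features (or the complement of the intron features
#' when no exons are annotated) after validating the GT-AG rule on every
#' intron, and recomputes frame and translation.
#'
#' @param x a [construct()] with exon/intron features.
#' @param allow_internal_stops passed to [coding_sequence()].
#' @return a [coding_sequence()].
#' @export
splice <- function(x, allow_internal_stops = FALSE) {
  abort_if(!is(x, "construct"), "splice() needs a construct")
  res <- x$sequence$residues
  intr <- construct_features(x, "intron")
  for (i in seq_len(nrow(intr))) {
    iseq <- substr(res, intr$start[i] + 1L, intr$end[i])
    abort_if(!(startsWith(iseq, "GT") && endsWith(iseq, "AG")),
             "intron at ", intr$start[i] + 1L, "-", intr$end[i],
             " violates the GT-AG rule")
  }
  ex <- construct_features(x, "exon")
  if (nrow(ex) == 0L) {
    # exons = complement of introns over the whole sequence
    keep <- rep(TRUE, nchar(res))
    for (i in seq_len(nrow(intr)))
      keep[(intr$start[i] + 1L):intr$end[i]] <- FALSE
    dna <- paste(seq_chars(res)[keep], collapse = "")
  } else {
    ex <- ex[order(ex$start), , drop = FALSE]
    dna <- paste(vapply(seq_len(nrow(ex)), function(i)
      substr(res, ex$start[i] + 1L, ex$end[i]), ""), collapse = "")
  }
  coding_sequence(dna, id = sub("_genomic$", "", x$sequence$id),
                  allow_internal_stops = allow_internal_stops)
}
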