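#' @importFrom BiocGenerics start end width score
NULL

FEATURE_KINDS <- c("promoter", "exon", "intron", "three_prime_utr", "tag",
                   "operon_linker", "p2a_linker", "backbone",
                   "golden_gate_site", "enhancer", "other")

#' Nucleotide sequence object
#'
#' The universal substrate for scoring and design: a validated DNA string over
#' {A,C,G,T,N}, uppercased on ingest, with linear or circular topology.
#' `N` is permitted but treated as a universal mismatch by every scan: it
#' breaks A/T runs, homopolymers and piRNA seed matches.
#'
#' @param residues character scalar, the DNA string.
#' @param id text label.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return an object of class `nt_seq` with fields `id`, `residues`,
#'   `topology`.
#' @examples
#' s <- nt_seq("acgtn", id = "demo")
#' s$residues  # "ACGTN"
#' @export
nt_seq <- function(residues, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  abort_if(length(residues) != 1L || !is.character(residues),
           "residues must be a single character string")
  residues <- toupper(residues)
  abort_if(nchar(residues) == 0L, "empty sequence for '", id, "'")
  bad <- regexpr("[^ACGTN]", residues)
  abort_if(bad > 0L,
           "illegal residue '", substr(residues, bad, bad),
           "' at position ", bad, " in '", id, "'")
  structure(list(id = as.character(id), residues = residues,
                 topology = topology),
            class = "nt_seq")
}

#' @export
print.nt_seq <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1, min(n, 60))
  cat(sprintf("<nt_seq> %s: %d bp, %s%s\n", x$id, n, x$topology,
              if (n > 60) paste0("\n  ", head, "...") else paste0("  ", head)))
  invisible(x)
}

#' @export
length.nt_seq <- function(x) nchar(x$residues)

as_nt_seq <- function(x, id = "seq") {
  if (is(x, "nt_seq")) x else nt_seq(x, id = id)
}

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file (one or more records).
#' @return list of [nt_seq()] objects, in file order.
#' @details Residues are uppercased; any character outside {A,C,G,T,N} is an
#'   error naming the offending position.
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  abort_if(length(set) == 0L, "no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) nt_seq(as.character(set[[i]]), id = ids[i]))
}

#' Write sequences to FASTA
#'
#' @param seqs a single [nt_seq()] or list of them.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is(seqs, "nt_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(NULL)
}

#' Feature annotation table
#'
#' Builds the feature table of a [construct()]: one row per feature with a
#' controlled `kind` vocabulary and 0-based half-open coordinates on the
#' construct sequence. Reports render these 1-based inclusive via
#' [coords_to_report()].
#'
#' @param kind one of `r paste(FEATURE_KINDS, collapse = ", ")`.
#' @param start,end integer, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param label free-text label.
#' @return data.frame with columns kind, start, end, strand, label.
#' @export
feature <- function(kind, start, end, strand = "+", label = "") {
  abort_if(!all(kind %in% FEATURE_KINDS),
           "unknown feature kind: ", setdiff(kind, FEATURE_KINDS)[1])
  n <- max(length(kind), length(start))
  data.frame(kind = rep_len(kind, n),
             start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             strand = rep_len(strand, n),
             label = rep_len(as.character(label), n),
             stringsAsFactors = FALSE)
}

empty_features <- function() feature("other", 0L, 1L)[0, ]

#' Annotated transgene construct
#'
#' A construct couples a sequence with an ordered feature table (promoter,
#' exons, introns, tag, 3'-UTR, backbone, ...) and typed metadata describing
#' how the transgene is delivered (injection concentration, delivery form,
#' culture temperature) — the experimental variables the lint rules examine.
#'
#' @param sequence [nt_seq()] or character.
#' @param features data.frame from [feature()] (possibly empty).
#' @param metadata named list; recognised keys:
#'   `injection_concentration_ng_per_ul` (numeric),
#'   `delivery_form` (one of circular_plasmid, linearized, pcr_product,
#'   gel_purified), `culture_temperature_c` (numeric).
#' @param check_frame when TRUE (default) and exon features exist, require the
#'   spliced exon concatenation to have length divisible by 3 (a declared CDS).
#' @return object of class `construct`.
#' @export
construct <- function(sequence, features = empty_features(),
                      metadata = list(), check_frame = TRUE) {
  sequence <- as_nt_seq(sequence)
  n <- length(sequence)
  if (nrow(features)) {
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    abort_if(!all(features$kind %in% FEATURE_KINDS), "unknown feature kind")
    abort_if(any(features$start < 0L) || any(features$end > n) ||
               any(features$start >= features$end),
             "feature coordinates outside sequence [0, ", n, ")")
    gene <- features[features$kind %in% c("exon", "intron"), , drop = FALSE]
    for (str in unique(gene$strand)) {
      g <- gene[gene$strand == str, , drop = FALSE]
      if (nrow(g) > 1L) {
        g <- g[order(g$start), ]
        abort_if(any(g$start[-1L] < g$end[-nrow(g)]),
                 "overlapping exon/intron features on strand ", str)
      }
    }
    ex <- features[features$kind == "exon", , drop = FALSE]
    if (check_frame && nrow(ex)) {
      abort_if(sum(ex$end - ex$start) %% 3L != 0L,
               "spliced exon length not divisible by 3")
    }
  }
  md <- metadata
  if (!is.null(md$injection_concentration_ng_per_ul))
    abort_if(!is.numeric(md$injection_concentration_ng_per_ul),
             "injection_concentration_ng_per_ul must be numeric")
  if (!is.null(md$delivery_form))
    md$delivery_form <- match.arg(md$delivery_form,
      c("circular_plasmid", "linearized", "pcr_product", "gel_purified"))
  if (!is.null(md$culture_temperature_c))
    abort_if(!is.numeric(md$culture_temperature_c),
             "culture_temperature_c must be numeric")
  structure(list(sequence = sequence, features = features, metadata = md),
            class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("<construct> %s: %d bp (%s), %d features\n",
              x$sequence$id, length(x$sequence), x$sequence$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    rep1 <- coords_to_report(x$features$start, x$features$end)
    tab <- cbind(x$features[c("kind", "strand", "label")], rep1)
    print(tab[, c("kind", "start1", "end1", "strand", "label")])
  }
  invisible(x)
}

construct_features <- function(x, kinds = NULL) {
  f <- x$features
  if (!is.null(kinds)) f <- f[f$kind %in% kinds, , drop = FALSE]
  f
}

# ---- GenBank-style flat file ------------------------------------------------
# Minimal reader/writer for the LOCUS/FEATURES/ORIGIN subset the construct
# model needs (no installed R package parses GenBank flat files).
#
# Feature-key mapping on read (documented qualifier table):
#   promoter -> promoter; exon -> exon; intron -> intron; 3'UTR ->
#   three_prime_utr; CDS with join(..) -> one exon per segment plus inferred
#   introns between consecutive segments; misc_feature -> kind named by a
#   /label or /note qualifier matching a feature kind (e.g. "tag",
#   "backbone"), else other; everything else -> other. `source` is skipped.

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3L) as.integer(m[2:3])
    else {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      abort_if(length(m1) != 2L, "cannot parse location: ", p)
      rep(as.integer(m1[2]), 2L)
    }
  })
  list(strand = strand,
       segs = do.call(rbind, segs))  # 1-based inclusive
}

#' Read a construct from a GenBank-style flat file
#'
#' Parses the LOCUS line (name, length, topology), the FEATURES table and the
#' ORIGIN sequence. See the package source for the documented feature-key
#' mapping; unknown keys map to kind `other`, and a `CDS` with a `join(...)`
#' location yields one exon per segment with introns inferred between
#' consecutive segments.
#'
#' @param path GenBank flat file.
#' @return a [construct()].
#' @export
read_construct <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  abort_if(length(locus) == 0L, "no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  seq_id <- if (length(toks) >= 2) toks[2] else "seq"
  topology <- if (any(grepl("circular", toks, ignore.case = TRUE)))
    "circular" else "linear"

  o <- grep("^ORIGIN", lines)
  abort_if(length(o) == 0L, "no ORIGIN section in ", path)
  seq_lines <- lines[(o[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- nt_seq(residues, id = seq_id, topology = topology)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(o[1] - 1L)]
    # fold continuation lines; a new feature starts with a key in column 6
    recs <- list()
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) recs[[length(recs) + 1L]] <- ln
      else if (length(recs)) recs[[length(recs)]] <-
          paste0(recs[[length(recs)]], "\n", ln)
    }
    rows <- list()
    for (rec in recs) {
      recl <- strsplit(rec, "\n", fixed = TRUE)[[1]]
      head <- strsplit(trimws(recl[1]), "\\s+")[[1]]
      key <- head[1]
      loc <- paste0(head[-1], collapse = "")
      quals <- trimws(recl[-1])
      # location may continue onto qualifier-less lines
      while (length(quals) && !startsWith(quals[1], "/")) {
        loc <- paste0(loc, quals[1]); quals <- quals[-1]
      }
      if (key == "source") next
      pl <- parse_gb_location(loc)
      abort_if(any(pl$segs > length(sequence)),
               "feature location beyond sequence end in ", path)
      getq <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NULL)
        gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      label <- getq("label") %||% getq("gene") %||% getq("note") %||% ""
      kind <- switch(key,
        promoter = "promoter", exon = "exon", intron = "intron",
        "3'UTR" = "three_prime_utr",
        misc_feature = {
          hint <- tolower(c(getq("label") %||% "", getq("note") %||% ""))
          k <- intersect(hint, FEATURE_KINDS)
          if (length(k)) k[1] else "other"
        },
        CDS = "exon",
        "other")
      segs0 <- coords_from_report(pl$segs[, 1], pl$segs[, 2])
      rows[[length(rows) + 1L]] <-
        feature(kind, segs0$start0, segs0$end0, pl$strand, label)
      if (key == "CDS" && nrow(segs0) > 1L) {
        # introns between consecutive CDS segments
        rows[[length(rows) + 1L]] <- feature("intron",
          segs0$end0[-nrow(segs0)], segs0$start0[-1L], pl$strand, label)
      }
    }
    # a CDS join() implies its introns; drop duplicates when they are also
    # annotated explicitly (same kind and coordinates, labels may differ)
    if (length(rows)) {
      feats <- do.call(rbind, rows)
      feats <- feats[!duplicated(feats[, c("kind", "start", "end", "strand")]), ]
    }
  }
  construct(sequence, feats, check_frame = FALSE)
}

#' Write a construct as a GenBank-style flat file
#'
#' Inverse of [read_construct()]: exons belonging to the same label are
#' emitted as one `CDS join(...)`, other kinds map back to their GenBank keys
#' or to `misc_feature` with a `/label` naming the kind.
#'
#' @param x a [construct()].
#' @param path output file.
#' @export
write_construct <- function(x, path) {
  seq <- x$sequence
  n <- length(seq)
  out <- c(sprintf("LOCUS       %s %d bp DNA %s UNK",
                   seq$id, n, seq$topology),
           "FEATURES             Location/Qualifiers")
  fmt_loc <- function(start0, end0, strand) {
    r <- coords_to_report(start0, end0)
    segs <- sprintf("%d..%d", r$start1, r$end1)
    loc <- if (length(segs) > 1L)
      sprintf("join(%s)", paste(segs, collapse = ",")) else segs
    if (strand == "-") sprintf("complement(%s)", loc) else loc
  }
  f <- x$features
  ex <- f[f$kind == "exon", , drop = FALSE]
  rest <- f[f$kind != "exon", , drop = FALSE]
  if (nrow(ex)) {
    for (lab in unique(ex$label)) {
      e <- ex[ex$label == lab, , drop = FALSE]
      out <- c(out,
        sprintf("     CDS             %s", fmt_loc(e$start, e$end, e$strand[1])),
        sprintf("                     /label=\"%s\"", lab))
    }
  }
  for (i in seq_len(nrow(rest))) {
    key <- switch(rest$kind[i],
      promoter = "promoter", intron = "intron",
      three_prime_utr = "3'UTR", "misc_feature")
    out <- c(out,
      sprintf("     %-15s %s", key,
              fmt_loc(rest$start[i], rest$end[i], rest$strand[i])),
      sprintf("                     /label=\"%s\"", rest$kind[i]),
      if (nzchar(rest$label[i]))
        sprintf("                     /note=\"%s\"", rest$label[i]))
  }
  out <- c(out, "ORIGIN")
  res <- tolower(seq$residues)
  for (s in seq(1L, n, by = 60L)) {
    chunk <- substr(res, s, min(n, s + 59L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  writeLines(c(out, "//"), path)
  invisible(NULL)
}

# ---- score tracks -----------------------------------------------------------

#' Per-base score track
#'
#' @param values numeric vector, one non-negative value per base.
#' @param sequence_id label for the scored sequence.
#' @return object of class `score_track`.
#' @export
score_track <- function(values, sequence_id = "seq") {
  abort_if(!is.numeric(values) || length(values) == 0L, "empty track")
  abort_if(any(values < 0), "track values must be >= 0")
  structure(list(sequence_id = as.character(sequence_id),
                 values = as.numeric(values)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s: %d bases, mean %.3f, max %.3f\n",
              x$sequence_id, length(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

track_granges <- function(track, per_base = FALSE) {
  n <- length(track$values)
  if (per_base) {
    gr <- GenomicRanges::GPos(track$sequence_id, IRanges::IRanges(1L, n))
    GenomicRanges::score(gr) <- track$values
  } else {
    r <- rle(track$values)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    gr <- GenomicRanges::GRanges(track$sequence_id,
                                 IRanges::IRanges(starts, ends),
                                 score = r$values)
  }
  GenomeInfoDb_safe_seqlengths(gr, track$sequence_id, n)
}

GenomeInfoDb_safe_seqlengths <- function(gr, id, n) {
  sl <- stats::setNames(n, id)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- sl)
  gr
}

#' Write a score track to bedGraph or wiggle
#'
#' bedGraph intervals are 0-based half-open with runs of equal values merged;
#' wiggle uses per-base `fixedStep start=1 step=1` (1-based), both per the
#' UCSC standards (serialized via rtracklayer).
#'
#' @param track a [score_track()].
#' @param path output file.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wiggle")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    rtracklayer::export(track_granges(track), path, format = "bedGraph")
  } else {
    rtracklayer::export(track_granges(track, per_base = TRUE), path,
                        format = "wig")
  }
  invisible(NULL)
}

#' Read a score track written by [write_track()]
#'
#' @param path bedGraph or wiggle file.
#' @param format `"bedgraph"` or `"wiggle"` (guessed from the extension when
#'   missing).
#' @return a [score_track()].
#' @export
read_track <- function(path, format = NULL) {
  abort_if(!file.exists(path), "no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.wig(gle)?$", path, ignore.case = TRUE))
      "wiggle" else "bedgraph"
  }
  gr <- rtracklayer::import(path, format = if (format == "wiggle") "wig"
                            else "bedGraph")
  n <- max(BiocGenerics::end(gr))
  vals <- numeric(n)
  for (i in seq_along(gr)) {
    vals[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <-
      GenomicRanges::score(gr)[i]
  }
  score_track(vals, as.character(GenomeInfoDb::seqnames(gr))[1])
}
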