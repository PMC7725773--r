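# Shared fixtures, all built in code (no files).

CODONS64 <- patcraft:::CODONS64
STOP_CODONS <- patcraft:::STOP_CODONS

# codon table with every weight 1 (CAI of anything is 1)
uniform_codon_table <- function() {
  codon_usage_table(data.frame(codon = CODONS64, weight = 1),
                    provenance = "uniform test table")
}

# uniform table with selected codons down-weighted
tweaked_codon_table <- function(down) {
  df <- data.frame(codon = CODONS64, weight = 1)
  df$weight[df$codon %in% names(down)] <- unlist(down)
  codon_usage_table(df, provenance = "tweaked test table")
}

random_protein <- function(n_aa, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed,
    paste(sample(aas, n_aa, replace = TRUE), collapse = ""))
}

# random CDS without internal stops
random_cds <- function(n_aa, seed) {
  sense <- setdiff(CODONS64, STOP_CODONS)
  withr::with_seed(seed,
    coding_sequence(paste(sample(sense, n_aa, replace = TRUE),
                          collapse = "")))
}

no_bsai <- function(x) {
  !grepl("GGTCTC", x, fixed = TRUE) && !grepl("GAGACC", x, fixed = TRUE)
}

# --- Golden-Gate fixture: acceptor with `n_slots` exchange stubs + donors --
#
# Acceptor stub anatomy (cuts at t_L and t_R, overhangs oL/oR):
#   GTAAGTTT | [oL] A GAGACC  filler  GGTCTC A [oR] | TTTTCAG
# i.e. both recognition sites sit inside the excised stub, so only a
# site-free donor insert can replace it. Donor circle:
#   CC GGTCTC A [oL] interior | [oR] A GAGACC  backbone-filler
GG_OVERHANGS <- list(c("AACG", "TCAC"), c("CGAA", "ATCG"), c("GCAT", "TGCA"))

gg_stub <- function(ov) {
  paste0(ov[1], "A", "GAGACC", "TTCATTCA", "GGTCTC", "A", ov[2])
}

gg_intron_with_stub <- function(ov) {
  paste0("GTAAGTTT", gg_stub(ov), "TTTTCAG")
}

make_gg_donor <- function(slot, interior = strrep("AAAAAAGCGG", 12)) {
  ov <- GG_OVERHANGS[[slot]]
  res <- paste0("CC", "GGTCTC", "A", ov[1], interior, ov[2], "A", "GAGACC",
                "TCTTCCTTCT")
  construct(nt_seq(res, id = sprintf("donor_site%d", slot),
                   topology = "circular"))
}

make_gg_acceptor <- function(n_slots = 3, n_aa = 60, seed = 42) {
  cds <- optimize_codons(random_protein(n_aa, seed),
                         table = uniform_codon_table(),
                         id = "cds")$cds
  L <- nchar(cds$dna)
  offsets <- as.integer(round(seq_len(n_slots) * L / (n_slots + 1)))
  bounds <- c(0L, offsets, nchar(cds$dna))
  promoter <- "TCTCCTCTTCCTTCTCCTTATAAATCCTCC"
  utr <- "TTATTCCATCTCCTTCTTCCATTTG"
  pieces <- promoter
  feats <- list(feature("promoter", 0L, nchar(promoter), label = "Ppie-1"))
  pos <- nchar(promoter)
  for (i in seq_len(length(bounds) - 1L)) {
    ex <- substr(cds$dna, bounds[i] + 1L, bounds[i + 1L])
    pieces <- c(pieces, ex)
    feats[[length(feats) + 1L]] <- feature("exon", pos, pos + nchar(ex),
                                           label = "cds")
    pos <- pos + nchar(ex)
    if (i <= n_slots) {
      intr <- gg_intron_with_stub(GG_OVERHANGS[[i]])
      pieces <- c(pieces, intr)
      feats[[length(feats) + 1L]] <- feature("intron", pos, pos + nchar(intr),
                                             label = sprintf("stub_%d", i))
      pos <- pos + nchar(intr)
    }
  }
  pieces <- c(pieces, utr)
  feats[[length(feats) + 1L]] <- feature("three_prime_utr", pos,
                                         pos + nchar(utr), label = "smu-1")
  res <- paste(pieces, collapse = "")
  construct(nt_seq(res, id = "acceptor", topology = "circular"),
            do.call(rbind, feats))
}

# --- lint fixture: promoter + intron-containing CDS + tag + UTR ------------
PATC_RICH_INTERIOR <- strrep("AAAAAAGCGG", 25)   # ~250 bp, density >> 100

make_lint_fixture <- function(tag_terminal = c("C", "N", "none"),
                              n_introns = 2, patc_rich = TRUE,
                              metadata = list(
                                injection_concentration_ng_per_ul = 25,
                                delivery_form = "pcr_product",
                                culture_temperature_c = 25),
                              db = NULL, seed = 7) {
  tag_terminal <- match.arg(tag_terminal)
  rep <- optimize_codons(random_protein(90, seed), db = db, id = "cds")
  cds <- rep$cds
  interior <- if (patc_rich) PATC_RICH_INTERIOR else strrep("CTATAC", 40)
  intron <- paste0("GTAAGTTT", interior, "TTTTCAG")
  genomic <- if (n_introns > 0) {
    # early first intron at base 48, the rest evenly spaced
    L <- nchar(cds$dna)
    offs <- unique(as.integer(c(48L, 48L + seq_len(n_introns - 1L) *
                                  (L - 48L) %/% n_introns)))
    insert_introns(cds, offs, intron)
  } else {
    construct(nt_seq(cds$dna, id = "cds_genomic"),
              feature("exon", 0L, nchar(cds$dna), label = "cds"))
  }
  promoter <- "TCTCCTCTTCCTTCTCCTTATAAATCCTCC"
  tag <- "TCCTCCGCCACCTCCTCCACCTCCGCCTCC"  # stand-in fluorophore region
  utr <- "TTATTCCATCTCCTTCTTCCATTTG"
  g <- genomic$sequence$residues
  gf <- genomic$features
  if (tag_terminal == "N") {
    res <- paste0(promoter, tag, g, utr)
    off <- nchar(promoter) + nchar(tag)
    feats <- rbind(
      feature("promoter", 0L, nchar(promoter)),
      feature("tag", nchar(promoter), off, label = "gfp"),
      feature(gf$kind, gf$start + off, gf$end + off, gf$strand, gf$label),
      feature("three_prime_utr", off + nchar(g), off + nchar(g) + nchar(utr)))
  } else {
    res <- paste0(promoter, g, if (tag_terminal == "C") tag else "", utr)
    off <- nchar(promoter)
    feats <- rbind(
      feature("promoter", 0L, nchar(promoter)),
      feature(gf$kind, gf$start + off, gf$end + off, gf$strand, gf$label),
      if (tag_terminal == "C")
        feature("tag", off + nchar(g), off + nchar(g) + nchar(tag),
                label = "gfp"),
      feature("three_prime_utr", off + nchar(g) +
                ifelse(tag_terminal == "C", nchar(tag), 0L),
              off + nchar(g) + ifelse(tag_terminal == "C", nchar(tag), 0L) +
                nchar(utr)))
  }
  construct(nt_seq(res, id = "lint_fixture"), feats, metadata)
}

# a piRNA guaranteed plantable into `cds`: its perfect target is a
# codon-aligned 21-nt window of the CDS, optionally recoded synonymously
# (`twist`) so that planting requires real substitutions
derive_plantable_pirna <- function(cds, codon_start = 4L, twist = FALSE) {
  codons <- patcraft:::split_codons(cds$dna)
  idx <- codon_start:(codon_start + 6L)
  stopifnot(max(idx) <= length(codons))
  win <- codons[idx]
  if (twist) {
    for (j in seq_along(win)) {
      syn <- patcraft:::synonymous_codons(Biostrings::GENETIC_CODE[win[j]])
      alt <- setdiff(syn, win[j])
      if (length(alt)) win[j] <- alt[1]
    }
  }
  list(pirna = revcomp(paste(win, collapse = "")),
       target_start = (codon_start - 1L) * 3L)
}

lint_statuses <- function(report) {
  stats::setNames(vapply(report$entries, `[[`, "", "status"),
                  vapply(report$entries, `[[`, "", "rule"))
}
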