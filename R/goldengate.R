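# BsaI digestion and Golden-Gate assembly simulation.
#
# BsaI recognizes GGTCTC and cuts outside the site: the top strand 1 nt 3'
# of the recognition sequence and the bottom strand 5 nt 3', leaving 4-nt 5'
# overhangs. In top-strand coordinates a site on either strand produces a
# cut pair (t, t + 4); the 4 bases seq[t .. t+3] are the programmable
# overhang. Fragments are represented with those 4 nt at the start of the
# downstream body, so bodies concatenate back to the input exactly and two
# ends ligate iff their overhang strings are equal.

#' Golden-Gate fragment
#'
#' @param body top-strand sequence of the double-stranded fragment, including
#'   the 4 overhang nt at its 5' end when present.
#' @param left_overhang,right_overhang 4-nt 5' overhang strings ("" for a
#'   blunt end).
#' @param source id of the construct the fragment came from.
#' @param source_start 0-based position of `body` in the source sequence.
#' @return object of class `gg_fragment`.
#' @export
gg_fragment <- function(body, left_overhang = "", right_overhang = "",
                        source = "seq", source_start = 0L) {
  abort_if(!nchar(left_overhang) %in% c(0L, 4L) ||
             !nchar(right_overhang) %in% c(0L, 4L),
           "overhangs must be empty or 4 nt")
  structure(list(body = toupper(body), left_overhang = left_overhang,
                 right_overhang = right_overhang, source = source,
                 source_start = as.integer(source_start)),
            class = "gg_fragment")
}

#' @export
print.gg_fragment <- function(x, ...) {
  cat(sprintf("<gg_fragment> %d bp from %s@%d  [%s ... %s]\n",
              nchar(x$body), x$source, x$source_start,
              ifelse(nzchar(x$left_overhang), x$left_overhang, "blunt"),
              ifelse(nzchar(x$right_overhang), x$right_overhang, "blunt")))
  invisible(x)
}

BSAI_SITE <- "GGTCTC"

# top-strand cut coordinates t (cut pair is (t, t+4)) for all BsaI sites on
# either strand; NA-free, restricted to cuts the enzyme can complete
bsaI_cut_points <- function(res, circular) {
  n <- nchar(res)
  scan <- if (circular) paste0(res, res) else res
  top <- motif_starts0(scan, BSAI_SITE)
  bot <- motif_starts0(scan, revcomp(BSAI_SITE))
  if (circular) { top <- top[top < n]; bot <- bot[bot < n] }
  t_top <- top + 7L
  t_bot <- bot - 5L
  if (circular) {
    ts <- sort(unique(c(t_top, t_bot) %% n))
  } else {
    ts <- sort(unique(c(t_top[t_top + 4L <= n & t_top >= 0L],
                        t_bot[t_bot + 4L <= n & t_bot >= 0L])))
  }
  as.integer(ts)
}

#' Digest a sequence with BsaI
#'
#' @param seq an [nt_seq()] (topology honored: circular inputs are cut
#'   across the origin) or character string.
#' @return list of [gg_fragment()]s in 5' to 3' order along the top strand.
#'   With zero completable cut sites a single blunt fragment is returned
#'   with a warning.
#' @export
bsaI_digest <- function(seq) {
  seq <- as_nt_seq(seq)
  res <- seq$residues
  n <- nchar(res)
  circular <- seq$topology == "circular"
  ts <- bsaI_cut_points(res, circular)
  ov_at <- function(t) {
    if (t + 4L <= n) substr(res, t + 1L, t + 4L)
    else paste0(substr(res, t + 1L, n), substr(res, 1L, t + 4L - n))
  }
  if (length(ts) == 0L) {
    warning("no BsaI site; returning a single blunt fragment")
    return(list(gg_fragment(res, source = seq$id)))
  }
  frags <- list()
  if (circular) {
    for (i in seq_along(ts)) {
      from <- ts[i]
      to <- if (i < length(ts)) ts[i + 1L] else ts[1L]
      body <- if (to > from) substr(res, from + 1L, to)
      else paste0(substr(res, from + 1L, n), substr(res, 1L, to))
      frags[[i]] <- gg_fragment(body, ov_at(from), ov_at(to),
                                source = seq$id, source_start = from)
    }
  } else {
    bounds <- unique(c(0L, ts, n))
    for (i in seq_len(length(bounds) - 1L)) {
      from <- bounds[i]; to <- bounds[i + 1L]
      frags[[i]] <- gg_fragment(substr(res, from + 1L, to),
                                if (from %in% ts) ov_at(from) else "",
                                if (to %in% ts) ov_at(to) else "",
                                source = seq$id, source_start = from)
    }
  }
  frags
}

frag_has_site <- function(f) {
  grepl(BSAI_SITE, f$body, fixed = TRUE) ||
    grepl(revcomp(BSAI_SITE), f$body, fixed = TRUE)
}

#' Simulate Golden-Gate intron exchange
#'
#' Digests the acceptor and every donor with BsaI and joins fragments by
#' unique overhang matching into a single closed product. Site-free
#' fragments take precedence at every junction, so a donor insert displaces
#' the acceptor's site-carrying exchange stub; a slot with no donor retains
#' its stub (recorded as a warning, since the stub's recognition sites
#' persist). Splice signals live on the acceptor side of each junction
#' (donor introns carry none), so after assembly the product is spliced and
#' its translation compared against the acceptor's reference CDS.
#'
#' @param acceptor a [construct()] with exon features and BsaI sites flanking
#'   its exchange stubs.
#' @param donors list of [construct()]s (or a single one), each carrying one
#'   insert flanked by BsaI sites. Donor order is irrelevant (set
#'   semantics).
#' @return list of class `gg_assembly`: `product` (circular [construct()]
#'   with remapped exon features and inferred introns), `spliced`
#'   ([coding_sequence()]), `junctions` (overhangs used), `retained_stubs`,
#'   `warnings`.
#' @export
golden_gate_assemble <- function(acceptor, donors = list()) {
  abort_if(!is(acceptor, "construct"), "acceptor must be a construct")
  if (is(donors, "construct")) donors <- list(donors)
  reference <- splice(acceptor)

  frags <- bsaI_digest(acceptor$sequence)
  origin <- rep("acceptor", length(frags))
  for (d in donors) {
    abort_if(!is(d, "construct"), "donors must be constructs")
    df <- bsaI_digest(d$sequence)
    frags <- c(frags, df)
    origin <- c(origin, rep("donor", length(df)))
  }
  ligatable <- vapply(frags, function(f)
    nchar(f$left_overhang) == 4L && nchar(f$right_overhang) == 4L, TRUE)
  site_free <- !vapply(frags, frag_has_site, TRUE)

  # ambiguity: two site-free ligatable fragments competing for one overhang
  lo <- vapply(frags, `[[`, "", "left_overhang")
  competing <- lo[ligatable & site_free]
  abort_if(anyDuplicated(competing) > 0,
           "ambiguous assembly: duplicate overhang ",
           competing[duplicated(competing)][1L])

  # start from the acceptor fragment with the smallest source start among
  # site-free ligatable fragments (deterministic)
  acc_idx <- which(origin == "acceptor" & ligatable & site_free)
  abort_if(!length(acc_idx), "acceptor contributes no ligatable fragment")
  startf <- acc_idx[order(vapply(frags[acc_idx], `[[`, 0L, "source_start"))][1L]

  pick_next <- function(ov, used) {
    pool <- which(ligatable & lo == ov & !seq_along(frags) %in% used)
    free <- pool[site_free[pool]]
    if (length(free) > 1L)
      stop("ambiguous assembly: duplicate overhang ", ov, call. = FALSE)
    if (length(free) == 1L) return(free)
    carr <- pool[!site_free[pool]]
    if (length(carr) > 1L)
      stop("ambiguous assembly: duplicate overhang ", ov, call. = FALSE)
    if (length(carr) == 1L) return(carr)
    stop("no closed product: dead end at overhang ", ov, call. = FALSE)
  }

  chain <- startf
  repeat {
    cur <- frags[[chain[length(chain)]]]
    if (length(chain) > 1L &&
        cur$right_overhang == frags[[startf]]$left_overhang) break
    chain <- c(chain, pick_next(cur$right_overhang, chain))
    abort_if(length(chain) > length(frags), "no closed product: cycle failure")
  }

  used <- frags[chain]
  retained <- chain[!site_free[chain]]
  warnings <- character(0)
  product_res <- paste(vapply(used, `[[`, "", "body"), collapse = "")
  # residual recognition sites in the closed product
  scan2 <- paste0(product_res, substr(product_res, 1L, 10L))
  residual <- length(motif_starts0(scan2, BSAI_SITE)) +
    length(motif_starts0(scan2, revcomp(BSAI_SITE)))
  if (residual > 0L) {
    abort_if(length(retained) == 0L,
             "residual BsaI site in assembled product")
    warnings <- c(warnings, sprintf(
      "%d residual BsaI recognition site(s) in %d retained exchange stub(s)",
      residual, length(retained)))
  }

  # rotate the circular product so position 0 coincides with the acceptor's
  # origin (which survives inside one acceptor fragment); otherwise the
  # product starts mid-gene and exon bookkeeping wraps
  sources <- c(list(acceptor), donors)
  src_of <- function(f) {
    for (s in sources) if (s$sequence$id == f$source) return(s)
    NULL
  }
  offs <- cumsum(c(0L, vapply(used, function(f) nchar(f$body), 0L)))
  n_prod <- nchar(product_res)
  n_acc <- length(acceptor$sequence)
  rot <- 0L
  for (i in seq_along(used)) {
    f <- used[[i]]
    if (f$source != acceptor$sequence$id) next
    span_end <- f$source_start + nchar(f$body)
    if (f$source_start == 0L) { rot <- offs[i]; break }
    if (span_end > n_acc) { rot <- offs[i] + (n_acc - f$source_start); break }
  }
  if (rot > 0L) {
    product_res <- paste0(substr(product_res, rot + 1L, n_prod),
                          substr(product_res, 1L, rot))
  }
  feats <- list()
  for (i in seq_along(used)) {
    f <- used[[i]]
    src <- src_of(f)
    if (is.null(src) || !nrow(src$features)) next
    n_src <- length(src$sequence)
    span <- c(f$source_start, f$source_start + nchar(f$body))
    ft <- src$features
    for (r in seq_len(nrow(ft))) {
      s0 <- ft$start[r]; e0 <- ft$end[r]
      shift <- if (s0 >= span[1] && e0 <= span[2]) 0L
      else if (s0 + n_src >= span[1] && e0 + n_src <= span[2]) n_src
      else next
      p0 <- (offs[i] + (s0 + shift - span[1]) - rot) %% n_prod
      p1 <- p0 + (e0 - s0)
      if (p1 > n_prod) next   # feature would span the rotated origin
      feats[[length(feats) + 1L]] <- feature(
        ft$kind[r], p0, p1, ft$strand[r], ft$label[r])
    }
  }
  feats <- if (length(feats)) do.call(rbind, feats) else empty_features()
  # drop stale intron annotations; introns are re-inferred between exons
  feats <- feats[feats$kind != "intron", , drop = FALSE]
  ex <- feats[feats$kind == "exon", , drop = FALSE]
  if (nrow(ex) > 1L) {
    ex <- ex[order(ex$start), ]
    gaps <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    if (nrow(gaps))
      feats <- rbind(feats, feature("intron", gaps$start, gaps$end,
                                    label = "inferred"))
  }
  product <- construct(nt_seq(product_res,
                              id = paste0(acceptor$sequence$id, "_assembled"),
                              topology = "circular"),
                       feats)
  spliced <- splice(product)
  abort_if(spliced$protein != reference$protein, "splice-integrity failure")

  structure(list(
    product = product, spliced = spliced,
    junctions = vapply(used, `[[`, "", "left_overhang"),
    fragments = data.frame(
      source = vapply(used, `[[`, "", "source"),
      origin = origin[chain],
      start = vapply(used, `[[`, 0L, "source_start"),
      length = vapply(used, function(f) nchar(f$body), 0L),
      overhang = vapply(used, `[[`, "", "left_overhang"),
      site_free = site_free[chain], stringsAsFactors = FALSE),
    retained_stubs = length(retained),
    warnings = warnings),
    class = "gg_assembly")
}

#' @export
print.gg_assembly <- function(x, ...) {
  cat(sprintf("<gg_assembly> %s: %d bp circular, %d fragments, junctions %s\n",
              x$product$sequence$id, length(x$product$sequence),
              nrow(x$fragments), paste(x$junctions, collapse = "/")))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}
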