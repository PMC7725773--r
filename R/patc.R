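# Periodic A_n/T_n Cluster (PATC) scoring.
#
# PATCs are a non-coding DNA signature of germline-expressed C. elegans
# genes: short mononucleotide A or T runs recurring in phase with the DNA
# helical repeat (~10 bp). The model here scores a sequence by (1) finding
# maximal A/T runs, (2) chaining runs whose center-to-center spacing is a
# near-multiple of the helical period via a longest-path DP on the run DAG,
# and (3) painting each chained cluster's score over its span.

#' PATC scoring parameters
#'
#' All constants of the run-chaining model, exposed so a parameter profile
#' can be pinned against an external reference implementation.
#'
#' @param min_run_length minimal A/T run length counted as a run (bp).
#' @param period_bp helical repeat used as the expected run spacing (bp).
#' @param period_tolerance_bp allowed deviation of a spacing from a period
#'   multiple (bp); must be `< period_bp / 2`.
#' @param max_skipped_periods runs may be `k * period_bp` apart for
#'   `k <= max_skipped_periods + 1`.
#' @param run_score_cap a run contributes `min(length, cap)` to a chain.
#' @param skip_penalty score subtracted per skipped period on an edge.
#' @param min_cluster_runs minimal chain length reported as a cluster.
#' @param mode `"classic"` scores the given strand; `"balanced"` averages the
#'   classic track with the position-mapped classic track of the reverse
#'   complement, making the score strand-symmetric by construction.
#' @return object of class `patc_params`.
#' @export
patc_params <- function(min_run_length = 3L, period_bp = 10,
                        period_tolerance_bp = 2, max_skipped_periods = 2L,
                        run_score_cap = 6L, skip_penalty = 1,
                        min_cluster_runs = 4L,
                        mode = c("classic", "balanced")) {
  mode <- match.arg(mode)
  p <- list(min_run_length = as.integer(min_run_length),
            period_bp = as.numeric(period_bp),
            period_tolerance_bp = as.numeric(period_tolerance_bp),
            max_skipped_periods = as.integer(max_skipped_periods),
            run_score_cap = as.integer(run_score_cap),
            skip_penalty = as.numeric(skip_penalty),
            min_cluster_runs = as.integer(min_cluster_runs),
            mode = mode)
  abort_if(any(unlist(p[1:7]) <= 0) && p$skip_penalty < 0,
           "all PATC parameters must be positive")
  abort_if(p$min_run_length < 1L, "min_run_length must be >= 1")
  abort_if(p$period_tolerance_bp >= p$period_bp / 2,
           "period_tolerance_bp must be < period_bp / 2")
  structure(p, class = "patc_params")
}

#' Find maximal A and T mononucleotide runs
#'
#' @param seq an [nt_seq()] or character string.
#' @param min_run_length minimal run length (>= 1).
#' @return data.frame with 0-based `start`, `length`, `base` (A or T) and
#'   `center = start + (length - 1) / 2`, sorted by start. `N` breaks runs.
#' @examples
#' find_at_runs("AAATTTT", 3)
#' @export
find_at_runs <- function(seq, min_run_length = 3L) {
  abort_if(min_run_length < 1L, "min_run_length must be >= 1")
  seq <- as_nt_seq(seq)
  r <- rle(seq_chars(seq$residues))
  ends <- cumsum(r$lengths)
  keep <- r$values %in% c("A", "T") & r$lengths >= min_run_length
  start <- (ends - r$lengths)[keep]          # 0-based
  len <- r$lengths[keep]
  data.frame(start = as.integer(start), length = as.integer(len),
             base = r$values[keep],
             center = start + (len - 1) / 2)
}

# periodicity predicate: for spacing d pick the k in 1..kmax minimizing
# |d - k*period|; feasible if the minimum is within tolerance.
best_skip_k <- function(d, params) {
  kmax <- params$max_skipped_periods + 1L
  ks <- seq_len(kmax)
  dev <- abs(d - ks * params$period_bp)
  k <- ks[which.min(dev)]
  if (min(dev) <= params$period_tolerance_bp) k else NA_integer_
}

run_base_score <- function(len, params)
  as.numeric(pmin(len, params$run_score_cap))

edge_weight <- function(len_j, k, params) {
  max(0, run_base_score(len_j, params) - params$skip_penalty * (k - 1L))
}

# DP over the run DAG; returns per-run best chain score S, predecessor index
# (NA when the run starts its best chain) and edge bookkeeping.
patc_chain_dp <- function(runs, params) {
  m <- nrow(runs)
  S <- run_base_score(runs$length, params)
  pred <- rep(NA_integer_, m)
  if (m >= 2L) {
    for (j in 2:m) {
      best <- S[j]; bi <- NA_integer_
      for (i in 1:(j - 1L)) {
        k <- best_skip_k(runs$center[j] - runs$center[i], params)
        if (is.na(k)) next
        cand <- S[i] + edge_weight(runs$length[j], k, params)
        # ties broken toward the predecessor with the smaller start, and
        # toward chaining over starting fresh (deterministic traceback)
        if (cand > S[j] || (cand == S[j] && is.na(bi))) {
          S[j] <- cand
          bi <- i
        }
      }
      pred[j] <- bi
    }
  }
  list(S = S, pred = pred)
}

traceback_chain <- function(j, pred) {
  chain <- j
  while (!is.na(pred[chain[1L]])) chain <- c(pred[chain[1L]], chain)
  chain
}

#' Score PATCs along a sequence
#'
#' Runs the chain model: maximal A/T runs are chained when consecutive run
#' centers sit a near-multiple of the helical period apart; each run adds
#' `min(length, run_score_cap)` minus a penalty per skipped period; the best
#' chain through each run is found by longest-path dynamic programming.
#' Chains of at least `min_cluster_runs` runs become clusters, and every base
#' in a cluster's span receives the chain score (overlaps take the maximum).
#'
#' @param seq an [nt_seq()] or character string.
#' @param params a [patc_params()] profile; its `mode` selects classic or
#'   balanced scoring.
#' @return list of class `patc_result` with elements `track`
#'   ([score_track()]), `clusters` (list; each has `runs`, `chain_score`,
#'   `span` 0-based half-open), `runs` and `params`.
#' @examples
#' res <- score_patc(strrep("AAAAAAGCGG", 8))
#' patc_summary(res)
#' @export
score_patc <- function(seq, params = patc_params()) {
  seq <- as_nt_seq(seq)
  if (params$mode == "balanced") {
    cl <- params; cl$mode <- "classic"
    fwd <- score_patc(seq, cl)
    rev <- score_patc(nt_seq(revcomp(seq$residues), id = seq$id), cl)
    vals <- (fwd$track$values + base::rev(rev$track$values)) / 2
    out <- fwd
    out$track <- score_track(vals, seq$id)
    out$params <- params
    return(out)
  }
  n <- length(seq)
  runs <- find_at_runs(seq, params$min_run_length)
  vals <- numeric(n)
  clusters <- list()
  if (nrow(runs) >= params$min_cluster_runs) {
    dp <- patc_chain_dp(runs, params)
    used_as_pred <- unique(dp$pred[!is.na(dp$pred)])
    terminals <- setdiff(seq_len(nrow(runs)), used_as_pred)
    for (j in terminals) {
      chain <- traceback_chain(j, dp$pred)
      if (length(chain) < params$min_cluster_runs || dp$S[j] <= 0) next
      span <- c(runs$start[chain[1L]],
                runs$start[j] + runs$length[j])      # 0-based half-open
      clusters[[length(clusters) + 1L]] <-
        list(runs = runs[chain, , drop = FALSE],
             chain_score = dp$S[j],
             span = as.integer(span))
      idx <- (span[1] + 1L):span[2]
      vals[idx] <- pmax(vals[idx], dp$S[j])
    }
    clusters <- clusters[order(vapply(clusters, function(cl) cl$span[1], 0))]
  }
  structure(list(track = score_track(vals, seq$id), clusters = clusters,
                 runs = runs, params = params),
            class = "patc_result")
}

#' @export
print.patc_result <- function(x, ...) {
  cat(sprintf("<patc_result> %s (%s mode): %d runs, %d clusters, density %.2f\n",
              x$track$sequence_id, x$params$mode, nrow(x$runs),
              length(x$clusters), mean(x$track$values)))
  invisible(x)
}

#' Exhaustive chain-score oracle
#'
#' Independent of the DP: enumerates every periodicity-respecting run chain
#' by depth-first search and returns the maximal chain score. Exponential in
#' the number of runs, intended for validation on instances with <= ~12 runs.
#'
#' @param runs run table from [find_at_runs()].
#' @param params a [patc_params()] profile.
#' @return maximal chain score over all chains (0 when there are no runs).
#' @export
patc_chain_bruteforce <- function(runs, params = patc_params()) {
  m <- nrow(runs)
  if (m == 0L) return(0)
  best <- 0
  extend <- function(j, sc) {
    best <<- max(best, sc)
    if (j < m) for (nx in (j + 1L):m) {
      k <- best_skip_k(runs$center[nx] - runs$center[j], params)
      if (!is.na(k))
        extend(nx, sc + edge_weight(runs$length[nx], k, params))
    }
  }
  for (s in seq_len(m)) extend(s, run_base_score(runs$length[s], params))
  best
}

#' Summarize a PATC track over a region
#'
#' @param x a `patc_result` from [score_patc()], or a bare [score_track()]
#'   (cluster counts then fall back to maximal positive-score segments).
#' @param region optional `c(start, end)`, 0-based half-open; default whole
#'   sequence.
#' @return list of class `patc_summary`: `density` (mean per-base score over
#'   the region — the normalization used in every report), `covered_fraction`
#'   (fraction of bases with positive score), `n_clusters`,
#'   `max_chain_score`.
#' @export
patc_summary <- function(x, region = NULL) {
  track <- if (is(x, "patc_result")) x$track else x
  abort_if(!is(track, "score_track"), "need a patc_result or score_track")
  n <- length(track$values)
  if (is.null(region)) region <- c(0L, n)
  abort_if(region[1] < 0 || region[2] > n || region[1] >= region[2],
           "empty or out-of-bounds region")
  vals <- track$values[(region[1] + 1L):region[2]]
  if (is(x, "patc_result")) {
    hit <- vapply(x$clusters, function(cl)
      cl$span[1] < region[2] && cl$span[2] > region[1], TRUE)
    ncl <- sum(hit)
    mx <- if (ncl) max(vapply(x$clusters[hit], `[[`, 0, "chain_score")) else 0
  } else {
    r <- rle(vals > 0)
    ncl <- sum(r$values)
    mx <- max(c(0, vals))
  }
  structure(list(density = mean(vals),
                 covered_fraction = mean(vals > 0),
                 n_clusters = as.integer(ncl),
                 max_chain_score = mx),
            class = "patc_summary")
}

#' @export
print.patc_summary <- function(x, ...) {
  cat(sprintf(
    "<patc_summary> density %.3f, covered %.1f%%, %d clusters, max chain %.1f\n",
    x$density, 100 * x$covered_fraction, x$n_clusters, x$max_chain_score))
  invisible(x)
}

#' Windowed PATC densities
#'
#' Scores the full sequence once, then summarizes the resulting track per
#' window (no per-window rescoring, so window sums are conserved).
#'
#' @param seq an [nt_seq()] or character string.
#' @param params a [patc_params()] profile.
#' @param window window width in bp (>= `period_bp`).
#' @param step step between window starts in bp (>= 1).
#' @return data.frame with 0-based half-open `start`, `end` and `density`
#'   columns, one row per window.
#' @export
scan_windows <- function(seq, params = patc_params(), window = 100L,
                         step = 50L) {
  seq <- as_nt_seq(seq)
  abort_if(window < params$period_bp, "window must be >= period_bp")
  abort_if(step < 1L, "step must be >= 1")
  n <- length(seq)
  res <- score_patc(seq, params)
  if (window > n) {
    warning("window longer than sequence; returning one whole-sequence row")
    return(data.frame(start = 0L, end = n,
                      density = mean(res$track$values)))
  }
  starts <- seq(0L, n - window, by = step)
  if (starts[length(starts)] + window < n &&
      (n - window) %% step != 0L) starts <- c(starts, n - window)
  dens <- vapply(starts, function(s)
    mean(res$track$values[(s + 1L):(s + window)]), 0)
  data.frame(start = as.integer(starts), end = as.integer(starts + window),
             density = dens)
}

#' Recompute registered intron densities from sequences
#'
#' Calibration helper: given the packaged intron-donor registry and a FASTA
#' of the corresponding intron sequences (named by plasmid id), recomputes
#' classic-mode densities under a parameter profile and tabulates them next
#' to the registered values. Intended for pinning a profile against an
#' external reference implementation; the sequences themselves are not
#' shipped and must be supplied by the user (Addgene ids are in the
#' registry).
#'
#' @param fasta path to a FASTA whose record ids are plasmid ids.
#' @param registry registry data.frame from [intron_donor_registry()].
#' @param params a [patc_params()] profile.
#' @return data.frame: plasmid, length_bp, registered density, recomputed
#'   density.
#' @export
patc_calibrate <- function(fasta, registry = intron_donor_registry(),
                           params = patc_params()) {
  seqs <- read_fasta(fasta)
  ids <- vapply(seqs, function(s) s$id, "")
  hit <- registry[registry$plasmid %in% ids, , drop = FALSE]
  abort_if(nrow(hit) == 0L, "no FASTA record matches a registry plasmid id")
  hit$recomputed_density <- vapply(hit$plasmid, function(p) {
    s <- seqs[[match(p, ids)]]
    mean(score_patc(s, params)$track$values)
  }, 0)
  hit
}
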