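# Rule-based linting of annotated constructs against eight germline-
# expression engineering rules (codon adaptation + piRNA depletion + introns;
# PATC-rich introns in the CDS; C-terminal tags; injection concentration;
# two early introns; backbone removal; co-expression linkers; 25 C culture).
# Statuses are advisory (pass/warn/fail/not_applicable/unknown), never
# blocking: the rules encode wet-lab findings, not logical necessities.

#' Lint thresholds
#'
#' @param min_cai minimal CAI (rule 1).
#' @param max_pirna_score maximal piRNA score (rule 1).
#' @param min_intron_patc_density balanced PATC density above which an intron
#'   counts as PATC-rich (rule 2). The default 100 sits between the
#'   registered control introns (<= 17) and PATC-rich introns (>= 365) and is
#'   recorded in the report.
#' @param min_introns,first_intron_max_offset_bp rule 5.
#' @param min_concentration_ng_per_ul rule 4.
#' @param recommended_temperature_c rule 8.
#' @return object of class `lint_thresholds`.
#' @export
lint_thresholds <- function(min_cai = 0.9, max_pirna_score = 0,
                            min_intron_patc_density = 100,
                            min_introns = 2L,
                            first_intron_max_offset_bp = 150L,
                            min_concentration_ng_per_ul = 25,
                            recommended_temperature_c = 25) {
  structure(list(min_cai = min_cai, max_pirna_score = max_pirna_score,
                 min_intron_patc_density = min_intron_patc_density,
                 min_introns = as.integer(min_introns),
                 first_intron_max_offset_bp =
                   as.integer(first_intron_max_offset_bp),
                 min_concentration_ng_per_ul = min_concentration_ng_per_ul,
                 recommended_temperature_c = recommended_temperature_c),
            class = "lint_thresholds")
}

lint_entry <- function(rule, status, message, evidence = list()) {
  list(rule = rule, status = status, message = message, evidence = evidence)
}

#' Lint a construct against the eight engineering rules
#'
#' @param x a [construct()]; exon features declare the CDS (without one, most
#'   rules are `not_applicable`).
#' @param thresholds a [lint_thresholds()].
#' @param table a [codon_usage_table()] for CAI.
#' @param db optional [pirna_db()]; without it the piRNA component of rule 1
#'   cannot be evaluated and degrades the status to `unknown` (unless another
#'   component already fails).
#' @param model a [pirna_model()].
#' @param params [patc_params()] profile for intron density (forced to
#'   balanced mode).
#' @return object of class `lint_report`: exactly eight entries (R1-R8),
#'   each with a status in pass/warn/fail/not_applicable/unknown, a message
#'   and the computed evidence. Purely deterministic in its inputs.
#' @export
lint_construct <- function(x, thresholds = lint_thresholds(),
                           table = celegans_codon_table(), db = NULL,
                           model = pirna_model(), params = patc_params()) {
  abort_if(!is(x, "construct"), "lint_construct() needs a construct")
  th <- thresholds
  params$mode <- "balanced"
  ex <- construct_features(x, "exon")
  intr <- construct_features(x, "intron")
  has_cds <- nrow(ex) > 0L
  entries <- vector("list", 8L)

  cds <- NULL
  if (has_cds) cds <- tryCatch(splice(x, allow_internal_stops = TRUE),
                               error = function(e) NULL)
  cds_groups <- if (has_cds) unique(ex$label) else character(0)
  # introns inside the (first) CDS span
  cds_span <- if (has_cds) c(min(ex$start), max(ex$end)) else NULL
  cds_introns <- if (has_cds && nrow(intr))
    intr[intr$start >= cds_span[1] & intr$end <= cds_span[2], , drop = FALSE]
  else intr[0, ]

  if (!has_cds || is.null(cds)) {
    na <- function(rule, msg) lint_entry(rule, "not_applicable", msg)
    entries[1:3] <- list(na("R1", "no declared CDS"),
                         na("R2", "no declared CDS"),
                         na("R3", "no declared CDS"))
    entries[[5]] <- na("R5", "no declared CDS")
    entries[[7]] <- na("R7", "no declared CDS")
  } else {
    cai_val <- cai(cds, table, allow_internal_stops = TRUE)
    pscore <- if (is.null(db)) NA_real_
    else pirna_score(scan_pirna_sites(cds, db, model))
    # R1: codon adaptation + piRNA depletion + at least one intron
    fails <- c(cai = cai_val < th$min_cai,
               pirna = !is.na(pscore) && pscore > th$max_pirna_score,
               introns = nrow(cds_introns) == 0L)
    st1 <- if (any(fails)) "fail"
    else if (is.na(pscore)) "unknown" else "pass"
    entries[[1]] <- lint_entry("R1", st1,
      if (st1 == "unknown")
        "CAI and introns pass; piRNA score unknown (no database supplied)"
      else if (st1 == "pass")
        "codon-adapted, piRNA-depleted, intron-containing"
      else paste("failing:", paste(names(fails)[fails], collapse = ", ")),
      list(cai = cai_val, pirna_score = pscore,
           n_introns = nrow(cds_introns)))

    # R2: >= 1 PATC-rich intron inside the coding region (PATCs in the
    # promoter or 3'-UTR are dispensable and not credited)
    dens <- vapply(seq_len(nrow(cds_introns)), function(i) {
      iseq <- substr(x$sequence$residues, cds_introns$start[i] + 1L,
                     cds_introns$end[i])
      mean(score_patc(iseq, params)$track$values)
    }, 0)
    entries[[2]] <- lint_entry("R2",
      if (any(dens >= th$min_intron_patc_density)) "pass" else "fail",
      sprintf("%d/%d CDS intron(s) with balanced PATC density >= %g (PATC-rich cutoff is a package default)",
              sum(dens >= th$min_intron_patc_density), length(dens),
              th$min_intron_patc_density),
      list(intron_densities = dens))

    # R3: tags at the C-terminus are less silencing-prone
    tags <- construct_features(x, "tag")
    entries[[3]] <- if (nrow(tags) == 0L)
      lint_entry("R3", "not_applicable", "no tag feature")
    else if (all(tags$start >= cds_span[2]))
      lint_entry("R3", "pass", "tag 3' of the host CDS")
    else lint_entry("R3", "warn",
                    "tag 5' of (or inside) the host CDS; C-terminal placement is less silencing-prone",
                    list(tag_start = tags$start))

    # R5: >= min_introns with the first one early in the CDS
    first_off <- NA_integer_
    if (nrow(cds_introns)) {
      first <- min(cds_introns$start)
      prior <- ex[ex$end <= first, , drop = FALSE]
      first_off <- sum(prior$end - prior$start)
    }
    ok5 <- nrow(cds_introns) >= th$min_introns &&
      !is.na(first_off) && first_off <= th$first_intron_max_offset_bp
    entries[[5]] <- lint_entry("R5", if (ok5) "pass" else "fail",
      sprintf("%d intron(s); first intron at CDS offset %s bp (need >= %d with first <= %d)",
              nrow(cds_introns),
              ifelse(is.na(first_off), "NA", first_off),
              th$min_introns, th$first_intron_max_offset_bp),
      list(n_introns = nrow(cds_introns), first_intron_offset = first_off))

    # R7: co-expression needs an operon (gpd-2 recommended) or 2A linker
    entries[[7]] <- if (length(cds_groups) < 2L)
      lint_entry("R7", "not_applicable", "single CDS")
    else {
      linkers <- construct_features(x, c("operon_linker", "p2a_linker"))
      lint_entry("R7", if (nrow(linkers)) "pass" else "fail",
        if (nrow(linkers)) "co-expression linker present"
        else "multiple CDSs without an operon (gpd-2 recommended) or 2A linker",
        list(n_cds = length(cds_groups), n_linkers = nrow(linkers)))
    }
  }

  # R4: injection concentration
  conc <- x$metadata$injection_concentration_ng_per_ul
  entries[[4]] <- if (is.null(conc))
    lint_entry("R4", "unknown", "injection concentration not recorded")
  else lint_entry("R4",
    if (conc >= th$min_concentration_ng_per_ul) "pass" else "warn",
    sprintf("injected at %g ng/ul (threshold %g)", conc,
            th$min_concentration_ng_per_ul),
    list(concentration = conc))

  # R6: vector backbone removal
  form <- x$metadata$delivery_form
  backbone <- construct_features(x, "backbone")
  entries[[6]] <- if (!is.null(form) &&
                      form %in% c("pcr_product", "gel_purified", "linearized"))
    lint_entry("R6", "pass", sprintf("backbone removed/digested (%s)", form))
  else if (nrow(backbone) == 0L)
    lint_entry("R6", "pass", "no backbone feature annotated")
  else if (is.null(form))
    lint_entry("R6", "unknown", "backbone present, delivery form not recorded")
  else lint_entry("R6", "warn",
                  "circular plasmid with vector backbone; remove by PCR or digest",
                  list(delivery_form = form))

  # R8: culture temperature
  temp <- x$metadata$culture_temperature_c
  entries[[8]] <- if (is.null(temp))
    lint_entry("R8", "unknown", "culture temperature not recorded")
  else lint_entry("R8",
    if (abs(temp - th$recommended_temperature_c) <= 0.5) "pass" else "warn",
    sprintf("cultured at %g C (recommended %g C)", temp,
            th$recommended_temperature_c),
    list(temperature = temp))

  structure(list(entries = entries, thresholds = th,
                 construct_id = x$sequence$id),
            class = "lint_report")
}

#' @export
print.lint_report <- function(x, ...) {
  cat(sprintf("Lint report for %s (coordinates 1-based inclusive; PATC density = mean per-base score)\n",
              x$construct_id))
  for (e in x$entries)
    cat(sprintf("  %-3s %-14s %s\n", e$rule, toupper(e$status), e$message))
  invisible(x)
}

#' @export
as.data.frame.lint_report <- function(x, ...) {
  data.frame(rule = vapply(x$entries, `[[`, "", "rule"),
             status = vapply(x$entries, `[[`, "", "status"),
             message = vapply(x$entries, `[[`, "", "message"),
             stringsAsFactors = FALSE)
}

lint_status <- function(report, rule) {
  for (e in report$entries) if (e$rule == rule) return(e$status)
  NA_character_
}
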