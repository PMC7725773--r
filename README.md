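# patcraft

Transgenes injected into the *Caenorhabditis elegans* germline as simple
extrachromosomal arrays are almost universally silenced by small-RNA and
chromatin pathways. A handful of sequence-level design choices counteracts
this: codon adaptation, removal of piRNA (21U-RNA) homology, two or more
introns with the first one early in the coding sequence, inclusion of
PATC-rich intronic DNA, removal of the vector backbone, high injection
concentration and culture at 25 °C. **patcraft** is the computational side of
that workflow, for worm labs building germline-expressed reporters and
gene-editing enzymes.

## What it computes

**PATC scoring.** Periodic A\_n/T\_n Clusters are runs of A or T recurring in
phase with the DNA helical repeat (~10 bp). patcraft finds all maximal A/T
runs (length ≥ *l*₀, default 3; `N` breaks runs), then chains runs on a DAG:
an edge *i* → *j* exists when the center spacing *d* = *c*ⱼ − *c*ᵢ satisfies
|*d* − *k*·*P*| ≤ τ for some *k* ≤ *k*max + 1 (period *P* = 10 bp, tolerance
τ = 2 bp, *k*max = 2 skipped periods), with weight
min(*len*ⱼ, cap) − λ(*k* − 1), cap = 6, λ = 1. A longest-path DP

&nbsp;&nbsp;&nbsp;&nbsp;*S*ⱼ = max( min(*len*ⱼ, cap), maxᵢ *S*ᵢ + *w*ᵢⱼ )

scores the best chain through every run; chains of ≥ 4 runs become clusters
and every base in a cluster span receives the chain score. *Density* is the
mean per-base score over a region. `mode = "balanced"` averages the forward
track with the position-mapped track of the reverse complement, making the
score strand-symmetric by construction. An exhaustive chain enumerator
(`patc_chain_bruteforce()`) ships as the independent oracle.

**Codon design.** CAI is the geometric mean of per-codon
relative-adaptiveness weights, 1.0 = all-preferred codons.
`optimize_codons()` first encodes each residue with its highest-weight codon,
then deterministically repairs violations — forbidden motifs on either strand
(BsaI GGTCTC/GAGACC by default), homopolymers > 8, and piRNA target sites —
by single synonymous substitutions at minimal CAI loss. The piRNA site model
requires perfect Watson–Crick pairing of the piRNA seed (positions 2–8,
facing positions 14–20 of a 21-nt sense window) and a non-seed cost budget
of 3.0, with G:U wobbles costing 0.5; the piRNA score of a design is the sum
of site weights. `deplete_pirna()` restricts the repair loop to piRNA sites,
prefers seed-breaking substitutions and is monotone in the score.

**Intron engineering.** `plan_intron_positions()` ranks exonic AG|G junctions
under the first-exon rules (< 350 bp, preferably < 150 bp),
`insert_introns()`/`splice()` are exact inverses under the GT–AG rule, and
`bsaI_digest()`/`golden_gate_assemble()` simulate one-pot exchange of
PATC-rich donor introns (Type IIS geometry: cut 1/5 nt outside GGTCTC,
4-nt 5′ overhangs). The packaged registry `intron_donor_registry()` lists the
donor-plasmid library with registered lengths, PATC densities and Addgene
accessions.

**Linting.** `lint_construct()` evaluates an annotated construct against the
eight engineering rules (R1 codon/piRNA/introns, R2 PATC-rich CDS introns,
R3 C-terminal tags, R4 ≥ 25 ng/µl, R5 two introns with one in the first
150 bp, R6 backbone removal, R7 operon/2A co-expression, R8 25 °C) and
returns pass/warn/fail/not_applicable/unknown per rule with the computed
evidence.

## Worked example

```r
library(patcraft)

# a synthetic PATC region: 10 A6-runs at 10-bp phasing in random background
fx  <- gen_patc_sequence(seed = 20201209)
res <- score_patc(fx$seq, patc_params(mode = "balanced"))
res
#> <patc_result> patc_fixture (balanced mode): 12 runs, 1 clusters, density 14.40
patc_summary(res, region = fx$span)
#> <patc_summary> density 60.000, covered 100.0%, 1 clusters, max chain 60.0

# design a codon-adapted, piRNA-free coding sequence and add early introns
db  <- gen_toy_pirna_db(3, seed = 20201209)
rep <- optimize_codons("MSKGEELFTGVVPILVELDGDVNGHKFSVSGEGEGDATYGKLTLKFICTTGKLPVPWPTLVTTF",
                       db = db, id = "ce-fp")
rep
#> <design_report> ce-fp: CAI 1.000, piRNA score 0, 0 residual violation(s)

g   <- insert_introns(rep$cds, c(48L, 120L),
                      paste0("GTAAGTTT", strrep("AAAAAAGCGG", 25), "TTTTCAG"))
con <- construct(g$sequence, g$features,
                 metadata = list(injection_concentration_ng_per_ul = 25,
                                 delivery_form = "pcr_product",
                                 culture_temperature_c = 25))
lint_construct(con, db = db)
#> Lint report for ce-fp_genomic (coordinates 1-based inclusive; ...)
#>   R1  PASS           codon-adapted, piRNA-depleted, intron-containing
#>   R2  PASS           2/2 CDS intron(s) with balanced PATC density >= 100 ...
#>   R3  NOT_APPLICABLE no tag feature
#>   R4  PASS           injected at 25 ng/ul (threshold 25)
#>   R5  PASS           2 intron(s); first intron at CDS offset 48 bp ...
#>   R6  PASS           backbone removed/digested (pcr_product)
#>   R7  NOT_APPLICABLE single CDS
#>   R8  PASS           cultured at 25 C (recommended 25 C)
```

The fixture's whole-sequence density is 14.4 (chain score 60 spread over a
400-bp window); over the planted cluster span itself the density is 60 — ten
capped runs at 6 points each — with 100 % coverage. The designed CDS reaches
CAI 1.0 with zero predicted piRNA sites, and the assembled construct passes
every applicable engineering rule.

A command-line wrapper over the same functions is installed at
`inst/scripts/patcraft.R` (`patc score|scan`, `design`, `lint`,
`fixtures make`, all emitting profile-stamped, 1-based reports).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch under a seed —
synthetic PATC fixture generation and scoring (classic and balanced), window
scanning, track export, codon optimization with piRNA depletion against a
seeded toy database, intron insertion with a splice round-trip check, and
linting — then writes its JSON manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

PATC scoring constants are exposed in `patc_params()` and are package
defaults, not the historical reference implementation's; recomputing the
registered donor-intron densities requires the plasmid sequences (fetch by
the Addgene ids in the registry) via `patc_calibrate()`. The shipped codon
weight table is a synthetic C. elegans-flavoured stand-in
(`inst/extdata/codon_weights_celegans_synthetic.tsv`); CAI values are
table-relative, so supply a measured table to match external tools.
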