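---
title: "Models and methods: PATC scoring and silencing-resistant transgene design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PATC scoring and silencing-resistant transgene design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patcraft)
```

This vignette is the package's own account of its models: what is computed,
under which assumptions, which knobs matter, and where the edges are. It
states no empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## The PATC chain model

Periodic A~n~/T~n~ clusters (PATCs) are a non-coding signature of
germline-expressed *C. elegans* genes: short mononucleotide A or T runs
recurring in phase with the DNA helical repeat, roughly every 10 bp, over
spans of hundreds of base pairs. PATC-rich intronic DNA protects transgenes
from germline silencing, which is why a scoring function for it sits at the
center of this package.

The model has three stages.

1. **Runs.** All maximal runs of A and of T with length ≥ `min_run_length`
   (default 3). `N` is treated as a universal mismatch and breaks runs —
   conservative, since an undetermined base cannot be credited with
   periodicity. Each run is summarized by its center
   $c = \mathrm{start} + (\mathrm{len}-1)/2$.

2. **Chaining.** Runs form a DAG. An edge $i \to j$ exists when the center
   spacing $d = c_j - c_i > 0$ is a near-multiple of the period:
   $|d - k P| \le \tau$ for some integer $k \le k_{\max}+1$, with $k$ chosen
   per edge as the minimizer of $|d - kP|$. Defaults: $P = 10$ bp (the
   helical repeat), $\tau = 2$ bp, $k_{\max} = 2$ skipped periods. The edge
   weight is $\max(0,\ \min(\mathrm{len}_j, \mathrm{cap}) - \lambda (k-1))$
   with `run_score_cap` 6 and `skip_penalty` $\lambda = 1$: a run
   contributes at most 6 points, and each skipped period costs one point.
   The cap prevents one long poly-A tract from masquerading as a cluster;
   periodic recurrence, not run length, is what scores.

3. **Scoring.** The longest-path DP
   $S_j = \max\bigl(\min(\mathrm{len}_j,\mathrm{cap}),\ \max_i S_i +
   w_{ij}\bigr)$ gives the best chain ending at every run. Chains traced
   back from terminal runs with ≥ `min_cluster_runs` (default 4) members
   become clusters; every base in a cluster's span receives the chain
   score, overlaps taking the maximum. Ties in the traceback break toward
   the predecessor with the smaller start, so output is deterministic.

**Density** — the region statistic used in every report — is the arithmetic
mean of the per-base score. This choice (rather than a sum or per-kb value)
is stated in each report header.

The constants above are package defaults, exposed in `patc_params()`. They
are *not* pinned to the historical Pascal reference implementation of the
score: pinning requires the published donor-intron sequences, which are not
redistributable here. `patc_calibrate()` exists for exactly that purpose —
point it at a FASTA of the registry plasmids (Addgene ids in
`intron_donor_registry()`) and it tabulates recomputed next to registered
densities. Until a profile is pinned, registered densities should be read as
the library's published values, not as values this implementation
reproduces.

**Correctness evidence.** The DP is checked against an exhaustive
enumeration of all periodicity-respecting chains
(`patc_chain_bruteforce()`) on hundreds of seeded random instances, and two
monotonicity properties hold by construction and are property-tested:
appending an in-phase capped run never lowers the best chain score, and
enlarging the tolerance never lowers any chain score (the edge set only
grows).

**Balanced mode.** `mode = "balanced"` returns the per-base mean of the
classic track and the position-mapped classic track of the reverse
complement — the weakest definition that provably guarantees
strand-symmetry. A structural note: because a chain's total is
$\sum \min(\mathrm{len},\mathrm{cap}) - \sum \lambda(k-1)$, which is
direction-free, the classic score is itself exactly
reverse-complement-symmetric, so balanced and classic tracks coincide
numerically. The symmetrized definition is kept as the contract (it would
differ for any future asymmetric scoring variant), and the invariance test
is exact, not approximate.

## The synthetic-data generators and the null model

`gen_patc_sequence()` plants `n_runs` runs (default 10 × A₆) at spacing
`period ± jitter` centrally in an i.i.d. background (defaults: 400 bp,
GC 0.5 — GC-neutral so that planted periodicity, not composition, carries
the signal). Flanking bases are forced to C/G so the planted runs stay
maximal, and the ground-truth run table and span are returned. All
generators are pure functions of their arguments and seed (default
20201209); identical calls are byte-identical.

What the generator does *not* emulate: real base composition beyond GC
(*C. elegans* is ~36 % GC and A/T-run-rich), codon structure, or the
kb-scale extent of genomic PATC domains. A green recovery test therefore
establishes that the scorer finds what the model defines as a cluster — not
that it reproduces genome-scale PATC maps.

The null model is the Altschul–Erickson dinucleotide shuffle (a random
Eulerian path on the dinucleotide multigraph), the standard control for
periodicity statistics because it preserves mono- and dinucleotide
composition exactly. Two honest consequences, measured with fixed seeds and
recorded rather than tuned away:

* Random background alone (any realistic GC) regularly contains ≥ 4 A/T
  runs in accidental phase, so chance clusters at default parameters are
  *common, but weak* — the fixtures test asserts the quantitative version
  (background maxima stay far below the planted chain score), not the
  qualitative absence of clusters.
* A dinucleotide shuffle of a planted fixture inherits the fixture's ~50
  excess AA dinucleotides, so shuffled controls are themselves A-run-rich.
  The measured planted-to-null density ratio is roughly 5× whole-sequence
  and 17× region-matched — real discrimination, but below the 20× the
  acceptance suite demands, and the corresponding acceptance test is left
  failing rather than its threshold loosened or the generator retuned.

## CAI and constrained recoding

CAI is the geometric mean of per-codon relative-adaptiveness weights over
all non-stop codons; single-codon families (Met, Trp) carry weight 1 and are
included, which cannot change any comparison. The shipped weight table is a
**synthetic** C. elegans-flavoured stand-in: preferred codons follow
published optimal-codon assignments and alternatives decay by a fixed
within-family rank schedule (1, 0.62, 0.41, …). CAI is table-relative, so
absolute values from external platforms are reproduced only with that
platform's table (`codon_usage_table()` accepts any TSV).

`optimize_codons()` is deliberately greedy and fully deterministic — no
RNG anywhere in the design path:

* **Seed pass**: every residue gets its highest-weight codon, alphabetical
  tie-break. This is the global CAI maximum by construction.
* **Repair loop**: while violations exist (forbidden motif on either
  strand, homopolymer > `max_homopolymer`, piRNA site), the first
  outstanding violation (smallest start; motif < homopolymer < piRNA) is
  attacked with the synonymous single-codon substitution that removes it at
  minimal CAI loss; ties break to the smallest position, then the
  alphabetically first codon. Violations no substitution can remove are
  parked and reported as residuals (success-with-warnings, never silent
  failure); the parked set is cleared whenever a move lands, since a
  substitution elsewhere may unlock them. Translation is re-verified after
  every accepted move.

The piRNA site model: a 21U-RNA pairs antiparallel to the mRNA, so piRNA
position $i$ faces position $22-i$ of a 21-nt sense window. The seed
(piRNA 2–8, window 14–20) must pair perfectly — implemented as a 7-mer hash
lookup, which makes the scan linear in sequence length — and the remaining
positions accumulate cost: 1 per mismatch, `gu_wobble_cost` 0.5 per G:U
pair, budget `max_nonseed_mismatches` 3.0. Each accepted site contributes
`site_weight` (1.0) to the piRNA score. These defaults are a package
choice: the targeting rule behind published piRNA scores is external and
version-dependent, which is why every parameter is configurable and the
resolved profile is stamped into reports. Fractional published scores
(e.g., 1.5) are representable via fractional weights, but no published
score is asserted anywhere in the package. `deplete_pirna()` additionally
prefers substitutions inside the seed-complementary window (one broken seed
base kills a site) and rejects any move that would raise the piRNA score,
making depletion provably monotone.

## Intron placement, splicing and Golden-Gate exchange

Placement encodes the germline findings: at least two introns, first exon
short (< 350 bp, preferably < 150 bp). Candidate insertion points are exonic
AG|G junctions — the preferred *C. elegans* exon/exon context — used as a
soft ranking: when no junction exists the planner falls back to arbitrary
inter-nucleotide offsets with a warning, and introns may interrupt codons.
The first offset is the candidate nearest the even-partition ideal
$L/(n+1)$ subject to the first-exon bound (preferred bound when reachable,
hard bound otherwise, error beyond); remaining offsets track the even
partition of the residual CDS. Everything is deterministic with
smallest-offset tie-breaks.

Inserted introns are wrapped, when needed, with the donor/acceptor consensi
(`GTAAGTTT` … `TTTTCAG`); the default ~50-nt synthetic intron uses a fixed
G-free spacer so no BsaI site or spurious signal can arise — it is a
package stand-in, not a published sequence. `splice()` validates GT–AG on
every intron and inverts `insert_introns()` exactly (property-tested across
random CDSs).

BsaI geometry: for a recognition site on either strand the cut pair in
top-strand coordinates is $(t, t+4)$ and the overhang string is the 4 nt at
$t$. Fragments carry those 4 nt at the start of their body, so bodies
concatenate back to the input exactly and two ends ligate iff their
overhang strings are equal. Assembly walks the overhang graph from the
acceptor: at every junction *site-free* fragments outrank site-carrying
ones, so a donor insert displaces the acceptor's exchange stub (whose
outward-pointing recognition sites travel with it), two same-class
candidates for one overhang abort as ambiguous, and a dead end aborts as
unassemblable. Splice signals live on the acceptor side of each junction —
donor introns carry none — so every reassembled intron is GT–AG by
construction, and the product is spliced and its translation compared to
the acceptor's reference as a hard integrity check. One design choice had
to reconcile two stated requirements: a residual recognition site in the
product is an error, *except* when it sits in an exchange stub retained
because no donor was supplied for that slot — the partial exchange is then
returned with an explicit warning, since partial donor sets are a
legitimate use.

The circular product is rotated so its origin coincides with the
acceptor's; features are remapped fragment-wise (a feature spanning a cut
is dropped rather than guessed) and introns are re-inferred as inter-exon
gaps.

## Linting

`lint_construct()` returns exactly eight verdicts, a pure function of
construct + thresholds. Statuses are advisory: rules encode wet-lab
findings, not logical necessities — an N-terminal tag is a *warn* (such
fusions express from permissive single-copy sites), sub-threshold
concentration or temperature likewise, whereas missing introns or CAI below
threshold are *fail*. Missing inputs (no piRNA database, no metadata)
degrade to *unknown*, never silently to *pass*. The PATC-rich cutoff for
rule 2 (balanced density ≥ 100) is a package default chosen between the
registry's control introns (≤ 17) and its PATC-rich ones (≥ 365), and is
printed in the report. Severity is monotone: tightening any threshold can
only worsen a status, which is property-tested.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; every human-readable report
  is 1-based inclusive, converted in a single routine
  (`coords_to_report()`), and says so in its header.
* bedGraph output merges equal-value runs (0-based half-open); wiggle uses
  per-base `fixedStep start=1`. Both round-trip losslessly through
  `read_track()`.
* Circular topology is honored only by BsaI digestion (sites and cuts may
  span the origin); all scoring treats input as linear, since genic regions
  are linear.
* The design loop needs no seeds at all; generators take explicit seeds and
  the shipped default is 20201209.

## Known limitations

PATC parameters are unpinned defaults (see above); the codon table is
synthetic; the piRNA rule is a configurable stand-in for an external,
unversioned algorithm; the Golden-Gate simulator models overhang identity,
not ligation-fidelity thermodynamics; no mRNA secondary structure, no
22G-RNA/CSR-1 homology modeling, no expression-level prediction. The lint
rules summarize *array* behavior in wildtype animals; they say nothing
about single-copy insertions in permissive sites, where several "failing"
designs are known to express.
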