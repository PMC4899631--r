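---
title: "Methods: somatic hypermutation analysis of single-V repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic hypermutation analysis of single-V repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmrep)
```

## Scope and model

`shmrep` analyses heavy-chain repertoires amplified from a **single germline V
segment** — the design used when one canonical V gene dominates a hapten
response and every read can be interpreted against that one reference. The
package deliberately does not do multi-gene V/D/J assignment or allele
calling: the reference is pluggable (`germline_reference()`), but there is
exactly one per analysis, and all coordinates, regions and mutations are
expressed on it. Internally coordinates are 0-based half-open (the region
map); every emitted table is 1-based.

The analysis chain is: align → filter → clone → consensus → classify →
summarise → trees. Each stage is an exported function, and
`run_pipeline()` composes them deterministically from a single config + seed.

## Alignment and filters

`align_to_germline()` performs a semi-global alignment (germline global, read
3′ tail free) so the CDR3 junction is never forced onto the V. Two
conventions matter:

* **Identity denominator.** Identity is matches over the *covered germline
  interval* of the V segment only; the junction is excluded and internal gaps
  count as mismatches. The homology filter is a *strict* `> 0.90` ("greater
  than 90 % identity"), so a read at exactly 0.90 fails.
* **Indels.** The aligner permits them, but any read whose best alignment has
  a V-region indel is flagged and excluded from mutation statistics. All
  downstream mutation classes (transition/transversion, replacement/silent)
  are substitution concepts; mixing in indel-containing reads would corrupt
  the per-position coordinate system.

A read is *productive* when it covers FR1-start through the CDR3 start, has
no V-region indel or ambiguous base, and translates without a stop codon from
the frame offset to the CDR3 start. Reads shorter than half the V are
"partial" and never analysed. Because `v_identity`, `productive` and the
junction are independent columns of the rearrangement table, filters commute
— a property the test suite asserts.

For indel-free reads (the overwhelming majority, and all synthetic reads) the
trivial position-by-position pairing is already optimal, so the aligner takes
a fast ungapped path when the read prefix matches the germline with at most
15 % mismatches; reads beyond that go through the dynamic-programming
aligner, which is also the only route that can report indels.

## Clones and consensus

Clones are keyed by the **exact CDR3 junction nucleotide string** — no fuzzy
clustering. With a single V reference and junctions generated by junctional
diversity, exact identity is the natural operational clone definition; a
hamming-threshold clustering stage is out of scope and would blur the
ground-truth comparisons the generator enables.

`clone_consensus()` exists to avoid double-counting mutational events shared
within a clone. The vote is **strict majority**: at each position, a
non-germline base is adopted only if more than half of the voting members
carry it; ties, and pluralities at or below half, revert to germline.
Members with `N` at a position abstain there. Strict majority is the
conservative reading — the consensus never contains a mutation most members
lack — and gives three provable properties (tested): the consensus mutation
set is a subset of the union of member mutation sets, consensus is
idempotent, and on star-shaped clones (shared founder mutations plus private
ones, size ≥ 3) it recovers the founder set exactly.

Two statistics deliberately use different units: **mutability, hotspot and
transition statistics use clone consensuses** (one vote per clonal event),
while **mutation loads are per sequence** (each read's own count) — the two
conventions the underlying figures use, exposed as explicit function choices
(`estimate_mutability()` on consensuses vs `sequence_loads()` on reads).

## Mutation classification

Mutations are mismatches to the germline at positions strictly before the
CDR3 start; the junction is never scored. Each mutation carries:

* **transition/transversion** — transition iff {from,to} is {A,G} or {C,T};
* **context class** — from the **germline-centred 5-mer**: WRC/GYW and WA/TW
  hotspots, SYC/GRS coldspots, else neutral. The germline (pre-mutation)
  context is used rather than the observed sequence because mutability is a
  property of the state AID acted on; this is an interpretive choice and the
  exported tables keep the raw 5-mers so the other convention is
  recomputable. Positions within two bases of a sequence end have no full
  5-mer and are "unscored" (excluded from hotspot denominators); in the
  generator these positions receive the neutral rate — a boundary convention
  of negligible mass. Neighbouring mutations do not invalidate a context:
  each mutation is scored from the clean germline 5-mer.
* **replacement/silent** — the germline codon containing the position is
  translated with and without the substitution (other codon positions at
  germline state); stop-creating changes are replacements. The
  classification is verified exhaustively against a translate-and-compare
  oracle over all 64 codons × 9 substitutions.

`estimate_mutability()` produces the hedgehog data: for each observed 5-mer,
mutation count, background count (occurrences as a germline context across
the analysed consensuses), the raw rate `count/background`, and a normalized
mutability scaled so the background-weighted mean is 1. "Adjusted for
background frequency" fixes the estimator only up to a constant; the
weighted-mean-1 normalization is the natural choice that makes 1 mean
"average site", and the raw rates are exported alongside so any other
normalization is recoverable. 5-mers never seen as a germline context are
absent from the table (no imputation — full S5F-style model fitting with
distance weighting is a non-goal).

## Lineage trees

`build_lineage_tree()` reconstructs a germline-rooted tree per clone,
minimizing total mutations along edges. Each unique sequence is its mutation
set versus germline; sequences are attached greedily in order of increasing
mutation count to the deepest node whose set they contain, and an inferred
intermediate is created whenever a new sequence shares with a sibling a
common mutation subset strictly larger than the parent's. Ties are broken by
larger node multiplicity, then lexicographic sequence order, making the
procedure deterministic. Reversions are never inferred; conflicting sites
resolve toward the root (a stated limitation).

On perfect-phylogeny input (each mutation arising once, no back-mutation) the
total weight provably equals the union of observed mutations, which is the
global minimum. On general small instances (≤ 4 unique sequences, 12-nt
toy germline) the test suite checks the greedy weight against an exhaustive
Steiner-tree search whose candidate intermediates are the closure of the
observed sets under union and intersection. Equivalence with any particular
published tree program is not claimed — the objective (minimum total
mutations, inferred precursors allowed) is stated here and verified by
oracle.

## Assay kinetics

`estimate_half_life()` fits OLS to `ln(count/count_initial)` against time;
`t½ = ln 2/|slope|`, flagged undefined when the slope is non-negative (flat
or growing series). The intercept is **free by default**: the series is
normalized to its first observation, but that observation is itself noisy,
and forcing the line through ratio 1 at day 0 would propagate its noise into
the slope. `through_origin = TRUE` provides the constrained fit for users who
prefer it.

`compare_decay_slopes()` is the classic two-regression slope-equality test:
pooled residual variance, `df = n1 + n2 − 4`, exactly t-distributed under the
null — its type-I error is verified by simulation (1000 null replicates,
rejection rate required in [0.03, 0.07] at α = 0.05).

The noisy-recovery property tests use a design of 8 timepoints, monthly over
210 days (~2.4 half-lives at t½ = 86 d) with 20 % lognormal CV — the natural
sampling scheme for a long-lived plasma-cell transfer followed over months.
Under that design the median relative error of the recovered half-life over
500 replicates is below 10 %; materially shorter windows (≤ ~1.6 half-lives)
do not constrain the slope well enough for any estimator at that noise level.

`neutralization_titre()` applies the 50 % specific-signal rule: threshold
`(OD_virus − OD_cell)/2 + OD_cell`; the titre is the highest dilution with OD
below threshold. "Highest" is ambiguous when the series is non-monotone, so
the implementation scans from the lowest dilution and takes the last
dilution of the *initial* run below threshold, flagging non-monotone series
(`non_monotone = TRUE`). Series entirely above threshold return a
below-first-dilution sentinel rather than a number; an assay with
`OD_virus ≤ OD_cell` has no window and errors.

## The synthetic repertoire generator

`simulate_repertoire()` produces data with exactly the structure the analysis
assumes, plus complete ground truth. What it emulates:

* **Clonal structure** — each clone is founded by the germline V joined to a
  unique random junction; clone sizes follow a fixed, geometric or zipf law
  (zipf default, exponent 1.5 — expanded repertoires are strongly skewed,
  and the pattern of a handful of clones dominating a sample is the regime
  of interest; the size law is a modelling choice, not an empirical claim).
* **Junctions** — random nucleotide strings, 24–45 nt (typical CDR3 lengths),
  by default multiples of 3, followed by a fixed 12-nt J-anchor stand-in so
  junction extraction has a right boundary. Full V(D)J recombination realism
  is unnecessary because only V-region mutations are analysed.
* **Lineage and SHM** — members descend from the founder through a branching
  process (random attachment, depth-capped); each edge adds
  Poisson-distributed mutations drawn by `apply_shm()`, which samples
  positions proportionally to the targeting model's mutability evaluated on
  the *current* sequence — contexts drift as mutations accrue, as in
  iterative SHM. The targeting model has three class rates (hotspot 5,
  coldspot 0.2, neutral 1 by default — an AID-like, roughly five-fold
  hotspot preference) and a transition fraction (default 0.6, a transition
  excess in the range typical of AID spectra), plus an optional per-5-mer
  override table.
* **Error floor** — uniform per-base sequencing error applied last and
  recorded separately from true SHM, so an error-only simulation reproduces
  an unmutated-control baseline (a fraction of a mutation per read)
  distinguishable from SHM by its flat context profile.
* **Determinism** — one root seed; per-clone substreams derived from the
  clone index, so identical configs are byte-identical and clone k's data
  does not depend on how other clones were sampled.

What it does **not** emulate: indels, class-switch recombination, functional
(antigen) selection, position-within-gene biases beyond the 5-mer model, or
platform-specific error structure (e.g. homopolymer errors). Two
consequences matter when reading test results. First, without selection
against nonsense mutations, heavily mutated simulated reads acquire stop
codons at the rate the genetic code dictates and are then removed by the
productivity filter — real plasma cells are pre-filtered for function, so
simulated funnels lose more reads than real ones at equal load. Second,
passing truth-recovery tests shows the informatics is correct on data obeying
the stated generative assumptions; it cannot certify behaviour on data
violating them (e.g. repertoires where distinct clones share junctions).

## Problem sizes and numerical conventions

The test suite runs entirely on synthetic data at desk scale: motif and codon
classifications are checked exhaustively (1024 5-mers; 576 codon cases);
truth round-trips use repertoires of ~25–30 clones; mutability recovery uses
1000 consensuses (≥ 2000 mutations) for the 5:1 hot:neutral design and 2500
consensuses (~10⁴ mutations) for the uniform calibration; kinetics
calibration uses 1000 null replicates and 500 recovery replicates. The
mutability table's background-weighted mean is asserted to 1 within 1e−9;
statistical recoveries use 3 (or, for the per-5-mer null calibration, 4)
binomial standard errors.

Degenerate inputs are defined, not crashed on: empty read sets give empty
clone sets; clones with all-tie votes give germline consensuses; zero scored
mutations give flagged-undefined hotspot fractions; S = 0 regions report an
infinite R/S marker; flat decay series flag `undefined`; all-above-threshold
OD series return the below-first-dilution sentinel.

## Known limitations

* Single-reference design: no V/D/J assignment, no allele calling, no
  chimera detection.
* Junction equality clustering will split clones whose junctions differ by
  sequencing error (mitigated by analysing error-free or consensus data) and
  merge truly distinct clones with identical junctions (vanishingly rare at
  these junction lengths).
* The greedy tree heuristic is exact on perfect phylogenies and verified on
  small instances, but carries no global optimality guarantee on arbitrary
  inputs with convergent mutations.
* The mutability estimator reports observed 5-mers only and assumes mutations
  are independent given context; it is a descriptive hedgehog summary, not a
  full generative targeting model.
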