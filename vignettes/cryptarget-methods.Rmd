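---
title: "Methods: duplex scoring, energy model, screens and generators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex scoring, energy model, screens and generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptarget)
```

This vignette is the package's own account of the methods it implements:
the models, the defaults and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical conventions. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The duplex model

A candidate interaction between a mature miRNA and an mRNA is modelled as
an **ungapped, antiparallel duplex**: the miRNA written 5′→3′ faces a
target region of identical length written 3′→5′, position by position.
Every published duplex this package reproduces is a 20/20 alignment with no
bulges, so gapped alignment is excluded by design and rejected loudly
(`alignDuplex` errors on unequal lengths). Positions are numbered 1-based
from the miRNA 5′ end, which is the frame of reference in which "positions
10–11" (the slicer site) and "positions 1–12 of the 5′ end" are defined.

Each apposition is classified deterministically from the two bases:
Watson–Crick (`|`), G:U wobble (`o`), or mismatch (`x`). Wobbles are
weighted 0.5 mismatches and everything else 1, giving the weighted mismatch
count used by three of the four filter criteria:

| criterion | quantity | default bound |
|---|---|---|
| 1 | weighted mismatch, positions 1–L | ≤ 4.0 |
| 2 | weighted mismatch, positions 10–11 | = 0 |
| 3 | weighted mismatch, positions 1–12 | ≤ 2.5 |
| 4 | \|ΔG(duplex)\| / \|ΔG(perfect complement)\| | ≥ 0.74 |

All thresholds live in `filterCriteria()` and are configurable; each
criterion can be toggled independently.

**Criterion 2 and wobbles.** "No mismatches at 10–11" is read strictly: a
wobble carries weight 0.5 > 0 and therefore fails. None of the published
duplexes has a wobble at those positions, so the strict and lenient
readings cannot be distinguished on the available data; the choice is
exposed as `centralWobbleFails` (strict by default).

**DNA input** (T, lower case) is silently normalized to U; any other
character is an error naming the offending symbol.

`scanTranscript` evaluates **every** offset of a transcript (the window
read 5′→3′ is reversed so target position *i* faces miRNA position *i*),
reports all passing sites sorted by (total mismatch, start), and offers a
best-per-transcript collapse because published target tables report one
region per mRNA. A fast integer-coded path does the scanning; the test
suite checks it offset-by-offset against a self-contained brute-force
re-scorer.

## The hybridization energy model

The energy criterion needs ΔG for an ungapped duplex. No specific energy
model is mandated by the filter itself, so the package uses a transparent
nearest-neighbor construction:

ΔG = ΔG_init + Σ stacks over adjacent paired positions + ΔG_loop × (number
of maximal mismatch runs).

* Stacking increments are the **Turner 2004 RNA set at 37 °C** (all 36
  ordered doublets of Watson–Crick and G:U pairs), shipped as a plain-text
  table (`inst/extdata/nn_stack_rna_37C.tsv`) with a provenance tag;
  ΔG_init = 4.10 kcal/mol from the same set. A doublet missing from a
  user-supplied table is a hard error, never silently zero.
* Mismatches terminate helices. A flat per-run penalty (ΔG_loop = 2.0
  kcal/mol by default) replaces sequence-dependent internal-loop terms:
  a single constant keeps the criterion reproducible and configurable, at
  the cost of realism for large loops.
* Terminal A:U / G:U end penalties are omitted (the ratio criterion
  compares a duplex against the perfect complement of the *same* miRNA, so
  shared end terms largely cancel).
* The criterion is evaluated as a ratio of **absolute** free energies,
  |ΔG(duplex)|/|ΔG(perfect)|; with negative ΔG a literal "≥ 74 % of the
  free energy" would invert the intended direction. A duplex with
  non-negative ΔG (no stabilizing helix) is clamped to ratio 0; a miRNA
  whose perfect complement has non-negative ΔG is degenerate and errors.

**Model dependence of the 0.74 boundary.** Under this model, a single
internal mismatch removes two stacks (~5 kcal/mol) and adds a loop
penalty, so duplexes with three or four scattered mismatches fall well
below 74 % of the perfect-complement energy even though they satisfy the
mismatch criteria. The regression suite freezes the computed ratios for
the shipped duplex table: they span 0.42–0.76 and only 3 of 24 reach 0.74.
The published screen evidently used a more permissive energy model (its
software and parameters are not recoverable), so the pass/fail boundary for
marginal duplexes is flagged as model-dependent in the documentation, the
ratios are reported rather than tuned, and the mismatch criteria (1)–(3) —
which reproduce exactly — carry the exact acceptance checks. Wobble-only
and perfect sites pass all four criteria under the default model, which is
what the end-to-end pipeline test exercises.

## Small-RNA summaries and the hairpin stand-in

Read filtering keeps the 18–30 nt window (inclusive); histograms and
5′-nucleotide bias are order-invariant tallies. Precursor validation needs
a secondary structure, for which the package implements the **Nussinov
maximum base-pairing** dynamic program: nested {A:U, G:C, G:U} pairs,
hairpin loops of at least `min_loop = 3` unpaired bases, deterministic
traceback (whenever the leftmost position can be paired optimally it pairs
with the smallest admissible partner). This is a documented stand-in for
energy-based folding — adequate for deciding whether a mature sequence sits
on one well-paired arm of a hairpin, not for predicting real structures.
A precursor validates when the mature sequence lies entirely on one side of
the fold's largest hairpin loop and ≥ 60 % of its positions are paired
(`min_paired_fraction`, configurable; the 0.6 default mirrors common
precursor-prediction practice).

## lncRNA classification and target screens

Classification uses full gene spans (no exon resolution is available in
the annotation this models), closed 1-based coordinates, and ≥ 1 bp
overlap: same-strand overlap → *sense*, opposite-strand only →
*antisense*, none → *lincRNA*. Published counts distinguish only lincRNA
and "natural sense" classes; whether antisense overlaps were merged into
the sense bucket is not reconcilable from the available totals, so
antisense is reported separately by default with a `mergeAntisense` flag.

*Cis* candidates are genes strictly closer than 100 kb (distance 0 for
overlap, otherwise bases strictly between nearest interval ends, strand
ignored). *Trans* candidates are pairs with |r| ≥ 0.9 by default —
inclusive, since "over 0.9" at printed precision cannot distinguish the
boundary — with 0.99 as the stricter shortlist preset.

The coding-potential label uses the −1/+1 three-band convention. The
score itself, `orfScore`, is a package-native heuristic, not a
reimplementation of any published calculator: with L the longest
forward-frame AUG..stop ORF (nt, including the stop) and cov = L / transcript
length,

score = −1.1 + 2.2 · min(1, cov/0.9) · min(1, L/270),

anchored so a 0-ORF transcript scores below −1 and an ORF covering ≥ 90 %
of a ≥ 300-nt transcript scores above +1 (the anchors are slightly outside
±1 so the banding is strict). Only the three forward frames are scanned:
transcript orientation is known.

## Expression analytics

2^−ΔΔCt quantification normalizes the target gene to a reference gene
within each sample and to a calibrator sample across samples; with a
replicate column the fold change is computed per biological replicate and
reported as mean with sd (six replicates being the design this mirrors).
The calibrator's own fold change is exactly 1 by construction.

Circadian profiles are fold changes relative to ZT2. Peaks are local
maxima with prominence ≥ 0.1 fold-change units (profiles normalized to a
baseline of 1 have shallow relative excursions, so a tenth of a unit is a
meaningful rise; configurable); the profile is called 24-h periodic when at
least two peaks occur and all consecutive spacings are within ±4 h (one
sampling interval) of 24 h.

Clustering is agglomerative with distance 1 − r and **average linkage** —
declared as this package's convention, since the similarity grouping it
reproduces names no method. Constant rows have undefined correlation and
are reported per feature rather than silently dropped.

## Network assembly

Nodes are typed (miRNA, mRNA, lincRNA); `represses` edges are directed
miRNA→mRNA, `coexpressed` edges undirected with the screen correlation as
weight, stored once with canonically ordered endpoints and deduplicated.
"Similar expression pattern" for ceRNA flagging is operationalized as
same-cluster membership at the configured cut. Functional annotations are
carried as free-text labels joined from a user table; no ontology lookup is
performed.

## Synthetic-data generators

The generators produce inputs with exactly the structure each stage
assumes, with one user seed fanned out to fixed per-generator substreams so
adding a generator never perturbs another's output. They emulate:

* transcripts with planted target sites built by mutating the miRNA's
  perfect complement (`n_x` non-pairing substitutions, `n_o`
  wobble-creating substitutions, optionally honoring the central-window and
  5′-window constraints), with ground truth recorded independently of the
  scanner;
* precursor hairpins (mature arm + loop + reverse-wobbled complement);
* circadian expression: focal gene = baseline 8 + amplitude 5 ·
  cos(2π(t − 6)/24) + N(0, 0.5) over ZT2–ZT46 at 4-h steps (two full
  cycles, 12 timepoints — the replicate count the trans-screen battery
  uses); planted lincRNAs as affine transforms with noise scaled in closed
  form to hit each target ρ in expectation (exact at zero noise); an
  anti-correlated planted miRNA; independent-noise decoys;
* Ct tables whose 2^−ΔΔCt round-trips planted fold changes exactly at zero
  noise;
* read sets with a 61 % mode at 21 nt inside 18–30 nt (the reported
  length composition) and a 5′-U excess (default probability 0.7; the
  real libraries report only a qualitative preference).

They do **not** emulate genome-scale realism: no repeats or GC skew, no
sequencing error, no read mapping, no transcript assembly, and decoy
expression is independent noise rather than correlated background. Passing
tests therefore demonstrate correctness of the computations on data with
the declared statistical structure, not robustness to the full noise
spectrum of real libraries.

## Problem sizes and determinism

The test batteries use sizes chosen to exercise the properties densely:
500 random sequences ≤ 12 nt against exhaustive fold enumeration, 100
random 200-nt transcripts against the exhaustive-offset scan oracle, 200
planted sites on 100–300-nt transcripts, 200 expression replicates at
planted ρ = 0.995 with n = 12, 50 random miRNAs for the energy-ratio
identity. All randomness is seeded; generator outputs are bit-reproducible
from (configuration, seed).

## Known limitations

* The energy model's flat loop penalty makes criterion 4 conservative for
  multi-mismatch duplexes (see above); users comparing against permissive
  screens should lower `minEnergyRatio` or disable the criterion.
* The Nussinov fold maximizes pair count, not stability; it can pair
  distant arms a thermodynamic fold would not.
* `orfScore` is a coarse ORF-content heuristic; it is not comparable
  numerically to published coding-potential scores, only band-compatible.
* Gene-level overlap logic ignores exon structure, and the cis screen
  treats all genes as single intervals.
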