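---
title: "Mining small heat shock proteins by anchored ACD detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining small heat shock proteins by anchored ACD detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdminer)
```

## The problem

Small heat shock proteins (sHsps) are defined by possession of the
α-crystallin domain (ACD), an immunoglobulin-like β-sandwich of about
seven to eight β-strands. The domain's primary sequence is poorly
conserved across distant taxa, while its structural elements — the
β-strands and a handful of signature residues — are strongly conserved.
A practical mining pipeline therefore has to (i) find ORFs in raw
transcript assemblies, (ii) decide whether a translated protein carries
one or more ACDs using structure-anchored sequence signals, (iii)
characterize the hits (physicochemistry, subfamily membership, putative
localization signals) and (iv) place the domain cores on a tree. This
vignette documents how each step is modeled, which parameters matter,
and which design decisions were genuinely open.

## Core geometry and the detection model

The modeled core runs from the β3 strand to the end of β9 — β2 is not
conserved well enough to anchor on. The geometry is two fixed-length
blocks bridged by one variable loop:

| segment | regions | columns |
|---|---|---|
| block 1 | β3(6) L34(7) β4(6) L45(5) β5(5) | 29 |
| bridge  | L57, 4–14 residues | 14 canonical |
| block 2 | β7(6) L78(8) β8(6) L89(5) β9(6) | 31 |

L57 is singled out as the variable region because it is where the
family diverges most: the small acidic subcluster (A1) has a
strikingly short L57 of 5–6 residues, while the B subclusters carry
11–14. With this geometry, A1 cores come out at 63–69 residues and the
other subclusters at 71–79, without a special case anywhere in the
scoring.

A detection hit requires three independent signals, in order of
evaluation:

1. a match of the β9 anchor motif `L-X-(V/T)-(E/K)-(A/L)-(P/K)`;
2. at least one of the L78 doublets `L-P` or `V-D` inside the L78 span
   implied by the geometry (positions `[end-25, end-17)` of the
   candidate core);
3. a PSSM log-odds score over the two strand blocks at or above the
   threshold, maximized over the admissible bridge lengths g ∈ [4, 14].

The PSSM column scores use a background-proportional pseudocount,
`log2(((c_ij + b_j)/(N + 1))/b_j)`, which is symmetric in equally
frequent residues and never produces −∞. The L57 bridge itself is not
scored: its length varies and its composition carries subfamily
signal (used later by the classifier), not family signal. Unknown
residues (X) score zero, i.e. neutrally. Overlapping candidate hits are
resolved greedily best-score-first; exact ties go to the leftmost
window, and within one β9 anchor a tie over bridge lengths goes to the
longer bridge (leftmost window start).

The bundled model is the profile of the package's seven template cores
(five monomeric subcluster templates plus both cores of the dimeric
template) with a uniform background. Its consensus realizes the
universal family motifs — the L-P and V-D doublets in L78, the
conserved glycine in L89, the β9 motif — so consensus-level checks and
detection anchors agree by construction.

**Threshold calibration.** No published numeric cut-off exists for
"contains an ACD" (the original screens combined similarity search,
secondary-structure prediction and manual curation). The default
threshold is therefore calibrated: it is the 99.9th percentile of the
best window score over 10,000 length-200 decoys drawn i.i.d. from the
model background at seed 1 (−38.20 bits; recompute with
`calibrate_threshold()`). Because detection additionally requires the
two motif gates, the realized false-positive rate per decoy ORF is far
below the 0.1% that the score quantile alone would suggest, while
planted cores score 100–170 bits — two orders of magnitude above the
gate. The threshold is stored in the model object and serialized with
it, so a run's provenance pins the exact cut-off used.

## Physicochemistry

- **GRAVY** is the arithmetic mean of Kyte–Doolittle hydropathy values;
  X residues are excluded from the average.
- **Molecular weight** sums average (isotope-averaged) residue masses
  plus one water; X residues get the mean residue mass — the least-bias
  choice — and are counted in the length.
- **Isoelectric point** solves net charge = 0 by bisection on pH
  ∈ [0, 14] to |charge| < 1e−4 (≈ 47 halvings; a 0.001-pH grid search
  agrees to < 0.01 pH, which the tests assert on 1,000 random
  sequences). The charge model is the standard Henderson–Hasselbalch
  sum over the two termini, D/E/C/Y and K/R/H.

Three named pKa sets are bundled. The default, `"sms"`, is the classic
textbook set used by SMS-family web calculators (D 3.65, E 4.25,
C 8.33, Y 10.07, K 10.53, R 12.48, H 6.00, N-term 8.2, C-term 3.65);
the exact values used by any particular release of such tools are not
always published, so small systematic pI offsets against numbers
computed elsewhere are expected, and every profile records the table it
was computed with. `"emboss"` is provided as a common alternative, and
`"bjellqvist"` mirrors the ExPASy-style set with residue-specific
terminal pKa — chosen so that an independent implementation
(`seqinr::computePI`) can serve as a cross-check oracle in the tests.

Group summaries report interquartile ranges with linear-interpolation
quantiles (R type 7), the most common convention, so published
per-cluster tables have a well-defined comparison. Incomplete
sequences (no initiator M or no terminating stop inside the contig)
are excluded from group summaries: their lengths, masses and termini
are censored, not observed.

## Subcluster classification

Monomeric sHsps are assigned by rules evaluated in precedence order
A1 → A2 → B1 → B3 → B2:

- **A1** — core ≤ 69 residues *and* protein < 130 residues *and* pI
  < 4.8 *and* no conserved arginine in β7. These are the miniature,
  very acidic proteins with the short L57.
- **A2** — protein ≥ 300 residues *and* pI ≥ 8.5 (the large, basic
  subfamily).
- **B1** — `K-K-K-X-K-K` in the β5-L57 zone *or* `F-X-S-E-S` in L34;
  an `E-E-X-X-E-E` match in L57-β7 is recorded as corroboration and
  raises the reported confidence but does not gate the label.
- **B3** — `L-D-V-X-X-F-X-P-E-E` in β3-L34 *or* `G-K-H-E-E-(R/K)` in
  β5-L57.
- **B2** — the residual class for any remaining protein with a
  detected ACD. B2 and B3 are the least separated groups in the source
  phylogenies, so treating B2 as the residual is the honest encoding
  of that uncertainty.

Numeric cut-offs sit deliberately *outside* the published interquartile
boxes (e.g. the A2 length gate is ≥ 300 against a printed IQR of
359–381): an IQR by construction excludes half the members, so gates at
the IQR edge would misclassify real dispersion. All cut-offs live in
one editable list (`CLASSIFIER_CUTOFFS`). Dimeric proteins are refused
by the classifier — the subcluster system is defined for monomeric
sHsps only, and assigning tandem-ACD proteins to it would be a category
error.

Motif zones are resolved from the hit's anchor coordinates, so the same
motif string is *not* accepted anywhere in the protein — `K-K-K-X-K-K`
counts for B1 only inside β5-L57.

The NLS scan reports the fairly well conserved `V-(R/K)-P` inside
β4-L45 and any 6-residue window with ≥ 4 K/R (merged into maximal
spans). This is a motif-level screen, not a localization predictor;
it flags candidates for external tools rather than replacing them.

## Alignment and trees

Cores are re-anchored against the model and laid onto the canonical
74-column geometry; only the L57 residues need placement, which is done
by global dynamic programming against the model's L57 consensus with
affine gaps (open 10, extend 1, BLOSUM62 similarity), gaps being
allowed only in the sequence — the model defines the column space.
All-gap columns are dropped, so two identical cores align gap-free and
a deletion in L57 produces gaps only in L57 columns (both are asserted
as tests).

Distances are p-distances with pairwise (not listwise) deletion of
gapped columns — listwise deletion would discard most of the signal in
the ragged L57 zone. The tree is Saitou–Nei neighbor joining written
in-house: negative branch lengths are clamped to zero with the deficit
moved to the sibling edge, preserving path lengths through the parent.
Maximum-likelihood and Bayesian inference are deliberately out of
scope: p-distance NJ with column-resampling bootstrap (default 100
replicates, seed mandatory) is self-contained, fast, and sufficient to
recover the coarse cluster structure that the downstream
characterization needs. `ape` supplies the tree containers, Newick I/O
and bipartition counting; the NJ implementation itself is checked
against `ape::nj` and against additive matrices (recovery to 1e−9) in
the tests, keeping implementation and oracle separate.

## The synthetic generator

The generator is the package's test substrate: it emulates the
statistical structure of a real repertoire, not its history. Per
subcluster it plants mutated copies of a frozen template whose
physicochemical profile sits inside the published per-cluster
interquartile box (whole protein *and* ACD core), wraps each in a
back-translated CDS (uniform synonymous codons, seeded) with random
UTRs — an in-frame stop terminates the 5' UTR so the planted ORF
translates exactly — and emits a ground-truth table.

The mutation model reflects the family's conservation structure:

- substitution rates differ between strand columns (default 0.01) and
  loop/flank columns (default 0.05), matching the observation that
  strands are conserved and loops variable;
- signature/anchor positions (the skeleton residues of each template)
  are exempt from substitution entirely. This mirrors the near-total
  conservation of those residues in the family's sequence logos —
  sites under strong purifying selection simply do not wander at these
  time scales — and it is what makes those motifs usable as detection
  anchors in the first place;
- indels are confined to unconstrained L57 stretches (keeping the
  bridge within 4–14 residues) and to the termini; strand columns never
  receive indels.

A configurable fraction of planted genes is emitted truncated (CDS
without a terminating stop, abutting the contig edge) to exercise the
incomplete-sequence rule. Decoys come in two kinds: random-background
ORFs and near-misses that carry *exactly one* signature motif each, to
stress the requirement that detection needs all three signals jointly.

What the generator does **not** emulate: expression levels, sequencing
error, assembly artifacts, codon-usage bias, within-subfamily
phylogenetic structure (all copies of a cluster are i.i.d. mutations of
one template), or genuinely novel subfamilies. Passing the synthetic
benchmarks therefore demonstrates the pipeline's internal consistency
and its robustness to point divergence and loop indels — not its
sensitivity to sHsps whose motifs have drifted beyond the degenerate
patterns, which on real data is handled by lowering the threshold and
reviewing the score distribution.

The dimeric template carries two tandem cores separated by a 25-residue
linker; its upstream core is diverged by far more than 30% from every
monomeric template, reflecting the fact that upstream ACDs of
tandem-domain sHsps form their own deeply separated cluster.

## Numerical conventions and degenerate inputs

- All exported coordinates are 0-based, half-open, forward-strand.
- Bisection tolerance 1e−4 on charge; quantiles type 7; IC in bits
  with gaps excluded from frequencies (gap fraction reported
  separately); the small-sample logo correction is off by default.
- A consensus call requires a *unique* residue at or above the
  threshold: an even two-residue split at t = 0.5 has no consensus and
  reports 'x'.
- ORFs: internal stop codons always terminate; a stop-terminated
  segment containing an M is trimmed to its first M and flagged
  complete; otherwise the whole segment is reported incomplete. The
  default minimum ORF length is 50 aa — comfortably below the shortest
  real monomeric sHsps (~89 aa) while suppressing fragment noise. ORFs
  are reported per reading frame without collapsing nested ORFs; the
  original tools' behavior here is undocumented, so the simplest
  deterministic policy won.
- Exact duplicate peptides within one input are collapsed for
  computation but retained in all outputs and counts, with labels
  propagated to the duplicates; 100%-identity containment (fragment of
  a longer protein) is deliberately *not* collapsed — the redundancy
  criterion used in manual curation is unstated, so only the reversible
  operation is automated.
- Empty inputs, invalid residues/nucleotides (the offending symbol is
  named), ragged alignments, non-symmetric or NA distance matrices and
  out-of-range hits all fail fast with stage-specific messages; a
  repertoire with no hits is a valid outcome, not an error.

## Problem sizes

The test suite and the acceptance script use repertoires of 30–45
planted genes plus 100 decoys, 1,000 random sequences for the pI
oracle, 10,000 decoys for threshold calibration, and 100 bootstrap
replicates on 40-tip trees — sizes chosen so a full verification run
completes in well under a minute on a single CPU while keeping every
proportion estimate at a resolution of 1/40 or finer. The same
machinery scales to real transcriptome assemblies (10^4–10^5 ORFs)
linearly in the number of candidate β9 anchors.

## Known limitations

- Detection requires a literal β9 motif match; an sHsp whose β9 has
  drifted outside the degenerate pattern is invisible at any
  threshold. On real data this is mitigated by the pattern's breadth
  (it matches all five subfamily variants) but not eliminated.
- The classifier's numeric gates were set from published group
  statistics of one clade (annelids); applying them to distant taxa
  will inflate the residual class (B2) rather than produce wrong
  confident labels, by construction of the precedence order.
- p-distance NJ recovers coarse structure; short internal edges between
  the B subclusters should not be over-interpreted, matching the weak
  separation of those groups in model-based trees.
- The pI is a sequence-only theoretical value; no post-translational
  modifications or folded-state pKa shifts are modeled.
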