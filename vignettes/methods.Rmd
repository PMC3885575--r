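---
title: "Predicting detailed enzyme function and extracting specificity-determining residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting detailed enzyme function and extracting specificity-determining residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Within a CATH homologous superfamily, enzymes share a scaffold but differ
in the reaction they catalyse, recorded as a four-digit EC number.
Transferring the full EC annotation by sequence similarity alone becomes
unreliable once the closest annotated relative drops below roughly 40%
identity. The premise of this package is that the residues that decide
*which* of the superfamily's functions a sequence performs are few and
localized — active-site residues (ASRs), ligand-binding residues (LBRs)
and strongly conserved positions (CSRs) — so similarity measured *at those
positions* should discriminate functions where whole-sequence similarity
cannot.

`efprf` implements this as a set of one-vs-rest binary predictors: one
random forest per (superfamily, EC) pair, each consuming a query's
alignment-score attributes. Alongside the label, the forest's attribute
importance ranking is mined for "rf-SDRs" — residue positions whose
attributes contribute most to discriminating the enzyme from the rest of
its superfamily, i.e. candidate specificity-determining residues.

## The attribute vector

A query is aligned globally (Needleman–Wunsch, affine gaps, cost
`open + L·ext` for a gap of length `L`, defaults 10/1) to the enzyme's
representative. From the alignment we compute, per scoring matrix:

* one **full-length score** — the mean per-column substitution score over
  columns where both sequences carry residues. The mean rather than the
  raw sum is used so the attribute does not trivially encode sequence
  length (the raw-sum variant is available by flag);
* one **position score per annotated site** — `sim(rep_i, query_i)` in
  matrix mode, or the profile column's value for the query residue in
  profile mode. A query gap at an annotated position is filled with the
  scorer's minimum at that position and flagged in a mask: a gap is
  maximally unlike the representative residue, and forests need complete
  vectors.

Two matrices are always available: BLOSUM62 and the enzyme's PSSM.
A third, structure-conditioned profile (an ESST-style table) can be
supplied as an external TSV; when present, the schema grows from
`n = 2m + 3` to `n = 3m + 4` attributes for `m` annotated positions. The
remaining attribute is a **BLAST-type top-hit bit score**: the maximum
local-alignment bit score of the query against the enzyme's positive
training sequences (Smith–Waterman with BLAST's 11/1 gap costs, converted
to bits with the published gapped-BLOSUM62 Karlin–Altschul constants
λ = 0.267, K = 0.041). During training a sequence's own record is excluded
from its reference set. Precomputed BLAST tabular files are accepted in
place of the built-in scorer, and externally computed alignments (e.g.
from a structure-aware aligner) in place of the built-in one.

## Functional positions

ASR/LBR sets are read from curated annotation tables; positions annotated
as active anywhere (or as both active and binding) are ASRs, binding-only
positions are LBRs, unioned over the annotating structures. A
distance-based contact detector over PDB coordinates is included as a
clearly labelled substitute for atom-level interaction classification
(donor–acceptor pairs within 3.5 Å **and** carbon–carbon contacts within
3.9 Å); it is off by default and intended only for preliminary
annotation.

Conservation is measured per alignment column as Shannon entropy in nats
over 21 symbols (20 residues + gap),

$$S_k = -\sum_i P_k^i \ln P_k^i,$$

with columns above 20% gaps excluded (strict inequality). The CSR set is
the `⌈0.10 · n_eligible⌉` lowest-entropy eligible columns, ties broken by
position index; positions already claimed as ASR or LBR stay in those
sets (precedence ASR > LBR > CSR), and the CSR set receives the
remainder.

The PSSM score of residue *j* at column *i* is a Gribskov-style profile
score with logarithmic occurrence weights:

$$\mathrm{score}(i, j) = \sum_k W_{ki}\,\mathrm{sim}(k, j), \qquad
  W_{ki} = \frac{\ln(c_{ki} + 1)}{\ln(N + 1)},$$

where `c_ki` counts residue *k* in column *i*, `N` is the number of
aligned sequences, and `sim` is BLOSUM62. `W_ki` is 0 for absent residues
and reaches 1 exactly for a gap-free single-residue column, so each
column's score vector is a convex-cone combination of BLOSUM62 rows.
These closed forms — natural-log entropy, the profile score, and the
logarithmic weight — are the simplest forms consistent with every stated
property of the method and are each isolated behind a single function so
an alternative is a one-line change. Natural logarithms are used for
*all* entropies in the package: with nats, the superfamily diversity
thresholds 0.5 and 1.5 (below) correspond to one, two-to-four, and more
than four equally frequent classes, which base-2 logarithms would not.

### Alignment strategy

Training sequences are star-aligned onto the enzyme representative: each
sequence is aligned pairwise and projected onto representative
coordinates, with query-insert columns dropped. Columns of the training
alignment therefore *are* representative positions, which is the
coordinate system the per-position attributes, annotations and reports
all use (1-based everywhere user-facing). Externally produced MSAs can
still be read and analysed; the star alignment is the pipeline default
because it requires no external aligner and keeps truth bookkeeping
exact.

## Dataset assembly

Within one (superfamily, EC) group, sequences are clustered at a 95%
identity cutoff (global-alignment identities divided by the shorter
sequence length, single linkage, input pre-sorted by id for order
invariance) and reduced to one sequence per cluster — the structure-linked
representative in its own cluster, the longest sequence elsewhere. The
group representative is the structure-linked member with the longest
sequence, ties broken by best resolution, then id. A predictor is built
for an enzyme iff (1) its superfamily has at least one other enzyme,
(2) it has a representative structure and ≥ 10 non-redundant sequences,
and (3) the other enzymes contribute ≥ 10 non-redundant sequences.
Each group is split 80/20 (round half away from zero) into train/test;
the representative is forced into training because the PSSM and
conservation profile are built from training data — leaving it in the
test set would leak. The split is per-sequence; a per-cluster split would
further reduce train/test leakage and is noted as a possible extension.

## Predictors and rf-SDRs

The forest uses 500 trees and `mtry = ⌊√n⌋`, with `n` the enzyme's
attribute count; both are recorded on the model. Importance is the mean
decrease in node impurity by default (the default output of the classic
R random-forest implementation), with permutation importance behind a
flag. Predictions are majority votes; a query is positive iff the
positive vote fraction exceeds 0.5, ties negative. The baseline "simple
model" is an entropy-criterion decision tree over the top-hit bit score
alone; on a one-attribute problem any entropy-based tree reduces to the
same optimal threshold structure.

The top `3·⌊√n⌋` attributes by importance (ties broken by schema index,
so results are reproducible) are the "highly contributing" set. Walking
that set, skipping the BLAST-type and full-length attributes, and
collecting the remaining attributes' positions — deduplicated across
matrices — yields the enzyme's rf-SDR set, each position tagged with its
site category and matrix provenance.

## Evaluation

For each test query and predictor we record the maximal
test-to-training sequence identity (MTTSI): the highest global-alignment
identity (identities over alignment length) between the query and the
predictor's positive training sequences. That reference-set choice is
recorded in the report header and switchable to all training sequences.
Results fall into eight left-closed bins ([0,30), [30,40), …, [90,100]);
precision `TP/(TP+FP)` and recall `TP/(TP+FN)` are computed per enzyme
per bin and macro-averaged over the enzymes for which the measure is
defined — undefined metrics are flagged, never zero-filled. Confidence
intervals use the normal approximation. One exception applies to
head-to-head *model comparisons* over a fixed query band: a model that
makes no positive call at all in the band is assigned precision 0 there,
so that "called nothing" and "called wrongly" both lose to a model that
calls correctly; within a single model's report, undefined stays
undefined. Models are compared with a
two-sided paired t-test over per-enzyme metrics (all-zero differences
report p = 1) and groups with the Wilcoxon rank-sum test, tie-corrected.

Superfamily functional diversity is the Shannon entropy (nats) of
predictor counts over distinct third-digit EC prefixes, classified low /
medium / high at 0.5 and 1.5; the fourth-digit classification uses raw
distinct-EC counts (1–5 / 6–10 / > 10). Amino-acid propensity of rf-SDRs
is the residue's frequency among rf-SDR positions (representative-sequence
letters, the only sequence on which positions are defined) divided by its
frequency over all pooled representative domains.

## The synthetic superfamily generator

Real superfamily corpora require large curated databases; the generator
instead emulates the statistical structure the method assumes, with known
ground truth. One ancestral scaffold; per class, *planted SDR positions*
carrying class-specific residues chosen greedily to be mutually
dissimilar under BLOSUM62 (pairwise score ≤ −1, so positional attributes
carry signal under every scorer); *shared conserved positions* identical
across classes; all other positions mutating i.i.d. per sequence at a
configured rate. The first sequence of each class is the class prototype
(its consensus), tagged with a dummy structure reference and therefore
selected as the representative. ASR/LBR annotations cover a declared
mixture of planted and shared positions, so the discriminative and
non-discriminative annotated positions are separately traceable. Indels
are off by default, keeping truth bookkeeping alignment-free; star-tree
(i.i.d.) mutation is deliberate — no phylogenetic structure is simulated.

The default configuration — 3 classes × 20 sequences of length 150, five
shared + five planted positions (all ten annotated: ASR = 3 planted + 2
shared, LBR = 2 planted + 3 shared), substitution rate 0.08 — was chosen
once as a realistic desk-scale family: ~92% within-class identity,
~85% between classes, groups comfortably above the ten-sequence
eligibility floor after redundancy removal. Band-constrained test queries
are produced by mutating background positions of a prototype until the
realized global-alignment identity falls in the requested band; planted
positions are never mutated, so class labels survive even at 25–30%
identity.

What passing tests on this generator do **not** show: robustness to
indels and alignment error, to annotation noise (positions mis-mapped
between structures), to phylogenetic correlation between training
sequences, or to the weaker, distributed specificity signals of real
families. They do show that the attribute construction, importance
ranking and rf-SDR extraction recover planted signal through the entire
pipeline, and that positional attributes — not whole-sequence
similarity — are what rescues precision at low identity.

## Numerical choices and degenerate inputs

* Gap character `-`; `.` normalized on read; residues outside the 20
  standard letters + X are rejected loudly rather than guessed.
* Redundancy cutoff comparison is ≥; gap-fraction eligibility is strict
  (> 0.20 excluded); CSR count uses the ceiling so tiny alignments still
  select one conserved position.
* Local bit scores are floored at 0 and masked for degenerate pairs.
* Forest and split seeds fully determine models, importances and
  predictions; enzyme-level training seeds are derived from the run seed.
* Groups smaller than two sequences go entirely to training with a
  warning; single-class training sets and empty reference sets are
  errors, not silent results.
* A PSSM from a single sequence is refused (the occurrence weight is
  degenerate there).

## Problem sizes

The validation experiments (test suite and `scripts/acceptance.R`) run
five seeds of the default synthetic configuration above: per seed, three
forests of 500 trees over ~50 attributes and ~48 training sequences, and
30 band-constrained queries evaluated against all three predictors. This
scale exercises every stage in a few minutes on one core while keeping
all ten annotated positions and both identity extremes represented.

## Known limitations

* The three-matrix design is reachable only when an external structural
  profile is supplied; the pipeline's self-contained mode is two-matrix.
* The contact detector is a geometric approximation, not an interaction
  classifier.
* Single-superfamily scope per dataset object; multi-domain proteins are
  assumed pre-cut into domain sequences.
* No probability calibration and no multi-class model: the design is
  strictly one-vs-rest, which is what makes per-enzyme importance
  rankings (and hence rf-SDRs) meaningful.
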