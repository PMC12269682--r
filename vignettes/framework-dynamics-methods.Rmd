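---
title: "Methods: framework mutational scanning and dynamics coupling analysis"
author: "fwdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: framework mutational scanning and dynamics coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdyn)
```

# Scope and model of the data

fwdyn supports a computational antibody framework (FW) engineering
workflow built from two complementary triage strategies:

1. **Structure/sequence-first triage.** A saturated per-position masked
   scan asks, for every position of a variable-domain sequence, how
   confidently a pluggable scorer (typically a protein language model)
   reproduces the wild-type residue; the FW positions of natural
   antibodies are expected to score near rank 1 while CDR loops do not.
   Candidate stabilizing double mutants from an external ddG scanner are
   then filtered against the predicted stability sign and against how
   often each mutant residue occurs in natural repertoires.
2. **Dynamics-first triage.** Molecular-dynamics ensembles of the
   antigen-bound and unbound antibody are compared through (a) geometric
   descriptors of antigen engagement and VH-VL packing, (b) geometric
   classification of non-covalent interactions and their residue
   networks, and (c) a structural-alphabet mutual-information analysis
   that calls "hub" fragment pairs whose backbone coupling differs
   between the bound and unbound states.

The package consumes standard text formats only: (multi-model) PDB for
structures and trajectories, FASTA for sequences, and TSV tables for
region maps, ddG records, repertoire profiles and all outputs. MD itself,
ddG scanning and antibody numbering are upstream tools whose outputs are
ingested, never recomputed.

# Mutational scanning

`scanPositions()` masks one position at a time and collects 20 raw scores
per position. Scorers declare whether they emit logits or probabilities;
logits pass through a plain softmax at temperature 1. The wild-type rank
at a position is `1 + #{amino acids scoring strictly higher}`, so ties
share the best rank — a deterministic convention that is optimistic for
the wild type and matches the "1 = best" reading of rank profiles.
Per-antibody aggregation of wild-type probability (for comparisons
against germline identity via `germlineIdentityCorrelation()`, a Spearman
test) supports both mean and median over positions; the mean is the
default used in the pipeline because rank profiles are strongly skewed in
FW regions and the mean preserves the contribution of rare low-confidence
FW positions.

`classifyStability()` labels ddG records by sign; exactly zero ddG is
classified destabilizing, so "stabilizing" always means strictly negative
predicted ddG. `filterDoubleMutants()` enforces two mandatory filters —
negative double-mutant ddG and per-residue repertoire occurrence above
1% — and *reports* (but does not enforce) sign consistency between the
double ddG and the sum of the single ddGs. The consistency flag is
informational because a double mutant can be genuinely stabilizing
through compensatory effects even when both singles are predicted
destabilizing; making it mandatory would discard exactly that class of
candidates.

# Geometric descriptors

All descriptors operate frame-wise on mass-weighted centers of mass
(COM). Antigen engagement is summarized as the distance between the COM
of the CDR loops and the COM of the antigen's contact region. VH-VL
packing uses (a) the straight-line VH-VL COM distance and (b) a planar
angle over three COMs: light-chain CDR, VL and VH. The vertex of that
angle is not uniquely determined by naming three points; fwdyn fixes it
at the VL COM (the domain flanked by the other two selections) and
exposes it as a parameter, so any alternative convention is one argument
away.

RMSD uses unweighted Kabsch superposition with reflections disallowed;
`rmsdSeries()` and the structural-alphabet encoder share this routine.
Native contacts are defined on the reference structure as heavy-atom
pairs within 4.5 Å whose residues are ≥ 3 apart in sequence (or on
different chains); a contact is retained in a frame when its distance
stays within 1.2× the cutoff. These three numbers are conventional
literature values, are exposed as arguments, and are recorded in the run
manifest.

Unbinding detection is a heuristic on a distance series: the baseline is
the mean of the first 5% of frames (≥ 2), and an unbinding call requires
a suffix of the series that never returns below the baseline and in
which at least 10% of frames exceed 1.5× the baseline; the onset is the
first above-threshold frame of that suffix. The persistence rule
deliberately rejects transient excursions that re-bind. Raising the
threshold factor can only remove calls, never add them, which the test
suite asserts as a property.

# Interaction classification

Three detector families share the convention that boundary equality
satisfies a criterion (≤ / ≥):

* **Hydrogen bonds** (Baker-Hubbard): H···acceptor ≤ 2.5 Å and
  donor-H-acceptor angle ≥ 120°. Donor triples are resolved from the
  topology (H within 1.25 Å of N/O/S in the same residue) or supplied
  explicitly for hydrogen-free topologies.
* **π–π stacking**: ring-COM distance ≤ 5.5 Å and inter-normal angle
  ≤ 30°. Ring normals come from the smallest principal axis of the ring
  atoms and are sign-ambiguous, so the angle is folded to [0°, 90°].
  Collinear "rings" have no defined plane and are skipped with a
  warning.
* **CH/NH–ring**: X-COMring distance ≤ 4.5 Å and X-H-COMring angle
  ≥ 120°, with X ∈ {C, N} deciding the event type.

The exact cutoff table used in any given study varies between
laboratories; the defaults above are standard values and every one of
them is configurable through `geomCriteria()` or a criteria config file,
and recorded in the manifest. For per-residue interaction counts a
side-chain-focused reading is supported by constructing ring/donor sets
from side-chain atoms (the `aromaticRings()` helper uses side-chain ring
atoms only).

Interaction networks treat an edge as (unordered residue pair, type);
each frame contributes 0/1 per edge regardless of event multiplicity,
and the edge weight is the fraction of frames with at least one event.
`diffNetwork()` joins the edge union of two networks (absent edge =
frequency 0) and marks residues perturbed when an incident edge changes
frequency by ≥ 0.25 — a threshold chosen to mean "present in one
condition in at least a quarter of frames more than the other", again
configurable.

# Structural-alphabet coupling analysis

Backbone dynamics are discretized by encoding consecutive four-residue
Cα fragments against an M-state alphabet of canonical fragments: per
frame and fragment, the state is the prototype with minimal Cα RMSD
after optimal superposition, ties broken to the lowest label. The
canonical 25-state backbone alphabet is not redistributable as
coordinates inside this package, so fwdyn loads any alphabet in a simple
TSV schema (`loadAlphabet()`); a clearly labelled synthetic stand-in
alphabet ships for demonstrations and the tests use small synthetic
alphabets throughout (`syntheticAlphabet()`).

Coupling between fragments i and j is the mutual information between
their state sequences over the analysis window (by default the last half
of each replica, mirroring analysis of the equilibrated tail of MD
trajectories; synthetic stationary sequences use the full window). The
plug-in MI is biased upward under finite sampling, so fwdyn subtracts
the first-order bias (Rx−1)(Ry−1)/(2F ln 2) bits (occupied state counts
Rx, Ry), or alternatively the mean MI over seeded shuffles of one
sequence. Normalization divides by the joint entropy after applying the
same correction:

> cNMI(X,Y) = max(0, I(X;Y) − b) / (H(X,Y) − b)

Correcting numerator and denominator consistently makes identical
non-constant sequences score exactly 1 and leaves independent sequences
at ≈ 0 (mean ≤ 0.01 at F = 2000 over 50 seeds, asserted in the
acceptance suite); two constant sequences define 0. Values are clamped
to [0, 1].

## Differential coupling and hub calling

Per fragment pair, the coupling contrast between conditions is the log2
fold change of condition means with a 1e-6 pseudocount, and a hub is a
pair with |log2FC| > 2 and BH-adjusted p < 0.01. The p-value defaults to
a limma empirical-Bayes moderated t-test (with a mean-variance trend)
across replicas, computed on the per-replica corrected MI values. This
choice is deliberate: with the typical 3-versus-3 replica design, a
replica-label permutation test has an exact p floor of 1/20 = 0.05 and
can never reach FDR < 0.01, and a per-pair Welch t-test rests on a
variance estimate with 2–4 degrees of freedom that is too unstable to
detect even an eightfold coupling change reliably. Moderating the
per-pair variance across all fragment pairs — the standard small-sample
remedy in genomics — restores power while keeping the null calibrated
(no pair reaches adjusted p < 0.01 in null simulations). Both
alternatives remain available (`test = "welch"` / `"permutation"`), and
the permutation test is verified against exhaustive enumeration of all
20 label assignments.

Per-residue hub frequency counts, for each residue, the hub pairs with a
member fragment covering it (fragment i covers residues i..i+3). Pair
counting is the default; counting unique partner fragments instead is a
one-line post-processing step on the hub table.

# Synthetic data: what it emulates, and what it does not

The generators provide every input the pipeline consumes, with ground
truth, under single-stream seeded RNG (each generator derives its stream
from the user seed plus a stable per-component offset, so adding outputs
never reshuffles existing ones):

* `genStateSequences()` draws i.i.d. uniform fragment states and injects
  pairwise couplings through a copy channel: y = x with probability s,
  else uniform. The channel MI is known in closed form
  (`analyticChannelMI()`). The default study condition couples one pair
  in both conditions with strengths 0.4736 (bound) and 0.16 (unbound)
  at M = 4, chosen once so the analytic MI ratio is exactly 8
  (log2FC = 3); 3 replicas × 2000 frames per condition and 10 fragments
  mirror a realistic replica design at desk scale.
* `genToyComplex()` builds rigid lattice "domains" (chains H, L), an
  antigen blob (G), optional exactly-placed interaction motifs, optional
  constant antigen drift (unbinding) and Gaussian thermal jitter. Frame
  1 is jitter-free so placed geometries are exact there; the true COM
  distance series is computed analytically from the layout.
* `genMutationScores()` emits deterministic logits with the wild-type
  logit raised by a per-region bias (default FW 10, CDR 0, reproducing
  the qualitative FW-vs-CDR rank contrast; bias 0 yields uniform ranks).
* `genRepertoire()` draws sequences from per-position residue
  distributions; the emitted profile equals the empirical fractions of
  the emitted FASTA exactly.

These generators validate statistical behaviour and geometric logic.
They do **not** emulate force-field physics, autocorrelated dynamics,
rotamer realism or sequence phylogeny: passing tests demonstrate that the
estimators, detectors and filters behave correctly under their stated
models, not that any particular biological system will show the same
effect sizes. In particular, real MD frames are temporally correlated,
which inflates effective MI sampling noise relative to the i.i.d.
synthetic case; the bias correction and replica-level testing mitigate
but do not remove this, and real analyses should treat the analysis
window and replica count as first-class design choices.

# Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; temperature is fixed at 1.
* Kabsch superposition guards the reflection branch by the sign of the
  rotation determinant and clamps tiny negative residuals to zero, so
  self-RMSD is 0 to ~1e-7 Å.
* Coincident COMs (separation < 1e-9 Å) make the packing angle
  undefined; affected frames are flagged NA with a warning.
* Fragments missing a Cα are excluded from encoding (and hence all
  pairs) with a warning; a chain needs ≥ 4 residues.
* Two constant state sequences have H(X,Y) = 0 and define cNMI = 0; the
  corrected numerator is clamped at 0 before normalization.
* Ties in prototype assignment break to the lowest state label;
  ddG = 0 classifies destabilizing; boundary equality satisfies
  geometric criteria. All three conventions are deterministic and
  documented where they apply.
* Manifest determinism: `manifest.json` contains only reproducible
  content (parameters, seeds, checksums, version); wall-clock timestamps
  live in `run.log`, so identical reruns produce identical manifests.

# Problem sizes used by the test and acceptance suites

The shipped suites run at the study's desk-scale conditions: MI
definition checks on 1,000 random pairs (F ≤ 200, M ≤ 6), corrected-MI
calibration at F = 2000 over 50 seeds, hub recovery and null calibration
over 50 seeded 3v3 × 2000-frame runs each, 100 random rigid motions on a
10-frame toy complex, 10×10 boundary-inclusive classifier grids per
detector family, 10 drift and 50 flat unbinding trajectories, 50 seeded
scans of a 120-residue chain, and a 20-point occurrence-threshold sweep.

# Known limitations

* PBC unwrapping, solvent handling, protonation and hydrogen placement
  are out of scope; inputs are assumed whole and, for hydrogen-bond
  detection from topology, protonated.
* The canonical M32K25 prototype coordinates must be supplied by the
  user in the TSV schema; results depend on the alphabet used.
* The moderated test assumes exchangeable replicas within condition;
  replicas of very different lengths should be windowed to comparable
  frame counts first.
* `mmCIF` is not parsed; convert to PDB upstream.
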