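---
title: "Predicting trans-prenyltransferase product chain length with the three-floors model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting trans-prenyltransferase product chain length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threefloors)
```

## The model and its assumptions

Short-chain *trans*-prenyltransferases share a fold in which ten α-helices
enclose the condensation pocket; the growing polyprenyl pyrophosphate
scrunches into an elongation tunnel formed by helices D, E and F. Residues
from these three helices whose side chains face the tunnel form three
"floors", one α-helix pitch (5.4 Å) apart — about the length of one C5
prenyl unit. Whether the chain passes a floor or is terminated there is
assumed to depend only on the bulk and rigidity of the three side chains in
that floor. Termination at floors 1, 2 and 3 yields FPP (C15), GGPP (C20)
and GFPP (C25); an enzyme open at all three floors makes products of C30 and
longer, which the package bins together as `GE_C30`.

The assumptions worth keeping in mind:

* **One tunnel per monomer.** Long-chain enzymes that elongate along the
  homodimer interface violate the model; such enzymes can carry bulky floor
  residues yet make ≥C30 products, and the predictor will call them too
  short. This is the model's known blind spot in bacteria.
* **Homodimeric, in vitro behavior.** Heterodimeric enzymes whose large
  subunit is re-programmed by a small regulatory subunit are outside scope.
* **No C10 call.** The floors begin above FPP length; a GPP synthase is
  typically called C20 by mistake. The class vocabulary keeps `C10` (and
  `NA`, no detected activity) for experimental labels only.

## The pipeline

`predict_chain_length()` runs three steps:

1. **Template selection.** The query is globally aligned (Needleman–Wunsch,
   affine gaps) against each of the eleven registry templates; the template
   with the highest percent identity wins. Identity is counted over columns
   where both rows carry a residue, so terminal overhangs do not dilute it.
   Ties go to the earlier template in the fixed registry order.
2. **Floor mapping.** The template's nine annotated floor positions are
   projected through the alignment onto the query. A gap in the query row
   yields a gap marker: a missing side chain blocks nothing, and the
   prediction is flagged `gap_at_floor` rather than failing silently. A
   query `X` at a floor site is an error — an unknown residue cannot be
   scored.
3. **Scoring and cascade.** Each floor's blocking score is the
   weight-averaged blocking score of its residues, compared against the
   floor's threshold top to bottom; the first strict exceedance terminates
   the chain. Equality falls through — a floor must actively block.

## Parameters

**Blocking table** (`default_blocking_table()`). `B(aa)` = side-chain van
der Waals volume (Creighton residue volumes minus the 48 Å³ glycine
baseline) normalized to tryptophan, times a torsional-rigidity factor: 1.00
for rigid/absent side chains (G, A, P), 0.95 for one-χ residues (S, C, T,
V), 0.90 for aromatics (the ring is rigid; H, F, Y, W), 0.85 for two-χ
branched residues (I, L, N, D), 0.70 for three-χ (M, E, Q) and 0.55 for
four-χ chains (K, R). Values are rounded to three decimals; the table runs
from `B(G) = 0` to `B(W) = 0.9`. The factor encodes that a long flexible
side chain can rotate out of the tunnel while an aromatic of similar volume
cannot; it is the package's own reconstruction of a volume-and-torsion
blocking scale and can be overridden per model.

**Site weights** (`default_weights()`, dimensionless, each floor summing
to 1). Floors 1 and 3 are dominated by their first two sites (site 3
contributes 1.1% and 0.6%); floor 2 is led by site 2 (20.0 / 55.3 / 24.7%).
A higher weight marks a site the elongating chain is more likely to pass,
so `trace_elongation_route()` orders sites per floor by descending weight.

**Thresholds** `θ = (0.43, 0.41, 0.43)` (score units). These sit between
the largest all-small-pool floor score (0.372, all-threonine) and the
smallest all-bulky-pool score (0.463, all-methionine), so the residue
vocabulary the model treats as "small" always passes and "bulky" always
blocks, with working margin on both sides; the printed bacterial worked
example (Ala/Thr/Ile first floor, score 0.272; Leu/Phe/Met second floor,
score 0.603) falls cleanly on the correct side of each.

**Ambiguity band** `δ = 0.05` (relative). A decisive comparison within
`δ·θ[f]` of its threshold emits the adjacent class as a secondary call,
rendered shorter-first (`C20/C25`). The band is this package's explicit
device for dual calls; a near-threshold floor is genuinely uncertain, and
the dual call makes that visible instead of hiding it. If the
counterfactual outcome is not adjacent (e.g. a marginal first-floor block
over an otherwise open tunnel), no secondary is emitted and the prediction
is flagged `ambiguous`.

**Alignment** (`alignment_params()`): BLOSUM62, gap open 11, gap extend 1 —
the common protein defaults; a gap of length L costs `open + L·extend`.
Matrices can be given by name, as a matrix, or as an NCBI-format file.
Predictions below 30% identity to their best template are flagged
`low_identity`; template-based floor mapping degrades with distance.

**Six-site mode** (`six_site = TRUE`). The near-zero-weight site 3 of
floors 1 and 3 can be dropped (weights renormalized), reducing the model to
six informative floor residues; exposed as an option, not the default.

## The synthetic registry and generator

The package ships no real PDB-derived chains. `make_synthetic_registry()`
deterministically builds a surrogate family: a 320-residue ancestor,
per-template substitutions away from the floor sites (12–38% divergence,
plus a few loop insertions and C-terminal truncations so templates differ
in length), and floor residues drawn from a bulky pool {W, F, Y, L, M} at
each template's decisive floor and a small pool {G, A, S, C, T} elsewhere.
Kingdom labels follow the organisms of the eleven template structures;
native product classes are synthetic assignments covering C15–≥C30. The
shipped file is frozen output of this function and a test keeps them equal.

`generate_floor_variants()` emulates a site-directed mutagenesis series on
a template backbone: decisive-floor residues from the bulky pool, other
floors small, background substitutions elsewhere (default 2% per residue),
and the label is the generating model's own `predict()` output. This makes
the fixtures *consistency* fixtures, not biological simulations: passing
tests show the pipeline is faithful to its own model, not that the model is
right about real enzymes. Real data differ in ways the generator does not
emulate — mixed-bulk floors, dimer-interface tunnels, floor-adjacent
indels, and genuinely noisy experimental labels.

`generate_site_probes()` adds a fixed series of 27 single-site and graded
mutants (tryptophan probes over glycine, threonine or lysine backgrounds;
methionine-against-lysine "sandwich" mutants) designed so that per-site
weights are identifiable from class labels alone: under the shipped model,
any zero-error weight assignment must give floor sites 1/3 and 3/3 near-zero
weight and make floor-2 site 2 dominant. Together with the eleven labeled
templates they form a 38-record stand-in for a curated training table.

## Calibration

`fit_model()` minimizes a classification loss over per-floor weights and
thresholds by exhaustive search: weights on a simplex grid (default step
0.01, matching the three-decimal precision of the default weights) and, for
each weight vector, a 1-D threshold sweep, coordinate-descending over
floors in order 1→2→3 until the parameters stop changing (at most 20
rounds). The loss is a step function of the thresholds, so grid search is
the right tool; the space (three independent 2-simplices) is small and the
result is bit-reproducible.

Numerical choices that matter:

* **Threshold candidates are midpoints** between consecutive distinct
  observed floor scores (plus block-all/pass-all sentinels). Placing a
  threshold exactly on an observed score is fragile: the same score
  recomputed through a different BLAS path can differ in the last ulp and
  flip a strict comparison.
* **Ties break toward uniform weights, then toward the higher threshold.**
  The permissive threshold tie matters for coordinate descent: early in the
  fit the floors below the current one are untrained, so many records are
  indifferent between blocking and passing, and a restrictive tie would
  block them all at floor 1 and permanently starve floors 2 and 3 of
  training signal.
* **Initialization** is uniform weights and pass-all thresholds; a floor no
  training record ever reaches keeps a finite pass-all threshold above every
  observed score.
* NA-labeled records are excluded (the model has no inactive class);
  unmappable records are excluded with a warning and counted.

Optional blocking-table refinement (`fit_blocking = TRUE`) perturbs one
residue at a time and keeps only improvements; it is off by default because
a few dozen training records cannot support 20 extra parameters.

`cross_validate()` wraps the fit in seed-deterministic stratified folds,
merging classes smaller than the fold count into one stratum with a
warning.

## Evaluation conventions

`score_predictions()` counts a prediction correct when *either* its primary
or its secondary class equals an experimental label (a `C20/C25` call is
credited for a C25 enzyme); dual experimental outcomes credit either
determined class. `GE_C30` matches any determined product of C30 or longer.
NA-labeled records count as errors unless `exclude_na = TRUE`. The
within-one-C5 accuracy additionally credits calls one class off. Reports
carry per-kingdom/phylum/template breakdowns, a 4×6 confusion matrix, the
predicted class distribution, and the mean best-template identity; printed
percentages are rounded half-up with full-precision fractions retained.

## Problem sizes in the shipped tests

The test suite validates alignment scores against an independent
three-state DP oracle on 200 random pairs of length ≤ 8 (the oracle itself
is checked against full alignment enumeration on shorter pairs); fits a
60-record synthetic training set (11 templates + 27 probes + 22 variants,
seed 42) at full 0.01 grid resolution, recovering zero training error and
the generating weight ranking wherever generating weights differ by more
than 0.05; runs the 180-prediction monotonicity sweep (20 residues × 9
sites); and exercises the evaluation arithmetic on a constructed 141-record
accounting fixture and a 100-variant class-structured screen. Coarser grids
(0.05–0.2) are used in unit tests where only mechanism, not resolution, is
under test.

## Known limitations

* Floor annotations are template data; a wrong annotation is a data bug the
  code cannot detect beyond range checks.
* The synthetic registry supports calibration and testing, not biological
  inference; swap in curated templates for real annotation work.
* Binary class labels carry limited information about weights: calibration
  pins near-zero sites into an interval (below ~5%), not to a point.
* Long-chain enzymes elongating along the dimer interface, heterodimeric
  regulation, and C10 products are outside the model by design.
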