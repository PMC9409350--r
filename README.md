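# threefloors

Predicts the predominant product chain length of *trans*-prenyltransferases
(trans-PTs) from protein sequence alone.

Trans-PTs condense IPP (C5) units onto an allylic prenyl diphosphate and hand
the growing polyprenyl pyrophosphate into an elongation tunnel lined by
α-helices D, E and F. Three tiers of tunnel-facing residues — the "floors",
one helical turn (5.4 Å ≈ one C5 unit) apart — decide where elongation stops:

* first floor blocked → FPP (**C15**),
* second floor blocked → GGPP (**C20**),
* third floor blocked → GFPP (**C25**),
* open tunnel → polyprenyl pyrophosphates of **≥C30**.

Because a single residue substitution at a floor site can change the product
class, plain homology annotation is unreliable for this family; scoring the
floors directly is both accurate and fast (well under a second per query).
The package is for anyone annotating trans-PT gene families — e.g. screening
plant genomes for GFPP synthases, the precursor enzymes of sesterterpenes.

## The model

Each amino acid carries a dimensionless **blocking score** `B(aa)` —
side-chain van der Waals volume normalized to tryptophan, down-weighted for
torsional flexibility (a lysine can swing out of the tunnel; a phenylalanine
cannot). For a query, the nine floor residues `r[f,s]` (floor `f`, site `s`,
one site per tunnel helix) are located by global alignment (BLOSUM62,
gap open 11 / extend 1) against the best of eleven bundled searching
templates, and each floor is scored

```
S[f] = Σ_s  w[f,s] · B(r[f,s]),       Σ_s w[f,s] = 1
```

with trained site weights `w`. The floors are then cascaded top to bottom
against thresholds `θ`: `S[1] > θ[1]` calls C15, else `S[2] > θ[2]` calls
C20, else `S[3] > θ[3]` calls C25, else ≥C30. A decisive comparison within
5% of its threshold emits the adjacent class as a dual call (e.g.
`C20/C25`). The default weights make floor sites 1 and 2 dominant on floors
1 and 3 (site 3 contributes 1.1% and 0.6%) while floor 2 is led by site 2
(55.3%); ordering sites by weight traces the prenyl chain's route through
the tunnel (`trace_elongation_route()`).

The bundled template registry is a **synthetic stand-in**: the true chains
of the eleven PDB templates are not redistributed, so a deterministic
surrogate family with annotated floors ships instead
(`make_synthetic_registry()`), and all shipped calibration is defined
against it. Point `read_registry()` at your own file to use curated
templates.

## Worked example

A bacterial trans-PT whose mapped floor residues are Ala/Thr/Ile on the
first floor and Leu/Phe/Met on the second (third floor open):

```r
library(threefloors)
fa <- floor_assignment(c("Ala", "Thr", "Ile",
                         "Leu", "Phe", "Met",
                         "Gly", "Gly", "Gly"))
prediction_from_assignment(fa)
#> query: C20  (floors 0.272/0.603/0.000; template -, identity -%)
```

The small first floor (score 0.272 ≤ θ₁ = 0.43) lets the chain pass; the
bulky second floor (0.603 > θ₂ = 0.41) terminates it at C20 (GGPP). From a
sequence, the full pipeline also reports the selected template and identity:

```r
reg <- default_registry()
predict_chain_length(reg$templates[["5E8H"]]$sequence)
#> query: C20  (floors 0.241/0.603/0.295; template 5E8H, identity 100.0%)
```

Batch prediction, calibration, accuracy accounting and synthetic fixtures:

```r
ds  <- generate_floor_variants(reg, default_model(),
                               generator_config(quota = c(C15 = 5, C20 = 5,
                                                          C25 = 5, GE_C30 = 5)))
rep <- predict_batch(ds)
score_predictions(rep, ds)
#> Prediction accuracy: 100% (20/20)
#> Within one C5 unit:  100%
#> ...
fit <- fit_model(ds)          # grid-search weights and thresholds
```

A command-line wrapper ships at `inst/cli/threefloors.R` with `predict`,
`train`, `evaluate` and `simulate` subcommands.

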