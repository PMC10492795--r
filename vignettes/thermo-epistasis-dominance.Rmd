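---
title: "Thermodynamic models of epistasis and dominance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic models of epistasis and dominance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidom)
```

## The question the package models

A diploid gene carrying two mutations can hold them in *cis* (both on one
allele, the other wild type) or in *trans* (one per allele). The first
arrangement is scored as intra-molecular epistasis, the second as a
between-allele interaction or — for homozygous parents — as dominance of a
compound heterozygote. `epidom` computes all of these scores on phenotypes
generated by explicit equilibrium thermodynamics, so that every interaction
in the output is a consequence of folding energetics, ligand competition, or
a nonlinear dose–response, never of an ad hoc assumption about how mutations
"should" combine.

## Models and assumptions

**Folding-only model.** Each allele expresses exactly half of the total
protein `X_T` (no allelic expression imbalance), the protein folds
cooperatively between two states, and the phenotype is the summed folded
concentration normalized to the wild-type homozygote (1 AU). Mutational
effects are additive on the free-energy scale within one molecule: a *cis*
double mutant sums its ΔΔG values before the Boltzmann factor is taken.
The two alleles are thermodynamically independent here, which is why
between-allele combinations are exactly additive in this model — the
additive null model for dominance is *derived*, not assumed.

**Folding + binding model.** A third state adds one-to-one ligand binding.
All species per allele collapse into a single lumped constant
`K_i = exp(ΔG_B,i/RT)·(1 + exp(ΔG_F,i/RT))`, and the free ligand solves
`L + Σ_i 0.5·X_T·L/(L + K_i) = L_T`. The left-hand side is strictly
increasing in `L`, which guarantees a unique root in `[0, L_T]` and makes
bracketed bisection globally convergent. Shared ligand couples the alleles;
every between-allele interaction and all dominance in this model flows
through that one coupling.

Assumptions worth stating: equilibrium (no kinetics), monomeric protein (no
dimerization or cooperativity), one ligand type, equal allelic expression,
and phenotypes proportional to one molecular species unless a linking
function says otherwise.

## Parameters, units, defaults

| Parameter | Unit | Default | Notes |
|---|---|---|---|
| `dG_folding_wt` | kcal/mol | −2 | moderately stable; −3.5 / −0.5 variants examined |
| `dG_binding_wt` | kcal/mol | −5 | moderate affinity; significand 2.91 for K_D |
| `R` | kcal/(mol·K) | 1.98e-3 | gas constant |
| `T` | K | 310.15 | 37 °C |
| `X_T` | conc. units | 1 | see below |
| `ligand_ratio` | — | 1 | 0.8 / 1 / 2 / 10 examined |
| linking `m` | — | 1.5 (concave/convex), 5 (sigmoidal) | sets {0.6, 1.5, 2.5, 3.8, 5.5} and {2.2, 3.5, 5, 7, 10} supported |
| ΔΔG grid | kcal/mol | −2 to 13 by 0.125 | 121 single mutants |
| phenotype grids | AU | 0.5–1.02 by 0.005 (singles), 0–1.02 by 0.01 (homozygotes) | inverted to ΔΔG |

**The concentration scale.** The conservation equation adds `exp(ΔG/RT)`
terms directly to concentrations, so the implicit unit is the
Boltzmann-factor unit, and the absolute scale of `X_T` is a genuine free
choice: nothing in the equations pins it down. The package defaults to
`X_T = 1`, which puts the wild type deep in the tight-binding regime
(K_D ≈ 2.9e-4 of `X_T`). That is the regime in which a 0.8 ligand ratio
binds ~80% of the protein and the null heterozygote floors at 62.5% of wild
type; users studying weak-binding regimes should lower `X_T` toward K_D and
should expect all ligand-competition effects to soften. The reported
dissociation constant `exp(ΔG_B/RT)` has significand 2.91 regardless of the
unit chosen; the package does not commit to a molar standard state because
the model does not need one.

## Scoring definitions

Expectations for a double mutant from singles `W_A`, `W_B` and wild type
`W_wt = 1`: additive `max(C, W_A + W_B − W_wt)` and log-additive
`max(C, W_A·W_B/W_wt)`, with `C = 0.5` within allele (the second allele is
always functional) and `C = 0` between alleles. Scores are observed minus
expected (additive scale) or log-observed minus log-expected; the log score
is flagged undefined, not raised, when either side is non-positive.
Dominance uses the midpoint expectation `(W_AA + W_BB)/2` — no lower bound
is applied to it — and the degree of dominance divides the heterozygote's
deviation from the midpoint by the less-fit homozygote's distance from it.
With that ordering the magnitude is label-invariant and the sign is
positive exactly when the fitter allele dominates; a heterozygote equal to
either parent scores ±1. Homozygotes closer than 1e-9 AU make the
denominator meaningless; such records are flagged undefined and kept.

## Linking functions

The concave, convex and sigmoidal transforms are anchored at (0,0) and
(1,1) and strictly increasing, with curvature `m`. All three are 0/0 at
`m = 0`; below `m = 1e-6` the package evaluates them as the identity, which
keeps the `m → 0` limit continuous to better than 1e-6 without catastrophic
cancellation. Inverses are analytic. The anchoring is only asserted on
[0, 1], but the formulas are evaluated as written up to 1.02 AU because the
phenotype grids extend there. Under a linking function the pipeline
transforms *all* observed phenotypes first and computes expectations,
clamps and scores on the transformed scale — including the `C = 0.5`
bound, which therefore refers to transformed units. That ordering follows
the transform-then-score convention of the simulation procedure; applying
the clamp on the raw scale instead would change scores near the floor.

## Numerical choices

* Boltzmann factors are clipped at `exp(±500)`; folded fractions go through
  the logistic function, stable for |ΔG/RT| of several hundred.
* The ligand root uses vectorized bisection, up to 200 iterations with an
  adjacent-double stopping rule; the returned state must satisfy both
  conservation laws to 1e-10 relative or the solver errors out with its
  bracket and residual. Whole mutation grids are solved as single
  vectorized sweeps.
* The wild-type reference equilibrium is recomputed per parameter/ratio
  pair and cached; it is never hard-coded, so WT/WT normalizes to exactly 1
  by construction.
* Phenotype→ΔΔG inversion brackets on [−40, 60] kcal/mol and polishes with
  `uniroot` at tolerance 1e-12, giving residuals below 1e-9 AU. Targets
  above the stabilizing-limit maximum (the folding-only single-heterozygote
  maximum is ≈1.019 AU at the defaults, so the 1.02 AU grid ceiling is
  unattainable there) or at/below the asymptotic minimum (0.5 AU for single
  heterozygotes) are flagged infeasible, dropped, and counted in the run
  summary — and dropped *symmetrically* from folding and binding panels so
  phenotype-matched comparisons stay paired.
* Scenario sweeps are deterministic: ordered pairs are stored, symmetry is
  tested rather than assumed, and no randomness is involved.

## What the synthetic flow data emulate — and what they do not

The generator emulates the structure of the scoring problem: 5000 events
per replicate, three biological replicates, optional batches, an
autofluorescence-only control population, a wild type in every batch, and
two scatter sub-populations (low-SSC cells around 170 units; a high-SSC
mode around 650 units that is 1.3× brighter in GFP, so the gate matters for
accuracy). Noise is multiplicative log-normal per event (sd 0.25 on the log
scale), with a per-replicate colony effect (log-sd 0.02) and a per-batch
gain (log-sd 0.05) that within-batch normalization cancels. These choices
are an emulation, not a cytometer model: there is no spectral spillover,
no instrument compensation, no event-rate artifacts, and the true
phenotypes are injected linearly. Passing the recovery tests therefore
demonstrates that the gating/normalization/error-propagation chain is
correct and calibrated for this noise family — not that it would be
unbiased on any real instrument's systematics.

The standard-error formulas (the nested-radical SE of the normalized
signal, the Pythagorean additive-expectation SE, the relative-error
log-expectation SE, and the interaction SE) are implemented exactly as
printed, without algebraic simplification, so the numbers are bit-faithful
to their definitions. Each population's SE is the standard error across
replicate means. With three replicates those SEs carry few degrees of
freedom, so "within 3·SE" coverage behaves like a t statistic rather than a
normal one; the conservative form of the normalized-signal SE (a relative
error used on the absolute scale for phenotypes below 1) is what keeps
coverage at the validated level.

## Problem sizes

The validation suite runs the full 121×121 ΔΔG grid for the folding-model
additivity identity, full grids at ligand ratios 1 and 1000 for the
sign-structure and decoupling checks, ~100×100 phenotype-matched pairs for
the folding/binding equivalence, and 100 generator seeds × 8 genotypes for
flow recovery; the whole suite completes in well under a minute on one
core except the flow-recovery sweep, which dominates at roughly a minute.

## Known limitations

* No dimerization, cooperativity, multi-ligand systems, non-equilibrium
  dynamics, or allele-specific expression imbalance.
* Ligand-excess decoupling is asymptotic, not exact at finite ratios: the
  free ligand still shifts by O(`X_T`) between genotypes, leaving residual
  between-allele interaction and dominance of order `X_T/L_T` (about 1e-4
  at ratio 1000 over the default grids). Similarly, the clean sign
  separation of within- (≤ 0) and between-allele (≥ 0) interaction scores
  at ligand ratio 1 holds over the moderate-effect region but reverses in
  the deep-detrimental corner, where the 0.5 clamp pins the within-allele
  expectation and ligand limitation drags doubles below the additive line —
  the same corner effects that appear at low ligand ratios.
* Flow ingest is delimited-table only (columns `FSC_A`, `SSC_A`, `GFP`,
  `genotype`, `replicate`, `batch`); binary cytometer formats are out of
  scope.
* Linking functions are applied, never fitted.
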