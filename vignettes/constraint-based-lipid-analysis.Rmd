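---
title: "Constraint-based analysis of lipid production in oleaginous yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of lipid production in oleaginous yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleoflux)
```

## The problem

Oleaginous yeasts such as *Rhodotorula toruloides* accumulate large amounts
of triacylglycerol when nitrogen limits growth while carbon is in excess, so
the molar carbon-to-nitrogen (C/N) ratio of the medium is the main control
knob for single-cell-oil processes on low-cost substrates (crude glycerol,
hemicellulosic xylose, acetate). Interpreting steady-state cultivation data
for such a process raises questions the measurements alone cannot answer:
how much of the consumed carbon could at best end up in lipid, which
pathways supply the NADPH and acetyl-CoA that lipid synthesis consumes,
whether measured gas-exchange rates are even consistent with the assumed
metabolism, and what an apparent carbon deficit in the balance says about
unmeasured excreted products. `oleoflux` answers these questions with flux
balance analysis (FBA) on a stoichiometric metabolic model, together with
the bioprocess arithmetic (rates, yields, respiratory quotient, carbon
recovery, exponential fed-batch design) needed around it.

## Flux balance analysis core

A model is a stoichiometric matrix $S$ (metabolites x reactions) with flux
bounds $l \le v \le u$ (mmol/gDW/h; the biomass flux is in 1/h). FBA solves

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

a linear program. No linear-programming backend is assumed: the package
ships a first-principles bounded-variable two-phase primal simplex
(`src/simplex.cpp`), dense because the models handled here have tens of
reactions. Numerical choices:

* solver feasibility tolerance `1e-9`; the public contract asserts
  $\|Sv\|_\infty \le 10^{-6}$ and bound violations below `1e-6`;
* Dantzig pricing with a switch to Bland's rule after `20 (n+m)` iterations
  to rule out cycling on degenerate vertices;
* ties among alternate optima are deliberately *not* broken: alternate
  optima are characterized explicitly by flux variability analysis
  (`fluxVariability`) and by random sampling, which is how the analysis
  treats the non-uniqueness of condition-constrained solutions;
* exchanges default to +-1000 mmol/gDW/h when a file declares none.

The test suite checks the solver against an exhaustive vertex-enumeration
oracle on small networks and against an independent interior-point/simplex
implementation (SciPy HiGHS) on the full toy model.

`sampleFluxes` performs random-objective vertex sampling: each sample
maximizes a random-signed, random-weighted objective, yielding vertices of
the feasible polytope. This is the standard field practice for
characterizing solution-space variability with a handful of constraints;
it is reproducible from a single seed, and needs no burn-in or thinning as hit-and-run samplers do. Random
weights are keyed to sorted reaction ids, so reordering reactions permutes
columns without changing the sample. The sample mean is a vertex-biased
summary of the feasible set, not a uniform average — which is what the
spread-between-extremes question posed here needs.

## The toy genome-scale model

`buildToyGEM()` returns a hand-built network (30 metabolites, 43 reactions)
covering exactly the pathway inventory the analysis interrogates: glycerol
assimilation through an NADP-dependent glycerol dehydrogenase (`GDH`) or
the kinase/G3P-dehydrogenase route (`GLYK`); xylose via
reductase/xylitol-dehydrogenase (with xylitol secretion as the classic
overflow); acetate via AMP-forming acetyl-CoA synthase (2 ATP); oxidative
and non-oxidative pentose phosphate pathway; phosphoketolase with
phosphotransacetylase and acetate kinase; glycolysis/gluconeogenesis; TCA
cycle with NADP-isocitrate dehydrogenase; glyoxylate shunt; malic enzyme;
ATP-citrate lyase; oxidative phosphorylation with a configurable P/O ratio
(default 1.5, a conservative textbook value for yeast mitochondria); lumped
lipid synthesis costing 2 NADPH and 1 ATP per acetyl-CoA incorporated (the
canonical fatty-acid elongation stoichiometry), with a C16 lipid unit; and
a macromolecular biomass equation over protein, lipid, carbohydrate,
nucleotide and "other" pseudo-metabolites with a growth-associated
maintenance (GAM) of 30 mmol ATP/gDW, representing polymerization cost.

Elemental bookkeeping is exact for carbon and nitrogen: every internal
reaction is C- and N-balanced (`checkMassBalance` verifies this), cofactor
pairs (ATP/ADP, NAD(P)H/NAD(P)) carry identical skeletons so they can never
leak carbon, and acetyl units are counted as C2 (coenzyme A itself is not
modeled). Water and protons are not modeled, so hydrogen and oxygen are
*not* conserved — the balance checker therefore defaults to carbon.
Monomer masses used to convert mass fractions to mmol/gDW are stated
constants (protein residue 89, carbohydrate unit 162, lipid unit 256,
nucleotide 330, other 62 g/mol).

The default biomass baseline (protein 0.45, lipid 0.15, carbohydrate 0.30,
nucleotide 0.06, other 0.04 g/gDW) is a typical pre-limitation composition
for an oleaginous yeast; since no canonical baseline is fixed by the
underlying data, the baseline is an explicit input of
`rescaleBiomass`.

## Closed-form theoretical lipid yields of the toy network

`theoreticalMaxLipidYield` fixes growth to zero ("minimal growth" is taken
as exactly zero — any positive floor only subtracts a constant), keeps
maintenance at its default (a lower bound of zero, so the yield is a pure
ratio and provably independent of the reference uptake), closes CO2 uptake
(no net fixation), opens lipid export and maximizes it. For the default
toy network the optima can be derived by hand from carbon/NADPH/ATP
accounting, and the package's LP must agree to 1e-6:

**Glycerol (yield 11/16 = 0.6875).** Take uptake $U$ (C3). All glycerol
enters via `GDH` (1 NADPH gained, 1 ATP spent, no carbon lost — NADPH is
worth more than the NADH of the alternative route). Triose phosphate is
then split between three routes: phosphoketolase (2 t3p -> 3 acetyl-CoA,
carbon-lossless, ATP-neutral once the gluconeogenic steps are accounted),
the oxidative PPP loop (1 t3p -> 1 acetyl-CoA + 1 CO2 + 2 NADPH) and
glycolysis/PDH (1 t3p -> 1 acetyl-CoA + 1 CO2 + 2 NADH + 2 ATP).
With $f_i$ the triose allocations, lipid demand (2 NADPH, 1 ATP per
acetyl-CoA) and a P/O of 1.5 give the binding system
$U + 2f_2 = 2A$, $5f_3 = U + A$, $A = 1.5f_1 + f_2 + f_3$,
$\sum f_i = U$, whose solution is $f_1 = U/16$, $f_2 = 17U/32$,
$f_3 = 13U/32$, $A = 33U/32$ acetyl-CoA, i.e. lipid carbon $2A$ out of $3U$
consumed carbon: $\mathbf{11/16}$.

**Xylose (yield 23/40 = 0.575).** Xylose costs one NADPH at the reductase
and one ATP at the kinase while yielding one NADH, so NADPH is scarcer than
on glycerol. With the same accounting (pentose phosphates interconverting
with hexose/triose through the non-oxidative PPP, oxidative PPP as the
NADPH source, glycolysis as the ATP source) the binding carbon/NADPH/ATP
system yields $A = 23U/16$ acetyl-CoA from $U$ xylose, i.e. lipid carbon
$2A$ of $5U$: $\mathbf{23/40}$.

**Acetate (yield 9/23 ≈ 0.391).** Acetyl-CoA is direct (2 ATP each), but
every NADPH must be made from acetyl carbon. The optimum combines the
glyoxylate shunt (carbon-conserving anaplerosis), malic enzyme and a
gluconeogenic oxidative-PPP loop. Writing $L$ for lipid flux and solving
the steady-state balances of the participating intermediates with the ATP
and NADPH constraints binding gives the oxidative-PPP feed
$n = 8L/9$ and uptake $U = 184L/9$, i.e. lipid carbon $16L$ of $2U$:
$\mathbf{9/23}$. (A first-pass accounting that only uses NADP-isocitrate
dehydrogenase gives 1/3 — the LP beats it because the glyoxylate shunt
loses no carbon while shuttling acetyl units to malate.)

The ordering glycerol > xylose > acetate matches what genome-scale analysis
reports for this organism; the toy network's absolute numbers are its own
and are *not* tuned to reproduce any genome-scale model's values.

## The condition pipeline

Given one steady-state measurement set (`ConditionData`: growth rate,
substrate uptake, byproduct excretions, OTR/CTR, protein and lipid
content), the pipeline builds a condition-specific model in five steps:

1. `rescaleBiomass` fits the biomass equation to measured protein and lipid
   content, keeps nucleotide/other at baseline, and lets storage
   carbohydrate close the composition to 1 g/gDW (an inconsistent
   composition is an error, not a silent renormalization).
2. `constrainCondition` fixes substrate uptake and every *measured*
   byproduct at its value (unmeasured exchanges stay open — that is what
   lets the model predict missing products); fixes growth at the measured
   rate or, if that is unreachable, at the simulated maximum (recorded in
   the fit report); fits O2/CO2 "as close as possible" to OTR/CTR by
   minimizing the L1 deviation with auxiliary variables — a deterministic,
   solver-friendly definition of "as close as possible" — and then fixes them at
   the achieved values; finally widens every constrained exchange to
   97.5–102.5% of its value (default relaxation 0.025). The relaxation is
   applied to *all* constrained exchanges, O2/CO2 included — the more
   permissive of the two defensible choices, and the one that leaves the
   gas fluxes free to co-vary during sampling.
3. `estimateNGAM` maximizes the ATP-hydrolysis flux under those
   constraints — the energy the cell could spend on non-growth processes.
4. `sampleCondition` holds NGAM at >= 97.5% of that maximum (fixing it
   exactly would empty the interior of the polytope) and draws
   random-objective vertex samples (default n = 5000; smaller n is used in
   the test suite, see below).
5. `attributeFluxes` converts samples into NADPH source shares (per-sample
   production fractions, then averaged), pathway carbon fractions for
   phosphoketolase / ATP-citrate lyase / malic enzyme (carbon entering the
   signature reaction over substrate carbon uptake; currency metabolites
   excluded from the carbon count), predicted RQ, and predicted byproducts
   as C-mol fractions of uptake. C-mol fractions make byproducts
   comparable across metabolites; the xylitol-vs-arabitol ambiguity of
   HPLC data is immaterial here because the pipeline accepts either id for
   the measured polyol.

## The synthetic-data generator

`makeConditionDataset` emulates a turbidostat steady state from the toy
model itself: the C/N ratio sets the biomass composition through a stylized
monotone trend (lipid 0.15 -> 0.50 and protein 0.50 -> 0.25 as C/N goes
60 -> 120, clipped to [0.10, 0.60] / [0.15, 0.55] — the direction and
magnitudes seen in nitrogen-limited oleaginous yeasts); the minimal uptake
supporting the requested growth is found by FBA and inflated by 15%
(`uptakeExcess = 1.15`), representing energy spilling, and the ground truth
is the maintenance-maximizing flux distribution at that uptake. Measured
values are truth times independent Gaussian noise (`noiseCV`, default 0.02,
truncated at zero) — independence and normality are modeling choices,
since steady-state measurement errors carry no canonical model. The generator returns the generating fluxes
alongside, so recovery is testable.

What passing recovery tests shows — and what it does not: the pipeline
re-derives rates that a self-consistent steady state implies, under the
generator's own network. Real data add model mismatch (reactions absent
from any model), correlated instrument error, and slow drifts that a
turbidostat only approximately removes; none of these are emulated, so
recovery here validates the *machinery*, not the biology of any particular
dataset.

## Fed-batch design and simulation

`feedRate` implements the open-loop exponential profile
$F(t) = Y_{XS}\,\mu_0\,x_0 V_0\, e^{\mu_0 t} / (c_f - c_s)$ with $c_s$ a
design-time constant (the profile is open-loop: it is not adapted to the
measured accumulation). $Y_{XS}$ is substrate consumed per biomass formed (g/gDW),
so vessel consumption is $Y_{XS}\,\mu\,xV$ — note this is a *consumption*
yield, not a biomass yield; the defining property is that under ideal
growth the vessel substrate concentration stays exactly at its initial
value and total biomass is exactly exponential. `simulateFedBatch`
integrates the three balances (volume, biomass, substrate) with a
fixed-step classical Runge-Kutta scheme, default dt = 0.01 h — smooth
exponential dynamics need no adaptivity, and the fixed step keeps
trajectories bit-reproducible. When a phased growth schedule under-runs the
design rate, substrate accumulates (the multi-phase behavior seen in
practice); when consumption would drive substrate negative, it is clipped
at zero and the trajectory flagged substrate-limited. Sampling withdrawals
and gas-phase dynamics are not modeled.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on the toy model:
sampling uses 60–300 vertices per condition and 20 seeds for the noise
study, sizes chosen so the whole suite completes in well under a minute
while leaving the statistical assertions comfortably powered; the
conventional sampling depth (n = 5000) remains the default of
`sampleCondition` and runs in ~15 s if requested. Every random step
(datasets, sampling) is reproducible from a single integer seed.

## Known limitations

* The toy network is single-compartment; compartmentation effects (e.g.
  mitochondrial vs cytosolic NADPH pools) are out of reach by design.
* Hydrogen/oxygen balancing is not modeled, so degree-of-reduction
  constraints on gas exchange are softer than in a fully balanced
  genome-scale model.
* The sample mean over vertices is not the centroid of the polytope;
  attribution numbers should be read as "typical extreme-point" summaries
  of the feasible range, not as polytope averages.
* `readGEM`'s SBML support covers Level 3 core plus fbc flux bounds,
  objectives, formulas and charges; gene associations, groups and
  annotations are ignored (nothing in this analysis consumes them).
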