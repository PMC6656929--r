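---
title: "The angionet model: assumptions, parameterization and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The angionet model: assumptions, parameterization and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angionet)
library(dplyr)
```

## The model

`angionet` simulates the extracellular reaction network of four angiogenic
factors in a well-mixed tumor tissue: the pro-angiogenic growth factors VEGF-A
(isoforms V165 and V121, plus the proteolytically inactivated V114) and FGF2,
and the anti-angiogenic factors TSP1 (with its cleaved, inactive form TSP1c)
and PF4. The tissue is divided into three regions — the endothelial cell
surface, the tumor cell surface, and the interstitium (which aggregates the
extracellular matrix and both basement membranes) — and every molecular
species lives in exactly one of them. Nine receptor types (VEGFR1, VEGFR2,
NRP1, FGFR1, CD36, CD47, LRP1, α~x~β~1~ integrins, CXCR3) sit on both cell
surfaces, together with a cell-surface heparan sulfate proteoglycan pool
(cHSPG) that acts as a co-receptor; a second, interstitial HSPG pool (iHSPG)
acts purely as a reservoir that traps free factors. MMP3 activates proMMP9;
active MMP9 cleaves TSP1 to TSP1c and V165 to V114.

The model is *rule-based*: the package declares monomers with named binding
sites, seed species, and a catalogue of pattern-level reaction rules
(binding/unbinding, lateral coupling of surface partners, production,
degradation, internalization with receptor recycling, and catalytic
conversion). `expand_network()` applies the rules to the seed species until no
new species appear, producing a concrete species list and a mass-action
reaction list; `assemble_odes()` turns that into a coupled nonlinear ODE
system. Species identity is decided by a canonical labeling of the site-graph
(partition refinement followed by enumeration of the residual symmetric
orderings — complexes here never exceed eight monomers, so exhaustive
tie-breaking is cheap and exact).

Key structural assumptions encoded in the rule catalogue:

* V165 carries one receptor-binding site and one shared exon-7 site, so NRP1
  and HSPG binding to V165 itself are mutually exclusive; the ternary
  VEGFR2·V165·NRP1:cHSPG complex forms via NRP1 *pre-coupled* with cHSPG.
  V121 has the receptor site only.
* VEGFR2 never touches HSPG or NRP1 directly; V165 bridges it to both.
  V165 does not bind VEGFR1 pre-coupled with NRP1, while VEGFR1–cHSPG
  coupling leaves VEGF binding unaffected.
* FGF2 signaling complexes assemble HSPG-first: FGF2 binds cHSPG, the binary
  complex recruits FGFR1 into a trimer, and two trimers dimerize into the
  signaling complex. Only dimers count as FGF2 signaling. A dedicated
  cHSPG-release rule lets undimerized trimers shed cHSPG, which populates
  the non-signaling FGF2:FGFR1 monomer pool; dimers dissolve only by
  receptor unpairing.
* Ligated TSP1 receptors (all four) can couple laterally to VEGFR2; VEGF held
  in such a coupled complex is counted as non-signaling.
* Internalization destroys the soluble cargo and returns receptors and cHSPG
  instantly to their free surface pools, so each receptor total and both HSPG
  pools are conserved exactly (this is asserted by `conservation_report()`).
  cHSPG is treated like a receptor (conserved pool), so cHSPG sweeps scale a
  conserved quantity.
* V114 and TSP1c are inert: they only degrade.
* Proteolysis is modeled as direct bimolecular catalytic conversion of the
  free substrate (no explicit enzyme–substrate intermediates).

One rule covers both cell surfaces (identical kinetics, separate densities),
and cross-surface binding is structurally impossible. The transcription
yields 21 monomer types, 31 seed species and 84 rules, which expand to 150
species (65 per surface, 20 interstitial) and 630 directed reactions. The
original formulation of this model reports 40 seed species, 127 rules and
168 species; the complete reaction list behind those counts is not part of
the openly printed description, so the catalogue here was reconstructed
from the published interaction schematic and textual constraints, and the
counts differ. The structural check against the published species count
therefore fails for this transcription, which we report rather than hide;
every described mechanism is present.

## Units and geometry

Internal ODE state is in mol/cm³ *tissue*; all reported concentrations are
fluid-phase (pmol/L or nmol/L of interstitial fluid), converted with the
interstitial fluid fraction (`tissue_to_fluid_concentration()`). The tissue
is a 33 cm³ breast tumor with fluid fraction 0.31. Cell densities default to
10⁷ endothelial and 10⁸ tumor cells per cm³, chosen so that the printed
CXCR3 density (2,500 receptors/cell, the "low" point of the
2,500/5,000/10,000 low/medium/high convention) yields an anti-angiogenic
PF4-receptor pool consistent with the reported baseline distribution.

Bimolecular rate constants are given in 1/(M·s) and converted with the fluid
fraction as if all reactants were dissolved in the interstitial fluid (the
*fluid-equivalent convention*). Surface-area densities are carried in the
geometry record for documentation but are not consumed by this convention;
per-area coupling constants of the prior compartmental models are absorbed
into the fluid-equivalent coupling rates.

## Parameterization and its provenance

Values printed in the main-text sources are encoded directly:

* PF4 axis: K~d~ = 1.85 nM (CXCR3) and 238 nM (LRP1), at the association-rate
  convention k~on~ = 5×10⁵ M⁻¹s⁻¹; factor–factor affinities PF4·V165 5 nM,
  PF4·FGF2 37 nM, TSP1·VEGF 10 nM, TSP1·FGF2 10.8 nM.
* Heparin K~d~ values 80/39/41/20 nM (V165/FGF2/TSP1/PF4) parameterize iHSPG
  binding directly and set cHSPG dissociation rates by scaling the FGF2–cHSPG
  pair (`derive_chspg_rates()`); the affinity order PF4 > FGF2 > TSP1 > V165
  is preserved by construction.
* Fold-scaling rules (`apply_fold_scalings()`): V165–NRP1 alone 20-fold weaker
  than V165–NRP1:cHSPG; the V165-synergistic NRP1–cHSPG couplings 10-fold
  stronger than bare NRP1–cHSPG; VEGFR1–NRP1 10-fold weaker than VEGFR2–NRP1;
  VEGFR1–cHSPG 5-fold stronger than NRP1–cHSPG. All are applied as koff
  scalings at fixed kon, single-shot.
* Half-lives: 60 min for VEGF and FGF2, 5 min for PF4; degradation rates are
  ln(2)/t~1/2~ (`kdeg_from_half_life()`).

Everything else (VEGF/TSP1-axis kinetics, receptor and HSPG densities, MMP
rates, the remaining half-lives) is a **placeholder transcription**: the
source supplementary parameter table was unavailable, so these entries were
chosen once, in the style of the prior compartmental models this model builds
on, and — where the printed baseline distribution pins them down — sized from
the printed steady-state observations (for example, the iHSPG site density of
1.2×10¹⁴ sites/cm³ ≈ 0.65 µM fluid-equivalent follows from the reported
ratios of iHSPG-bound to unbound factor at the measured free concentrations).
Each such entry is marked `provenance: placeholder` in the shipped parameter
file. They are fixed package defaults, not fitting degrees of freedom.

Production rates are the one set the original study itself tunes: baseline
secretion is calibrated so that predicted tissue concentrations sit at the
reported aims inside the measured ranges (unbound VEGF 180.2 pM, total TSP1
3.0 nM, unbound PF4 4.7 nM, total FGF2 3.9 nM, total MMP3 5.0 nM, total MMP9
9.2 nM). `calibrate_baseline()` performs this tuning at run time by
coordinate-wise log-space root finding (proportional probes, then a log-log
secant step safeguarded by bisection once the aim is bracketed). A plain
proportional update oscillates for VEGF because the free pool switches
between a receptor-buffered and a saturated regime; the bracketed secant
handles both. The shipped production rates are the converged output of this
calibration, so re-running it returns unit multipliers in a single pass.

## Numerical choices

* Stiff integration with `deSolve::lsoda` (rate constants span about nine
  orders of magnitude); relative tolerance 1e-8, absolute tolerance the
  tissue-unit equivalent of 1e-3 pmol/L. States are floored at zero; any
  excursion below −1e-15 is an error.
* Steady state is declared when every species above a reporting floor changes
  by less than 0.01% (relative) across a one-simulated-hour window — strict
  relative to the fastest half-life in the model (5 min) — with a hard cap of
  50 simulated days; hitting the cap returns a flagged result. With the
  shipped parameters the baseline reaches steady state within the first
  simulated day.
* Depot release: an injected dose enters a depot state that empties into free
  interstitial PF4 with first-order rate 2.8×10⁻⁵ s⁻¹; the depot itself does
  not degrade. Dose additions are solver events.
* Homodimerization (the FGF2 trimer pairing) uses rate k·[T]² with symmetry
  factor 1, the distinct-molecule counting convention of rule-based
  generators; the shipped dimerization constants already absorb this choice.
* Canonicalization prunes permutations by Weisfeiler–Lehman-style partition
  refinement, so pathological same-type chains (used to test the
  polymerization guard) stay tractable; `expand_network()` aborts past
  `max_species` with an "unbounded polymerization" error.
* Calibration tolerance is 5% per aim with at most 15 outer passes.

## The in-silico experiments

`distribution_profile()` classifies every factor-containing species as
surface signaling / surface non-signaling / interstitial unbound /
iHSPG-bound / factor-bound / cleaved-inactive, instance-weighted so each
factor's column closes to 100%. Complexes holding two tracked factors count
toward both factors' factor-bound pools. `angiogenic_ratio()` is the summed
concentration of pro-angiogenic signaling complexes (VEGFR1-, VEGFR2- and
NRP1-bound VEGF — NRP1-bound VEGF counts as signaling — plus FGF2 dimers)
over anti-angiogenic ones (receptor-ligated TSP1 and PF4); a zero denominator
is flagged infinite rather than an error.

`secretion_scan_2d()` sweeps a pro/anti factor pair over 0.01–10× baseline
(default 13 log-spaced points per axis) and normalizes all outputs to the
(1, 1) baseline point. `chspg_pf4_grid()` sweeps cHSPG level
{0.01, 0.1, 0.5, 1, 2, 10} against PF4 secretion, normalizing per cHSPG level
to the 0.01× PF4 point; `biphasic_flag()` tests for the interior maximum of
VEGF signaling along the cHSPG axis. `monte_carlo_secretion()` samples
secretion multipliers log-uniformly over 0.01–10× (the published source
states only a sampling range; log-uniform spreads the probes evenly across
the decades) with a mandatory seed. `pf4_pulse()` releases two 5 mg PF4
depot doses (PF4 modeled at 7.78 kDa) at days 1 and 3.5 into the
steady-state tissue and reports peak free PF4 and per-species fold-changes
(peak-vs-pre-pulse for increases, pre-pulse-vs-trough for decreases), at low
(0.1×), medium (1×) and high (10×) cHSPG.

With the shipped parameterization the qualitative mechanisms of the study
reproduce: VEGF stays predominantly surface-bound and PF4 predominantly
iHSPG-trapped; FGF2 signaling dimers decrease monotonically with PF4
secretion at every cHSPG level; VEGF signaling has an interior maximum along
the cHSPG sweep; and at high cHSPG a PF4 pulse *raises* unbound VEGF and
NRP1-bound VEGF. The quantitative pulse fold-changes of individual VEGF- and
FGF2-axis species are sensitive to the placeholder kinetics and are not all
reproduced (the tests report the measured values); the peak-PF4 magnitude,
which depends only on printed quantities and the documented geometry, is.

## What the tests do and do not show

The property-style suite (expansion fixpoint and permutation invariance,
conservation, per-pair equilibrium against the closed form, production/
degradation and depot closed forms, profile closure, scan normalization,
the biphasic and monotonicity properties, sampler distribution) validates
the machinery independently of the transcribed parameter values. The
baseline-distribution and ratio checks validate the parameterization against
the printed steady-state observations. None of this is evidence about real
tumors beyond what the underlying model family claims: the tissue is
well-mixed (no gradients or transport), receptor totals are static, soluble
HSPG is not modeled, and intracellular signaling is out of scope. Problem
sizes used by the test suite (3×3 scan grids, 6 Monte Carlo samples, a
reduced pulse protocol) are package choices that keep the default run quick;
the full-resolution experiments are one function call away.
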