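---
title: "Modeling HGF/Met signaling with integrin-dependent receptor trafficking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling HGF/Met signaling with integrin-dependent receptor trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgfmet)
```

## The model

`hgfmet` implements a mechanistic ordinary-differential-equation model of
hepatocyte growth factor (HGF) signaling through the Met receptor tyrosine
kinase in liver cells, with an explicit representation of the
alpha5beta1-integrin co-receptor.  The biological hypothesis the model
encodes is that integrin association does not change how Met is activated
by its ligand, but changes how the activated receptor is *trafficked*:

* free Met that binds HGF and autophosphorylates is internalized and
  degraded quickly and recycled poorly;
* integrin-bound Met is internalized and degraded slowly and recycled
  efficiently, so it accumulates signaling-competent phospho-receptor,
  much of it in endosomes.

Downstream, phospho-Met (surface and endosomal pools both count) activates
the adapters Gab1 and Grb2.  Gab1 drives the PI3K -> PIP3 -> PDK1 -> Akt
arm; Grb2 drives the SOS -> Ras -> Raf -> MEK -> ERK -> RSK arm.  All
intracellular proteins interconvert between an inactive and an active
(phosphorylated) form with constant totals, so each protein defines a
conservation group; amounts are molecules per cell, extracellular ligand
and drugs are clamped concentrations in nM, and time is in minutes.

Five regulatory links couple the two arms and are essential for the
model's characteristic behaviors:

1. double-phosphorylated RSK inhibits SOS (negative feedback),
2. phospho-ERK enhances Raf activation (positive feedback),
3. active PDK1 phosphorylates MEK (crosstalk into the ERK arm),
4. phospho-ERK and active Ras both enhance PI3K activation (crosstalk
   into the Akt arm),
5. phospho-Akt suppresses Raf activation ("Akt-side suppression" of the
   ERK arm).

The Ras -> PI3K term deserves a note: a narrative feedback set containing
only links 1-3 and the ERK -> PI3K part of 4 cannot raise steady-state
phospho-Akt when Raf is inhibited, yet that paradoxical response is a
documented behavior of this pathway (release of the RSK -> SOS brake
raises active Ras, which must have somewhere to push).  Routing part of
the PI3K input through Ras is the standard mechanism and is what this
package encodes.

Receptor turnover details that matter for the drug scenarios: basal
surface turnover (synthesis `ksyn_Met`, degradation `kdeg_Met0`) applies
to free and integrin-bound Met alike, with the integrin released when the
receptor is degraded.  Without that, integrin binding would shelter Met
from basal turnover, and the defining invariant of the trafficking
hypothesis — that equalizing the integrin-route trafficking rates with
the free-route rates makes the integrin-knockout scenario
indistinguishable from baseline — would fail.

Four drug mechanisms are built in:

* **AXT050** (integrin-binding mimetic peptide): mass-action binding to
  free surface integrin, depleting the Met-integrin heterodimer.
  Peptide-bound integrin cannot engage Met; pre-formed complexes drain
  through their normal dissociation.
* **Cabozantinib**: first-order binding to Met; bound receptor can
  engage neither HGF nor integrin.  The drug reaches integrin-bound Met
  too, ejecting the integrin on binding — an ATP-competitive kinase
  inhibitor has no reason to be excluded by an extracellular co-receptor
  contact, and a scheme where the heterodimer shields the receptor from
  the drug is also thermodynamically inconsistent (it would let the
  binding cycle do net work).  The shielded variant, tried first, made
  AXT050 *potentiate* cabozantinib by stripping the shield, an artifact
  rather than a prediction.
* **Rilotumumab**: ligand depletion under the excess-antibody
  equilibrium, `HGF_free = HGF_total * Kd / (Kd + dose)`.
* **Sorafenib and the calibration-time node inhibitors** (Met, PDK1,
  MEK, PI3K, ERK): the signal leaving the node is multiplied by
  `1 - strength` (strength-scaled blockade at the calibration dose).
  Sorafenib on Raf additionally carries a saturating dose-occupancy
  factor `dose / (dose + K_inh)`, which is this package's choice for
  making dose-response curves generable from a strength that was
  calibrated at a single dose.

## The reference parameterization is synthetic

No externally calibrated parameter vector is bundled with this package.
The reference parameterization built by `build_reference_model()` is
**synthetic**: the network
topology and structural counts (52 species, 69 parameters, 56 of them
free) follow the published description, protein totals are
order-of-magnitude estimates for hepatocytes (1e4 to 5e5 molecules/cell),
and the rate constants were calibrated by this package's own
pattern-search machinery against the anchor measurements the study
reports in its text:

* ~50% of surface Met internalized 15 min after HGF stimulation,
* ~73% of total phospho-Met in the endosomal pool at 120 min under
  40 ng/ml HGF,
* sorafenib IC50 of ~200 nM for steady-state phospho-ERK,
* the qualitative treatment responses (the MEK-inhibition paradox on
  pMEK; PDK1 inhibition out-cutting MEK inhibition on pAkt; near-complete
  pAkt suppression by receptor-level drugs; sorafenib sparing or raising
  steady-state pAkt; pAkt responding more strongly than pERK to loss of
  the Met-integrin interaction).

The fixed drug constants follow the same anchoring logic: cabozantinib's
Met affinity is set to the reported ~1.3 nM, and the antibody-ligand Kd
for rilotumumab is set to 0.05 nM — within its reported sub-nanomolar
affinity range, and the value at which the top studied dose (10 nM)
reproduces the near-complete steady-state pAkt suppression described for
the antibody.

Quantities that depend on the full 56-dimensional calibrated vector
rather than on these anchors — most notably the exact MuSyC synergy
values of the drug combinations — are *predictions* of this synthetic
parameterization and can differ from the published ones; the acceptance
suite reports both without adjustment.  In practice this
parameterization reproduces the strong potency antagonism of the
AXT050 + cabozantinib pair and the small efficacy-synergy magnitudes
throughout, while the weaker potency interactions (sorafenib and
rilotumumab pairs) come out near zero or mildly positive rather than
mildly negative: those values reflect the curvature of the response
surface around the operating point, which the printed anchors do not
pin down.

Other conventions: 40 ng/ml HGF converts to 0.5 nM using an 80 kDa
molecular weight for mature HGF; "steady state" is operationalized as the
value at 120 min; every simulation starts from the same relaxed basal
state obtained by pre-simulating 1000 unstimulated minutes (cached per
parameterization); drug pre-incubation is simulated piecewise (drug-only
segment, then HGF added at t = 0) rather than with solver events.

## Simulation and numerics

The 52-state system is integrated with `deSolve::lsoda` (rtol 1e-8, atol
1e-6 molecules).  Two derivative implementations exist: a fast hand-coded
path used everywhere, and a generic evaluator that executes the
declarative rate-law expressions through the stoichiometry matrix.  The
test suite holds them to exact agreement, and the generic path is what
imported SBML models use.  SBML import/export is a purpose-built Level-3
subset (xml2-based, MathML restricted to arithmetic operators) because no
SBML library is available to R here; round trips are exact to full
floating-point precision.

```{r counts}
model <- build_reference_model()
model
```

## Calibration

`calibration_objective()` is the summed root-mean-square error between
normalized simulated readouts and normalized observed means across all
datasets/conditions, optionally SD-weighted (default unweighted, since
the study states RMSE only).  Normalization of simulated readouts is by
the maximum over the drug-free control time course (`control_max`),
switchable to per-condition maximum; the published convention is not
printed, so both are implemented.

`pattern_search()` is a generalized pattern search in log10 parameter
space with bound constraints: poll each coordinate at +/- the mesh size,
accept the first improvement in a fixed coordinate order (deterministic
tie-break), double the mesh after a successful sweep, halve after a
failed one, stop at mesh tolerance or evaluation budget.  It never
returns a point worse than its start and is fully deterministic.
Simulation failures inside the objective return a large finite penalty
(1e6) so polling can continue.

`fit_inhibitor_strengths()` freezes the globally calibrated parameters
and fits only node-inhibition strengths to mono-treatment data, which is
how combination-treatment predictions are validated.

## Uncertainty and identifiability

`resample_datasets()` draws log-normal replicates about each observed
mean (median at the mean, sdlog = sqrt(log(1 + cv^2)), cv = 0.10 — the
stated 10% measurement error).  `refit_ensemble()` refits every replicate
by pattern search started at the base fit within +/- one decade.
`confidence_band()` reports pointwise 2.5/50/97.5 percentiles (the
published band is not stated to be simultaneous, so pointwise is
implemented).  `local_sensitivities()` uses central finite differences of
log-output with respect to log-parameter (1% relative step), and
`classify_identifiability()` applies the 95% sign-consistency rule: a
parameter is practically identifiable if, for at least one output, 95% of
its ensemble sensitivity distribution keeps one sign.  Near-zero
sensitivities (|s| < 1e-6) carry no sign, so a parameter with no path to
any output is classified non-identifiable rather than trivially
consistent.

The study ran 201 replicates; the desk-scale default here is 25 (the
vignette-scale experiments in `analysis/03_uncertainty.R` accept the
study-scale count as an argument).  With 25 replicates the 95% parameter
intervals still cover a synthetic truth, which is what the acceptance
suite asserts.

## Global sensitivity

`lhs_sample()` stratifies every parameter into n equal-probability bins
of a uniform +/-50% range around nominal (linear scale, per the study's
wording).  `sensitivity_pipeline()` varies all 56 free parameters plus
the 13 scalable protein abundances, simulates the reference stimulation,
and computes PRCCs at 15 and 120 min.  The PRCC implementation inverts
the joint rank-correlation matrix; an explicit residual-regression route
is kept as the brute-force cross-check and the two agree to 1e-10.
P-values use t = r sqrt((n-2-k)/(1-r^2)) with k = p-1 conditioning
variables; PRCCs with p >= 0.01 are zeroed in reported (filtered) form.
The study scale is n = 5000; desk scale is 300-500, enough for the sign
structure asserted in the tests.

## Synergy

Dose-response effects are readouts normalized to the zero-dose control
(E0 = 1 by construction), evaluated at 15 or 120 min under 40 ng/ml HGF.
`fit_ic50()` fits a 4-parameter Hill curve; the fitted C is the dose of
half-maximal inhibition.  The two-drug surface is

E(d1,d2) = [E0 C1^h1 C2^h2 + E1 d1^h1 C2^h2 + E2 C1^h1 d2^h2 +
E3 alpha2 d1^h1 d2^h2] / [C1^h1 C2^h2 + d1^h1 C2^h2 + C1^h1 d2^h2 +
alpha2 d1^h1 d2^h2],

which reduces to the single-drug Hill curves on the axes; alpha2 scales
the co-occupied state's weight, so log10(alpha2) > 0 is synergistic
potency (the EC50-like analogy), and

beta_obs = (min(E1, E2) - E3) / (E0 - min(E1, E2))

is the efficacy gain of the combination beyond the stronger single agent
(the Emax-like analogy).  Fitting is bounded Levenberg-Marquardt
initialized from the axis Hill fits, deterministic by construction.
Grids are 8x8 log-spaced plus zero anchors; drug 1 is AXT050 by
convention.  On isobolograms: within this surface family the exactly
straight Loewe isobole corresponds to the alpha2 -> 0 (no co-occupancy)
limit, and larger alpha2 bows the contour inward — the test suite asserts
exactly that, rather than the loose folklore that alpha2 = 1 is
"additive".

## Virtual patients

`scale_model()` multiplies protein abundances by 2^(log2 fold change) —
conservation-group totals for intracellular proteins, synthesis rates for
Met and integrin — keeping every rate constant untouched (the stated
mRNA-as-proxy assumption, a known limitation).  `generate_cohort()`
draws per-protein log2 fold changes i.i.d. Normal(mean, sd) per patient;
the defaults (mean 0.15, sd 0.6, n = 50 in the analysis script) emulate
the spread of tumor/normal expression ratios in a 50-pair cohort.  What
synthetic cohorts do **not** emulate: gene-gene correlation structure,
heavy tails, and tumor subtypes — so cohort-level results here
demonstrate the machinery, not patient-level conclusions.  Monotherapy
uses the top of each drug's studied dose range (the study does not print
its monotherapy doses).

## Problem sizes and known limitations

The test and acceptance runs use desk-scale sizes chosen as the smallest
that exercise each method's statistical behavior: 150-300 LHS samples,
25 resampling replicates, 3-parameter recovery problems, 6x6 to 8x8
synergy grids.  The analysis scripts accept study-scale arguments
(n = 5000, 201 replicates, 50 patients).

Known limitations: the reference parameterization is a synthetic
calibration, not the published vector (see above); HGF-independent Met
activation via fibronectin-bound integrin is not modeled; no
pharmacokinetics, spatial structure, or other receptor pathways; the
node-inhibitor dose mapping outside sorafenib is a 0/1 switch at the
calibration dose.
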