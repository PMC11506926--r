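---
title: "Methods: a mechanistic PBPK model of piperine as a CYP3A4 inactivator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanistic PBPK model of piperine as a CYP3A4 inactivator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piperpbpk)
```

## The problem

Piperine, the main pungent alkaloid of black pepper, is consumed daily in
amounts of roughly 5–20 mg and is a time-dependent (mechanism-based)
inactivator of CYP3A4, the enzyme responsible for the oxidative clearance
of more marketed drugs than any other.  A sustained dietary intake of
piperine therefore behaves pharmacologically like a chronic low-dose
perpetrator in a drug–drug interaction: it removes active enzyme faster
than turnover replaces it, and every CYP3A4 substrate taken on top of that
background sees a reduced first-pass extraction and a reduced systemic
clearance.

`piperpbpk` implements the full chain needed to quantify that effect from
bench data: microsomal substrate-depletion kinetics → in vitro intrinsic
clearance → whole-organ clearance by IVIVE → a reduced oral PBPK model of
piperine → CYP3A4 turnover dynamics at liver and gut → victim co-simulation
and AUC/Cmax ratios → fold-error validation against observed clinical
exposure.

## Intrinsic clearance from substrate depletion

A depletion experiment incubates the substrate with human liver microsomes
and samples the remaining percentage at 0, 7, 17, 30 and 60 min.  Under
first-order conditions $\ln(\%\,\mathrm{remaining})$ is linear in time and

$$\mathrm{CL_{int}} \;=\; \frac{1000 \times \text{slope}}{P}
\quad\left[\mu\mathrm{L\,min^{-1}\,mg^{-1}}\right],$$

with $P$ the microsomal protein concentration (mg/mL).  `fit_depletion_slope()`
fits the regression by ordinary least squares, including the 0-min anchor
point (no exclusion rule is justified for a log-linear design), negates the
coefficient so the stored slope is a positive decay rate, and reports
$R^2$.  Replicate incubations are averaged per time point before fitting,
matching the convention of reporting one estimate (± SD) per incubation
condition.

Six condition-level values enter the model input: four in-house conditions
(0.33/0.5 mg/mL protein × 0.1/1 µM substrate) and two literature
determinations.  `pool_clint()` takes their **unweighted arithmetic mean**
(24.2 µL/min/mg protein); no variance weights are available for the
literature values, and the unweighted mean is the only combination
consistent with the printed pooled input.

## Distribution: Rodgers–Rowland method 2

The steady-state volume of distribution is predicted mechanistically from
tissue composition.  For a moderate-to-strong monoprotic base the unbound
tissue:plasma-water partition coefficient is

$$K_{pu} \;=\; f_{EW} \;+\; \frac{X}{Y} f_{IW}
 \;+\; \frac{K_{a,AP}\,[AP]\,10^{\,pK_a - pH_{IW}}}{Y}
 \;+\; \frac{P\,f_{NL} + (0.3P + 0.7)\,f_{NP}}{Y},$$

where $X = 1 + 10^{pK_a - pH_{IW}}$ and $Y = 1 + 10^{pK_a - pH_p}$ are the
ionization ratios at intracellular and plasma pH, $P$ the logP-derived
membrane affinity (vegetable-oil scale for adipose,
$\log P_{vo} = 1.115 \log P - 1.35$), and $K_{a,AP}$ the association
constant of the ionized base to tissue acidic phospholipids.  $K_{a,AP}$ is
back-calculated from erythrocyte partitioning,
$K_{pu,BC} = (B\!/\!P - (1 - Hct)) / (Hct \cdot f_u)$, by subtracting the
water and neutral-lipid components and attributing the remainder to the
acidic-phospholipid term (`ka_ap_from_blood()`).  With piperine's pKa of
12.22 the compound is >99.998% ionized at every relevant pH, so the
acidic-phospholipid term dominates every tissue.

$$V_{ss} = V_{plasma} + f_{u,p} \sum_t V_t\, K_{pu,t},$$

with erythrocytes included through their fractional volume and the
measured $K_{pu,BC}$.  For acids and neutrals the phospholipid term is
replaced in the published method by a tissue-protein association term;
without measured tissue albumin ratios that term is zero here, so those
types reduce to water + neutral-lipid partitioning — exactly the limit the
test suite uses (a water-only compound distributes into ~0.6 L/kg, total
body water).

**Tissue table provenance and the expected bias.**  The bundled
composition table uses the published rat-derived fractional contents
(the standard choice in open implementations — no measured human set
exists) with ICRP-style human fractional volumes and a muscle-like
rest-of-body compartment closing the body volume at ~1 L/kg.  With the
piperine inputs it predicts **0.665 L/kg**, ~20% below the 0.826 L/kg
obtained by the commercial platform from its internal (unpublished) human
composition table.  This magnitude of table-to-table disagreement is
expected for strong bases, whose $V_{ss}$ is nearly proportional to the
muscle acidic-phospholipid concentration; no partition scalar is applied
to compensate (scalar = 1).  The PK simulations use the platform-predicted
0.826 L/kg as their distribution input, as the original analysis did; the
mechanistic prediction is reported alongside for comparison.

## Elimination: IVIVE and the well-stirred liver

$$\mathrm{CL_{int,liver}} = \mathrm{CL_{int,HLM}} \times
\mathrm{MPPGL} \times W_{liver},\qquad
\mathrm{CL_h} = \frac{Q_h\, f_{u,b}\, \mathrm{CL_{int,u}}}
                    {Q_h + f_{u,b}\, \mathrm{CL_{int,u}}},$$

with MPPGL 40 mg/g, liver 1650 g, $Q_h$ 90 L/h and
$f_{u,b} = f_{u,p}/(B\!/\!P)$.  The measured CLint is divided by the
microsomal unbound fraction (fu_mic 0.863) before scaling — standard IVIVE
practice; a switch (`fu_mic_correction = FALSE`) disables it, and both
variants stay within the two-fold validation band.  Liver and kidney are
the only eliminating organs; renal elimination is filtration-only
($f_{u,b} \cdot$ GFR) and defaults to **off** for piperine, for which no
urinary-excretion datum exists.

## The reduced oral PBPK model

The full commercial absorption model (multi-segment dissolution /
precipitation transit) is proprietary in its parameterization.  It is
reduced here to the principal structural simplification of the package:
first-order absorption with $k_a = 2 P_{eff}/R$ (2.11 h⁻¹ from
$P_{eff} = 5.13\times10^{-4}$ cm/s, R = 1.75 cm) and complete release
(fa = 1), feeding an enterocyte compartment drained by the Qgut hybrid
flow.  States per compound:

* gut lumen: $\dot A_{lum} = -k_a A_{lum}$ (+ dose impulses),
* enterocyte: $\dot A_{ent} = k_a A_{lum} - Q_{gut} C_{ent}
  - f_{u,gut}\,\mathrm{CL_{int,gut,u}}\,E_{gut}(t)\, C_{ent}$,
* systemic: volume $V_{ss} \times BW$, receiving
  $F_h(t) \cdot Q_{gut} C_{ent}$ and cleared at
  $Q_h E_h(t)$ on blood concentrations (+ optional renal filtration).

The liver is treated as an instantaneous well-stirred extractor
(quasi-steady-state availability $F_h(t) = 1 - E_h(t)$ recomputed each
step from the active-enzyme-scaled intrinsic clearance) rather than an
explicit compartment; under the perfusion-limited assumption the two are
equivalent at the reporting timescale.  Amounts are in mg, output
concentrations in plasma ng/mL via B/P.  Integration uses `deSolve::lsoda`
(rtol 1e-8, atol 1e-12 mg) on a 0.05 h output grid with doses as exact
state discontinuities; the engine is verified against the Bateman closed
form (pointwise to 0.1%), mass balance (0.1%), superposition and
grid-convergence properties.

Dissolution-rate limitation deserves a comment: piperine's aqueous
solubility is low (0.004 mg/mL), but at a 20 mg dose the validation
against observed exposure remains within two-fold without modeling
precipitation, which is why the reduction is acceptable for this use.

## CYP3A4 inactivation and the interaction model

Mechanism-based inactivation removes active enzyme at
$\lambda = k_{inact} I_u / (K_{app,u} + I_u)$, opposed by resynthesis:

$$\frac{dE}{dt} = k_{deg}(1 - E) - \lambda(I_u(t))\,E, \qquad E(0) = 1,$$

at two sites with independent turnover: liver ($k_{deg}$ 0.0193 h⁻¹,
half-life ≈ 36 h) and gut (0.03 h⁻¹, ≈ 23 h) — widely used turnover values;
the source analysis does not print its own.  $K_{app,u} = K_{app} \times
fu_{mic} = 6.74 \times 0.863$ µM.  Drivers:

* **liver**: unbound blood concentration at the liver inlet,
  $I_u = f_{u,b}(C_b + Q_{gut}C_{ent}/Q_h)$;
* **gut**: the **total** enterocyte concentration (default
  `gut_driver = "total"`).

The gut driver choice is a genuine design decision.  Applying piperine's
very low predicted enterocyte unbound fraction (fu_gut 0.0211) to the
interaction driver makes the cumulative gut inactivation exposure
negligible (since $\int C_{ent}\,dt = \mathrm{dose}/Q_{gut}$ is fixed,
the daily inactivation would be <1% against 72%/day resynthesis), which is
irreconcilable with the strong first-pass component evident in the
interactions this model is meant to reproduce (simvastatin's Cmax ratio
rises almost as much as its AUC ratio).  The total-concentration driver is
also the conservative convention of regulatory static models (fu_gut = 1).
The unbound variant remains available (`gut_driver = "unbound"`) for
sensitivity analysis.

Victims are one-compartment oral models on the same engine: hepatic
CYP3A4-mediated intrinsic clearance scaled by $f_m E_{liver}(t) + (1-f_m)$,
gut intrinsic clearance by $E_{gut}(t)$.  `cosimulate_ddi()` runs victim
alone and victim + 7 days of 20 mg/day piperine, with the victim single
dose given **together with the last piperine dose** (the co-administration
timing is not specified more finely in the source clinical protocols; the
simultaneous choice maximizes comparability across victims) and exposure
read over 168 h from the victim dose in both arms.

The closed-form static oracle
$\mathrm{AUCR} = (F_{g}'/F_g) / (f_m E_{ss} + 1 - f_m)$ provides an
independent cross-check: under a near-constant perpetrator exposure the
dynamic ratio matches it to 1%.

Reversible (competitive) inhibition by piperine is omitted: the
interaction input set contains only time-dependent-inactivation constants.
Piperine auto-inhibition of its own clearance is off by default (its
clearance is not assigned to CYP3A4 in the input set), although the
observed day-7/day-1 accumulation exceeds the linear prediction — a config
flag (`auto_inhibition`) exists for exploring that hypothesis.

## Victim fixture table

The ten victims (carbamazepine 400 mg, clarithromycin 250 mg, midazolam
5 mg, itraconazole 200 mg, ritonavir 100 mg, nifedipine 20 mg,
cyclosporine 200 mg, triazolam 0.25 mg, alfentanil 0.043 mg, simvastatin
40 mg) are parameterized once from standard literature PK constants — fu,
B/P, Vss, plasma clearance, fm(CYP3A4), baseline Fg, ka — because the
commercial platform's built-in compound files are unpublished.  Hepatic
unbound CLint is back-calculated from plasma clearance through the
well-stirred model, gut CLint from baseline Fg through
$F_g = Q_{gut}/(Q_{gut} + \mathrm{CL_{int,gut,u}})$.  Renal components are
folded into the non-CYP3A4 clearance fraction.  Consequences: the
*ordering* of predicted AUC ratios (simvastatin strongest — near-total
CYP3A4 dependence at both sites; carbamazepine weakest — partial fm, no
gut extraction) and the midazolam ratio (~1.2, clinically corroborated)
are robust, deliberately tested properties, while the exact ratios of the
other eight victims depend on unpublished platform files and are not
asserted as point targets.

## Validation

`fold_error()` is predicted/observed; `within_twofold()` applies the
inclusive two-fold acceptance band [0.5, 2.0] conventional in PBPK model
qualification (1.5- and 3-fold bands exist as a config knob).  Display
rounds to one decimal; comparisons never use rounded values.
`validation_report()` evaluates single-dose Cmax and AUC(0–24 h) and
day-7 Cmax against the bundled observed clinical comparators; with the
default inputs all fold-errors are ~0.7–1.0, comfortably inside the band.
The multiple-dose AUC comparator is bundled but not auto-evaluated: its
observation window is not published, so the comparison would be
window-arbitrary.

## Virtual population

Between-subject variability is restricted to what is quantified for this
system: log-normal median-1 multipliers on CYP3A4 abundance (CV 41%,
applied to the CYP3A4-mediated clearance terms at both sites) and
degradation rate (CV 68%), with $\sigma = \sqrt{\ln(1 + CV^2)}$.
Demographic covariates are out of scope.  The 10-trials × 10-subjects
design is reproduced by `run_trials()`; per-subject seeds come from a
counter-based stream (master seed + subject index, default master
20241011) so enlarging a population never reshuffles existing subjects.
Summaries are geometric mean, SEM on the natural scale (no log-scale SEM
convention is stated for the comparator tables) and empirical 5th/95th
percentiles.  Printed SEMs of the commercial population are not
reproduction targets — they depend on its proprietary covariate model.

## Synthetic data

All inputs can be generated with known ground truth: `gen_depletion()`
(exponential depletion, median-1 log-normal proportional noise, zero noise
at t = 0), `gen_observed_profile()` (perturbed-parameter simulation,
proportional noise, clinical-like sparse sampling at 0.5–24 h), and the
victim fixture loader.  Noise is multiplicative log-normal throughout:
concentrations are positive and variability in this field is expressed as
a CV.  Every generator is a pure function of (parameters, seed), and each
stage satisfies a zero-noise round-trip property.

## Numerical choices and problem sizes

Integrator lsoda, rtol 1e-8, atol 1e-12 mg; output grid 0.05 h (NCA
metrics change <0.1% on halving); enterocyte distribution volume 1 L
(results are insensitive: the enterocyte time constant V/Qgut ≈ 4 min is
fast against every other scale); dose events at exact times; negative
state excursions at the integrator tolerance are clamped before entering
the inactivation Michaelis term.  Simulated designs in the test suite and
study report: 24 h single dose, 168 h multiple dose, 312 h DDI co-simulation
per victim arm; population demonstrations use reduced designs (e.g. 4 × 3
subjects at a 0.2 h grid) with the full 10 × 10 design available through
the same interface.

## Known limitations

* First-order absorption with fa = 1 replaces dissolution/transit
  modeling; inappropriate for doses where solubility truly limits
  absorption.
* The mechanistic Vss under-predicts by ~20% against the platform value;
  the bias source (tissue table provenance) is documented, not corrected.
* Victim models are one-compartment with literature constants; exact
  victim AUC ratios other than the tested properties are not claims.
* No transporters, no CYP3A5, no parent–metabolite victim kinetics
  (simvastatin is modeled as the lactone probe), no induction, no
  enterohepatic recirculation.
* Passing tests demonstrate internal consistency and agreement with the
  bundled clinical comparators under these study conditions — not
  predictive accuracy for other doses, formulations or populations.
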