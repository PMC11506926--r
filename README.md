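# piperpbpk

Mechanistic pharmacokinetic modeling of dietary **piperine** (the main
alkaloid of black pepper) as a time-dependent **CYP3A4** inactivator, and
prediction of the resulting food–drug interactions.

Daily pepper consumption delivers roughly 5–20 mg of piperine, which
irreversibly inactivates CYP3A4 — the enzyme clearing midazolam,
simvastatin, cyclosporine and many other drugs.  This package provides an
open, tested implementation of the full modeling chain a DDI scientist
needs to quantify that risk from bench data:

1. **`depletion_clint`** — intrinsic clearance from microsomal
   substrate-depletion time courses:
   `CLint = 1000 × slope / P` with the slope from the OLS regression of
   ln(% remaining) on time; condition-level estimates pooled by
   unweighted mean (`fit_depletion_slope()`, `pool_clint()`).
2. **Rodgers–Rowland method 2** — mechanistic tissue:plasma-water
   partition coefficients and steady-state volume of distribution for an
   ionized base, with the acidic-phospholipid association constant
   back-calculated from blood-cell partitioning (`vss_method2()`).
3. **IVIVE / well-stirred liver** —
   `CLh = Qh·fu_b·CLint_u / (Qh + fu_b·CLint_u)` after scaling by MPPGL
   and liver weight (`whole_liver_clint()`, `well_stirred_clh()`).
4. **Reduced oral PBPK engine** — gut lumen → enterocyte (Qgut first
   pass) → well-stirred liver → systemic compartment sized by Vss, with
   multiple dosing, dense-grid integration (deSolve) and NCA
   (`build_model()`, `simulate_pk()`, `nca()`).
5. **Mechanism-based inactivation** — enzyme turnover
   `dE/dt = kdeg(1−E) − λ(Iu)·E` with `λ = kinact·Iu/(Kapp_u + Iu)` at
   liver and gut, coupled victim co-simulation and AUC/Cmax ratios
   (`cosimulate_ddi()`, `static_auc_ratio()`).
6. **Virtual trials** — log-normal between-subject variability on CYP3A4
   abundance (CV 41%) and turnover (CV 68%), 10 trials × 10 subjects
   (`sample_population()`, `run_trials()`, `summarize_metrics()`).
7. **Validation** — fold-error (predicted/observed) with the inclusive
   two-fold acceptance band \[0.5, 2.0\] (`validation_report()`).

A synthetic-data module (`gen_depletion()`, `gen_observed_profile()`,
`victim_fixtures()`) generates every pipeline input with known ground
truth, so the whole chain is testable offline.

## Worked example

```r
library(piperpbpk)
study <- run_study()
print(study)
```

```
== piperine FDI study ==
pooled CLint      24.2 uL/min/mg
Vss predicted     0.665 L/kg (input 0.826)
<validation_report> band [0.5, 2], pass: TRUE
              metric predicted observed fold_error within_band evaluated
   single_cmax_ng_ml  296.4803      290        1.0        TRUE      TRUE
  single_auc_ng_ml_h 4328.3024     5642        0.8        TRUE      TRUE
 multiple_cmax_ng_ml  410.0010      595        0.7        TRUE      TRUE
victim interaction (sorted by AUC ratio):
         victim dose_mg auc_ratio cmax_ratio flag_1_25
  carbamazepine 400.000      1.07       1.02     FALSE
 clarithromycin 250.000      1.12       1.07     FALSE
      ritonavir 100.000      1.15       1.09     FALSE
   itraconazole 200.000      1.16       1.10     FALSE
     nifedipine  20.000      1.17       1.13     FALSE
      triazolam   0.250      1.21       1.11     FALSE
   cyclosporine 200.000      1.24       1.17     FALSE
     alfentanil   0.043      1.24       1.16     FALSE
      midazolam   5.000      1.25       1.19      TRUE
    simvastatin  40.000      1.38       1.32      TRUE
```

Reading the output: the six pooled in vitro CLint conditions give the
24.2 µL/min/mg elimination input; the mechanistic Vss prediction
(0.665 L/kg) is reported next to the platform-predicted input the
simulations use (0.826 L/kg); simulated 20 mg single-dose Cmax
(296 ng/mL), AUC₀–₂₄ (4328 ng/mL·h) and day-7 Cmax under 20 mg/day
(410 ng/mL) all fall within two-fold of the observed clinical values —
the model-acceptance criterion.  The interaction table shows victim
exposure ratios after seven days of 20 mg/day piperine: midazolam rises
by ~25% (clinical corroboration: ~20% reported for short piperine
pretreatment), simvastatin — near-totally CYP3A4-dependent at both gut
and liver — shows the strongest interaction, and carbamazepine the
weakest.  `flag_1_25` marks ratios at or above the 1.25 regulatory
threshold for a clinical interaction study.

Single pieces are available directly, e.g.:

```r
fit_depletion_slope(gen_depletion(33.2, 0.33))   # CLint round trip
vss_method2(piperine_params())                   # Kpu table + Vss
cosimulate_ddi(piperine_params(), victim_fixtures()$midazolam)
```

See `vignettes/piperine-fdi-methods.Rmd` for the model equations, design
decisions and limitations.

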