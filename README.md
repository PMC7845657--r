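# clopbpk

Whole-body PBPK-PD simulation of clopidogrel bioactivation and its
antiplatelet effect.

Clopidogrel is an antiplatelet prodrug: ~85% of the absorbed dose is
hydrolysed by carboxylesterase 1 (CES1) to an inactive acid, and only a
small fraction is oxidised — via CYP1A2/CYP2B6/CYP2C19 to
2-oxo-clopidogrel and then via CYP2B6/CYP2C9/CYP2C19/CYP3A4 — to the
active thiol metabolite that irreversibly blocks the platelet P2Y12
receptor.  Because CYP2C19 acts in both oxidation steps, its
loss-of-function phenotypes reduce the active-metabolite exposure, and
coronary-artery-disease (CAD) patients — especially those with diabetes
— show clopidogrel resistance.  `clopbpk` is for pharmacometricians and
clinical-pharmacology researchers who want a mechanistic, scriptable
simulator of these effects.

The model couples:

* a 14-organ whole-body circulation of all three species,
  `V_t dC_t/dt = Q_t (C_art − C_t / K_t/b)`, with portal drainage of
  stomach, spleen and five gut-wall segments into the liver;
* a gastric-emptying + five-segment gut-transit absorption chain with
  P-gp efflux, with absorption constants derived from Caco-2
  permeability (`log Peff = 0.4926 log Papp − 0.1454`,
  `Ka = 2 Peff / r`);
* hepatic clearance as linear CES1 hydrolysis competing with saturable
  CYP oxidation, `CL_int,CYP = Σ Vmax·content / (Km·fumic + C_free)`,
  scaled by 55,120 mg of hepatic microsomal protein, cascading 1:1 into
  each metabolite;
* an indirect-response platelet model
  `dM/dt = kin − kout·M − kirre·C_ven,AM·fub·M`, `IPA = (1 − M)·100`,
  with `kout` from the 3.7-day platelet half-life and
  `kirre = 47.576 ml/nmol/h`;
* CYP2C19 phenotype multipliers (UM 1.58 / EM 1 / IM 0.5 / PM 0) and
  population presets for CAD (flows × 0.90, kirre × 0.7) and CAD+DM
  (additionally enzyme multipliers, CES1 × 1.27 and diabetic gut
  transit).

The methods vignette (`vignettes/clopidogrel-pbpk-pd.Rmd`) documents
every convention, parameter and numerical choice.

## Worked example

A 300 mg single dose to a healthy CYP2C19 extensive metabolizer:

```r
library(clopbpk)
mp  <- build_parameters("healthy", "EM")
res <- simulate_pbpk(scenario(300, horizon = 24), mp)
nca_from_sim(res, "AM", c(0, 24))
#> NCA [0, 24] h: Cmax 19.58 at 0.95 h, AUC 49.72
max(ipa_trace(res))          # 55.85  (% inhibition of aggregation)
mass_balance(res)            # 1.75e-15
```

The active metabolite peaks at 19.6 ng/ml about an hour after dosing
and accumulates 49.7 ng·h/ml of exposure over 24 h, driving platelet
inhibition to a peak of ~56%; the mass-balance residual shows the
integration conserves the dose to machine precision.  A poor
metabolizer (CYP2C19 Vmax = 0) retains about half that exposure:

```r
pm <- simulate_pbpk(scenario(300, horizon = 24),
                    build_parameters("healthy", "PM"))
nca_from_sim(pm, "AM", c(0, 24))$auc / nca_from_sim(res, "AM", c(0, 24))$auc
#> 0.499
```

Decomposing why diabetic CAD patients are resistant (600 mg dose, CAD
baseline, each diabetic alteration applied alone):

```r
dm_mimic(600)
#>          factor    auc pct_change
#> 1      baseline  97.45         NA
#> 2         kt_dm 153.59      57.61
#> 3    ces1_x1.27  52.79     -45.83
#> 4 cyp2c19_x0.54  74.29     -23.77
#> 5  cyp3a4_x0.62  86.46     -11.27
#> 6      combined  46.31     -52.48
```

Slower diabetic gut transit raises exposure (+58%), but CES1 induction
(−46%) outweighs the CYP2C19 (−24%) and CYP3A4 (−11%) losses, so the
net diabetic effect is a 52% exposure loss versus CAD alone — CES1,
not CYP2C19, dominates diabetic clopidogrel resistance in this model.

Other entry points: `steady_ipa()` (trough IPA at steady state),
`find_maintenance_dose()` (dose matching a target trough IPA),
`sensitivity_scan()`, `sample_population()` + `vpc_bands()`
(virtual-population percentile bands), and a command-line interface
(`inst/cli/clopbpk` with subcommands `params`, `simulate`, `nca`,
`dosefind`, `sensitivity`, `vpc`).

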