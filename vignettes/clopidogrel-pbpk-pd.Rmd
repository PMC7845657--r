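---
title: "A whole-body PBPK-PD model of clopidogrel bioactivation and platelet inhibition"
author: "clopbpk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body PBPK-PD model of clopidogrel bioactivation and platelet inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clopbpk)
```

## The problem

Clopidogrel (CLOP) is an antiplatelet prodrug.  After an oral dose,
carboxylesterase 1 (CES1) hydrolyses roughly 85% of the absorbed parent
to an inactive acid; the small remainder is oxidised by CYP450s (CYP1A2,
CYP2B6, CYP2C19) to 2-oxo-clopidogrel, which is again split between CES1
hydrolysis and a second oxidation (CYP2B6, CYP2C9, CYP2C19, CYP3A4) to
the active thiol metabolite (CLOP-AM).  CLOP-AM irreversibly blocks the
platelet P2Y12 receptor.  Because CYP2C19 contributes to both oxidation
steps, loss-of-function phenotypes (intermediate and poor metabolizers)
reduce active-metabolite exposure and antiplatelet effect, and patients
with coronary artery disease (CAD) — particularly those with diabetes
(DM) — often show clopidogrel resistance.

`clopbpk` implements a whole-body physiologically-based
pharmacokinetic–pharmacodynamic (PBPK-PD) model of this cascade: all
three species circulate through a 14-organ body, the liver carries the
competing CES1/CYP clearances, and the venous concentration of the
active metabolite drives an indirect-response (turnover) model of
platelet aggregation.  Deterministic subjects are defined by a
population preset (healthy, CAD, CAD+DM) and a CYP2C19 phenotype
(UM/EM/IM/PM).

## Model structure

### Circulation

Each perfusion-limited tissue $t$ obeys

$$V_t \frac{dC_t}{dt} = Q_t \left(C_{art} - \frac{C_t}{K_{t/b}}\right),$$

with tabulated volumes $V_t$ and blood flows $Q_t$.  The venous pool
collects all tissue outflows, passes through the lung at the cardiac
output, and feeds the arterial pool.  Spleen, stomach and the five
gut-wall segments drain into the liver (portal inflow); the liver
drains at the pooled flow $Q_{liv} + Q_{sp} + Q_{st} + \sum_i Q_{gw,i}$.
This topology is implied by the organ/flow table (lung, vein and artery
all carry the cardiac output) and is the standard whole-body assembly.

Two conventions in the source description of the blood partition
coefficient conflict: the prose defines $K_{t/b}$ as the *product* of
the tissue:plasma ratio $K_{t/p}$ and the blood:plasma ratio $R_{bp}$,
while the accompanying formula shows a quotient.  The package adopts
the product, $K_{t/b} = K_{t/p} \times R_{bp}$, and reports venous
blood concentrations directly in mass units.  This pairing was selected
because it is the only one of the candidate conventions under which the
model reproduces the reference predicted exposure values used for
validation (fold errors 0.87–0.92 across the single-dose, multidose and
diabetic endpoints); the quotient-plus-plasma-conversion alternative
overshoots the same endpoints by ~1.5-fold.  Both choices are isolated
behind single functions (`clopbpk:::ktb_matrix()` and
`venous_conc()`), so the alternative convention is a two-line change.

### Absorption

The dose enters the stomach lumen as solution and empties at
$K_{t,0} = 4.8\,h^{-1}$ into a five-segment transit chain (duodenum,
jejunum, ileum, caecum, colon) with transit rates 4.2, 1.8, 2.4, 0.18
and 0.06 $h^{-1}$.  Absorptive segments exchange drug with their gut
wall: uptake at $K_{a,i} = 2 P_{eff}/r_i$ and P-gp-mediated efflux back
into the lumen at fixed $K_{b,i}$ scaled by the gut-wall free fraction
($f_{u,gut} = 0.02$).  Colonic transit is irreversible faecal loss.

$P_{eff}$ comes from the Caco-2 apparent permeability through the
log-linear correlation $\log P_{eff} = 0.4926 \log P_{app} - 0.1454$.
The unit convention — $P_{app}$ in $10^{-6}$ cm/s in, $P_{eff}$ in
$10^{-4}$ cm/s out — is fixed by requiring that $P_{app} = 0.675$
reproduce all three reference absorption constants (0.21, 0.26,
0.29 $h^{-1}$) simultaneously; no other pairing does.  The efflux
constants (0.07, 0.12, 0.16 $h^{-1}$) are shipped as constants rather
than recomputed: the printed directional-permeability identities they
were derived from cannot be reconciled algebraically with the reported
permeability pair, so the stated results are treated as authoritative.
Caecum and colon, for which no radius or transporter scaling factor is
given, are non-absorptive.

### Hepatic elimination and the metabolite cascade

The liver clears each species by linear CES1 hydrolysis (276,650, 2,200
and 529 L/h for parent, 2-oxo and active metabolite) acting on the free
liver concentration $C_{liv} f_{ub} / K_{liv/b}$, and oxidises parent
and 2-oxo by saturable CYP kinetics:

$$CL_{int,CYP} = \sum_{isoforms} \frac{V_{max} \cdot content}
  {K_m f_{u,mic} + C_{liv} f_{ub} / K_{liv/b}},$$

scaled by the total hepatic microsomal protein
$PBSF = 55{,}120$ mg (liver weight × microsomal yield; the packaged
factorisation 1378 g × 40 mg/g is one consistent choice — only the
product is authoritative).  $V_{max}$ (pmol product/min/pmol P450) times
isoform content (pmol P450/mg) converts to nmol/h/mg; with $K_m$ in
nmol/L the per-mg clearance is in L/h/mg.  A useful internal
consistency check: at low concentration this gives a whole-liver CYP
clearance of ≈46,100 L/h for the parent, i.e. CES1 carries ≈85.7% of
the parent's total intrinsic clearance, matching the stated 85% share.
Each oxidation step feeds the next species 1:1 on a molar basis.

CYP2C19 phenotypes scale only $V_{max,CYP2C19}$ (both substrates):
×1.58 (UM), ×1 (EM), ×0.5 (IM), ×0 (PM); affinities are unchanged.

### Platelet pharmacodynamics

Normalised platelet aggregation $M$ follows an indirect-response model
driven by the free venous active metabolite:

$$\frac{dM}{dt} = k_{in} - k_{out} M -
  k_{irre}\, C_{ven,AM}\, f_{ub,AM}\, M, \qquad IPA(\%) = (1 - M)\times 100.$$

$k_{out} = \ln 2 / t_{1/2}$ with the 3.7-day platelet half-life
(0.007804 $h^{-1}$), $k_{in} = k_{out} M_0$ with $M_0 = 1$, and
$k_{irre} = 47.576$ ml/nmol/h (a fixed constant of the model;
`fit_kirre()` provides a generic least-squares re-estimation facility
for user-supplied IPA profiles, but the original estimation input is
not part of the package).  The concentration enters in nmol/ml to match
the unit of $k_{irre}$.  Binding consumes no drug mass, so the PD state
does not feed back on the PK.

### Population presets

* **CAD**: all blood flows scaled by the cardiac-output ratio 0.90;
  platelet responsiveness $k_{irre}$ × 0.7 (reduced ADP response in CAD
  patients).
* **CAD+DM**: the CAD changes (the tabulated diabetic flow column
  equals the CAD column, and the diabetic $k_{irre}$ is assumed equal
  to the CAD value) *plus* hepatic enzyme activity multipliers
  (CYP1A2 1.23, CYP2B6 0.55, CYP2C9 1.26, CYP2C19 0.54, CYP3A4 0.62),
  CES1 × 1.27 for all three species, and diabetic gastrointestinal
  transit (stomach 2.31, duodenum 2.30, jejunum 0.99, ileum 1.32,
  caecum 0.20, colon 0.04 $h^{-1}$, mapped positionally in that order).

Population scaling and phenotype scaling are both multiplicative on
$V_{max,CYP2C19}$, so they commute; the packaged order is population
first, phenotype second.

## Units and reporting

Internally: hours, liters, nanomoles, nmol/L.  Doses in mg convert to
nmol through the parent molecular weight; reported concentrations are
venous blood in ng/ml through each species' molecular weight.  The
molecular weights (321.82, 337.82, 355.82 g/mol for parent, 2-oxo and
active metabolite) are not part of the tabulated parameter record; they
are standard free-base values from the chemistry literature, shipped as
editable fields of the parameter object.

The interpretation of the CES1 value "276,650 1/h" as liters/hour
follows from dimensional consistency with the other two CES1 values
(printed in l/h) and from the 85% clearance-share check above.

## Exposure metrics and endpoint conventions

`nca()` computes Cmax/Tmax from the dense output grid and AUC by linear
trapezoid.  Integration bounds are not part of the source record, so
the package adopts: 0–24 h for single doses, and one 24-h dosing
interval starting at the stated day's dose for maintenance regimens
(e.g. the day-8 value integrates 168–192 h).  The default output grid
(0.05 h) keeps the trapezoid discretisation error below 0.1%.

"Matching the reference subject's effect" in `find_maintenance_dose()`
is operationalised as matching the *trough* (pre-dose) steady-state
IPA: the trough is the clinically conservative index and the only
scalar that is unambiguous for a once-daily regimen.  The finder
bisects on the maintenance dose (trough IPA is monotone in dose) to
0.1 IPA percentage points, with continuous dose granularity.  Default
regimen length is 30 daily doses; `steady_ipa()` flags runs whose
trough still moves more than 0.5 points/day.

## Sensitivity analysis

`sensitivity_scan()` perturbs one group at a time — all transit rates
jointly (including gastric emptying), $V_{max}$ of CYP2C9/CYP2C19/
CYP3A4, CES1 of all species jointly, or $k_{irre}$ — over a default
multiplier grid {0.25, 0.5, 1, 2, 4} (the grid itself is a package
choice; conclusions quoted in the tests use only orderings and the
stated single-factor percentages).  `dm_mimic()` decomposes the
diabetes effect by applying each DM alteration alone to the CAD
baseline (600 mg single dose) and reports percent change of the
active-metabolite AUC; in this model the diabetic transit slowdown
*raises* exposure (+58%), while CES1 ×1.27, CYP2C19 ×0.54 and CYP3A4
×0.62 lower it (−46%, −24%, −11%), and the combined preset lowers it
net — reproducing the finding that clopidogrel resistance under
diabetes is driven more by CES1 induction than by CYP2C19 loss.

## Virtual population

`sample_population()` draws independent lognormal multipliers
(median 1) on the four groups with reported inter-individual
variability: CYP2C19 activity, CES1 clearance, transit rates and
$k_{irre}$.  The underlying variances were estimated in the original
population analysis but not published, so the package defaults to a
30% CV on each group — a typical magnitude for hepatic enzyme
abundance and transit variability — and treats it as a user-settable
assumption, not a calibrated quantity.  `vpc_bands()` returns
pointwise 5/50/95 percentiles of active-metabolite concentration and
IPA.  What this generator emulates is *between-subject* parameter
variability only: no covariate structure (age, weight, sex, CES1
genotype), no within-subject or assay noise, and no model-structure
uncertainty.  Percentile bands should therefore be read as parametric
uncertainty envelopes, not as full predictive distributions for
clinical data.

## Numerical choices

* Stiff integration (`lsoda`) with rtol $10^{-8}$, atol $10^{-10}$
  nmol/L: effective rate constants span ~0.008 to ~800 $h^{-1}$
  (platelet turnover vs. hepatic extraction of the parent).
* Dose events are impulses added to the stomach-lumen state with the
  integrator restarted at each event (initial step $10^{-6}$ h after
  restarts avoids step-size underflow diagnostics).
* The right-hand side exists twice: a C implementation (the default
  engine, ~30 ms per simulated day-long scenario) and a plain-R
  assembly used for inspection and as a cross-check; the test suite
  holds them to agreement and additionally checks the transport-only
  system against a matrix-exponential solution to $10^{-8}$.
* Mass balance (dose = in-system + CES1-hydrolysed + faecal loss) is
  tracked by bookkeeping states and closes at solver precision
  (≲$10^{-12}$ relative in routine runs; the tests require $10^{-6}$).
* Problem sizes used by the tests and the acceptance script: 24-h
  single-dose runs on a 0.05-h grid, steady-state regimens of 30 daily
  doses on a 0.5-h grid, and a 1,000-subject virtual population on a
  0.25-h grid — sizes at which every reported quantity is stable to
  well below its acceptance tolerance.

## Known limitations

* No enterohepatic recirculation, renal elimination, plasma protein
  binding kinetics, or chemical degradation of the active metabolite in
  blood; none of these are part of the source model.
* P-gp efflux is linear (no saturation), and dissolution is not
  modelled (dose enters as solution).
* Multidose accumulation of the *parent* is modest in this
  implementation (≈8% at 75 mg daily); the original validation record
  reports larger multidose parent values that are not mutually
  consistent with its own single-dose kinetics, and multidose parent
  exposure is deliberately not an endpoint here.
* The CES1 activity of special populations is a single scalar
  multiplier; CES1 genetic variants are out of scope.

## A worked run

```{r example, eval = FALSE}
mp  <- build_parameters("healthy", "EM")
res <- simulate_pbpk(scenario(300, horizon = 24), mp)
nca_from_sim(res, "AM", c(0, 24))
max(ipa_trace(res))
mass_balance(res)
```
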