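---
title: "Models and methods: CYP3A inhibition kinetics and genotype-stratified DDI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp3addi)
```

This vignette documents the models implemented in `cyp3addi`, the
assumptions behind them, the tunable parameters and their defaults, and
the numerical and design choices a user should know before trusting the
output.

## The scientific setting

Tacrolimus is cleared by two closely related enzymes, CYP3A4 and CYP3A5,
through two modelled oxidative pathways (13-O-desmethyl and 12-hydroxy
tacrolimus). Per pmol of enzyme, CYP3A5 clears tacrolimus more than
twice as fast as CYP3A4, so carriers of a functional *CYP3A5\*1* allele
("expressers") eliminate the drug substantially faster than \*3/\*3
"non-expressers". Two Wuzhi-capsule lignans, schisantherin A (STA) and
schisandrin A (SIA), inhibit these enzymes by two distinct mechanisms:
instantaneous reversible (competitive) inhibition, characterized by
`Ki`, and time-dependent mechanism-based inactivation, characterized by
`kinact` (maximal inactivation rate) and `K_I` (concentration at
half-maximal rate). The package estimates both kinds of constants from
microsomal assay data and propagates them into a dynamic PBPK model to
predict the genotype-specific change in tacrolimus exposure.

## Reversible-inhibition estimation

The canonical estimator is a global nonlinear least-squares fit of the
competitive model

$$v = \frac{V_{max} S}{K_m (1 + I/K_i) + S}$$

over the full substrate × inhibitor grid (`fit_competitive_ki()`),
using `minpack.lm::nlsLM`. Design choices:

* **Replicates enter individually**, not as cell means, preserving the
  triplicate error structure. An `average_replicates` flag restores the
  averaged path since the original analyses do not state which was used.
* **Only the competitive model is implemented.** The assays this package
  mirrors showed a competitive pattern; mixed and uncompetitive models
  are out of scope, and the Dixon diagnostic would not be meaningful for
  them.
* **The Dixon analysis is a cross-check, not the canonical estimator.**
  `dixon_regression()` fits per-substrate lines of $1/v$ against $I$ and
  estimates `Ki` as the median negated abscissa of all pairwise line
  intersections (under exact competitive kinetics every pair crosses at
  $I = -K_i$). Pairwise-intersection aggregation is not uniquely defined
  in the classical literature; the median is robust to one badly
  determined line. The global fit uses all data under a single
  objective, which is why it is canonical. On noise-free data the two
  agree to numerical precision (tested to 1e-6 relative).
* **"No inhibition" is a first-class outcome.** `detect_inhibition()`
  calls a grid uninhibited when no substrate level shows a significant
  negative velocity trend in inhibitor concentration (two-sided t-test,
  `alpha = 0.05`) *and* the largest mean-velocity reduction at the top
  inhibitor level is below 20%. Both thresholds are package choices — the underlying assays report
  only a qualitative absence of change — and are arguments. With unreplicated cells or a perfect fit the t-test
  degenerates and a flagged slope-sign + reduction heuristic is used.
  `fit_competitive_ki()` runs this classifier first and returns
  `mode = "none"` (no `Ki`) on uninhibited grids — mirroring how a flat
  assay is reported as "no reversible inhibition" rather than as an
  enormous `Ki` with an absurd standard error.
* **CYP3A5 isolation.** Reading assay data (`read_ri_data()`) enforces
  the genotyped-microsome design: CYP3A5 parameters come from \*1/\*3
  microsomes with the selective CYP3A4 inactivator CYP3cide present, and
  CYP3A4 parameters from \*3/\*3 microsomes without it. CYP3cide is
  treated as complete, selective CYP3A4 silencing; residual CYP3A4
  activity is assumed zero since none is reported.

Degenerate Michaelis–Menten designs are flagged instead of silently
fitted: a velocity grid flat in substrate (saturation) reports
`Km` at its zero boundary, and a grid proportional to substrate (far
below `Km`) reports only the identifiable ratio `Vmax/Km`.

## Time-dependent-inactivation estimation

`estimate_kobs()` regresses the **natural logarithm** of
percent-remaining activity on pre-incubation time per inhibitor level;
`kobs` is the negated slope (the 1/min units demand the natural
logarithm). The `t = 0` point is included.
By default activity is first normalized to the inhibitor-free control at
the *matched* pre-incubation time, which cancels inhibitor-independent
activity loss; normalization to each series' own `t = 0`, or none, are
options. Negative estimated rates are clamped to zero; a slope more than
two standard errors above zero triggers a warning, because a
statistically *increasing* activity suggests a data problem rather than
noise around a stable control.

`fit_inactivation()` then estimates the saturation model

$$k_{obs}(I) = \frac{k_{inact}\, I}{K_I + I}$$

canonically by the double-reciprocal (Kitz–Wilson) line — ordinary least
squares of $1/k_{obs}$ on $1/I$, so $k_{inact}$ is the reciprocal
intercept and $K_I$ the slope/intercept ratio — with a direct nonlinear
fit always computed alongside. A non-positive reciprocal intercept means
the data show no saturation and is a fit error by contract. Whether raw
or control-corrected `kobs` feeds the fit is a flag (`use_corrected`,
default off, the conventional uncorrected reading). Note
the saturation form written above is the standard one; a denominator of
$K_I \times I$ sometimes seen in print is dimensionally a constant and
incompatible with a double-reciprocal line, so it is not implemented.

Inactivation efficiency is the unit identity
`efficiency = 1000 · kinact / K_I` (1/min/µM = L/min/µmol →
mL/min/µmol), enforced always.

The two-step dilution protocol (20 µL primary incubation into 180 µL
secondary) is treated as quenching inactivation: no continued
inactivation during the secondary incubation is modelled.

## The PBPK model

The simulator (`simulate_pk()`) is a deliberately minimal whole-body
model — gut lumen, enterocyte, well-stirred liver, central blood,
adipose, lumped rest-of-body — that reproduces the *mechanisms* of the
interaction (first-pass gut + liver CYP3A elimination, Kp-driven
adipose distribution, dual-mechanism inhibition) rather than any
proprietary full-PBPK engine. Published exposure values are therefore
treated as order-of-magnitude anchors (the conventional two-fold
fitness bound), not exact targets.

Key equations and conventions:

* **Hepatic elimination** is well-stirred: metabolic flux
  $= CL_{int,u} \cdot f_{u,b} C_{liver,out}$ with
  $CL_{int,u} = \sum_{iso}\sum_{path} ISEF \cdot V_{max}/K_{m,u} \cdot
  \text{abundance}_{iso} \cdot MPPGL \cdot M_{liver}$, converted to L/h.
  Hepatic abundances are pmol per mg microsomal protein scaled by MPPGL
  (default 40 mg/g) and liver mass (1650 g Caucasian, 1500 g Chinese);
  intestinal abundances are interpreted as nmol of total gut enzyme
  (published abundance tables frequently omit units; these are the
  conventional readings).
* **Gut extraction is first-pass only.** Absorbed drug enters the
  enterocyte, where metabolism competes with villous-blood washout, so
  the fraction escaping is $F_g = Q_{villi}/(Q_{villi} + f_{u,gut}
  CL_{int,gut})$; systemically circulating drug is not re-extracted by
  the gut wall. This matches the Qgut convention; routing systemic blood
  through the enterocyte enzyme pool would add a large artificial
  systemic gut clearance.
* **Elimination is linearized by default** ($CL_{int} = ISEF \cdot
  V_{max}/K_{m,u}$); full saturable Michaelis–Menten elimination is
  available via `elimination = "michaelis_menten"`. At a 2 mg dose
  unbound concentrations sit well below the ~0.2 µM `Km,u`, so the two
  agree (tested at tracer doses).
* **Inhibition driving concentrations** are the unbound liver-outflow
  concentration for hepatic enzymes and the unbound enterocyte
  concentration for gut enzymes — the mechanistic-dynamic convention.
  RI scales each isoform's intrinsic clearance by $1/(1 + I_u/K_i)$;
  TDI evolves the active-enzyme fraction per organ × isoform by
  $dE/dt = k_{deg}(1 - E) - \frac{k_{inact} I_u}{K_I + I_u} E$.
* **Enzyme turnover** defaults: $k_{deg}$ = 0.0193 1/h in liver and
  0.03 1/h in gut (CYP3A half-lives ≈ 36 h and 23 h, the widely used
  values); both are arguments since turnover is not measured here.
* **Whole-blood output.** The model tracks amounts; concentrations are
  converted to ng/mL whole blood via the molecular weight and the
  blood:plasma ratio embedded in the compound definition. Tacrolimus
  partitions extensively into erythrocytes, hence its high default
  B:P of 15 and low plasma `fu` of 0.013.
* **Dosing** is an instantaneous addition of `Fa · dose` to the gut
  lumen at each dose time (no lag); the solver is `deSolve::lsoda` with
  absolute/relative tolerances 1e-9/1e-7 and a default 0.05 h output
  grid. Halving the grid or tightening tolerances moves AUC by well
  under 0.1% (tested).

The victim defaults (`compound_tacrolimus()`) combine the fitted CYP
kinetics with literature-typical disposition constants (fu 0.013,
B:P 15, ka 1/h, Fa 0.94, renal clearance 0) — the CYP table is the
measured input; the rest are documented assumptions, overridable per
call. The adipose partition coefficient defaults to its maximal screened
value, Kp = 1000, which reproduces the long distribution phase;
`kp_sensitivity_scan()` re-simulates over a Kp grid and verifies the
expected monotone peak suppression.

The perpetrator definitions (`compound_sta()`, `compound_sia()`) carry
the microsomal inhibition constants; their absorption/disposition
parameters are **illustrative** values for moderately persistent
dibenzocyclooctadiene lignans, chosen once (fu 0.5, ka 1/h, lumped
hepatic `CLint,u` 20 L/h, modest Kp values), because the originals
reside in an appendix of a prior study that is not reproduced here.
Predicted AUCR magnitudes therefore carry that uncertainty; the
mechanistic *orderings* (combined ≥ each single mechanism; multidose
TDI ≥ single-dose TDI; AUCR = 1 at zero dose) hold regardless and are
what the test suite asserts.

A mechanistic-static closed form
(`static_aucr()`),
$AUCR = 1/\left(\sum_i \frac{fm_i}{RI_i \cdot TDI_i} + (1 - \sum_i fm_i)\right)$
with $RI_i = 1 + I_u/K_i$ and
$TDI_i = 1 + k_{inact} I_u / (k_{deg}(K_I + I_u))$, serves as an
independent oracle: holding the unbound perpetrator exposure constant
and pre-equilibrating the enzyme pools, the dynamic model must agree
with it (tested to 5%; observed agreement is far tighter because the
well-stirred oral AUC is exactly $F_a D / (f_{u,b} CL_{int})$).

## Scenario grid and reporting

`run_scenario_grid()` mirrors the study design: 2 mg victim dose,
Chinese populations for DDI runs (Caucasian presets retained for
baseline verification), perpetrator doses 7.325 mg (STA) and 7.20 mg
(SIA), each under a single co-dose and a 13-day twice-daily regimen, and
three mechanism cases (RI only / TDI only / combined). In the multidose
setting the victim is co-administered with the first perpetrator dose on
day 13 — the victim timing in such designs is rarely reported, so this
choice is explicit and configurable — and victim exposure is always measured from
the victim dose time, with AUC(0–∞) by default (trapezoid plus terminal
log-linear extrapolation over the final 20% of the profile; AUC(0–t) by
flag, since the published integration limits are unstated).

Cells whose active mechanism cannot engage any expressed isoform — SIA
RI-only and combined cells in non-expressers, where SIA has no CYP3A4
`Ki` and the population has no CYP3A5 — are reported as skipped (the
"—" convention) unless `force_all_cells` is set, in which case the
combined cell demonstrably equals the TDI-only cell. Report tables round
half-even to two decimals for display while the JSON keeps full
precision, so the displayed AUCR always equals the ratio of the
displayed AUC columns recomputed at full precision and then rounded — an
internal-consistency property the suite asserts.

## Synthetic data: what it does and does not emulate

The generators produce exactly the data structures the estimators
consume, under the assay designs used throughout: substrate
0.2/0.4/0.8/1.6 µM × inhibitor grids for RI, inhibitor ×
0/5/10/20/30 min grids for TDI, triplicates, multiplicative log-normal
noise (`sigma = sqrt(log(1 + CV^2))`) at 5% CV by default. Log-normal
noise was chosen because the measurements are strictly positive ratios
of chromatographic peak areas; the true error family of the original
LC-MS/MS measurements (calibration-range truncation, heteroscedastic
matrix effects) is *not* emulated. Consequently, passing recovery tests
demonstrate estimator correctness and protocol adequacy under
well-behaved noise — not robustness to real-world analytical artefacts.
`gen_observed_profiles()` adds log-normal inter-individual variability
on fu/ka/CLint and residual sampling noise around the representative
simulation; it approximates virtual-trial percentile bands qualitatively
only, with no covariate model.

## Problem sizes and determinism

Every stochastic routine takes a mandatory seed, and the pipeline is
fully deterministic given config and seed (byte-identical report CSVs on
rerun, tested). The shipped analyses use: 200-replicate Monte-Carlo
ladders for kinetics recovery; 0.05 h output grids with 312 h post-dose
horizons for headline exposure numbers; and coarser 0.1–0.25 h grids
with 96–144 h horizons for property checks, where the assertions concern
orderings and ratios that are insensitive to grid resolution (verified
by the refinement test).

## Known limitations

* The compartment structure is minimal: no transporter kinetics, no
  mechanistic absorption model, no transplant-patient physiology, no
  renal-impairment scaling, and a representative-individual default
  rather than a full virtual population with covariates.
* Perpetrator disposition parameters are illustrative (above), so
  absolute AUCR values are scenario-dependent; cross-study comparison
  should rely on the fitted inhibition constants and the qualitative
  genotype contrasts.
* Whole-extract (multi-component) dosing is out of scope; STA and SIA
  are simulated individually.
* CYP3cide is assumed to silence CYP3A4 completely in \*1/\*3
  microsomes; any residual CYP3A4 activity would bias the CYP3A5
  constants toward CYP3A4's.
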