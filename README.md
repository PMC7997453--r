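# cyp3addi

Genotype-stratified CYP3A inhibition kinetics and PBPK drug–drug
interaction prediction for tacrolimus.

Tacrolimus, the first-line immunosuppressant in organ transplantation, is
cleared almost entirely by CYP3A4 and CYP3A5, and the *CYP3A5* genotype
(expressers carry at least one functional \*1 allele; \*3/\*3
non-expressers have none) is a major determinant of its dose requirement.
Two lignans of the Wuzhi capsule, schisantherin A (STA) and schisandrin A
(SIA), inhibit CYP3A both reversibly and by mechanism-based inactivation,
raising tacrolimus exposure when co-prescribed. `cyp3addi` implements the
full analysis chain for quantifying that interaction per genotype:

1. **Reversible inhibition (RI)** — competitive inhibition constants
   `Ki` estimated from microsomal velocity grids by global nonlinear least
   squares of
   `v = Vmax·S / (Km·(1 + I/Ki) + S)`,
   with the classical Dixon-plot intersection (lines of `1/v` vs `I`
   crossing at `I = −Ki`) as a diagnostic cross-check, and a trend-based
   classifier for assays showing no inhibition at all.
2. **Time-dependent inactivation (TDI)** — per-concentration inactivation
   rates `kobs` from log-linear regression of percent-remaining activity
   against pre-incubation time, then `kinact` and `K_I` from the
   saturation model
   `kobs(I) = kinact·I / (K_I + I)`
   via the double-reciprocal (Kitz–Wilson) line, with a direct nonlinear
   fit alongside; inactivation efficiency is `1000·kinact/K_I`
   (mL/min/µmol).
3. **PBPK simulation** — a minimal whole-body model (gut lumen →
   enterocyte → liver, central blood, Kp-driven adipose depot,
   rest-of-body) with well-stirred hepatic elimination scaled from
   per-pmol CYP kinetics (`CLint,u = Σ ISEF·Vmax/Km,u · abundance ·
   MPPGL · liver mass`), Qgut-style first-pass gut extraction, and
   genotype-specific CYP3A4/5 abundances for virtual Chinese and
   Caucasian expresser / non-expresser populations. A co-dosed
   perpetrator couples to the victim's enzymes through
   `CLint/(1 + Iu/Ki)` (RI) and enzyme turnover
   `dE/dt = kdeg·(1−E) − kinact·Iu/(K_I+Iu)·E` (TDI).
4. **DDI scenarios** — AUC ratios (AUCR = AUC with / AUC alone) across
   perpetrator × regimen (single co-dose, or twice-daily for 13 days) ×
   mechanism case (RI only, TDI only, combined), plus fold-error
   verification (`FE = max(pred/obs, obs/pred)`, acceptable below 2) and
   a mechanistic-static AUCR oracle for cross-checks.
5. **Synthetic data** — seeded generators for velocity grids, activity
   time courses and virtual observed blood profiles with multiplicative
   log-normal noise, so the whole pipeline runs without any external
   download.

## Worked example

Fit an inhibition constant from a (synthetic) triplicate velocity grid on
the tacrolimus × STA assay design, cross-check it with the Dixon
analysis, and predict the DDI:

```r
library(cyp3addi)

d <- gen_ri_dataset(vmax = 10, km = 0.4, ki = 0.15, cv = 0.05, seed = 42)
fit_competitive_ki(d)
#> Reversible-inhibition fit (nonlinear)
#>   mode: competitive; Ki = 0.1499 uM (SE 0.0099)
#>   Vmax = 9.507 pmol/min/mg, Km = 0.3664 uM, R2 = 0.9857
dixon_regression(d)
#> Dixon analysis: Ki = 0.1558 uM (median of 6 intersections)
```

The generating `Ki` of 0.15 µM (the STA–CYP3A4 estimate) is recovered to
within its standard error; the Dixon intersection agrees. The same works
for inactivation kinetics — on noise-free data the recovery is exact:

```r
td <- gen_tdi_dataset(kinact = 0.11, ki_conc = 2.45, cv = 0, seed = 1)
fit_inactivation(estimate_kobs(td))
#> Time-dependent-inactivation fit (double_reciprocal)
#>   kinact = 0.11 1/min, KI = 2.45 uM
#>   efficiency kinact/KI = 44.9 mL/min/umol
```

Simulate 2 mg tacrolimus in a CYP3A5 non-expresser with and without a
single 7.325 mg co-dose of STA (both mechanisms active):

```r
pop <- build_population("chinese", "non_expresser")
alone <- simulate_pk(compound_tacrolimus(), regimen(2), pop, horizon_h = 312)
withp <- simulate_pk(compound_tacrolimus(), regimen(2), pop,
                     perpetrator = compound_sta(),
                     perpetrator_regimen = regimen(7.325),
                     mechanism = "both", horizon_h = 312)
m0 <- compute_metrics(alone); m1 <- compute_metrics(withp)
round(c(auc_alone = m0$auc, auc_with = m1$auc, aucr = aucr(m1$auc, m0$auc)), 2)
#> auc_alone  auc_with      aucr
#>    175.20    403.12      2.30
```

The whole-blood AUC (ng/mL·h) rises 2.30-fold: STA both competes with
tacrolimus at the active site and destroys enzyme that takes days
(t½ ≈ 36 h in liver) to resynthesize. `run_scenario_grid(ddi_config())`
executes the full genotype × perpetrator × regimen × mechanism grid and
`render_report()` writes the result tables; `autoplot()` methods display
profiles, Dixon lines and kobs saturation curves.

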