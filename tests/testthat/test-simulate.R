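test_that("mass is conserved when all elimination is switched off", {
  vic <- compound_tacrolimus()
  prof <- simulate_pk(vic, regimen(2), pop_no_enzyme(),
                      horizon_h = 72, dt = 0.2)
  dosed <- vic$fa * 2 * 1000 / vic$mw
  total <- rowSums(prof[, victim_amount_cols])
  expect_equal(tail(total, 1), dosed, tolerance = 1e-4)
  expect_equal(max(abs(total - dosed)) / dosed, 0, tolerance = 1e-4)
})

test_that("oral AUC matches the closed-form well-stirred value", {
  # no gut metabolism: AUC(0-inf) = Fa * Dose / (fu_b * CLint,u),
  # independent of hepatic flow under the well-stirred model
  pop <- pop_nonexpresser()
  pop$gut_abundance[] <- 0
  vic <- compound_tacrolimus()
  prof <- simulate_pk(vic, regimen(2), pop, horizon_h = 2000, dt = 0.5)
  m <- compute_metrics(prof)
  clint <- hepatic_clint_u(tacrolimus_kinetics(), pop)$clint_l_h
  fu_b <- vic$fu_plasma / vic$bp_ratio
  analytic <- vic$fa * 2000 / (fu_b * clint)   # ng/mL.h for a 2 mg dose
  expect_equal(m$auc, analytic, tolerance = 0.005)
})

test_that("AUC is dose-linear under linear elimination", {
  pop <- pop_nonexpresser()
  aucs <- vapply(c(1, 2, 5), function(d) {
    compute_metrics(simulate_pk(compound_tacrolimus(), regimen(d), pop,
                                horizon_h = 312, dt = 0.2))$auc / d
  }, numeric(1))
  expect_lt(max(abs(aucs / aucs[1] - 1)), 0.001)
})

test_that("non-expressers attain higher victim exposure than expressers", {
  auc_e <- compute_metrics(simulate_pk(compound_tacrolimus(), regimen(2),
                                       pop_expresser(),
                                       horizon_h = 312, dt = 0.2))$auc
  auc_n <- compute_metrics(simulate_pk(compound_tacrolimus(), regimen(2),
                                       pop_nonexpresser(),
                                       horizon_h = 312, dt = 0.2))$auc
  expect_gt(auc_n, auc_e)
})

test_that("a null perpetrator reproduces the victim-alone profile", {
  pop <- pop_nonexpresser()
  vic <- compound_tacrolimus()
  alone <- simulate_pk(vic, regimen(2), pop, horizon_h = 96, dt = 0.2)
  null_p <- simulate_pk(vic, regimen(2), pop,
                        perpetrator = compound_sta(),
                        perpetrator_regimen = regimen(0),
                        mechanism = "both", horizon_h = 96, dt = 0.2)
  expect_equal(null_p$blood_conc_ng_ml, alone$blood_conc_ng_ml,
               tolerance = 1e-9)
  expect_equal(
    compute_metrics(null_p)$auc / compute_metrics(alone)$auc, 1,
    tolerance = 1e-9
  )
})

test_that("solver-grid refinement leaves AUC essentially unchanged", {
  pop <- pop_nonexpresser()
  vic <- compound_tacrolimus()
  a1 <- compute_metrics(simulate_pk(vic, regimen(2), pop, horizon_h = 312,
                                    dt = 0.2))$auc
  a2 <- compute_metrics(simulate_pk(vic, regimen(2), pop, horizon_h = 312,
                                    dt = 0.1, rtol = 1e-8, atol = 1e-10))$auc
  expect_equal(a1, a2, tolerance = 0.001)
})

test_that("active enzyme recovers after perpetrator washout", {
  pop <- pop_nonexpresser()
  prof <- simulate_pk(compound_tacrolimus(), regimen(2), pop,
                      perpetrator = compound_sta(),
                      perpetrator_regimen = regimen(7.325),
                      mechanism = "both", horizon_h = 600, dt = 0.5)
  # inactivation bites first ...
  expect_lt(min(prof$enz_liver_cyp3a4), 0.95)
  # ... and turnover restores the pool once the perpetrator is gone
  expect_gt(tail(prof$enz_liver_cyp3a4, 1), 0.99)
  expect_gt(tail(prof$enz_gut_cyp3a4, 1), 0.99)
})

test_that("constant-exposure dynamic AUCR matches the mechanistic-static oracle", {
  pop <- pop_expresser()
  pop$gut_abundance[] <- 0    # hepatic-only so fm sums to 1
  vic <- compound_tacrolimus()
  sta <- compound_sta()
  shares <- hepatic_clint_u(tacrolimus_kinetics(), pop)$shares
  fm <- setNames(shares$share, shares$isoform)
  base <- compute_metrics(simulate_pk(vic, regimen(2), pop,
                                      horizon_h = 400, dt = 0.2))$auc
  for (mech in c("ri_only", "tdi_only", "both")) {
    prof <- simulate_pk(vic, regimen(2), pop, perpetrator = sta,
                        perpetrator_exposure = list(liver_u = 0.1, gut_u = 0),
                        mechanism = mech, preequilibrate_enzymes = TRUE,
                        horizon_h = 400, dt = 0.2)
    dyn <- compute_metrics(prof)$auc / base
    stat <- static_aucr(fm, 0.1, sta$inhibition, mech)
    expect_equal(dyn, stat, tolerance = 0.05)
  }
})

test_that("static AUCR algebra behaves at its limits", {
  inh <- compound_sta()$inhibition
  expect_equal(static_aucr(c(CYP3A4 = 0.5), 0, inh, "both"), 1)
  expect_equal(static_aucr(c(CYP3A4 = 1), 0.15, inh, "ri_only"), 2,
               tolerance = 1e-12)  # I_u = Ki doubles the RI term
  expect_error(static_aucr(c(CYP3A4 = 0.7, CYP3A5 = 0.5), 0.1, inh), "at most 1")
})

test_that("adipose Kp scan shows volume-driven peak suppression", {
  pop <- pop_nonexpresser()
  scan <- kp_sensitivity_scan(compound_tacrolimus(), regimen(2), pop,
                              kp_values = c(250, 500, 1000),
                              horizon_h = 96, dt = 0.2)
  expect_true(attr(scan, "cmax_monotone_nonincreasing"))
  # duplicated Kp values give identical rows (determinism)
  scan2 <- kp_sensitivity_scan(compound_tacrolimus(), regimen(2), pop,
                               kp_values = c(500, 500),
                               horizon_h = 48, dt = 0.2)
  expect_equal(scan2$auc[1], scan2$auc[2], tolerance = 1e-12)
  expect_equal(scan2$cmax[1], scan2$cmax[2], tolerance = 1e-12)
})

test_that("saturable elimination reduces to the linear model at tracer doses", {
  pop <- pop_nonexpresser()
  vic <- compound_tacrolimus()
  lin <- compute_metrics(simulate_pk(vic, regimen(0.01), pop,
                                     horizon_h = 200, dt = 0.2))$auc / 0.01
  mm <- compute_metrics(simulate_pk(vic, regimen(0.01), pop,
                                    horizon_h = 200, dt = 0.2,
                                    elimination = "michaelis_menten"))$auc / 0.01
  expect_equal(mm, lin, tolerance = 0.02)
  # at higher doses saturation raises dose-normalized exposure
  mm_hi <- compute_metrics(simulate_pk(vic, regimen(20), pop,
                                       horizon_h = 200, dt = 0.2,
                                       elimination = "michaelis_menten"))$auc / 20
  expect_gt(mm_hi, mm)
})
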