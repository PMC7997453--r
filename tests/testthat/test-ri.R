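test_that("Michaelis-Menten fit recovers generating values and flags degeneracy", {
  d <- gen_ri_dataset(10, 0.5, Inf, inhibitor_um = 0, cv = 0, seed = 1)
  f <- fit_michaelis_menten(d)
  expect_equal(f$vmax, 10, tolerance = 1e-6)
  expect_equal(f$km, 0.5, tolerance = 1e-6)
  expect_identical(f$degenerate, "none")

  # saturation limit: identical velocities across substrate push Km to 0
  dsat <- tibble::tibble(substrate_um = rep(c(0.2, 0.4, 0.8, 1.6), 2),
                         velocity = 10)
  fsat <- fit_michaelis_menten(dsat)
  expect_identical(fsat$degenerate, "saturated")

  # linear limit: v proportional to S identifies only Vmax/Km
  dlin <- tibble::tibble(substrate_um = c(0.001, 0.002, 0.004, 0.008),
                         velocity = c(0.001, 0.002, 0.004, 0.008) * 20)
  flin <- fit_michaelis_menten(dlin)
  expect_identical(flin$degenerate, "linear")
  expect_true(is.na(flin$vmax) && is.na(flin$km))
  expect_equal(flin$vmax_over_km, 20, tolerance = 1e-6)

  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate_um = c(1, 2),
                                        velocity = c(1, 2))),
    "3 distinct substrate"
  )
})

test_that("competitive fit recovers Ki exactly on noiseless grids", {
  d <- gen_ri_dataset(10, 0.4, 0.15, cv = 0, seed = 1)
  f <- fit_competitive_ki(d)
  expect_identical(f$mode, "competitive")
  expect_equal(f$ki, 0.15, tolerance = 1e-6)
  expect_equal(f$vmax, 10, tolerance = 1e-6)
  expect_equal(f$km, 0.4, tolerance = 1e-6)
})

test_that("flat grids are classified as showing no reversible inhibition", {
  # effectively infinite Ki
  d <- gen_ri_dataset(10, 0.4, 1e9, cv = 0.05, seed = 2)
  f <- fit_competitive_ki(d)
  expect_identical(f$mode, "none")
  expect_true(is.na(f$ki))

  # zero-noise identical velocities across I
  dz <- gen_ri_dataset(10, 0.4, Inf, cv = 0, seed = 1)
  expect_identical(detect_inhibition(dz)$call, "none")

  # strong effect: Ki far below the inhibitor grid
  ds <- gen_ri_dataset(10, 0.4, 0.1 * 0.125, cv = 0.05, seed = 3)
  expect_identical(detect_inhibition(ds)$call, "inhibited")

  # null-like data at 5% noise (the no-CYP3A4-inhibition pattern)
  dn <- gen_ri_dataset(10, 0.4, Inf, inhibitor_um = c(0, 2.4, 7.2, 12),
                       cv = 0.05, seed = 4)
  expect_identical(detect_inhibition(dn)$call, "none")
})

test_that("single-replicate designs fall back to the flagged slope heuristic", {
  d <- gen_ri_dataset(10, 0.4, 0.15, cv = 0, replicates = 1, seed = 1)
  det <- detect_inhibition(d)
  expect_true(det$degenerate_test)
  expect_identical(det$call, "inhibited")
})

test_that("Dixon intersections coincide at -Ki on noiseless data", {
  d <- gen_ri_dataset(12, 0.3, 0.11, cv = 0, seed = 1)
  dx <- dixon_regression(d)
  used <- dx$intersections[!dx$intersections$excluded, ]
  expect_true(all(abs(used$i_intersect + 0.11) < 1e-9))
  expect_equal(dx$ki, 0.11, tolerance = 1e-9)

  # zero inhibitor effect: all lines flat and parallel -> fit error
  dflat <- gen_ri_dataset(10, 0.4, Inf, cv = 0, seed = 1)
  expect_error(dixon_regression(dflat), "parallel")
})

test_that("nonlinear and Dixon estimators agree on noiseless data", {
  for (ki in c(0.11, 0.5, 2)) {
    d <- gen_ri_dataset(10, 0.4, ki, cv = 0, seed = 1)
    f <- fit_competitive_ki(d)
    dx <- dixon_regression(d)
    expect_equal(f$ki, dx$ki, tolerance = 1e-6)
  }
})

test_that("competitive fit is invariant to row order and velocity rescaling", {
  d <- gen_ri_dataset(10, 0.4, 0.3, cv = 0.05, seed = 9)
  f <- fit_competitive_ki(d)

  set.seed(1)
  dperm <- d[sample(nrow(d)), ]
  fperm <- fit_competitive_ki(dperm)
  expect_equal(fperm$ki, f$ki, tolerance = 1e-6)

  dscale <- dplyr::mutate(d, velocity = velocity * 1000)
  fscale <- fit_competitive_ki(dscale)
  expect_equal(fscale$ki, f$ki, tolerance = 1e-6)
  expect_equal(fscale$vmax, f$vmax * 1000, tolerance = 1e-6)
})

test_that("estimated Ki is monotone in the generating Ki", {
  ladder <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  est <- vapply(ladder, function(ki) {
    fit_competitive_ki(gen_ri_dataset(10, 0.4, ki, cv = 0, seed = 1))$ki
  }, numeric(1))
  expect_false(is.unsorted(est))
})

test_that("an all-zero inhibitor column reduces to the Michaelis-Menten fit", {
  d <- gen_ri_dataset(10, 0.5, Inf, inhibitor_um = 0, cv = 0.03, seed = 6)
  f <- fit_competitive_ki(d)
  mm <- fit_michaelis_menten(d)
  expect_identical(f$mode, "none")
  expect_equal(f$vmax, mm$vmax, tolerance = 1e-10)
  expect_equal(f$km, mm$km, tolerance = 1e-10)
})

test_that("fit objects expose broom-style summaries", {
  d <- gen_ri_dataset(10, 0.4, 0.15, cv = 0.02, seed = 1)
  f <- fit_competitive_ki(d)
  td <- tidy(f)
  expect_identical(td$term, c("ki", "vmax", "km"))
  expect_true(all(td$estimate > 0))
  gl <- glance(f)
  expect_identical(gl$mode, "competitive")
  expect_gt(gl$r.squared, 0.99)
})
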