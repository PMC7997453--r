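test_that("kobs is the negated log-linear slope, exact on exact data", {
  times <- c(0, 5, 10, 20, 30)
  d <- tibble::tibble(
    inhibitor_um = 1, time_min = times, replicate = 1,
    activity_pct = 100 * exp(-0.05 * times)
  )
  ko <- estimate_kobs(d, normalize = "none")
  expect_equal(ko$kobs, 0.05, tolerance = 1e-12)

  # constant activity: kobs = 0
  dc <- dplyr::mutate(d, activity_pct = 100)
  expect_equal(estimate_kobs(dc, normalize = "none")$kobs, 0)
})

test_that("kobs estimation is invariant to activity rescaling and catches bad cells", {
  d <- gen_tdi_dataset(0.08, 1, inhibitor_um = c(0, 1), cv = 0.03, seed = 2)
  k1 <- estimate_kobs(d, normalize = "none")
  k2 <- estimate_kobs(dplyr::mutate(d, activity_pct = activity_pct * 7),
                      normalize = "none")
  expect_equal(k1$kobs, k2$kobs, tolerance = 1e-12)

  dbad <- d
  dbad$activity_pct[5] <- 0
  expect_error(estimate_kobs(dbad), "non-positive activity")
})

test_that("noisy decay recovers the generating kobs within 10%", {
  d <- gen_tdi_dataset(
    kinact = 0.16, ki_conc = 1,   # kobs = 0.08 at I = 1
    inhibitor_um = c(0, 1), cv = 0.03, replicates = 3, seed = 13
  )
  ko <- estimate_kobs(d)
  expect_equal(ko$kobs[ko$inhibitor_um == 1], 0.08, tolerance = 0.1)
})

test_that("control-matched normalization removes inhibitor-independent loss", {
  d <- gen_tdi_dataset(0.11, 2.45, background_kobs = 0.01, cv = 0, seed = 1)
  ko <- estimate_kobs(d, normalize = "control_matched")
  # after normalization the control series is flat and each inhibited
  # series decays at exactly the saturation-model rate
  expect_equal(ko$kobs[ko$inhibitor_um == 0], 0, tolerance = 1e-12)
  i <- ko$inhibitor_um[ko$inhibitor_um > 0]
  expect_equal(ko$kobs[ko$inhibitor_um > 0], 0.11 * i / (2.45 + i),
               tolerance = 1e-9)
})

test_that("inactivation fit inverts exact kobs values to machine precision", {
  for (p in list(c(0.11, 2.45), c(0.019, 2.54), c(0.014, 2.07))) {
    i <- c(0.25, 0.5, 1, 2)
    kobs <- tibble::tibble(inhibitor_um = i,
                           kobs = p[1] * i / (p[2] + i))
    f <- fit_inactivation(kobs)
    expect_equal(f$kinact, p[1], tolerance = 1e-9)
    expect_equal(f$ki_conc, p[2], tolerance = 1e-9)
    # double-reciprocal and nonlinear estimators agree on exact data
    expect_equal(f$double_reciprocal$kinact, f$nonlinear$kinact,
                 tolerance = 1e-9)
    expect_equal(f$double_reciprocal$ki_conc, f$nonlinear$ki_conc,
                 tolerance = 1e-9)
  }
})

test_that("saturation model properties hold", {
  kinact <- 0.11; ki_conc <- 2.45
  kobs_at <- function(i) kinact * i / (ki_conc + i)
  # kobs at I = KI equals kinact/2
  expect_equal(kobs_at(ki_conc), kinact / 2, tolerance = 1e-15)
  # monotone increasing, bounded by kinact
  grid <- c(0.1, 1, 10, 100, 1e4)
  vals <- kobs_at(grid)
  expect_false(is.unsorted(vals))
  expect_true(all(vals < kinact))
  expect_equal(kobs_at(1e9), kinact, tolerance = 1e-6)
})

test_that("round-trip recovery works on arbitrary positive grids", {
  set.seed(42)
  for (rep in 1:5) {
    kinact <- runif(1, 0.01, 0.5)
    ki_conc <- runif(1, 0.5, 20)
    i <- sort(runif(4, 0.1, 30))
    kobs <- tibble::tibble(inhibitor_um = i,
                           kobs = kinact * i / (ki_conc + i))
    f <- fit_inactivation(kobs)
    expect_equal(f$kinact, kinact, tolerance = 1e-6)
    expect_equal(f$ki_conc, ki_conc, tolerance = 1e-6)
  }
})

test_that("no saturation (linear kobs in I) is a fit error", {
  # superlinear kobs growth: the reciprocal plot is convex through the
  # origin, so its least-squares line has a non-positive intercept
  i <- c(0.25, 0.5, 1, 2)
  kobs <- tibble::tibble(inhibitor_um = i, kobs = 0.01 * i^1.3)
  expect_error(fit_inactivation(kobs), "intercept|saturation")
  expect_error(
    fit_inactivation(tibble::tibble(inhibitor_um = c(1, 2), kobs = c(1, 1))),
    "3 positive"
  )
})

test_that("efficiency arithmetic and homogeneity", {
  expect_equal(inactivation_efficiency(0.11, 2.45), 1000 * 0.11 / 2.45)
  c_ <- 3.7
  expect_equal(inactivation_efficiency(c_ * 0.11, c_ * 2.45),
               inactivation_efficiency(0.11, 2.45), tolerance = 1e-12)
  expect_error(inactivation_efficiency(-1, 2), "positive")
})

test_that("end-to-end TDI pipeline recovers kinetics from activity grids", {
  d <- gen_tdi_dataset(0.11, 2.45, cv = 0, seed = 1)
  f <- fit_inactivation(estimate_kobs(d))
  expect_equal(f$kinact, 0.11, tolerance = 1e-6)
  expect_equal(f$ki_conc, 2.45, tolerance = 1e-6)
})
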