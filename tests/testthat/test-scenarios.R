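# a compact configuration used across the pipeline tests: one perpetrator,
# coarse grid, short post-dose horizon (well past Tmax, AUC extrapolated)
small_config <- function(...) {
  ddi_config(
    perpetrators = list(STA = compound_sta()),
    perpetrator_doses_mg = c(STA = 7.325),
    dt = 0.25, horizon_after_victim_h = 144,
    ...
  )
}

test_that("the scenario grid covers all cells with mechanistically ordered AUCRs", {
  res <- run_scenario_grid(small_config())
  expect_s3_class(res, "ddi_results")
  ok <- dplyr::filter(res, status == "ok", perpetrator != "none")
  expect_equal(nrow(ok), 12)   # 2 genotypes x 2 regimens x 3 cases
  expect_true(all(ok$aucr >= 1))

  wide <- tidyr::pivot_wider(ok, id_cols = c("population", "regimen"),
                             names_from = "case", values_from = "aucr")
  # combined inhibition is at least as strong as either mechanism alone
  expect_true(all(wide$both >= pmax(wide$ri_only, wide$tdi_only) - 1e-9))

  # multidose accumulation strengthens time-dependent inhibition
  tdi <- tidyr::pivot_wider(ok[ok$case == "tdi_only", ],
                            id_cols = "population",
                            names_from = "regimen", values_from = "aucr")
  expect_true(all(tdi$multidose >= tdi$single - 1e-9))
})

test_that("degenerate mechanism cells are skipped unless forced", {
  cfg <- ddi_config(
    perpetrators = list(SIA = compound_sia()),
    perpetrator_doses_mg = c(SIA = 7.20),
    genotypes = "non_expresser",
    dt = 0.25, horizon_after_victim_h = 96
  )
  res <- run_scenario_grid(cfg)
  cells <- dplyr::filter(res, perpetrator == "SIA")
  # no CYP3A4 reversible constant and no expressed CYP3A5: only the
  # TDI-only cells are informative
  expect_true(all(cells$status[cells$case != "tdi_only"] == "skipped"))
  expect_true(all(cells$status[cells$case == "tdi_only"] == "ok"))

  forced <- run_scenario_grid(
    ddi_config(perpetrators = list(SIA = compound_sia()),
               perpetrator_doses_mg = c(SIA = 7.20),
               genotypes = "non_expresser", force_all_cells = TRUE,
               dt = 0.25, horizon_after_victim_h = 96)
  )
  expect_true(all(forced$status == "ok"))
  # with RI unable to engage, combined equals TDI-only
  f <- dplyr::filter(forced, perpetrator == "SIA", regimen == "single")
  expect_equal(f$aucr[f$case == "both"], f$aucr[f$case == "tdi_only"],
               tolerance = 1e-6)
  expect_equal(f$aucr[f$case == "ri_only"], 1, tolerance = 1e-6)
})

test_that("a zero perpetrator dose yields AUCR 1 everywhere", {
  cfg <- ddi_config(
    perpetrators = list(STA = compound_sta()),
    perpetrator_doses_mg = c(STA = 0),
    genotypes = "expresser",
    dt = 0.25, horizon_after_victim_h = 96
  )
  res <- run_scenario_grid(cfg)
  ok <- dplyr::filter(res, status == "ok", perpetrator != "none")
  expect_equal(ok$aucr, rep(1, nrow(ok)), tolerance = 1e-8)
})

test_that("report rendering is deterministic and validates its input", {
  res <- run_scenario_grid(small_config(genotypes = "expresser",
                                        cases = "both"))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  render_report(res, dir1)
  render_report(res, dir2)
  h <- function(p) unname(tools::md5sum(p))
  expect_identical(h(file.path(dir1, "table2_like.csv")),
                   h(file.path(dir2, "table2_like.csv")))
  expect_true(file.exists(file.path(dir1, "run.json")))
  expect_true(file.exists(file.path(dir1, "report.md")))
  expect_error(render_report(res[0, ], withr::local_tempdir()), "empty")

  # report AUCR equals aucr() applied to its own printed AUC columns,
  # within the displayed half-even 2 d.p. rounding
  tab <- readr::read_csv(file.path(dir1, "table2_like.csv"),
                         show_col_types = FALSE)
  cell <- dplyr::filter(tab, status == "ok", perpetrator != "none")
  raw <- dplyr::filter(res, status == "ok", perpetrator != "none")
  expect_equal(cell$aucr, round(raw$auc_with / raw$auc_alone, 2),
               tolerance = 1e-9)
})

test_that("displayed rounding is half-even at 2 decimals", {
  expect_equal(cyp3addi:::round2(1.899), 1.90)
  expect_equal(cyp3addi:::round2(1.125), 1.12)  # exact midpoint -> even digit
  expect_equal(cyp3addi:::round2(2.675000001), 2.68)
})

test_that("the baseline dose table computes fold errors when observations exist", {
  obs <- tibble::tibble(
    dose_mg = 2, population = c("expresser", "non_expresser"),
    metric = "auc", observed = c(60.83, 119.02)
  )
  tab <- baseline_dose_table(doses_mg = 2, observed = obs,
                             horizon_h = 144, dt = 0.25)
  auc_rows <- dplyr::filter(tab, metric == "auc")
  expect_true(all(is.finite(auc_rows$fold_error)))
  expect_true(all(auc_rows$fold_error >= 1))
})
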