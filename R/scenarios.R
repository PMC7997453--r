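#' Build a DDI scenario-grid configuration
#'
#' Assembles the full simulation plan mirrored on the study design:
#' victim (2 mg tacrolimus) in Chinese CYP3A5 expresser and non-expresser
#' populations, each perpetrator under a single co-dose and a 13-day
#' twice-daily multidose regimen, across the three inhibition cases
#' (reversible only, time-dependent only, combined). In the multidose
#' setting the perpetrator is dosed BID for 13 days and the victim is
#' co-administered with the first perpetrator dose on day 13; victim
#' exposure is always measured from the victim dose time.
#'
#' @param victim Victim compound (default [compound_tacrolimus()]).
#' @param victim_dose_mg Victim dose, mg.
#' @param perpetrators Named list of perpetrator compounds.
#' @param perpetrator_doses_mg Named numeric vector of per-administration
#'   perpetrator doses, mg (names matching `perpetrators`).
#' @param ethnicity Population ethnicity for the DDI runs.
#' @param genotypes Genotype classes simulated.
#' @param cases Inhibition-mechanism cases.
#' @param multidose_days,multidose_interval_h Duration and interval of
#'   the perpetrator multidose regimen.
#' @param force_all_cells Also run cells whose reversible-inhibition
#'   mechanism cannot engage any expressed isoform (reported as `"-"`
#'   by default, e.g. schisandrin A RI in non-expressers).
#' @param horizon_after_victim_h Simulated time after the victim dose, h.
#' @param dt Output grid step, h.
#' @param auc AUC mode, `"inf"` or `"last"`.
#' @param seed Integer recorded in the run provenance (the pipeline is
#'   deterministic; the seed matters only for synthetic add-ons).
#'
#' @return A list of class `ddi_config`.
#' @export
ddi_config <- function(victim = compound_tacrolimus(),
                       victim_dose_mg = 2,
                       perpetrators = list(STA = compound_sta(),
                                           SIA = compound_sia()),
                       perpetrator_doses_mg = c(STA = 7.325, SIA = 7.20),
                       ethnicity = "chinese",
                       genotypes = c("expresser", "non_expresser"),
                       cases = c("ri_only", "tdi_only", "both"),
                       multidose_days = 13, multidose_interval_h = 12,
                       force_all_cells = FALSE,
                       horizon_after_victim_h = 312,
                       dt = 0.05,
                       auc = "inf",
                       seed = 1L) {
  if (!all(names(perpetrators) %in% names(perpetrator_doses_mg))) {
    abort("every perpetrator needs an entry in `perpetrator_doses_mg`")
  }
  structure(
    list(
      victim = victim, victim_dose_mg = victim_dose_mg,
      perpetrators = perpetrators,
      perpetrator_doses_mg = perpetrator_doses_mg,
      ethnicity = ethnicity, genotypes = genotypes, cases = cases,
      multidose_days = multidose_days,
      multidose_interval_h = multidose_interval_h,
      force_all_cells = force_all_cells,
      horizon_after_victim_h = horizon_after_victim_h,
      dt = dt, auc = auc, seed = as.integer(seed)
    ),
    class = "ddi_config"
  )
}

# a cell is degenerate when the active mechanisms cannot engage any
# expressed isoform (e.g. RI-only for a perpetrator with no reversible
# constant on the only expressed enzyme)
cell_is_degenerate <- function(perp, population, case) {
  if (case == "tdi_only") mechs <- "tdi" else
    if (case == "ri_only") mechs <- "ri" else mechs <- c("ri", "tdi")
  inh <- perp$inhibition
  expressed <- names(population$liver_abundance)[population$liver_abundance > 0]
  engaged <- FALSE
  for (m in mechs) {
    col <- if (m == "ri") "ki" else "kinact"
    ok <- inh$isoform %in% expressed & !is.na(inh[[col]])
    engaged <- engaged || any(ok)
  }
  if (case == "both") {
    # combined duplicates TDI-only when RI cannot engage at all
    ri_ok <- any(inh$isoform %in% expressed & !is.na(inh$ki))
    return(!ri_ok)
  }
  !engaged
}

#' Run the full DDI scenario grid
#'
#' Simulates the victim-alone baseline for each genotype population,
#' then every (perpetrator, regimen, inhibition case) combination, and
#' summarizes each cell as AUC-alone / AUC-with / AUCR plus exposure
#' metrics. Cells whose mechanism cannot engage any expressed isoform
#' are reported with `status = "skipped"` (and no AUCR) unless
#' `force_all_cells` is set in the config. A simulation failure in one
#' cell is recorded (`status = "error"`) and the remaining cells proceed.
#'
#' @param config A `ddi_config`.
#' @return A tibble with one row per scenario cell: `population`,
#'   `perpetrator`, `regimen`, `case`, `auc_alone`, `auc_with`, `aucr`,
#'   `cmax`, `tmax`, `status`. Baseline rows carry
#'   `perpetrator = "none"`. The tibble keeps the config as attribute
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- ddi_config(dt = 0.2, horizon_after_victim_h = 96,
#'                   perpetrators = list(STA = compound_sta()),
#'                   perpetrator_doses_mg = c(STA = 7.325))
#' run_scenario_grid(cfg)
#' }
run_scenario_grid <- function(config) {
  stopifnot(inherits(config, "ddi_config"))
  vreg <- regimen(config$victim_dose_mg)

  rows <- list()
  for (gt in config$genotypes) {
    pop <- build_population(config$ethnicity, gt)
    base_prof <- simulate_pk(
      config$victim, vreg, pop,
      horizon_h = config$horizon_after_victim_h, dt = config$dt
    )
    base_m <- compute_metrics(base_prof, auc = config$auc)
    rows[[length(rows) + 1]] <- tibble::tibble(
      population = gt, perpetrator = "none", regimen = "single",
      case = "none",
      auc_alone = base_m$auc, auc_with = NA_real_, aucr = NA_real_,
      cmax = base_m$cmax, tmax = base_m$tmax, status = "ok"
    )

    for (pname in names(config$perpetrators)) {
      perp <- config$perpetrators[[pname]]
      pdose <- config$perpetrator_doses_mg[[pname]]
      for (reg_kind in c("single", "multidose")) {
        if (reg_kind == "single") {
          preg <- regimen(pdose)
          vreg_k <- regimen(config$victim_dose_mg, start_h = 0)
        } else {
          n <- config$multidose_days * 24 / config$multidose_interval_h
          preg <- regimen(pdose, n_doses = n,
                          interval_h = config$multidose_interval_h)
          # victim co-dosed with the first perpetrator dose on the last day
          vstart <- (config$multidose_days - 1) * 24
          vreg_k <- regimen(config$victim_dose_mg, start_h = vstart)
        }
        for (case in config$cases) {
          degenerate <- cell_is_degenerate(perp, pop, case)
          if (degenerate && !config$force_all_cells) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              population = gt, perpetrator = pname, regimen = reg_kind,
              case = case,
              auc_alone = base_m$auc, auc_with = NA_real_, aucr = NA_real_,
              cmax = NA_real_, tmax = NA_real_, status = "skipped"
            )
            next
          }
          cell <- tryCatch({
            prof <- simulate_pk(
              config$victim, vreg_k, pop,
              perpetrator = perp, perpetrator_regimen = preg,
              mechanism = case,
              horizon_h = max(dose_times(vreg_k)) +
                config$horizon_after_victim_h,
              dt = config$dt
            )
            m <- compute_metrics(prof, auc = config$auc)
            tibble::tibble(
              population = gt, perpetrator = pname, regimen = reg_kind,
              case = case,
              auc_alone = base_m$auc, auc_with = m$auc,
              aucr = aucr(m$auc, base_m$auc),
              cmax = m$cmax, tmax = m$tmax, status = "ok"
            )
          }, error = function(e) {
            tibble::tibble(
              population = gt, perpetrator = pname, regimen = reg_kind,
              case = case,
              auc_alone = base_m$auc, auc_with = NA_real_, aucr = NA_real_,
              cmax = NA_real_, tmax = NA_real_,
              status = paste0("error: ", conditionMessage(e))
            )
          })
          rows[[length(rows) + 1]] <- cell
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("ddi_results", class(out))
  out
}

#' Simulate the dose-ranging victim verification table
#'
#' Victim-alone exposure metrics over a dose grid per genotype, with
#' fold errors against observed values when supplied -- the verification
#' summary preceding any DDI run.
#'
#' @param doses_mg Victim dose grid, mg.
#' @param observed Optional tibble with columns `dose_mg`, `population`,
#'   `metric` (`"auc"`, `"cmax"` or `"tmax"`), `observed`.
#' @param ethnicity,genotypes Population selectors.
#' @param victim Victim compound.
#' @param ... Passed to [simulate_pk()].
#' @return A tibble: `dose_mg`, `population`, `metric`, `predicted`, and
#'   when observed values are supplied `observed` and `fold_error`.
#' @export
baseline_dose_table <- function(doses_mg = c(1, 2, 5),
                                observed = NULL,
                                ethnicity = "chinese",
                                genotypes = c("expresser", "non_expresser"),
                                victim = compound_tacrolimus(), ...) {
  rows <- purrr::map_dfr(genotypes, function(gt) {
    pop <- build_population(ethnicity, gt)
    purrr::map_dfr(doses_mg, function(d) {
      prof <- simulate_pk(victim, regimen(d), pop, ...)
      m <- compute_metrics(prof)
      tibble::tibble(
        dose_mg = d, population = gt,
        metric = c("auc", "cmax", "tmax"),
        predicted = c(m$auc, m$cmax, m$tmax)
      )
    })
  })
  if (!is.null(observed)) {
    check_columns(observed, c("dose_mg", "population", "metric", "observed"),
                  "observed table")
    rows <- dplyr::left_join(rows, observed,
                             by = c("dose_mg", "population", "metric"))
    fe <- rep(NA_real_, nrow(rows))
    ok <- !is.na(rows$observed) & rows$observed > 0 & rows$predicted > 0
    fe[ok] <- fold_error(rows$predicted[ok], rows$observed[ok])
    rows$fold_error <- fe
  }
  rows
}

#' Write scenario results to report files
#'
#' Renders a `ddi_results` table (and optionally a verification table)
#' to CSV, JSON and markdown under `dir`. Displayed values are rounded
#' half-even to 2 decimals; full-precision values are retained in the
#' JSON. Fold-error cells at or above 2 are flagged in the markdown.
#' Skipped (degenerate) cells print as `-`.
#'
#' @param results A `ddi_results` tibble from [run_scenario_grid()].
#' @param dir Output directory (created if needed).
#' @param baseline Optional tibble from [baseline_dose_table()].
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, dir, baseline = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    abort("empty scenario list; nothing to render")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  tab2 <- results |>
    dplyr::mutate(dplyr::across(
      c("auc_alone", "auc_with", "aucr", "cmax", "tmax"),
      ~ round2(.x)
    ))
  p_csv <- file.path(dir, "table2_like.csv")
  readr::write_csv(tab2, p_csv)
  paths <- c(paths, p_csv)

  if (!is.null(baseline)) {
    tab1 <- baseline |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round2(.x)))
    p1 <- file.path(dir, "table1_like.csv")
    readr::write_csv(tab1, p1)
    paths <- c(paths, p1)
  }

  p_json <- file.path(dir, "run.json")
  cfg <- attr(results, "config")
  jsonlite::write_json(
    list(
      seed = cfg$seed %||% NA,
      auc_mode = cfg$auc %||% "inf",
      results = as.data.frame(results),
      baseline = if (!is.null(baseline)) as.data.frame(baseline) else NULL
    ),
    p_json, auto_unbox = TRUE, digits = NA, na = "null"
  )
  paths <- c(paths, p_json)

  p_md <- file.path(dir, "report.md")
  md <- c(
    "# DDI scenario report", "",
    "| population | perpetrator | regimen | case | AUC alone | AUC with | AUCR |",
    "|---|---|---|---|---|---|---|",
    purrr::map_chr(seq_len(nrow(tab2)), function(i) {
      r <- tab2[i, ]
      fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
      sprintf("| %s | %s | %s | %s | %s | %s | %s |",
              r$population, r$perpetrator, r$regimen, r$case,
              fmt(r$auc_alone), fmt(r$auc_with), fmt(r$aucr))
    })
  )
  if (!is.null(baseline) && "fold_error" %in% names(baseline)) {
    flagged <- baseline[!is.na(baseline$fold_error) & baseline$fold_error >= 2, ]
    if (nrow(flagged) > 0) {
      md <- c(md, "", "Fold-error cells at or above 2 (poor fit):",
              sprintf("- %s %g mg %s: FE %.2f", flagged$population,
                      flagged$dose_mg, flagged$metric, flagged$fold_error))
    }
  }
  writeLines(md, p_md)
  paths <- c(paths, p_md)
  invisible(paths)
}
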