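#' Read a reversible-inhibition dataset from CSV (+ YAML sidecar)
#'
#' Long-format CSV with columns `substrate_um`, `inhibitor_um`,
#' `replicate`, `velocity`; an optional YAML sidecar carries the assay
#' design (enzyme target, microsome genotype, CYP3cide concentration,
#' protein concentration, incubation time).
#'
#' @param csv Path to the velocity CSV.
#' @param design Optional path to the YAML design sidecar.
#' @return A tibble of velocities; the parsed design (if any) is
#'   attached as attribute `design`.
#' @export
read_ri_data <- function(csv, design = NULL) {
  d <- readr::read_csv(csv, show_col_types = FALSE)
  check_columns(d, c("substrate_um", "inhibitor_um", "velocity"), csv)
  if (any(d$velocity < 0)) abort("velocities must be non-negative")
  if (!is.null(design)) {
    attr(d, "design") <- validate_ri_design(yaml::read_yaml(design))
  }
  d
}

#' Read a time-dependent-inhibition dataset from CSV (+ YAML sidecar)
#'
#' Long-format CSV with columns `inhibitor_um`, `time_min`, `replicate`,
#' `activity_pct`.
#'
#' @param csv Path to the activity CSV.
#' @param design Optional path to the YAML design sidecar.
#' @return A tibble of activities with optional `design` attribute.
#' @export
read_tdi_data <- function(csv, design = NULL) {
  d <- readr::read_csv(csv, show_col_types = FALSE)
  check_columns(d, c("inhibitor_um", "time_min", "activity_pct"), csv)
  if (!is.null(design)) {
    attr(d, "design") <- yaml::read_yaml(design)
  }
  d
}

# the genotyped-microsome design rules: CYP3A5 activity is isolated in
# *1/*3 microsomes under CYP3cide; CYP3A4 is measured in *3/*3 without it
validate_ri_design <- function(design) {
  target <- design$enzyme_target
  genotype <- design$microsome_genotype
  cyp3cide <- design$cyp3cide_conc %||% 0
  if (!is.null(target)) {
    if (target == "CYP3A5" &&
        (!identical(genotype, "CYP3A5*1/*3") || cyp3cide <= 0)) {
      abort("a CYP3A5 assay requires *1/*3 microsomes with CYP3cide present")
    }
    if (target == "CYP3A4" &&
        (!identical(genotype, "CYP3A5*3/*3") || cyp3cide != 0)) {
      abort("a CYP3A4 assay requires *3/*3 microsomes without CYP3cide")
    }
  }
  design
}

#' Write a fit report as JSON
#'
#' Serializes an `ri_fit` or `tdi_fit` (parameters, standard errors,
#' diagnostics, both estimator variants) to a JSON file for downstream
#' consumption.
#'
#' @param fit An `ri_fit` or `tdi_fit` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  payload <- if (inherits(fit, "ri_fit")) {
    list(
      kind = "reversible_inhibition",
      mode = fit$mode, method = fit$method,
      ki_um = fit$ki, vmax = fit$vmax, km_um = fit$km,
      se = list(ki = fit$ki_se, vmax = fit$vmax_se, km = fit$km_se),
      rss = fit$rss, r_squared = fit$r_squared, n_obs = fit$n_obs
    )
  } else if (inherits(fit, "tdi_fit")) {
    list(
      kind = "time_dependent_inactivation",
      method = fit$method,
      kinact_per_min = fit$kinact, ki_conc_um = fit$ki_conc,
      efficiency_ml_min_umol = fit$efficiency,
      double_reciprocal = fit$double_reciprocal,
      nonlinear = fit$nonlinear,
      kobs = as.data.frame(fit$kobs)
    )
  } else {
    abort("`fit` must be an ri_fit or tdi_fit")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a simulated profile as tidy CSV
#'
#' @param profile A `sim_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(path)
}
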