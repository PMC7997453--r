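#' Simulate a reversible-inhibition velocity grid
#'
#' Generates Michaelis-Menten velocities under competitive inhibition,
#' \eqn{v = V_{max} S / (K_m (1 + I/K_i) + S)}, on a substrate x inhibitor
#' concentration grid with multiplicative log-normal noise. The default
#' grids are the tacrolimus / schisantherin A microsomal assay design
#' (substrate 0.2--1.6 uM, inhibitor 0--0.5 uM, triplicate).
#'
#' @param vmax Maximal velocity, pmol/min/mg protein.
#' @param km Michaelis constant, uM.
#' @param ki Competitive inhibition constant, uM. Use `Inf` for a compound
#'   with no reversible effect (velocities then ignore the inhibitor).
#' @param substrate_um Substrate concentrations, uM (strictly positive,
#'   increasing).
#' @param inhibitor_um Inhibitor concentrations, uM (non-negative, must
#'   include 0, increasing).
#' @param cv Coefficient of variation of the multiplicative observation
#'   noise (0 gives exact model values).
#' @param replicates Number of replicates per grid cell.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return A tibble with columns `substrate_um`, `inhibitor_um`,
#'   `replicate`, `velocity` (pmol/min/mg).
#' @export
#' @examples
#' gen_ri_dataset(vmax = 10, km = 0.4, ki = 0.15, cv = 0, seed = 1)
gen_ri_dataset <- function(vmax, km, ki,
                           substrate_um = c(0.2, 0.4, 0.8, 1.6),
                           inhibitor_um = c(0, 0.125, 0.25, 0.5),
                           cv = 0.05, replicates = 3, seed) {
  check_positive(vmax, "vmax")
  check_positive(km, "km")
  if (!(is.numeric(ki) && length(ki) == 1 && ki > 0)) {
    abort("`ki` must be a single positive number (Inf allowed)")
  }
  validate_ri_grid(substrate_um, inhibitor_um)
  if (cv < 0) abort("`cv` must be non-negative")
  if (missing(seed)) abort("`seed` is mandatory for reproducible generation")
  set.seed(as.integer(seed))

  grid <- tidyr::expand_grid(
    substrate_um = substrate_um,
    inhibitor_um = inhibitor_um,
    replicate = seq_len(replicates)
  )
  inhib_term <- if (is.finite(ki)) 1 + grid$inhibitor_um / ki else 1
  v <- vmax * grid$substrate_um / (km * inhib_term + grid$substrate_um)
  grid$velocity <- v * cv_noise(nrow(grid), cv)
  grid
}

#' Simulate a time-dependent-inactivation activity grid
#'
#' Generates percent-remaining enzyme activity over an inhibitor x
#' pre-incubation-time grid. Activity decays mono-exponentially with the
#' observed inactivation rate \eqn{k_{obs}(I) = k_{inact} I / (K_I + I)};
#' the inhibitor-free control decays at an optional background rate.
#' Default grids are the schisantherin A two-step dilution assay design.
#'
#' @param kinact Maximal inactivation rate, 1/min.
#' @param ki_conc Inhibitor concentration at half-maximal inactivation
#'   (\eqn{K_I}), uM.
#' @param inhibitor_um Inhibitor concentrations, uM (must include 0).
#' @param time_min Pre-incubation times, min (must include 0, increasing).
#' @param background_kobs Inactivation rate of the inhibitor-free control,
#'   1/min (default 0: a stable control).
#' @param cv Coefficient of variation of multiplicative noise.
#' @param replicates Replicates per cell.
#' @param seed Integer seed (mandatory).
#'
#' @return A tibble with columns `inhibitor_um`, `time_min`, `replicate`,
#'   `activity_pct`.
#' @export
#' @examples
#' gen_tdi_dataset(kinact = 0.11, ki_conc = 2.45, cv = 0, seed = 1)
gen_tdi_dataset <- function(kinact, ki_conc,
                            inhibitor_um = c(0, 0.25, 0.5, 1, 2),
                            time_min = c(0, 5, 10, 20, 30),
                            background_kobs = 0,
                            cv = 0.05, replicates = 3, seed) {
  if (kinact < 0) abort("`kinact` must be non-negative")
  check_positive(ki_conc, "ki_conc")
  if (!any(inhibitor_um == 0)) abort("`inhibitor_um` must include 0")
  if (!any(time_min == 0) || is.unsorted(time_min, strictly = TRUE) ||
      any(time_min < 0)) {
    abort("`time_min` must be non-negative, include 0 and be strictly increasing")
  }
  if (missing(seed)) abort("`seed` is mandatory for reproducible generation")
  set.seed(as.integer(seed))

  grid <- tidyr::expand_grid(
    inhibitor_um = inhibitor_um,
    time_min = time_min,
    replicate = seq_len(replicates)
  )
  kobs <- ifelse(grid$inhibitor_um == 0,
                 background_kobs,
                 background_kobs +
                   kinact * grid$inhibitor_um / (ki_conc + grid$inhibitor_um))
  act <- 100 * exp(-kobs * grid$time_min)
  grid$activity_pct <- act * cv_noise(nrow(grid), cv)
  grid
}

#' Simulate virtual "observed" blood concentration profiles
#'
#' Runs the PBPK model for a cohort of virtual subjects whose key
#' disposition parameters (fraction unbound, intrinsic clearance,
#' absorption rate) are perturbed log-normally around the representative
#' individual, then overlays multiplicative residual observation noise.
#' Serves as a stand-in for clinical concentration-time observations when
#' exercising the pipeline end to end.
#'
#' @param victim A compound definition, e.g. [compound_tacrolimus()].
#' @param regimen A dose regimen from [regimen()].
#' @param population A population from [build_population()].
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param iiv_cv Coefficient of variation of the log-normal
#'   inter-individual perturbation applied to `fu_plasma`, `ka` and the
#'   hepatic intrinsic clearance scalar.
#' @param residual_cv Coefficient of variation of the multiplicative
#'   residual observation noise on each sampled concentration.
#' @param sample_times_h Observation time grid, h.
#' @param seed Integer seed (mandatory).
#' @param ... Passed on to [simulate_pk()] (e.g. `dt`, `horizon_h`).
#'
#' @return A list with `subjects` (tibble: `subject`, `time_h`,
#'   `blood_conc_ng_ml`) and `summary` (tibble: `time_h`, `mean`, `p05`,
#'   `p95` across subjects).
#' @export
gen_observed_profiles <- function(victim, regimen, population,
                                  n_subjects = 10, iiv_cv = 0.3,
                                  residual_cv = 0.1,
                                  sample_times_h = c(0.5, 1, 2, 4, 8, 12, 24),
                                  seed, ...) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1")
  if (missing(seed)) abort("`seed` is mandatory for reproducible generation")
  set.seed(as.integer(seed))

  subjects <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    subj <- victim
    subj$fu_plasma <- min(1, victim$fu_plasma * cv_noise(1, iiv_cv))
    subj$ka <- victim$ka * cv_noise(1, iiv_cv)
    subj$clint_scalar <- (victim$clint_scalar %||% 1) * cv_noise(1, iiv_cv)
    prof <- simulate_pk(subj, regimen, population, ...)
    conc <- approx(prof$time_h, prof$blood_conc_ng_ml,
                   xout = sample_times_h, rule = 2)$y
    tibble::tibble(
      subject = i,
      time_h = sample_times_h,
      blood_conc_ng_ml = conc * cv_noise(length(conc), residual_cv)
    )
  })
  summary <- subjects |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      mean = mean(.data$blood_conc_ng_ml),
      p05 = quantile(.data$blood_conc_ng_ml, 0.05, names = FALSE),
      p95 = quantile(.data$blood_conc_ng_ml, 0.95, names = FALSE),
      .groups = "drop"
    )
  list(subjects = subjects, summary = summary)
}

# shared grid validation for RI designs
validate_ri_grid <- function(substrate_um, inhibitor_um) {
  if (any(substrate_um <= 0) || is.unsorted(substrate_um, strictly = TRUE)) {
    abort("`substrate_um` must be strictly positive and strictly increasing")
  }
  if (any(inhibitor_um < 0) || !any(inhibitor_um == 0) ||
      is.unsorted(inhibitor_um, strictly = TRUE)) {
    abort("`inhibitor_um` must be non-negative, include 0 and be strictly increasing")
  }
  invisible(TRUE)
}
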