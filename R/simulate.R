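#' Simulate whole-blood concentration-time profiles
#'
#' Numerically integrates a minimal whole-body PBPK model: gut lumen ->
#' enterocyte -> portal inflow -> well-stirred liver, a central blood
#' compartment, a Kp-driven adipose depot and a lumped rest-of-body
#' compartment. Victim elimination runs through CYP3A4/CYP3A5 in liver
#' (abundance x MPPGL x liver mass scaling) and enterocyte (total gut
#' enzyme scaling) plus optional renal clearance. Enterocyte extraction
#' acts on absorbed drug only, competing with villous-blood washout (the
#' fraction escaping the gut wall is
#' \eqn{F_g = Q_{villi}/(Q_{villi} + fu_{gut} CL_{int,gut})}); systemic
#' drug is not re-extracted by the gut wall. A co-dosed perpetrator
#' is simulated through the same compartment structure and couples to the
#' victim's enzymes by reversible inhibition (intrinsic clearance scaled
#' by \eqn{1/(1 + I_u/K_i)}) and/or mechanism-based inactivation (active
#' enzyme pool \eqn{dE/dt = k_{deg}(E_0 - E) - k_{inact} I_u/(K_I + I_u)
#' E} per organ and isoform), each driven by the unbound local (liver
#' outflow / enterocyte) perpetrator concentration.
#'
#' @param victim Victim `pbpk_compound` (e.g. [compound_tacrolimus()]).
#' @param regimen Victim `dose_regimen`.
#' @param population A `cyp_population` from [build_population()].
#' @param perpetrator Optional perpetrator `pbpk_compound`.
#' @param perpetrator_regimen Regimen for the perpetrator (required when
#'   `perpetrator` is given unless `perpetrator_exposure` is used).
#' @param mechanism Which inhibition mechanisms are active:
#'   `"none"`, `"ri_only"`, `"tdi_only"` or `"both"`.
#' @param perpetrator_exposure Optional list `list(liver_u =, gut_u =)`
#'   holding constant unbound perpetrator concentrations (uM); replaces
#'   the dynamic perpetrator disposition (used for steady-state
#'   cross-checks against the mechanistic-static model).
#' @param horizon_h Simulation end time, h. Defaults to 312 h after the
#'   last victim dose.
#' @param dt Output grid step, h.
#' @param elimination `"linear"` (CLint = ISEF Vmax/Km_u, default) or
#'   `"michaelis_menten"` (saturable, full Vmax/Km form).
#' @param kdeg_liver_h,kdeg_gut_h First-order enzyme degradation rates
#'   (1/h); defaults 0.0193 and 0.03 correspond to hepatic and intestinal
#'   CYP3A turnover half-lives of about 36 h and 23 h.
#' @param preequilibrate_enzymes With `perpetrator_exposure`, start the
#'   enzyme pools at their inhibited steady state rather than at 1.
#' @param rtol,atol Solver relative/absolute tolerances.
#'
#' @return A tibble of class `sim_profile`: `time_h`,
#'   `blood_conc_ng_ml` (victim whole blood), `perp_blood_conc_ng_ml`,
#'   compartment amount columns (umol) and active-enzyme-fraction columns
#'   (`enz_liver_cyp3a4`, ...). Attributes carry the scenario definition
#'   and the victim dose time.
#' @export
#' @examples
#' \donttest{
#' pop <- build_population("chinese", "non_expresser")
#' prof <- simulate_pk(compound_tacrolimus(), regimen(2), pop,
#'                     horizon_h = 96, dt = 0.1)
#' compute_metrics(prof)
#' }
simulate_pk <- function(victim, regimen, population,
                        perpetrator = NULL, perpetrator_regimen = NULL,
                        mechanism = c("none", "ri_only", "tdi_only", "both"),
                        perpetrator_exposure = NULL,
                        horizon_h = NULL, dt = 0.05,
                        elimination = c("linear", "michaelis_menten"),
                        kdeg_liver_h = 0.0193, kdeg_gut_h = 0.03,
                        preequilibrate_enzymes = FALSE,
                        rtol = 1e-7, atol = 1e-9) {
  mechanism <- match.arg(mechanism)
  elimination <- match.arg(elimination)
  stopifnot(inherits(victim, "pbpk_compound"),
            inherits(regimen, "dose_regimen"),
            inherits(population, "cyp_population"))
  if (victim$role != "victim") abort("`victim` must have role 'victim'")
  if (!is.null(perpetrator) && perpetrator$role != "perpetrator") {
    abort("`perpetrator` must have role 'perpetrator'")
  }
  if (!is.null(perpetrator) && is.null(perpetrator_regimen) &&
      is.null(perpetrator_exposure)) {
    abort("a perpetrator needs `perpetrator_regimen` (or `perpetrator_exposure`)")
  }
  phys <- population$physiology
  p <- build_ode_params(victim, population, perpetrator, mechanism,
                        perpetrator_exposure, elimination,
                        kdeg_liver_h, kdeg_gut_h)

  vtimes <- dose_times(regimen)
  horizon_h <- horizon_h %||% (max(vtimes) + 312)
  if (horizon_h <= max(vtimes)) abort("`horizon_h` must extend past the last victim dose")

  events <- tibble::tibble(
    var = "v_lum",
    time = vtimes,
    value = victim$fa * regimen$dose_mg * 1000 / victim$mw,
    method = "add"
  )
  if (!is.null(perpetrator) && !is.null(perpetrator_regimen) &&
      is.null(perpetrator_exposure)) {
    ptimes <- dose_times(perpetrator_regimen)
    events <- dplyr::bind_rows(events, tibble::tibble(
      var = "p_lum",
      time = ptimes,
      value = perpetrator$fa * perpetrator_regimen$dose_mg * 1000 /
        perpetrator$mw,
      method = "add"
    ))
  }
  events <- events |>
    dplyr::filter(.data$value > 0, .data$time <= horizon_h) |>
    dplyr::arrange(.data$time)

  times <- sort(unique(c(seq(0, horizon_h, by = dt), events$time)))
  y0 <- c(
    v_lum = 0, v_ent = 0, v_liv = 0, v_cen = 0, v_adi = 0, v_rob = 0,
    p_lum = 0, p_ent = 0, p_liv = 0, p_cen = 0, p_adi = 0, p_rob = 0,
    e_l4 = 1, e_l5 = 1, e_g4 = 1, e_g5 = 1
  )
  if (preequilibrate_enzymes && !is.null(perpetrator_exposure)) {
    ss <- enzyme_steady_state(p)
    y0[c("e_l4", "e_l5", "e_g4", "e_g5")] <- ss
  }

  # doses falling exactly on the initial time go into the initial state
  at_start <- events$time == times[1]
  if (any(at_start)) {
    for (k in which(at_start)) {
      y0[events$var[k]] <- y0[events$var[k]] + events$value[k]
    }
    events <- events[!at_start, ]
  }

  sol <- deSolve::lsoda(
    y = y0, times = times, func = pbpk_deriv, parms = p,
    events = if (nrow(events) > 0) list(data = as.data.frame(events)) else NULL,
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0("ODE solver failed; final state: ",
                 paste(sprintf("%s=%.3g", colnames(sol)[-1], sol[nrow(sol), -1]),
                       collapse = ", ")))
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_h"
  neg <- min(out$v_cen, out$p_cen)
  if (neg < -1e-6) abort(sprintf("negative state beyond tolerance (%.3g)", neg))

  out <- out |>
    dplyr::mutate(
      blood_conc_ng_ml = pmax(.data$v_cen, 0) / phys$v_blood * victim$mw,
      perp_blood_conc_ng_ml = if (!is.null(perpetrator)) {
        pmax(.data$p_cen, 0) / phys$v_blood * perpetrator$mw
      } else {
        0
      }
    ) |>
    dplyr::rename(
      enz_liver_cyp3a4 = "e_l4", enz_liver_cyp3a5 = "e_l5",
      enz_gut_cyp3a4 = "e_g4", enz_gut_cyp3a5 = "e_g5"
    ) |>
    dplyr::relocate("time_h", "blood_conc_ng_ml", "perp_blood_conc_ng_ml")

  structure(
    out,
    class = c("sim_profile", class(out)),
    victim = victim$name,
    perpetrator = if (!is.null(perpetrator)) perpetrator$name else NULL,
    mechanism = mechanism,
    population = paste(population$ethnicity, population$genotype_class),
    victim_dose_time = min(vtimes),
    dose_mg = regimen$dose_mg,
    v_blood = phys$v_blood
  )
}

# assemble the parameter closure consumed by pbpk_deriv()
build_ode_params <- function(victim, population, perpetrator, mechanism,
                             perpetrator_exposure, elimination,
                             kdeg_liver_h, kdeg_gut_h) {
  phys <- population$physiology
  iso <- c("CYP3A4", "CYP3A5")

  scale_victim <- function(kin, organ_scale) {
    # per-pathway Vmax in umol/h at full abundance; linear CLint follows
    kin |>
      dplyr::mutate(
        vmax_umol_h = .data$isef * .data$vmax * organ_scale[.data$isoform] *
          60 / 1e6 * victim$clint_scalar / victim$fu_mic
      )
  }
  liver_scale <- setNames(
    population$liver_abundance[iso] * phys$mppgl * phys$liver_mass_g, iso
  )
  gut_scale <- setNames(population$gut_abundance[iso] * 1000, iso)
  kin_liv <- scale_victim(victim$enzyme_kinetics, liver_scale)
  kin_gut <- scale_victim(victim$enzyme_kinetics, gut_scale)
  lin_cl <- function(kin) {
    v <- vapply(iso, function(z) {
      k <- kin[kin$isoform == z, ]
      sum(k$vmax_umol_h / k$km_u)
    }, numeric(1))
    setNames(v, iso)
  }

  inh <- perpetrator$inhibition
  get_inh <- function(col) {
    v <- setNames(rep(NA_real_, 2), iso)
    if (!is.null(inh)) {
      m <- match(inh$isoform, iso)
      v[m[!is.na(m)]] <- inh[[col]][!is.na(m)]
    }
    v
  }
  ki <- get_inh("ki")
  ki[is.na(ki)] <- Inf
  kinact_h <- get_inh("kinact") * 60   # 1/min -> 1/h
  kinact_h[is.na(kinact_h)] <- 0
  ki_conc <- get_inh("ki_conc")
  ki_conc[is.na(ki_conc)] <- Inf
  if (!is.null(perpetrator) && !is.null(perpetrator$fu_mic) &&
      perpetrator$fu_mic != 1) {
    # microsomal-binding correction of assay-derived constants
    ki <- ki * perpetrator$fu_mic
    ki_conc <- ki_conc * perpetrator$fu_mic
  }

  list(
    phys = phys,
    elimination = elimination,
    v = list(
      ka = victim$ka,
      fu_b = victim$fu_plasma / victim$bp_ratio,
      fu_gut = victim$fu_gut,
      kpb_liv = victim$kp$liver / victim$bp_ratio,
      kpb_adi = victim$kp$adipose / victim$bp_ratio,
      kpb_rob = victim$kp$rest / victim$bp_ratio,
      renal = victim$renal_cl_l_h,
      cl_liv = lin_cl(kin_liv),
      cl_gut = lin_cl(kin_gut),
      kin_liv = kin_liv, kin_gut = kin_gut
    ),
    p = if (!is.null(perpetrator)) list(
      ka = perpetrator$ka,
      fu_b = perpetrator$fu_plasma / perpetrator$bp_ratio,
      fu_gut = perpetrator$fu_gut,
      kpb_liv = perpetrator$kp$liver / perpetrator$bp_ratio,
      kpb_adi = perpetrator$kp$adipose / perpetrator$bp_ratio,
      kpb_rob = perpetrator$kp$rest / perpetrator$bp_ratio,
      renal = perpetrator$renal_cl_l_h,
      clint_hep = perpetrator$clint_hepatic_l_h,
      clint_gut = perpetrator$clint_gut_l_h
    ) else NULL,
    ri_on = mechanism %in% c("ri_only", "both"),
    tdi_on = mechanism %in% c("tdi_only", "both"),
    ki = ki, kinact_h = kinact_h, ki_conc = ki_conc,
    kdeg_liver = kdeg_liver_h, kdeg_gut = kdeg_gut_h,
    const_exposure = perpetrator_exposure
  )
}

# inhibited steady-state enzyme fractions under constant exposure
enzyme_steady_state <- function(p) {
  iu_l <- p$const_exposure$liver_u %||% 0
  iu_g <- p$const_exposure$gut_u %||% 0
  lam <- function(iu) if (p$tdi_on) p$kinact_h * iu / (p$ki_conc + iu) else c(0, 0)
  ll <- lam(iu_l); lg <- lam(iu_g)
  c(
    p$kdeg_liver / (p$kdeg_liver + ll),
    p$kdeg_gut / (p$kdeg_gut + lg)
  )
}

pbpk_deriv <- function(t, y, p) {
  phys <- p$phys
  v <- p$v

  # --- perpetrator disposition and local unbound concentrations
  if (!is.null(p$const_exposure)) {
    iu_liv <- p$const_exposure$liver_u %||% 0
    iu_gut <- p$const_exposure$gut_u %||% 0
    dp <- rep(0, 6)
  } else if (!is.null(p$p)) {
    pp <- p$p
    c_cen <- y["p_cen"] / phys$v_blood
    c_ent <- y["p_ent"] / phys$v_enterocyte
    c_liv <- y["p_liv"] / (phys$v_liver * pp$kpb_liv)
    c_adi <- y["p_adi"] / (phys$v_adipose * pp$kpb_adi)
    c_rob <- y["p_rob"] / (phys$v_rest * pp$kpb_rob)
    cu_liv <- pp$fu_b * c_liv
    cu_ent <- pp$fu_gut * c_ent
    met_liv <- pp$clint_hep * cu_liv
    met_gut <- pp$clint_gut * cu_ent
    dp <- c(
      -pp$ka * y["p_lum"],
      pp$ka * y["p_lum"] - phys$q_villous * c_ent - met_gut,
      phys$q_villous * c_ent + phys$q_hepatic * c_cen -
        phys$q_hepatic * c_liv - met_liv,
      phys$q_hepatic * c_liv + phys$q_adipose * c_adi + phys$q_rest * c_rob -
        (phys$q_hepatic + phys$q_adipose + phys$q_rest) * c_cen -
        pp$renal * c_cen,
      phys$q_adipose * (c_cen - c_adi),
      phys$q_rest * (c_cen - c_rob)
    )
    iu_liv <- cu_liv
    iu_gut <- cu_ent
  } else {
    iu_liv <- 0
    iu_gut <- 0
    dp <- rep(0, 6)
  }

  # --- enzyme turnover with mechanism-based inactivation
  e <- y[c("e_l4", "e_l5", "e_g4", "e_g5")]
  if (p$tdi_on) {
    lam_l <- p$kinact_h * iu_liv / (p$ki_conc + iu_liv)
    lam_g <- p$kinact_h * iu_gut / (p$ki_conc + iu_gut)
  } else {
    lam_l <- c(0, 0)
    lam_g <- c(0, 0)
  }
  de <- c(
    p$kdeg_liver * (1 - e[1:2]) - lam_l * e[1:2],
    p$kdeg_gut * (1 - e[3:4]) - lam_g * e[3:4]
  )

  # --- reversible-inhibition scaling of victim intrinsic clearance
  if (p$ri_on) {
    ri_l <- 1 + iu_liv / p$ki
    ri_g <- 1 + iu_gut / p$ki
  } else {
    ri_l <- c(1, 1)
    ri_g <- c(1, 1)
  }

  # --- victim disposition
  c_cen <- y["v_cen"] / phys$v_blood
  c_ent <- y["v_ent"] / phys$v_enterocyte
  c_liv <- y["v_liv"] / (phys$v_liver * v$kpb_liv)
  c_adi <- y["v_adi"] / (phys$v_adipose * v$kpb_adi)
  c_rob <- y["v_rob"] / (phys$v_rest * v$kpb_rob)
  cu_liv <- v$fu_b * c_liv
  cu_ent <- v$fu_gut * c_ent

  if (p$elimination == "linear") {
    met_liv <- sum(e[1:2] / ri_l * v$cl_liv) * cu_liv
    met_gut <- sum(e[3:4] / ri_g * v$cl_gut) * cu_ent
  } else {
    mm_rate <- function(kin, efrac, ri, cu) {
      iso <- c("CYP3A4", "CYP3A5")
      sum(vapply(seq_along(iso), function(j) {
        k <- kin[kin$isoform == iso[j], ]
        efrac[j] * sum(k$vmax_umol_h * cu / (k$km_u * ri[j] + cu))
      }, numeric(1)))
    }
    met_liv <- mm_rate(v$kin_liv, e[1:2], ri_l, cu_liv)
    met_gut <- mm_rate(v$kin_gut, e[3:4], ri_g, cu_ent)
  }

  dv <- c(
    -v$ka * y["v_lum"],
    v$ka * y["v_lum"] - phys$q_villous * c_ent - met_gut,
    phys$q_villous * c_ent + phys$q_hepatic * c_cen -
      phys$q_hepatic * c_liv - met_liv,
    phys$q_hepatic * c_liv + phys$q_adipose * c_adi + phys$q_rest * c_rob -
      (phys$q_hepatic + phys$q_adipose + phys$q_rest) * c_cen -
      v$renal * c_cen,
    phys$q_adipose * (c_cen - c_adi),
    phys$q_rest * (c_cen - c_rob)
  )

  list(c(dv[1], dv[2], dv[3], dv[4], dv[5], dv[6],
         dp[1], dp[2], dp[3], dp[4], dp[5], dp[6],
         de))
}

#' Mechanistic-static AUC-ratio oracle
#'
#' Closed-form AUC ratio under constant unbound inhibitor exposure:
#' \deqn{AUCR = \frac{1}{\sum_i fm_i / (RI_i \cdot TDI_i) + (1 - \sum_i fm_i)}}
#' with \eqn{RI_i = 1 + I_u/K_i} and
#' \eqn{TDI_i = 1 + k_{inact} I_u / (k_{deg} (K_I + I_u))}. Serves as an
#' independent steady-state cross-check of the dynamic model.
#'
#' @param fm Named numeric vector of fractions metabolized per isoform
#'   (sum <= 1; the remainder is uninhibited clearance).
#' @param inhibitor_u Constant unbound inhibitor concentration, uM.
#' @param inhibition Inhibition tibble (`isoform`, `ki`, `kinact` 1/min,
#'   `ki_conc`), e.g. `compound_sta()$inhibition`.
#' @param mechanism As in [simulate_pk()].
#' @param kdeg_h Enzyme degradation rate, 1/h.
#'
#' @return The dimensionless AUC ratio.
#' @export
#' @examples
#' static_aucr(c(CYP3A4 = 1), 0.1, compound_sta()$inhibition, "ri_only")
static_aucr <- function(fm, inhibitor_u, inhibition,
                        mechanism = c("both", "ri_only", "tdi_only", "none"),
                        kdeg_h = 0.0193) {
  mechanism <- match.arg(mechanism)
  if (sum(fm) > 1 + 1e-9) abort("`fm` must sum to at most 1")
  validate_inhibition(inhibition)
  ri_on <- mechanism %in% c("ri_only", "both")
  tdi_on <- mechanism %in% c("tdi_only", "both")
  terms <- vapply(names(fm), function(z) {
    row <- inhibition[inhibition$isoform == z, ]
    ki <- if (nrow(row) == 1 && !is.na(row$ki)) row$ki else Inf
    kinact_h <- if (nrow(row) == 1 && !is.na(row$kinact)) row$kinact * 60 else 0
    ki_conc <- if (nrow(row) == 1 && !is.na(row$ki_conc)) row$ki_conc else Inf
    ri <- if (ri_on) 1 + inhibitor_u / ki else 1
    tdi <- if (tdi_on) {
      1 + kinact_h * inhibitor_u / (kdeg_h * (ki_conc + inhibitor_u))
    } else {
      1
    }
    fm[z] / (ri * tdi)
  }, numeric(1))
  1 / (sum(terms) + (1 - sum(fm)))
}

#' Adipose partition-coefficient sensitivity scan
#'
#' Re-simulates the victim baseline for each candidate adipose Kp value,
#' all else fixed, and reports exposure metrics with simple monotonicity
#' diagnostics (a larger distribution volume should not raise the peak).
#'
#' @param victim Victim compound.
#' @param regimen Victim regimen.
#' @param population Population.
#' @param kp_values Positive adipose Kp candidates.
#' @param ... Passed to [simulate_pk()] (e.g. `horizon_h`, `dt`).
#'
#' @return A tibble (`kp_adipose`, `auc`, `cmax`, `tmax`) with attributes
#'   `cmax_monotone_nonincreasing` and `auc_monotone`.
#' @export
kp_sensitivity_scan <- function(victim, regimen, population, kp_values, ...) {
  if (any(kp_values <= 0)) abort("`kp_values` must be positive")
  rows <- purrr::map_dfr(kp_values, function(kp) {
    vic <- victim
    vic$kp$adipose <- kp
    prof <- simulate_pk(vic, regimen, population, ...)
    m <- compute_metrics(prof)
    tibble::tibble(kp_adipose = kp, auc = m$auc, cmax = m$cmax, tmax = m$tmax)
  })
  ord <- order(rows$kp_adipose)
  structure(
    rows,
    cmax_monotone_nonincreasing = !is.unsorted(-rows$cmax[ord]),
    auc_monotone = !is.unsorted(rows$auc[ord]) || !is.unsorted(-rows$auc[ord])
  )
}
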