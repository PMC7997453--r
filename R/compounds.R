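#' Define a compound for PBPK simulation
#'
#' Low-level constructor for victim and perpetrator compound
#' definitions. Victims eliminate through CYP3A enzyme kinetics scaled to
#' the simulated population; perpetrators use a lumped unbound hepatic
#' intrinsic clearance and carry the inhibition constants acting on the
#' victim's enzymes.
#'
#' @param name Compound name.
#' @param role `"victim"` or `"perpetrator"`.
#' @param mw Molecular weight, g/mol.
#' @param fu_plasma Fraction unbound in plasma (0 < fu <= 1).
#' @param bp_ratio Whole-blood to plasma concentration ratio.
#' @param fu_mic Fraction unbound in the microsomal incubation (applied
#'   to intrinsic clearances and, for perpetrators, assay-derived
#'   inhibition constants; default 1).
#' @param ka First-order absorption rate, 1/h.
#' @param fa Fraction absorbed from the lumen (0 < Fa <= 1).
#' @param fu_gut Fraction unbound in the enterocyte (default 1).
#' @param kp Named list of tissue-to-plasma partition coefficients with
#'   entries `liver`, `adipose`, `rest`.
#' @param renal_cl_l_h Renal (blood) clearance, L/h.
#' @param enzyme_kinetics For victims: tibble as [tacrolimus_kinetics()].
#' @param clint_hepatic_l_h For perpetrators: lumped unbound hepatic
#'   intrinsic clearance, L/h.
#' @param clint_gut_l_h For perpetrators: lumped unbound gut intrinsic
#'   clearance, L/h (default 0).
#' @param inhibition For perpetrators: tibble with columns `isoform`,
#'   `ki` (uM, NA when no reversible inhibition), `kinact` (1/min, NA
#'   when no inactivation) and `ki_conc` (\eqn{K_I}, uM).
#' @param clint_scalar Multiplier on the victim's intrinsic clearances
#'   (used for inter-individual variability; default 1).
#'
#' @return An object of class `pbpk_compound` (a list).
#' @export
pbpk_compound <- function(name, role = c("victim", "perpetrator"),
                          mw, fu_plasma, bp_ratio, fu_mic = 1,
                          ka, fa, fu_gut = 1,
                          kp = list(liver = 1, adipose = 1, rest = 1),
                          renal_cl_l_h = 0,
                          enzyme_kinetics = NULL,
                          clint_hepatic_l_h = NULL,
                          clint_gut_l_h = 0,
                          inhibition = NULL,
                          clint_scalar = 1) {
  role <- match.arg(role)
  check_positive(mw, "mw")
  if (fu_plasma <= 0 || fu_plasma > 1) abort("`fu_plasma` must be in (0, 1]")
  if (fa <= 0 || fa > 1) abort("`fa` must be in (0, 1]")
  check_positive(bp_ratio, "bp_ratio")
  check_positive(ka, "ka")
  if (any(unlist(kp) <= 0)) abort("all `kp` values must be positive")
  if (!all(c("liver", "adipose", "rest") %in% names(kp))) {
    abort("`kp` needs entries liver, adipose and rest")
  }
  if (role == "victim" && is.null(enzyme_kinetics)) {
    abort("a victim compound needs `enzyme_kinetics`")
  }
  if (role == "perpetrator" && is.null(clint_hepatic_l_h)) {
    abort("a perpetrator compound needs `clint_hepatic_l_h`")
  }
  if (!is.null(inhibition)) validate_inhibition(inhibition)
  structure(
    list(
      name = name, role = role, mw = mw,
      fu_plasma = fu_plasma, bp_ratio = bp_ratio, fu_mic = fu_mic,
      ka = ka, fa = fa, fu_gut = fu_gut, kp = kp,
      renal_cl_l_h = renal_cl_l_h,
      enzyme_kinetics = enzyme_kinetics,
      clint_hepatic_l_h = clint_hepatic_l_h,
      clint_gut_l_h = clint_gut_l_h,
      inhibition = inhibition,
      clint_scalar = clint_scalar
    ),
    class = "pbpk_compound"
  )
}

validate_inhibition <- function(inhibition) {
  check_columns(inhibition, c("isoform", "ki", "kinact", "ki_conc"),
                "inhibition kinetics")
  both <- is.na(inhibition$kinact) == is.na(inhibition$ki_conc)
  if (!all(both)) abort("`kinact` and `ki_conc` must be present or absent together")
  has_any <- !is.na(inhibition$ki) | !is.na(inhibition$kinact)
  if (!any(has_any)) abort("at least one inhibition mechanism must be present")
  invisible(inhibition)
}

#' Tacrolimus victim compound
#'
#' The victim drug definition used throughout: CYP3A4/5 elimination via
#' [tacrolimus_kinetics()], extensive erythrocyte partitioning (high
#' blood:plasma ratio), very low plasma fraction unbound, and a maximal
#' adipose partition coefficient (Kp = 1000), which reproduces the long
#' distribution phase. Disposition constants not reported with the CYP
#' kinetics (fu, B:P, ka, Fa, Kp) are literature-typical assumptions and
#' can be overridden.
#'
#' @param ... Overrides passed to [pbpk_compound()] fields.
#' @return A `pbpk_compound` victim definition.
#' @export
#' @examples
#' compound_tacrolimus()
#' compound_tacrolimus(kp = list(liver = 30, adipose = 500, rest = 30))
compound_tacrolimus <- function(...) {
  defaults <- list(
    name = "tacrolimus", role = "victim",
    mw = 804.02,
    fu_plasma = 0.013,
    bp_ratio = 15,
    fu_mic = 1,
    ka = 1.0, fa = 0.94, fu_gut = 1,
    kp = list(liver = 30, adipose = 1000, rest = 30),
    renal_cl_l_h = 0,
    enzyme_kinetics = tacrolimus_kinetics()
  )
  do.call(pbpk_compound, utils::modifyList(defaults, list(...)))
}

#' Schisantherin A (STA) perpetrator compound
#'
#' Reversible inhibitor of CYP3A4 (Ki = 0.15 uM) and CYP3A5
#' (Ki = 0.11 uM) and time-dependent inactivator of CYP3A4
#' (kinact = 0.11 1/min, KI = 2.45 uM). The absorption/disposition
#' parameters (fu, ka, Kp, clearance) are illustrative values for a
#' moderately persistent dibenzocyclooctadiene lignan, not assay-derived;
#' the inhibition constants are the microsomal estimates.
#'
#' @param ... Overrides passed to [pbpk_compound()] fields.
#' @return A `pbpk_compound` perpetrator definition.
#' @export
compound_sta <- function(...) {
  defaults <- list(
    name = "schisantherin A", role = "perpetrator",
    mw = 536.57,
    fu_plasma = 0.5,
    bp_ratio = 1,
    ka = 1.0, fa = 0.9, fu_gut = 0.5,
    kp = list(liver = 4, adipose = 10, rest = 1.5),
    clint_hepatic_l_h = 20,
    inhibition = tibble::tribble(
      ~isoform, ~ki, ~kinact, ~ki_conc,
      "CYP3A4", 0.15, 0.11, 2.45,
      "CYP3A5", 0.11, NA, NA
    )
  )
  do.call(pbpk_compound, utils::modifyList(defaults, list(...)))
}

#' Schisandrin A (SIA) perpetrator compound
#'
#' No measurable reversible inhibition of CYP3A4; reversible inhibitor of
#' CYP3A5 (Ki = 8.74 uM); weak time-dependent inactivator of both CYP3A4
#' (kinact = 0.019 1/min, KI = 2.54 uM) and CYP3A5 (kinact = 0.014 1/min,
#' KI = 2.07 uM). Disposition parameters are illustrative, as for
#' [compound_sta()].
#'
#' @param ... Overrides passed to [pbpk_compound()] fields.
#' @return A `pbpk_compound` perpetrator definition.
#' @export
compound_sia <- function(...) {
  defaults <- list(
    name = "schisandrin A", role = "perpetrator",
    mw = 416.51,
    fu_plasma = 0.5,
    bp_ratio = 1,
    ka = 1.0, fa = 0.9, fu_gut = 0.5,
    kp = list(liver = 4, adipose = 10, rest = 1.5),
    clint_hepatic_l_h = 20,
    inhibition = tibble::tribble(
      ~isoform, ~ki, ~kinact, ~ki_conc,
      "CYP3A4", NA, 0.019, 2.54,
      "CYP3A5", 8.74, 0.014, 2.07
    )
  )
  do.call(pbpk_compound, utils::modifyList(defaults, list(...)))
}

#' Define a dose regimen
#'
#' @param dose_mg Dose per administration, mg (>= 0; 0 gives a
#'   null regimen useful for perpetrator-absent controls).
#' @param n_doses Number of doses (>= 1).
#' @param interval_h Dosing interval, h (required when `n_doses > 1`).
#' @param start_h Time of the first dose, h.
#'
#' @return An object of class `dose_regimen`.
#' @export
#' @examples
#' regimen(2)                        # single 2 mg dose at t = 0
#' regimen(7.325, 26, 12)            # 7.325 mg BID for 13 days
regimen <- function(dose_mg, n_doses = 1, interval_h = NULL, start_h = 0) {
  if (dose_mg < 0) abort("`dose_mg` must be non-negative")
  if (n_doses < 1) abort("`n_doses` must be at least 1")
  if (n_doses > 1 && (is.null(interval_h) || interval_h <= 0)) {
    abort("`interval_h` must be positive when n_doses > 1")
  }
  structure(
    list(
      dose_mg = dose_mg, n_doses = as.integer(n_doses),
      interval_h = interval_h, start_h = start_h
    ),
    class = "dose_regimen"
  )
}

dose_times <- function(reg) {
  if (reg$n_doses == 1) return(reg$start_h)
  reg$start_h + (seq_len(reg$n_doses) - 1) * reg$interval_h
}
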