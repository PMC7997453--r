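#' Estimate observed inactivation rates from an activity time course
#'
#' For each inhibitor concentration, regresses the natural logarithm of
#' percent-remaining activity on pre-incubation time; the observed
#' inactivation rate \eqn{k_{obs}} is the negated slope. Activity is by
#' default normalized to the inhibitor-free control at the matched
#' pre-incubation time, which removes inhibitor-independent activity loss
#' before the log-linear regression.
#'
#' @param data TDI activity data: columns `inhibitor_um`, `time_min`,
#'   `replicate`, `activity_pct` (strictly positive).
#' @param normalize One of `"control_matched"` (default: divide by the
#'   mean control activity at the same time), `"t0"` (divide by the mean
#'   activity of the same inhibitor level at time 0) or `"none"`.
#' @param clamp_se_mult Any positive slope (activity increasing with
#'   time) is clamped to `kobs = 0`; slopes more than this many standard
#'   errors above zero are additionally flagged with a warning, since a
#'   statistically positive slope suggests a data problem rather than
#'   noise around a stable control.
#'
#' @return A tibble of class `kobs_table` with one row per inhibitor
#'   level: `inhibitor_um`, `kobs` (1/min), `kobs_se`, `r_squared`,
#'   `kobs_corrected` (kobs minus the control kobs), `clamped`.
#' @export
#' @examples
#' d <- gen_tdi_dataset(0.11, 2.45, cv = 0, seed = 1)
#' estimate_kobs(d)
estimate_kobs <- function(data,
                          normalize = c("control_matched", "t0", "none"),
                          clamp_se_mult = 2) {
  normalize <- match.arg(normalize)
  check_columns(data, c("inhibitor_um", "time_min", "activity_pct"), "TDI data")
  bad <- data$activity_pct <= 0
  if (any(bad)) {
    row <- which(bad)[1]
    abort(sprintf(
      "non-positive activity at inhibitor %g uM, time %g min (log is taken)",
      data$inhibitor_um[row], data$time_min[row]
    ))
  }
  n_times <- data |>
    dplyr::group_by(.data$inhibitor_um) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$time_min), .groups = "drop")
  if (any(n_times$n < 3)) {
    abort("each inhibitor level needs at least 3 pre-incubation times")
  }

  if (normalize == "control_matched") {
    if (!any(data$inhibitor_um == 0)) {
      abort("control-matched normalization requires an inhibitor-free (0 uM) series")
    }
    control <- data |>
      dplyr::filter(.data$inhibitor_um == 0) |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(control_mean = mean(.data$activity_pct), .groups = "drop")
    data <- data |>
      dplyr::left_join(control, by = "time_min") |>
      dplyr::mutate(activity_pct = 100 * .data$activity_pct / .data$control_mean) |>
      dplyr::select(-"control_mean")
  } else if (normalize == "t0") {
    t0 <- data |>
      dplyr::filter(.data$time_min == 0) |>
      dplyr::group_by(.data$inhibitor_um) |>
      dplyr::summarise(t0_mean = mean(.data$activity_pct), .groups = "drop")
    data <- data |>
      dplyr::left_join(t0, by = "inhibitor_um") |>
      dplyr::mutate(activity_pct = 100 * .data$activity_pct / .data$t0_mean) |>
      dplyr::select(-"t0_mean")
  }

  out <- data |>
    dplyr::group_by(.data$inhibitor_um) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(log(activity_pct) ~ time_min, data = d)
      sm <- suppressWarnings(summary(fit))$coefficients
      slope <- sm["time_min", "Estimate"]
      se <- sm["time_min", "Std. Error"]
      kobs <- -slope
      clamped <- FALSE
      if (kobs < 0) {
        clamped <- is.finite(se) && se > 0 && kobs < -clamp_se_mult * se
        kobs <- 0
      }
      tibble::tibble(
        kobs = kobs,
        kobs_se = se,
        r_squared = suppressWarnings(summary(fit))$r.squared,
        clamped = clamped
      )
    }) |>
    dplyr::ungroup()
  if (any(out$clamped)) {
    warn("positive log-activity slope beyond tolerance; kobs clamped to 0")
  }
  kobs0 <- if (any(out$inhibitor_um == 0)) {
    out$kobs[out$inhibitor_um == 0]
  } else {
    0
  }
  out$kobs_corrected <- pmax(out$kobs - kobs0, 0)
  class(out) <- c("kobs_table", class(out))
  out
}

#' Fit maximal inactivation kinetics from observed rates
#'
#' Estimates \eqn{k_{inact}} and \eqn{K_I} from per-concentration observed
#' inactivation rates under the saturation model
#' \eqn{k_{obs}(I) = k_{inact} I / (K_I + I)}. The canonical estimator is
#' the double-reciprocal (Kitz-Wilson) line, ordinary least squares of
#' \eqn{1/k_{obs}} on \eqn{1/I}: \eqn{k_{inact}} is the reciprocal
#' intercept and \eqn{K_I} the slope/intercept ratio. A direct nonlinear
#' fit of the saturation model is always computed alongside as a
#' cross-check.
#'
#' @param kobs A `kobs_table` from [estimate_kobs()], or any data frame
#'   with columns `inhibitor_um` and `kobs`.
#' @param use_corrected Use the control-corrected rates
#'   (`kobs_corrected`) instead of raw `kobs` (default FALSE).
#' @param method Which estimate populates the canonical `kinact` / `ki_conc`
#'   fields: `"double_reciprocal"` (default) or `"nonlinear"`.
#'
#' @return An object of class `tdi_fit`: `kinact` (1/min), `ki_conc`
#'   (\eqn{K_I}, uM), `efficiency` (mL/min/umol), `method`, both estimator
#'   variants (`double_reciprocal`, `nonlinear` sub-lists with estimates
#'   and diagnostics), and the `kobs` table used.
#' @export
#' @examples
#' kobs <- tibble::tibble(
#'   inhibitor_um = c(0.25, 0.5, 1, 2),
#'   kobs = 0.11 * c(0.25, 0.5, 1, 2) / (2.45 + c(0.25, 0.5, 1, 2))
#' )
#' fit_inactivation(kobs)
fit_inactivation <- function(kobs, use_corrected = FALSE,
                             method = c("double_reciprocal", "nonlinear")) {
  method <- match.arg(method)
  check_columns(kobs, c("inhibitor_um", "kobs"), "kobs table")
  rate_col <- if (use_corrected) "kobs_corrected" else "kobs"
  if (use_corrected) check_columns(kobs, "kobs_corrected", "kobs table")
  d <- tibble::tibble(i = kobs$inhibitor_um, kobs = kobs[[rate_col]]) |>
    dplyr::filter(.data$i > 0, .data$kobs > 0)
  if (nrow(d) < 3) {
    abort("inactivation fit needs at least 3 positive (I, kobs) pairs with I > 0")
  }

  # double-reciprocal (Kitz-Wilson) line
  dr_fit <- lm(I(1 / kobs) ~ I(1 / i), data = d)
  intercept <- unname(coef(dr_fit)[1])
  slope <- unname(coef(dr_fit)[2])
  if (intercept <= 0) {
    abort("double-reciprocal intercept <= 0: no saturation of kobs observed")
  }
  dr <- list(
    kinact = 1 / intercept,
    ki_conc = slope / intercept,
    intercept = intercept,
    slope = slope,
    r_squared = suppressWarnings(summary(dr_fit))$r.squared
  )

  # direct nonlinear fit of the saturation model
  nl <- tryCatch({
    nfit <- minpack.lm::nlsLM(
      kobs ~ kinact * i / (ki_conc + i),
      data = d,
      start = list(
        kinact = max(dr$kinact, max(d$kobs) * 1.2),
        ki_conc = max(dr$ki_conc, median(d$i))
      ),
      lower = c(kinact = 1e-12, ki_conc = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    est <- coef(nfit)
    se <- summary(nfit)$coefficients[, "Std. Error"]
    list(
      kinact = unname(est["kinact"]), ki_conc = unname(est["ki_conc"]),
      kinact_se = unname(se["kinact"]), ki_conc_se = unname(se["ki_conc"]),
      rss = sum((d$kobs - predict(nfit))^2)
    )
  }, error = function(e) NULL)

  canonical <- if (method == "double_reciprocal" || is.null(nl)) dr else nl
  structure(
    list(
      kinact = canonical$kinact,
      ki_conc = canonical$ki_conc,
      efficiency = inactivation_efficiency(canonical$kinact, canonical$ki_conc),
      method = if (method == "nonlinear" && is.null(nl)) "double_reciprocal" else method,
      double_reciprocal = dr,
      nonlinear = nl,
      use_corrected = use_corrected,
      kobs = kobs
    ),
    class = "tdi_fit"
  )
}

#' Inactivation efficiency kinact/KI
#'
#' The ratio of the maximal inactivation rate to the half-maximal
#' inactivation concentration, converted from 1/min/uM (= L/min/umol)
#' to the conventional mL/min/umol.
#'
#' @param kinact Maximal inactivation rate, 1/min (> 0).
#' @param ki_conc Half-maximal inactivation concentration \eqn{K_I},
#'   uM (> 0).
#' @return Efficiency in mL/min/umol: `1000 * kinact / ki_conc`.
#' @export
#' @examples
#' inactivation_efficiency(0.11, 2.45) # 44.90 mL/min/umol
inactivation_efficiency <- function(kinact, ki_conc) {
  if (any(kinact <= 0) || any(ki_conc <= 0)) {
    abort("`kinact` and `ki_conc` must be positive")
  }
  1000 * kinact / ki_conc
}
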