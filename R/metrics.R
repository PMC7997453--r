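#' Summarize a concentration-time profile
#'
#' AUC by the linear trapezoid on the output grid, Cmax as the maximum
#' concentration and Tmax as the earliest time attaining it, all relative
#' to the victim dose time. In `auc = "inf"` mode the terminal slope
#' \eqn{\lambda_z} is fitted by log-linear regression over the final
#' stretch of the profile and \eqn{C_{last}/\lambda_z} is added.
#'
#' @param profile A `sim_profile` from [simulate_pk()], or any data frame
#'   with columns `time_h` and `blood_conc_ng_ml`.
#' @param auc `"inf"` (default): trapezoid plus \eqn{\lambda_z}
#'   extrapolation; `"last"`: trapezoid to the end of the grid only.
#' @param from_time_h Time origin, h; defaults to the profile's victim
#'   dose time when present, else 0.
#' @param lambda_z_frac Fraction of the post-dose span (from the end)
#'   used for the terminal-slope regression.
#'
#' @return A one-row tibble: `auc` (ng/mL.h), `cmax` (ng/mL), `tmax` (h,
#'   relative to the dose), `auc_last`, `lambda_z` (1/h, NA in "last"
#'   mode or when no terminal decline is identifiable),
#'   `extrap_fraction`.
#' @export
#' @examples
#' prof <- tibble::tibble(time_h = seq(0, 48, 0.05),
#'                        blood_conc_ng_ml = 10 * exp(-0.5 * seq(0, 48, 0.05)))
#' compute_metrics(prof)
compute_metrics <- function(profile, auc = c("inf", "last"),
                            from_time_h = NULL, lambda_z_frac = 0.2) {
  auc <- match.arg(auc)
  check_columns(profile, c("time_h", "blood_conc_ng_ml"), "profile")
  if (nrow(profile) < 2) abort("profile must contain at least 2 time points")
  from_time_h <- from_time_h %||% attr(profile, "victim_dose_time") %||% 0

  if (is.unsorted(profile$time_h, strictly = TRUE)) {
    abort("non-monotone time grid")
  }
  d <- dplyr::filter(profile, .data$time_h >= from_time_h)
  t <- d$time_h - from_time_h
  c_ <- d$blood_conc_ng_ml

  auc_last <- sum(diff(t) * (head(c_, -1) + tail(c_, -1)) / 2)
  cmax <- max(c_)
  tmax <- t[which.max(c_)]

  lambda_z <- NA_real_
  extrap <- 0
  auc_total <- auc_last
  if (auc == "inf" && cmax > 0) {
    t_cut <- max(t) - lambda_z_frac * (max(t) - tmax)
    term <- t >= t_cut & c_ > 0 & t > tmax
    if (sum(term) >= 3) {
      fit <- lm(log(c_[term]) ~ t[term])
      slope <- coef(fit)[2]
      if (is.finite(slope) && slope < 0) {
        lambda_z <- -unname(slope)
        extrap <- tail(c_, 1) / lambda_z
        auc_total <- auc_last + extrap
      }
    }
  }
  tibble::tibble(
    auc = auc_total, cmax = cmax, tmax = tmax,
    auc_last = auc_last, lambda_z = lambda_z,
    extrap_fraction = if (auc_total > 0) extrap / auc_total else 0
  )
}

#' Two-sided fold error between prediction and observation
#'
#' \eqn{FE = \max(pred/obs, obs/pred)}; the conventional PBPK fitness
#' measure, equal to 1 only when prediction and observation coincide and
#' deemed acceptable below 2.
#'
#' @param predicted,observed Positive numeric vectors (recycled).
#' @return Numeric vector of fold errors (>= 1).
#' @export
#' @examples
#' fold_error(22.50, 19.34) # 1.16 at 2 d.p.
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    abort("`predicted` and `observed` must be positive")
  }
  pmax(predicted / observed, observed / predicted)
}

#' AUC ratio (fold-increase in exposure)
#'
#' @param auc_with Victim AUC with the perpetrator co-dosed.
#' @param auc_alone Victim AUC alone (> 0).
#' @return `auc_with / auc_alone`.
#' @export
#' @examples
#' aucr(195.23, 102.80) # 1.90 at 2 d.p.
aucr <- function(auc_with, auc_alone) {
  if (any(auc_alone <= 0)) abort("`auc_alone` must be positive")
  auc_with / auc_alone
}
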