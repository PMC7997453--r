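#' Fit the Michaelis-Menten model to inhibitor-free velocities
#'
#' Least-squares fit of \eqn{v = V_{max} S / (K_m + S)} to velocity
#' observations at zero inhibitor. Degenerate designs are flagged rather
#' than silently fitted: a saturated grid (velocity flat in substrate)
#' drives \eqn{K_m} to its lower boundary, and a far-below-\eqn{K_m} grid
#' (velocity proportional to substrate) identifies only the ratio
#' \eqn{V_{max}/K_m}.
#'
#' @param data A data frame with columns `substrate_um` and `velocity`
#'   (and optionally `inhibitor_um`, which must then be all zero).
#' @param start Optional named list of starting values (`vmax`, `km`).
#'
#' @return An object of class `mm_fit`: a list with `vmax`, `km`,
#'   standard errors, `rss`, `r_squared`, `degenerate` flag (one of
#'   `"none"`, `"saturated"`, `"linear"`) and the underlying `nls` object.
#' @export
#' @examples
#' d <- gen_ri_dataset(10, 0.5, Inf, inhibitor_um = 0, cv = 0, seed = 1)
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, start = NULL) {
  check_columns(data, c("substrate_um", "velocity"), "RI data")
  if ("inhibitor_um" %in% names(data)) {
    data <- dplyr::filter(data, .data$inhibitor_um == 0)
  }
  if (dplyr::n_distinct(data$substrate_um) < 3) {
    abort("Michaelis-Menten fit needs at least 3 distinct substrate levels at I = 0")
  }
  if (any(data$velocity < 0)) abort("velocities must be non-negative")

  s <- data$substrate_um
  v <- data$velocity

  # saturation limit: velocity flat in substrate leaves Km unidentified at
  # its zero boundary (and a singular Jacobian), so report it directly
  means <- tapply(v, s, mean)
  if (max(means) - min(means) <= 1e-10 * max(means)) {
    return(structure(
      list(
        vmax = mean(v), km = 0,
        vmax_se = sd(v) / sqrt(length(v)), km_se = NA_real_,
        rss = sum((v - mean(v))^2),
        r_squared = NA_real_,
        degenerate = "saturated",
        n_obs = length(v),
        fit = NULL
      ),
      class = "mm_fit"
    ))
  }

  # linear limit: velocity proportional to substrate (far below Km) only
  # identifies the ratio Vmax/Km; the parameters diverge individually
  ratio <- v / s
  if (max(ratio) - min(ratio) <= 1e-10 * max(ratio)) {
    return(structure(
      list(
        vmax = NA_real_, km = NA_real_,
        vmax_se = NA_real_, km_se = NA_real_,
        vmax_over_km = mean(ratio),
        rss = 0,
        r_squared = 1,
        degenerate = "linear",
        n_obs = length(v),
        fit = NULL
      ),
      class = "mm_fit"
    ))
  }

  start <- start %||% list(vmax = max(v) * 1.2, km = median(s))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      start = start,
      lower = c(vmax = 1e-12, km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf("Michaelis-Menten fit did not converge: %s", conditionMessage(e)))
    }
  )
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  res <- v - predict(fit)
  rss <- sum(res^2)
  tss <- sum((v - mean(v))^2)

  # degeneracy diagnostics: Km at boundary (saturation) or Km far above
  # the grid (linear regime, only Vmax/Km identified)
  degenerate <- "none"
  if (est["km"] < 1e-6 * min(s)) degenerate <- "saturated"
  if (est["km"] > 100 * max(s)) degenerate <- "linear"

  structure(
    list(
      vmax = unname(est["vmax"]), km = unname(est["km"]),
      vmax_se = unname(se["vmax"]), km_se = unname(se["km"]),
      rss = rss,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      degenerate = degenerate,
      n_obs = length(v),
      fit = fit
    ),
    class = "mm_fit"
  )
}

#' Test whether an inhibitor measurably slows the reaction
#'
#' Classifies a velocity grid as `"inhibited"` or `"none"`. For each
#' substrate level the velocity is regressed on inhibitor concentration;
#' the dataset is called inhibited if any level shows a significant
#' negative trend (two-sided t-test on the slope) or the mean velocity at
#' the top inhibitor level drops by more than `min_reduction` relative to
#' the inhibitor-free mean at the same substrate level. With a single
#' replicate per cell (or an exactly collinear fit) the t-test degenerates
#' and a slope-sign + reduction heuristic is used, flagged in the result.
#'
#' @param data RI velocity data (`substrate_um`, `inhibitor_um`,
#'   `velocity`).
#' @param alpha Significance level of the per-substrate trend test.
#' @param min_reduction Minimum fractional reduction of mean velocity at
#'   the top inhibitor level needed to call inhibition (default 0.2).
#'
#' @return A list with `call` (`"inhibited"` or `"none"`), `max_reduction`
#'   (largest fractional mean-velocity drop at the top inhibitor level
#'   over substrate levels), per-substrate `trend` tibble, and
#'   `degenerate_test` flag.
#' @export
detect_inhibition <- function(data, alpha = 0.05, min_reduction = 0.2) {
  check_columns(data, c("substrate_um", "inhibitor_um", "velocity"), "RI data")
  if (dplyr::n_distinct(data$inhibitor_um) < 2) {
    abort("inhibition detection needs at least 2 inhibitor levels")
  }
  top_i <- max(data$inhibitor_um)
  cell_counts <- data |>
    dplyr::count(.data$substrate_um, .data$inhibitor_um)
  single_replicate <- all(cell_counts$n == 1)

  trend <- data |>
    dplyr::group_by(.data$substrate_um) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(velocity ~ inhibitor_um, data = d)
      sm <- suppressWarnings(summary(fit))$coefficients
      slope <- sm["inhibitor_um", "Estimate"]
      p <- sm["inhibitor_um", "Pr(>|t|)"]
      v0 <- mean(d$velocity[d$inhibitor_um == 0])
      vtop <- mean(d$velocity[d$inhibitor_um == top_i])
      reduction <- if (v0 > 0) (v0 - vtop) / v0 else 0
      # a perfect (zero-residual) fit yields p = NaN; with unreplicated
      # cells the residual carries model curvature, not noise -- both
      # fall back on a slope-sign + reduction heuristic
      degenerate <- !is.finite(p) || single_replicate
      tibble::tibble(
        slope = slope, p_value = p, reduction = reduction,
        degenerate = degenerate
      )
    }) |>
    dplyr::ungroup()

  degenerate_test <- any(trend$degenerate)
  sig_negative <- with(
    trend,
    ifelse(degenerate, slope < 0 & reduction > min_reduction,
           slope < 0 & p_value < alpha)
  )
  max_reduction <- max(trend$reduction)
  call <- if (any(sig_negative) || max_reduction >= min_reduction) {
    "inhibited"
  } else {
    "none"
  }
  list(
    call = call,
    max_reduction = max_reduction,
    trend = trend,
    degenerate_test = degenerate_test,
    alpha = alpha,
    min_reduction = min_reduction
  )
}

#' Estimate a competitive inhibition constant by global nonlinear fit
#'
#' Canonical Ki estimator: nonlinear least squares of
#' \eqn{v = V_{max} S / (K_m (1 + I/K_i) + S)} over the full substrate x
#' inhibitor grid, each replicate entering as an individual observation.
#' When [detect_inhibition()] classifies the grid as showing no inhibitor
#' effect (or the data carry no positive inhibitor level) the result has
#' `mode = "none"` and reduces to the plain Michaelis-Menten fit.
#'
#' @param data RI velocity data (`substrate_um`, `inhibitor_um`,
#'   `replicate`, `velocity`).
#' @param detect Run the inhibition-presence classifier first (default
#'   TRUE: a flat grid is reported as showing no reversible inhibition
#'   rather than as an enormous, meaningless Ki).
#' @param average_replicates Average replicate velocities per grid cell
#'   before fitting (off by default; the triplicate design enters the
#'   objective observation-wise).
#' @param start Optional named list of starting values
#'   (`vmax`, `km`, `ki`).
#'
#' @return An object of class `ri_fit`: `mode` ("competitive" or "none"),
#'   `ki`, `vmax`, `km`, standard errors, `rss`, `r_squared`,
#'   `method = "nonlinear"`, `detection` (the classifier output) and the
#'   `nls` object.
#' @export
#' @examples
#' d <- gen_ri_dataset(10, 0.4, 0.15, cv = 0, seed = 1)
#' fit_competitive_ki(d)
fit_competitive_ki <- function(data, detect = TRUE,
                               average_replicates = FALSE, start = NULL) {
  check_columns(data, c("substrate_um", "inhibitor_um", "velocity"), "RI data")
  if (average_replicates) {
    data <- data |>
      dplyr::group_by(.data$substrate_um, .data$inhibitor_um) |>
      dplyr::summarise(velocity = mean(.data$velocity), .groups = "drop")
  }
  n_s <- dplyr::n_distinct(data$substrate_um)
  n_i <- dplyr::n_distinct(data$inhibitor_um)

  # no positive inhibitor level: the model reduces to Michaelis-Menten
  if (all(data$inhibitor_um == 0)) {
    mm <- fit_michaelis_menten(data)
    return(ri_fit_none(mm, detection = NULL))
  }
  if (n_s < 3 || n_i < 3 || !any(data$inhibitor_um == 0)) {
    abort("competitive fit needs >= 3 substrate levels and >= 3 inhibitor levels including 0")
  }

  detection <- if (detect) detect_inhibition(data) else NULL
  if (!is.null(detection) && detection$call == "none") {
    # no inhibitor effect: pool the full grid (velocity independent of I)
    mm <- fit_michaelis_menten(dplyr::select(data, -"inhibitor_um"))
    return(ri_fit_none(mm, detection))
  }

  s <- data$substrate_um
  i <- data$inhibitor_um
  v <- data$velocity
  start <- start %||% list(
    vmax = max(v) * 1.2,
    km = median(s),
    ki = median(i[i > 0])
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km * (1 + i / ki) + s),
      start = start,
      lower = c(vmax = 1e-12, km = 1e-12, ki = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(sprintf("competitive Ki fit did not converge: %s", conditionMessage(e)))
    }
  )
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  res <- v - predict(fit)
  rss <- sum(res^2)
  tss <- sum((v - mean(v))^2)

  structure(
    list(
      mode = "competitive",
      ki = unname(est["ki"]), vmax = unname(est["vmax"]), km = unname(est["km"]),
      ki_se = unname(se["ki"]), vmax_se = unname(se["vmax"]),
      km_se = unname(se["km"]),
      rss = rss,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      method = "nonlinear",
      n_obs = length(v),
      detection = detection,
      fit = fit
    ),
    class = "ri_fit"
  )
}

ri_fit_none <- function(mm, detection) {
  structure(
    list(
      mode = "none",
      ki = NA_real_, vmax = mm$vmax, km = mm$km,
      ki_se = NA_real_, vmax_se = mm$vmax_se, km_se = mm$km_se,
      rss = mm$rss, r_squared = mm$r_squared,
      method = "nonlinear",
      n_obs = mm$n_obs,
      detection = detection,
      fit = mm$fit
    ),
    class = "ri_fit"
  )
}

#' Dixon-plot analysis of a competitive inhibition grid
#'
#' For each substrate level, fits the ordinary least-squares line of
#' reciprocal velocity against inhibitor concentration (the Dixon plot).
#' Under competitive inhibition all lines intersect at \eqn{I = -K_i};
#' the Ki estimate is the median of the negated intersection abscissae
#' over all line pairs. Serves as a graphical cross-check of the
#' nonlinear estimator from [fit_competitive_ki()].
#'
#' @param data RI velocity data (`substrate_um`, `inhibitor_um`,
#'   `velocity`; strictly positive velocities since reciprocals are taken).
#' @param average_replicates Average replicates per cell before the
#'   regression (off by default).
#' @param parallel_tol Relative slope-difference tolerance below which a
#'   line pair is treated as parallel and excluded from the intersection
#'   estimate.
#'
#' @return An object of class `dixon_fit`: `ki` (median intersection
#'   estimate), `lines` (tibble of per-substrate intercepts/slopes),
#'   `intersections` (tibble of pairwise intersection points with an
#'   `excluded` flag), and `method = "dixon"`.
#' @export
dixon_regression <- function(data, average_replicates = FALSE,
                             parallel_tol = 1e-8) {
  check_columns(data, c("substrate_um", "inhibitor_um", "velocity"), "RI data")
  if (any(data$velocity <= 0)) {
    abort("Dixon analysis requires strictly positive velocities (1/v is regressed)")
  }
  if (dplyr::n_distinct(data$substrate_um) < 2 ||
      dplyr::n_distinct(data$inhibitor_um) < 2) {
    abort("Dixon analysis needs >= 2 substrate and >= 2 inhibitor levels")
  }
  if (average_replicates) {
    data <- data |>
      dplyr::group_by(.data$substrate_um, .data$inhibitor_um) |>
      dplyr::summarise(velocity = mean(.data$velocity), .groups = "drop")
  }

  lines <- data |>
    dplyr::group_by(.data$substrate_um) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(I(1 / velocity) ~ inhibitor_um, data = d)
      tibble::tibble(
        intercept = coef(fit)[1],
        slope = coef(fit)[2],
        r_squared = suppressWarnings(summary(fit))$r.squared
      )
    }) |>
    dplyr::ungroup()

  # a line is uninformative when the inhibitor range moves 1/v by less
  # than `parallel_tol` of its intercept (no measurable inhibitor effect)
  i_max <- max(data$inhibitor_um)
  flat <- abs(lines$slope) * i_max <= parallel_tol * abs(lines$intercept)
  if (all(flat)) {
    abort("all Dixon slopes are ~0 (no inhibitor effect): line pairs parallel, Ki intersection undefined")
  }

  pairs <- utils::combn(seq_len(nrow(lines)), 2)
  intersections <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dslope <- lines$slope[a] - lines$slope[b]
    parallel <- flat[a] && flat[b] ||
      abs(dslope) <= parallel_tol * max(abs(lines$slope[a]),
                                        abs(lines$slope[b]))
    x <- if (parallel) NA_real_ else
      (lines$intercept[b] - lines$intercept[a]) / dslope
    tibble::tibble(
      substrate_a = lines$substrate_um[a],
      substrate_b = lines$substrate_um[b],
      i_intersect = x,
      inv_v_intersect = if (parallel) NA_real_ else
        lines$intercept[a] + lines$slope[a] * x,
      excluded = parallel
    )
  })

  usable <- intersections$i_intersect[!intersections$excluded]
  if (length(usable) == 0) {
    abort("all Dixon line pairs are parallel within tolerance; Ki intersection undefined")
  }
  structure(
    list(
      ki = median(-usable),
      lines = lines,
      intersections = intersections,
      method = "dixon"
    ),
    class = "dixon_fit"
  )
}
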