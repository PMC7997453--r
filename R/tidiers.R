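#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vmax", "km"),
    estimate = c(x$vmax, x$km),
    std.error = c(x$vmax_se, x$km_se)
  )
}

#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, r.squared = x$r_squared,
    degenerate = x$degenerate, nobs = x$n_obs
  )
}

#' @exportS3Method generics::tidy
tidy.ri_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ki", "vmax", "km"),
    estimate = c(x$ki, x$vmax, x$km),
    std.error = c(x$ki_se, x$vmax_se, x$km_se)
  )
}

#' @exportS3Method generics::glance
glance.ri_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, method = x$method,
    rss = x$rss, r.squared = x$r_squared, nobs = x$n_obs
  )
}

#' @exportS3Method generics::tidy
tidy.dixon_fit <- function(x, ...) {
  x$lines |>
    dplyr::rename(term = "substrate_um") |>
    dplyr::mutate(term = paste0("S=", .data$term))
}

#' @exportS3Method generics::glance
glance.dixon_fit <- function(x, ...) {
  tibble::tibble(
    ki = x$ki, method = x$method,
    n_lines = nrow(x$lines),
    n_pairs_used = sum(!x$intersections$excluded)
  )
}

#' @exportS3Method generics::tidy
tidy.tdi_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kinact", "ki_conc", "efficiency"),
    estimate = c(x$kinact, x$ki_conc, x$efficiency)
  )
}

#' @exportS3Method generics::glance
glance.tdi_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    dr_r_squared = x$double_reciprocal$r_squared,
    kinact_dr = x$double_reciprocal$kinact,
    ki_conc_dr = x$double_reciprocal$ki_conc,
    kinact_nl = if (!is.null(x$nonlinear)) x$nonlinear$kinact else NA_real_,
    ki_conc_nl = if (!is.null(x$nonlinear)) x$nonlinear$ki_conc else NA_real_
  )
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Reversible-inhibition fit (", x$method, ")\n", sep = "")
  if (x$mode == "none") {
    cat("  mode: none (no measurable reversible inhibition)\n")
    cat(sprintf("  Vmax = %.4g, Km = %.4g\n", x$vmax, x$km))
  } else {
    cat(sprintf("  mode: competitive; Ki = %.4g uM (SE %.3g)\n", x$ki, x$ki_se))
    cat(sprintf("  Vmax = %.4g pmol/min/mg, Km = %.4g uM, R2 = %.4f\n",
                x$vmax, x$km, x$r_squared))
  }
  invisible(x)
}

#' @export
print.tdi_fit <- function(x, ...) {
  cat("Time-dependent-inactivation fit (", x$method, ")\n", sep = "")
  cat(sprintf("  kinact = %.4g 1/min, KI = %.4g uM\n", x$kinact, x$ki_conc))
  cat(sprintf("  efficiency kinact/KI = %.4g mL/min/umol\n", x$efficiency))
  invisible(x)
}

#' @export
print.dixon_fit <- function(x, ...) {
  cat(sprintf("Dixon analysis: Ki = %.4g uM (median of %d intersections)\n",
              x$ki, sum(!x$intersections$excluded)))
  invisible(x)
}

#' @export
print.cyp_population <- function(x, ...) {
  cat(sprintf("Virtual population: %s %s\n", x$ethnicity, x$genotype_class))
  cat("  liver (pmol/mg):",
      paste(names(x$liver_abundance), x$liver_abundance, collapse = ", "), "\n")
  cat("  gut (nmol):",
      paste(names(x$gut_abundance), x$gut_abundance, collapse = ", "), "\n")
  invisible(x)
}
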