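# internal helpers shared across modules

# validate that `data` carries the named columns, with a caller-friendly error
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# positive scalar check used by kinetic constructors
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

# half-even rounding to 2 decimals, the presentation rule used in reports
# (base round() is half-even up to floating-point representation)
round2 <- function(x, digits = 2) {
  round(x, digits)
}

# log-normal multiplicative noise with a given coefficient of variation on
# the natural scale: exp(N(0, sigma)) with sigma = sqrt(log(1 + cv^2))
cv_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = 0, sd = sigma))
}
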