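# Numeric helpers shared across the package. All times are ages: the
# present is 0 and t increases into the past.

# log(1 - exp(-x)) for x > 0, stable for both small and large x.
log1mexp <- function(x) {
  out <- x
  small <- x <= log(2)
  out[small] <- log(-expm1(-x[small]))
  out[!small] <- log1p(-exp(-x[!small]))
  out[x <= 0] <- -Inf
  out
}

# log(1 + e^v), stable for large v.
log1pexp <- function(v) {
  out <- v
  lo <- v <= 30
  out[lo] <- log1p(exp(v[lo]))
  out[!lo] <- v[!lo] + log1p(exp(-v[!lo]))
  out
}

# Relative tolerance used to detect the critical process (lambda == mu),
# where the generic closed forms are 0/0 and an analytic limit is taken.
CRITICAL_EPS <- 1e-8

is_critical <- function(lambda, mu) {
  abs(lambda - mu) < CRITICAL_EPS * pmax(lambda, mu, 1)
}

# Quadrature tolerances for tabulated rate models (piecewise-constant
# models use exact interval sums and never hit the quadrature path).
QUAD_REL_TOL <- 1e-10
QUAD_ABS_TOL <- 1e-12

quad <- function(f, lower, upper) {
  if (upper <= lower) return(0)
  stats::integrate(f, lower, upper,
    rel.tol = QUAD_REL_TOL, abs.tol = QUAD_ABS_TOL,
    subdivisions = 500L, stop.on.error = FALSE
  )$value
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be a single number.", name),
      class = "bdltt_validation_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf(
      "`%s` must be a single finite number in [%s, %s].",
      name, format(lower), format(upper)
    ), class = "bdltt_validation_error")
  }
  invisible(x)
}
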