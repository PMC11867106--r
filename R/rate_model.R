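#' Diversification rate models
#'
#' A rate model specifies a per-lineage birth (speciation) rate
#' \eqn{\lambda(t)}, a death (extinction) rate \eqn{\mu(t)}, and a sampling
#' fraction \eqn{\rho}: the probability that an extant lineage is included
#' in the sample at the present. All rate functions are functions of *age*
#' `t`, measured backwards from the present (`t = 0` now, increasing into
#' the past). The process itself runs forward in real time; every formula
#' in the package is written in ages.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{`constant`}{fixed \eqn{\lambda}, \eqn{\mu}; closed forms are
#'     used throughout.}
#'   \item{`piecewise_constant`}{rates constant on intervals between
#'     strictly increasing change-point ages; all time integrals are
#'     computed exactly as sums of rate times interval length. At a
#'     change point the rate takes the value of the *younger* piece; the
#'     older piece applies immediately above it.}
#'   \item{`tabulated`}{rates given at a grid of ages and interpolated
#'     linearly (constant beyond the last knot); integrals use adaptive
#'     quadrature with relative tolerance `1e-10`.}
#' }
#'
#' @param lambda,mu Non-negative constant rates (events per lineage per
#'   unit time).
#' @param rho Sampling fraction in `(0, 1]`.
#' @param change_points Strictly increasing ages of rate changes (may be
#'   empty).
#' @param lambdas,mus Per-piece rates, youngest piece first; must have
#'   `length(change_points) + 1` elements.
#' @param ages For `make_tabulated_model()`, strictly increasing knot
#'   ages at which the rates are tabulated.
#'
#' @return An object of class `rate_model`.
#' @examples
#' make_constant_model(1, 0.5, 1)
#' # two-epoch Yule rates, young epoch first:
#' make_piecewise_model(66, c(0.125, 0.025), c(0, 0))
#' @seealso [bdp_p0()], [gbdp_p1()], [pulled_rate()], [simulate_forward()]
#' @export
make_constant_model <- function(lambda, mu, rho = 1) {
  check_number(lambda, "lambda", lower = 0)
  check_number(mu, "mu", lower = 0)
  new_rate_model("constant", lambda = lambda, mu = mu, rho = rho)
}

#' @rdname make_constant_model
#' @export
make_piecewise_model <- function(change_points, lambdas, mus, rho = 1) {
  change_points <- as.numeric(change_points)
  if (length(change_points) == 0L) {
    return(make_constant_model(lambdas, mus, rho))
  }
  if (anyNA(change_points) || any(!is.finite(change_points)) ||
      any(change_points <= 0) || is.unsorted(change_points, strictly = TRUE)) {
    abort("`change_points` must be finite, positive and strictly increasing.",
      class = "bdltt_validation_error")
  }
  k <- length(change_points) + 1L
  if (length(lambdas) != k || length(mus) != k) {
    abort(sprintf(
      "need %d per-piece rates for %d change points, got %d lambdas and %d mus.",
      k, k - 1L, length(lambdas), length(mus)
    ), class = "bdltt_validation_error")
  }
  if (any(lambdas < 0) || any(mus < 0)) {
    abort("rates must be non-negative.", class = "bdltt_validation_error")
  }
  new_rate_model("piecewise_constant",
    lambda = as.numeric(lambdas), mu = as.numeric(mus), rho = rho,
    change_points = change_points
  )
}

#' @rdname make_constant_model
#' @export
make_tabulated_model <- function(ages, lambdas, mus, rho = 1) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L || is.unsorted(ages, strictly = TRUE) ||
      any(ages < 0) || any(!is.finite(ages))) {
    abort("`ages` must be >= 2 strictly increasing finite non-negative knots.",
      class = "bdltt_validation_error")
  }
  if (length(lambdas) != length(ages) || length(mus) != length(ages)) {
    abort("`lambdas` and `mus` must match `ages` in length.",
      class = "bdltt_validation_error")
  }
  if (any(lambdas < 0) || any(mus < 0)) {
    abort("rates must be non-negative.", class = "bdltt_validation_error")
  }
  new_rate_model("tabulated",
    lambda = as.numeric(lambdas), mu = as.numeric(mus), rho = rho,
    knots = ages
  )
}

new_rate_model <- function(kind, lambda, mu, rho,
                           change_points = numeric(), knots = NULL) {
  check_number(rho, "rho", lower = 1e-300, upper = 1)
  if (rho <= 0) {
    abort("`rho` must be in (0, 1].", class = "bdltt_validation_error")
  }
  structure(
    list(kind = kind, lambda = lambda, mu = mu, rho = rho,
         change_points = change_points, knots = knots),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model:", x$kind, ">\n")
  switch(x$kind,
    constant = cat(sprintf("  lambda = %g, mu = %g\n", x$lambda, x$mu)),
    piecewise_constant = {
      cat("  change-point ages:", paste(format(x$change_points), collapse = ", "), "\n")
      cat("  lambda (young -> old):", paste(format(x$lambda), collapse = ", "), "\n")
      cat("  mu     (young -> old):", paste(format(x$mu), collapse = ", "), "\n")
    },
    tabulated = cat(sprintf("  %d knots on ages [%g, %g]\n",
      length(x$knots), min(x$knots), max(x$knots)))
  )
  cat(sprintf("  sampling fraction rho = %g\n", x$rho))
  invisible(x)
}

is_rate_model <- function(x) inherits(x, "rate_model")

stop_not_model <- function(x) {
  if (!is_rate_model(x)) {
    abort("expected a `rate_model` object.", class = "bdltt_validation_error")
  }
}

# Piece index for a vector of ages; an age exactly at a change point
# belongs to the younger piece.
piece_index <- function(t, change_points) {
  findInterval(t, change_points, left.open = TRUE) + 1L
}

#' Evaluate the rate functions of a model
#'
#' `birth_rate()` and `death_rate()` return \eqn{\lambda(t)} and
#' \eqn{\mu(t)} at a vector of ages.
#'
#' @param model A [rate model][make_constant_model].
#' @param t Vector of non-negative ages.
#' @return Numeric vector of rates.
#' @export
birth_rate <- function(model, t) rate_eval(model, t, "lambda")

#' @rdname birth_rate
#' @export
death_rate <- function(model, t) rate_eval(model, t, "mu")

rate_eval <- function(model, t, which) {
  stop_not_model(model)
  v <- model[[which]]
  switch(model$kind,
    constant = rep_len(v, length(t)),
    piecewise_constant = v[piece_index(t, model$change_points)],
    tabulated = approx(model$knots, v, xout = t, rule = 2)$y
  )
}

# ---- exact cumulative integrals -------------------------------------------
# R(t) = Lambda(t) - M(t) with Lambda = int_0^t lambda, M = int_0^t mu, and
# A(t) = int_0^t lambda(s) e^{R(s)} ds. These three determine p0, p1 and the
# pulled speciation rate in closed form:
#   p0(t) = 1 - rho e^{R} / (1 + rho A),  p1(t) = rho e^{R} / (1 + rho A)^2,
#   Lambda_p(t) = log(1 + rho A).

cum_lambda <- function(model, t) cum_rate(model, t, "lambda")
cum_mu <- function(model, t) cum_rate(model, t, "mu")

cum_rate <- function(model, t, which) {
  v <- model[[which]]
  switch(model$kind,
    constant = v * t,
    piecewise_constant = {
      b <- c(0, model$change_points)
      at_knot <- c(0, cumsum(v[-length(v)] * diff(b)))
      i <- piece_index(t, model$change_points)
      at_knot[i] + v[i] * (t - b[i])
    },
    tabulated = lin_cumint(model$knots, v, t)
  )
}

# Exact integral of the piecewise-linear interpolant (constant beyond the
# knot range) from 0 to each t.
lin_cumint <- function(x, y, t) {
  if (x[1] > 0) {
    x <- c(0, x)
    y <- c(y[1], y)
  }
  at_knot <- c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  n <- length(x)
  i <- pmin(findInterval(t, x), n - 1L)
  yt <- approx(x, y, xout = t, rule = 2)$y
  partial <- ifelse(t >= x[n],
    at_knot[n] + y[n] * (t - x[n]),
    at_knot[i] + (t - x[i]) * (y[i] + yt) / 2
  )
  partial
}

cum_A <- function(model, t) {
  switch(model$kind,
    constant = const_A(t, model$lambda, model$mu),
    piecewise_constant = piecewise_A(model, t),
    tabulated = vapply(t, function(tt) {
      quad(function(s) {
        birth_rate(model, s) * exp(cum_lambda(model, s) - cum_mu(model, s))
      }, 0, tt)
    }, numeric(1))
  )
}

# Vectorized over every argument.
const_A <- function(t, lambda, mu) {
  n <- max(length(t), length(lambda), length(mu))
  t <- rep_len(t, n)
  lambda <- rep_len(lambda, n)
  mu <- rep_len(mu, n)
  r <- lambda - mu
  crit <- is_critical(lambda, mu)
  safe_r <- ifelse(crit, 1, r)
  ifelse(crit, lambda * t, lambda * expm1(r * t) / safe_r)
}

piecewise_A <- function(model, t) {
  b <- c(0, model$change_points)
  lam <- model$lambda
  mu <- model$mu
  r <- lam - mu
  k <- length(lam)
  # R and A accumulated at the knots
  R_knot <- c(0, cumsum(r[-k] * diff(b)))
  A_piece <- numeric(k - 1L)
  if (k > 1L) {
    w <- diff(b)
    for (j in seq_len(k - 1L)) {
      A_piece[j] <- exp(R_knot[j]) * const_A(w[j], lam[j], mu[j])
    }
  }
  A_knot <- c(0, cumsum(A_piece))
  i <- piece_index(t, model$change_points)
  A_knot[i] + exp(R_knot[i]) * const_A(t - b[i], lam[i], mu[i])
}

#' Tabulate a model's rate functions on a grid of ages
#'
#' Convenience for plotting and for the command-line `congruence` report.
#'
#' @inheritParams birth_rate
#' @return A tibble with columns `t`, `lambda`, `mu`.
#' @export
rate_table <- function(model, t) {
  stop_not_model(model)
  tibble(t = t, lambda = birth_rate(model, t), mu = death_rate(model, t))
}
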