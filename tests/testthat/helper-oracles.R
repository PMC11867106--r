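# Independent numerical oracles used across the suite. These integrate
# the defining ODEs (or sum defining series) directly and never call the
# closed-form code paths they are used to check.

# p0/p1 by direct integration of the backward ODEs
#   p0' = -(l+m) p0 + m + l p0^2,   p0(0) = 1 - rho
#   p1' = -(l+m) p1 + 2 l p0 p1,    p1(0) = rho
ode_p0_p1 <- function(t, lambda_fun, mu_fun, rho = 1) {
  rhs <- function(s, y, parms) {
    l <- lambda_fun(s)
    m <- mu_fun(s)
    list(c(
      -y[1] * (l + m) + m + y[1]^2 * l,
      -y[2] * (l + m) + 2 * y[2] * y[1] * l
    ))
  }
  out <- deSolve::ode(c(p0 = 1 - rho, p1 = rho), c(0, t), rhs, NULL,
                      rtol = 1e-12, atol = 1e-14)
  unname(out[nrow(out), c("p0", "p1")])
}

ode_p0_p1_const <- function(t, lambda, mu, rho = 1) {
  ode_p0_p1(t, function(s) lambda, function(s) mu, rho)
}

ode_p0_p1_model <- function(t, model) {
  ode_p0_p1(t, function(s) birth_rate(model, s),
            function(s) death_rate(model, s), model$rho)
}

# Yule p_n by iteratively solving the chain of pure-birth ODEs
#   p_n' = -n l p_n + (n-1) l p_{n-1},   p_1(0) = 1.
ode_yule_pn <- function(n_max, t, lambda) {
  rhs <- function(s, y, parms) {
    n <- seq_along(y)
    list(-n * lambda * y + c(0, (n[-1] - 1) * lambda * y[-length(y)]))
  }
  y0 <- c(1, rep(0, n_max - 1))
  out <- deSolve::ode(y0, c(0, t), rhs, NULL, rtol = 1e-12, atol = 1e-14)
  unname(out[nrow(out), -1])
}

# Kendall's complete-sampling eta through the death-rate integral: with
# R(s) = int_0^s (lambda - mu) obtained by quadrature of the rate
# functions, the survival-form uses W = e^{-R(t)} int_0^t mu(s) e^{R(s)} ds
# (time measured forward from the lineage's birth), giving
# eta = 1 - 1 / (e^{R(t)} (1 + W)). Independent of the package's exact
# interval-sum integrals.
eta_via_W <- function(t, model) {
  stopifnot(model$rho == 1)
  seg_quad <- function(f, upper) {
    segs <- sort(unique(c(0, model$change_points[model$change_points < upper],
                          upper)))
    sum(vapply(seq_len(length(segs) - 1), function(i) {
      stats::integrate(f, segs[i], segs[i + 1], rel.tol = 1e-10,
                       subdivisions = 500L)$value
    }, numeric(1)))
  }
  Rfun <- function(s) {
    vapply(s, function(ss) {
      seg_quad(function(y) birth_rate(model, y) - death_rate(model, y), ss)
    }, numeric(1))
  }
  W <- exp(-Rfun(t)) *
    seg_quad(function(s) death_rate(model, s) * exp(Rfun(s)), t)
  1 - 1 / (exp(Rfun(t)) * (1 + W))
}

random_constant_model <- function() {
  make_constant_model(runif(1, 0.05, 2), runif(1, 0, 1.5), runif(1, 0.2, 1))
}

random_piecewise_model <- function(k = 3, rho = NULL) {
  cp <- sort(runif(k - 1, 0.3, 4))
  make_piecewise_model(cp, runif(k, 0.05, 1.5), runif(k, 0, 1),
                       rho %||% runif(1, 0.3, 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Truncated-exponential kernel CDF on [0, t0] (stem-conditioned Yule).
trunc_exp_cdf <- function(x, lambda, t0) {
  (1 - exp(-lambda * x)) / (1 - exp(-lambda * t0))
}

# Forward Yule simulation conditioned on the sampled tip count by
# rejection; returns the node ages of one accepted replicate.
sim_yule_given_n <- function(n, t0, lambda) {
  sim <- simulate_forward_conditional(
    make_constant_model(lambda, 0, 1), t0,
    accept = function(s) s$n_sampled == n
  )
  ltt_from_tree(sim)$age
}
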