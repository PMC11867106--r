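#' Yule transition probabilities
#'
#' Probability that a single lineage alive at age `t` leaves exactly `n`
#' descendants at the present under a pure-birth (Yule) process with rate
#' `lambda`: \eqn{p_n(t) = e^{-\lambda t}(1 - e^{-\lambda t})^{n-1}}, the
#' geometric law obtained by iteratively solving the birth-process ODEs.
#'
#' @param n Number of descendants, `n >= 1` (a pure-birth lineage cannot
#'   die, so `n = 0` is an error).
#' @param t Age (time before present), `t >= 0`.
#' @param lambda Birth rate, `lambda >= 0`.
#' @param log Return the log probability?
#' @return Probability (or log probability); vectorized over `n` and `t`.
#' @examples
#' yule_pn(2, 10, 0.1) # exp(-2) * (exp(1) - 1)
#' sum(yule_pn(1:200, 1, 1)) # sums to 1 over n
#' @export
yule_pn <- function(n, t, lambda, log = FALSE) {
  if (any(n < 1)) {
    abort("`n` must be >= 1: a pure-birth lineage cannot go extinct.",
      class = "bdltt_validation_error")
  }
  if (any(t < 0) || lambda < 0) {
    abort("need `t >= 0` and `lambda >= 0`.", class = "bdltt_validation_error")
  }
  k <- pmax(n, 1)
  lt <- lambda * t
  lp <- ifelse(k == 1, -lt, -lt + (k - 1) * log1mexp(lt))
  # lambda * t == 0: all mass on n = 1
  lp[lt == 0] <- ifelse(k[lt == 0] == 1, 0, -Inf)
  if (log) lp else exp(lp)
}

# log(1 + rho * A) for the constant-rate model, computed in log space so
# that large |lambda - mu| * t does not overflow.
log1p_rho_A_const <- function(t, lambda, mu, rho) {
  r <- lambda - mu
  if (lambda == 0) return(rep_len(0, length(t)) + log1p(0))
  if (is_critical(lambda, mu)) {
    return(log1p(rho * lambda * t))
  }
  logA <- if (r > 0) {
    log(lambda / r) + r * t + log1mexp(r * t)
  } else {
    log(lambda / (-r)) + log1mexp(-r * t)
  }
  logA[t == 0] <- -Inf
  log1pexp(log(rho) + logA)
}

#' Constant-rate birth-death transition probabilities
#'
#' `bdp_p0()` is the probability that a lineage alive at age `t` has no
#' *sampled* descendant at the present; `bdp_p1()` the probability of
#' exactly one. Each extant descendant is sampled independently with
#' probability `rho`, giving initial conditions `p0(0) = 1 - rho` and
#' `p1(0) = rho`. The critical case `lambda == mu` is handled by its
#' analytic limit (`rho = 1`: `p0 = lambda t / (1 + lambda t)`,
#' `p1 = 1 / (1 + lambda t)^2`).
#'
#' @param t Age, `t >= 0`; vectorized.
#' @param lambda,mu Birth and death rates, non-negative.
#' @param rho Sampling fraction in `(0, 1]`.
#' @param log Return log probabilities?
#' @return Probability (or log probability) vector.
#' @examples
#' bdp_p0(1, 1, 0.5)  # ~0.282
#' bdp_p1(1, 1, 0.5)  # ~0.312
#' @export
bdp_p0 <- function(t, lambda, mu, rho = 1, log = FALSE) {
  check_bdp_args(t, lambda, mu, rho)
  r <- lambda - mu
  l1pa <- log1p_rho_A_const(t, lambda, mu, rho)
  one_minus_p0 <- exp(log(rho) + r * t - l1pa)
  p0 <- 1 - pmin(one_minus_p0, 1)
  if (log) base::log(p0) else p0
}

#' @rdname bdp_p0
#' @export
bdp_p1 <- function(t, lambda, mu, rho = 1, log = FALSE) {
  check_bdp_args(t, lambda, mu, rho)
  r <- lambda - mu
  lp <- log(rho) + r * t - 2 * log1p_rho_A_const(t, lambda, mu, rho)
  if (log) lp else exp(lp)
}

check_bdp_args <- function(t, lambda, mu, rho) {
  if (any(t < 0)) abort("`t` must be >= 0.", class = "bdltt_validation_error")
  check_number(lambda, "lambda", lower = 0)
  check_number(mu, "mu", lower = 0)
  check_number(rho, "rho", lower = 1e-300, upper = 1)
}

#' Generalized birth-death transition probabilities
#'
#' Transition probabilities for a birth-death process whose rates
#' \eqn{\lambda(t)}, \eqn{\mu(t)} are deterministic functions of age,
#' with sampling fraction \eqn{\rho}. Writing
#' \eqn{R(t) = \int_0^t [\lambda(s) - \mu(s)]\,ds} and
#' \eqn{A(t) = \int_0^t \lambda(s) e^{R(s)}\,ds}, the solutions of the
#' backward ODEs with initial conditions \eqn{p_0(0) = 1-\rho},
#' \eqn{p_1(0) = \rho} are
#' \deqn{p_0(t) = 1 - \frac{\rho e^{R(t)}}{1 + \rho A(t)}, \qquad
#'       p_1(t) = \frac{\rho e^{R(t)}}{(1 + \rho A(t))^2}.}
#' For piecewise-constant models `R` and `A` are exact interval sums; for
#' tabulated models they use adaptive quadrature. With complete sampling
#' `p1` factorizes as \eqn{(1 - p_0)(1 - \eta_t)} with
#' \eqn{\eta_t = A/(1 + A)} (Kendall's form); [gbdp_eta()] exposes
#' \eqn{\eta_t}, generalized to \eqn{\rho A/(1+\rho A)} under sampling.
#'
#' @param t Age vector, `t >= 0`.
#' @param model A [rate model][make_constant_model].
#' @param log Return log probabilities?
#' @return Probability (or log probability) vector.
#' @examples
#' m <- make_piecewise_model(1, c(1, 0.5), c(0.2, 0.1), rho = 0.8)
#' gbdp_p0(c(0, 0.5, 2), m)
#' @export
gbdp_p0 <- function(t, model, log = FALSE) {
  stop_not_model(model)
  if (any(t < 0)) abort("`t` must be >= 0.", class = "bdltt_validation_error")
  if (model$kind == "constant") {
    return(bdp_p0(t, model$lambda, model$mu, model$rho, log = log))
  }
  R <- cum_lambda(model, t) - cum_mu(model, t)
  A <- cum_A(model, t)
  p0 <- 1 - pmin(model$rho * exp(R) / (1 + model$rho * A), 1)
  if (log) base::log(p0) else p0
}

#' @rdname gbdp_p0
#' @export
gbdp_p1 <- function(t, model, log = FALSE) {
  stop_not_model(model)
  if (any(t < 0)) abort("`t` must be >= 0.", class = "bdltt_validation_error")
  if (model$kind == "constant") {
    return(bdp_p1(t, model$lambda, model$mu, model$rho, log = log))
  }
  R <- cum_lambda(model, t) - cum_mu(model, t)
  lp <- log(model$rho) + R - 2 * log1p(model$rho * cum_A(model, t))
  if (log) lp else exp(lp)
}

#' @rdname gbdp_p0
#' @export
gbdp_eta <- function(t, model) {
  stop_not_model(model)
  rA <- model$rho * cum_A(model, t)
  rA / (1 + rA)
}

#' @rdname gbdp_p0
#' @return `transition_probs()` returns a tibble with columns `t`, `p0`,
#'   `p1`, `eta`.
#' @export
transition_probs <- function(t, model) {
  tibble(t = t, p0 = gbdp_p0(t, model), p1 = gbdp_p1(t, model),
         eta = gbdp_eta(t, model))
}

# Probability of n sampled descendants for a single lineage after time t
# under the (generalized) BDP: geometric conditional on survival,
# P(n) = (1 - p0)(1 - eta) eta^{n-1}, n >= 1. Used for conditioning the
# constant-rate likelihood on n.
gbdp_log_prob_n <- function(n, t, model) {
  if (any(n < 1)) abort("`n` must be >= 1.", class = "bdltt_validation_error")
  eta <- gbdp_eta(t, model)
  log1p(-gbdp_p0(t, model)) + log1p(-eta) +
    ifelse(n == 1, 0, (n - 1) * log(eta))
}
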