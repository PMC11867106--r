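#' The pulled speciation rate and model congruence
#'
#' Any generalized birth-death process (GBDP) assigns the same likelihood
#' to lineage-through-time data as a pure-birth (generalized Yule)
#' process with the *pulled speciation rate*
#' \deqn{\lambda_p(t) = \lambda(t)\,[1 - p_0(t)],}
#' so the two models are congruent and cannot be told apart by such data.
#' `pulled_rate()` builds that generalized Yule process from a rate
#' model. The cumulative pulled rate has the exact representation
#' \eqn{\Lambda_p(t) = \log[1 + \rho A(t)]} with
#' \eqn{A(t) = \int_0^t \lambda(s) e^{R(s)} ds}
#' (differentiating recovers \eqn{\lambda(t)[1 - p_0(t)]}), which for
#' piecewise-constant models involves no quadrature at all. For a
#' constant-rate completely sampled model the familiar closed form
#' \deqn{\Lambda_p(t) = (\lambda-\mu) t +
#'   \log\frac{\lambda - e^{-(\lambda-\mu)t}\mu}{\lambda-\mu}}
#' is exposed as `$Lambda_p_closed` and agrees with the general route.
#'
#' @param model A [rate model][make_constant_model].
#' @return An object of class `pulled_rate`: a list with functions
#'   `lambda_p(t)` and `Lambda_p(t)`, the source `model`, and (constant
#'   rates, complete sampling only) `Lambda_p_closed(t)`.
#' @examples
#' pr <- pulled_rate(make_constant_model(1, 0.5))
#' pr$lambda_p(1) # ~0.7176
#' @export
pulled_rate <- function(model) {
  stop_not_model(model)
  lambda_p <- function(t) birth_rate(model, t) * (1 - gbdp_p0(t, model))
  Lambda_p <- function(t) log1p(model$rho * cum_A(model, t))
  out <- list(lambda_p = lambda_p, Lambda_p = Lambda_p, model = model)
  if (model$kind == "constant" && model$rho == 1 &&
      !is_critical(model$lambda, model$mu)) {
    out$Lambda_p_closed <- function(t) {
      r <- model$lambda - model$mu
      r * t + log((model$lambda - exp(-r * t) * model$mu) / r)
    }
  }
  structure(out, class = "pulled_rate")
}

#' @export
print.pulled_rate <- function(x, ...) {
  cat("<pulled_rate> generalized Yule process congruent to:\n")
  print(x$model)
  invisible(x)
}

#' Numerical verification of the congruence identity
#'
#' The congruence of a GBDP with its pulled-rate Yule process rests on
#' the pointwise identity
#' \eqn{\lambda(t)\,p_1(t) = \lambda_p(t)\,e^{-\Lambda_p(t)}};
#' `congruence_deviation()` evaluates both sides on a grid of ages and
#' reports their difference (contract: at most about `1e-8` in rate
#' units for any valid model). `likelihood_congruence_check()` performs
#' the end-to-end version: the absolute difference between the GBDP
#' log-likelihood of a dataset and the generalized-Yule log-likelihood
#' under the pulled rate (contract: about `1e-6` in log units).
#'
#' @param model A [rate model][make_constant_model].
#' @param grid Vector of non-negative ages.
#' @param data LTT data with a stem age.
#' @return `congruence_deviation()`: a tibble with columns `t`,
#'   `lambda`, `mu`, `lambda_p`, `Lambda_p`, `bdp_side`, `gyp_side`,
#'   `deviation` (take `max(.$deviation)` for the summary).
#'   `likelihood_congruence_check()`: a single non-negative double.
#' @examples
#' dev <- congruence_deviation(make_constant_model(1, 0.5), seq(0, 10, 0.1))
#' max(dev$deviation)
#' @export
congruence_deviation <- function(model, grid) {
  stop_not_model(model)
  if (any(grid < 0)) {
    abort("`grid` ages must be >= 0.", class = "bdltt_validation_error")
  }
  pr <- pulled_rate(model)
  bdp_side <- birth_rate(model, grid) * gbdp_p1(grid, model)
  gyp_side <- pr$lambda_p(grid) * exp(-pr$Lambda_p(grid))
  tibble(
    t = grid,
    lambda = birth_rate(model, grid),
    mu = death_rate(model, grid),
    lambda_p = pr$lambda_p(grid),
    Lambda_p = pr$Lambda_p(grid),
    bdp_side = bdp_side,
    gyp_side = gyp_side,
    deviation = abs(bdp_side - gyp_side)
  )
}

#' @rdname congruence_deviation
#' @export
likelihood_congruence_check <- function(data, model) {
  data <- as_ltt(data)
  stop_not_model(model)
  abs(gbdp_loglik(data, model) - gyp_loglik(data, pulled_rate(model)))
}

#' Congruent constant-rate parameterizations
#'
#' Within the congruence class of a constant-rate model with incomplete
#' sampling sits a completely sampled model with rescaled rates
#' \eqn{\lambda' = \rho\lambda}, \eqn{\mu' = \mu - (1-\rho)\lambda}
#' (valid whenever \eqn{\mu' \ge 0}): both share the same pulled
#' speciation rate and hence the same likelihood for all LTT data. This
#' is the constant-rate corner of the congruence class; enumeration of
#' general congruence classes is out of scope.
#'
#' @param model A constant-kind [rate model][make_constant_model] with
#'   `rho < 1`.
#' @return The congruent completely sampled `rate_model`, or an error if
#'   the implied death rate is negative.
#' @export
congruent_complete_sampling_model <- function(model) {
  stop_not_model(model)
  if (model$kind != "constant") {
    abort("only constant-rate models are supported here.",
      class = "bdltt_validation_error")
  }
  mu2 <- model$mu - (1 - model$rho) * model$lambda
  if (mu2 < 0) {
    abort("no valid congruent complete-sampling model: implied death rate < 0.",
      class = "bdltt_validation_error")
  }
  make_constant_model(model$rho * model$lambda, mu2, 1)
}
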