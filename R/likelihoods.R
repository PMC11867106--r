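#' Yule-process likelihoods of speciation times
#'
#' Log-densities of the rank-ordered node ages `t1 > ... > t(n-1)` of a
#' reconstructed tree under a constant-rate pure-birth process, under the
#' conditioning schemes in use in the literature. The schemes differ and
#' none is a silent default: choose the function that matches how your
#' data were ascertained.
#'
#' * `yule_joint_loglik()`: joint density of the ages *and* the tip count
#'   given the stem age,
#'   \eqn{f(t, n \mid t_0) = (n-1)!\,\lambda^{n-1} e^{-\lambda \sum_{i=0}^{n-1} t_i}}
#'   (the sum includes the stem age).
#' * `yule_loglik_given_stem()`: conditional on the tip count and stem
#'   age. Two printed routes exist — dividing the joint by the tip-count
#'   probability (`route = "conditional"`), or the order-statistics form
#'   with truncated-exponential kernel
#'   \eqn{f(x) = \lambda e^{-\lambda x} / (1 - e^{-\lambda t_0})}
#'   (`route = "order_stats"`); they are algebraically identical.
#' * `yule_loglik_given_root()`: conditional on the tip count and the
#'   root age `t1` (taken as the oldest supplied age), the scheme most
#'   natural for observed phylogenies since the stem is unobservable.
#'
#' Data impossible under the model (an age at or above the conditioning
#' age, births with `lambda = 0`) yield `-Inf` rather than an error, so
#' optimizers may probe the boundary freely. Combinatorial factors use
#' `lgamma`.
#'
#' @param data LTT data ([ltt_data()]); the stem-age attribute is
#'   required by the stem-conditioned schemes.
#' @param lambda Birth rate, `>= 0`.
#' @param route For `yule_loglik_given_stem()`, which printed algebraic
#'   form to evaluate (they agree to rounding error).
#' @return Log-density (natural log), a single double.
#' @examples
#' x <- ltt_data(c(2, 1), stem_age = 3)
#' yule_joint_loglik(x, 0.5) # log 2 + 2 log 0.5 - 3
#' @export
yule_joint_loglik <- function(data, lambda) {
  data <- as_ltt(data)
  t0 <- require_stem(data)
  check_number(lambda, "lambda", lower = 0)
  ages <- node_ages(data)
  n <- n_tips(data)
  if (any(ages >= t0)) return(-Inf)
  if (lambda == 0 && n >= 2) return(-Inf)
  lgamma(n) + (n - 1) * log(lambda) - lambda * (t0 + sum(ages))
}

#' Marginal tip-count probabilities under the Yule process
#'
#' `yule_prob_n_given_stem()` is the probability of `n` tips at the
#' present for a process started with one lineage at stem age `t0`
#' (identical to [yule_pn()] evaluated at `t0`).
#' `yule_prob_n_given_root()` is the probability of `n` tips given the
#' root age `t1`, i.e. the convolution
#' \eqn{\sum_{i=1}^{n-1} p_i(t_1) p_{n-i}(t_1) =
#' (n-1) e^{-2\lambda t_1}(1 - e^{-\lambda t_1})^{n-2}}, which requires
#' `n >= 2`.
#'
#' @param n Tip count.
#' @param t0,t1 Stem age / root age.
#' @inheritParams yule_pn
#' @return Probability (or log probability).
#' @export
yule_prob_n_given_stem <- function(n, t0, lambda, log = FALSE) {
  yule_pn(n, t0, lambda, log = log)
}

#' @rdname yule_prob_n_given_stem
#' @export
yule_prob_n_given_root <- function(n, t1, lambda, log = FALSE) {
  if (any(n < 2)) {
    abort("`n` must be >= 2: a root subtends two surviving lineages.",
      class = "bdltt_validation_error")
  }
  if (any(t1 < 0) || lambda < 0) {
    abort("need `t1 >= 0` and `lambda >= 0`.", class = "bdltt_validation_error")
  }
  lt <- lambda * t1
  lp <- log(n - 1) - 2 * lt + ifelse(n == 2, 0, (n - 2) * log1mexp(lt))
  if (log) lp else exp(lp)
}

#' @rdname yule_joint_loglik
#' @export
yule_loglik_given_stem <- function(data, lambda,
                                   route = c("conditional", "order_stats")) {
  route <- match.arg(route)
  data <- as_ltt(data)
  t0 <- require_stem(data)
  check_number(lambda, "lambda", lower = 0)
  ages <- node_ages(data)
  n <- n_tips(data)
  if (any(ages >= t0)) return(-Inf)
  if (lambda == 0) return(if (n >= 2) -Inf else 0)
  if (route == "conditional") {
    yule_joint_loglik(data, lambda) -
      yule_prob_n_given_stem(n, t0, lambda, log = TRUE)
  } else {
    # order statistics of n-1 iid truncated-exponential kernel draws
    lgamma(n) +
      sum(log(lambda) - lambda * ages - log1mexp(lambda * t0))
  }
}

#' @rdname yule_joint_loglik
#' @export
yule_loglik_given_root <- function(data, lambda) {
  data <- as_ltt(data)
  check_number(lambda, "lambda", lower = 0)
  ages <- node_ages(data)
  n <- n_tips(data)
  if (n < 2) {
    abort("root conditioning needs at least 2 tips.",
      class = "bdltt_validation_error")
  }
  if (lambda == 0) return(if (n > 2) -Inf else 0)
  t1 <- ages[1]
  lgamma(n - 1) + (n - 1) * log(lambda) - lambda * sum(ages) +
    2 * lambda * t1 -
    (if (n == 2) 0 else (n - 2) * log1mexp(lambda * t1))
}

#' Likelihoods under time-varying-rate processes
#'
#' `gbdp_loglik()` evaluates the joint density of node ages and tip
#' count given the stem age under a generalized birth-death process,
#' \deqn{f(t, n \mid t_0) = (n-1)!\; p_1(t_0) \prod_{i=1}^{n-1}
#'   \lambda(t_i)\,p_1(t_i),}
#' with \eqn{p_1} from [gbdp_p1()] (the \eqn{(n-1)!} carries the rank
#' factors \eqn{i\lambda} of the event intensities, so values are
#' directly comparable with [yule_joint_loglik()]). `gyp_loglik()` evaluates the same
#' object for a generalized Yule (pure-birth, time-varying-rate) process
#' with birth rate \eqn{\lambda_p(t)}:
#' \deqn{e^{-\Lambda_p(t_0)} \prod_i \lambda_p(t_i) e^{-\Lambda_p(t_i)},
#'  \qquad \Lambda_p(t) = \int_0^t \lambda_p(s)\,ds.}
#' When `pulled` is the [pulled_rate()] of a GBDP the two functions
#' return identical values for all data — the models are congruent and
#' hence non-identifiable from LTT data.
#'
#' @param data LTT data with a stem age.
#' @param model A [rate model][make_constant_model].
#' @param pulled A [pulled_rate()] object, or a plain non-negative rate
#'   function of age (its cumulative integral is then obtained by
#'   quadrature).
#' @param condition_on_survival Divide by the probability
#'   \eqn{1 - p_0(t_0)} that the stem leaves at least one sampled
#'   descendant (default). A reconstructed tree is only ever observed
#'   when the stem survives to the sample, and only with this
#'   conditioning does the stem factor \eqn{p_1(t_0)/[1 - p_0(t_0)]}
#'   reduce to the pure-birth \eqn{e^{-\Lambda_p(t_0)}}, making the
#'   congruence with the pulled-rate Yule process exact. With
#'   `condition_on_survival = FALSE` the raw joint density is returned
#'   (the two coincide whenever extinction and incomplete sampling are
#'   absent).
#' @return Log-density, a single double (`-Inf` for impossible data).
#' @export
gbdp_loglik <- function(data, model, condition_on_survival = TRUE) {
  data <- as_ltt(data)
  stop_not_model(model)
  t0 <- require_stem(data)
  ages <- node_ages(data)
  if (any(ages >= t0)) return(-Inf)
  lam <- birth_rate(model, ages)
  if (any(lam == 0)) return(-Inf)
  stem_term <- gbdp_p1(t0, model, log = TRUE) -
    (if (condition_on_survival) log1p(-gbdp_p0(t0, model)) else 0)
  # lgamma(n) carries the (n-1)! ranking factor, making values directly
  # comparable with the constant-rate joint density
  lgamma(length(ages) + 1) + stem_term +
    sum(log(lam) + gbdp_p1(ages, model, log = TRUE))
}

#' @rdname gbdp_loglik
#' @export
gyp_loglik <- function(data, pulled) {
  data <- as_ltt(data)
  t0 <- require_stem(data)
  ages <- node_ages(data)
  if (any(ages >= t0)) return(-Inf)
  if (inherits(pulled, "pulled_rate")) {
    lam_p <- pulled$lambda_p
    Lam_p <- pulled$Lambda_p
  } else if (is.function(pulled)) {
    lam_p <- pulled
    Lam_p <- function(t) vapply(t, function(tt) quad(pulled, 0, tt), numeric(1))
  } else {
    abort("`pulled` must be a pulled_rate object or a rate function.",
      class = "bdltt_validation_error")
  }
  lam <- lam_p(ages)
  if (any(lam <= 0) && length(ages)) return(-Inf)
  lgamma(length(ages) + 1) - Lam_p(t0) + sum(log(lam) - Lam_p(ages))
}

#' Two-epoch Yule likelihood
#'
#' Log-likelihood of the partitioned node ages under a pure-birth process
#' with rate `lambda0` above the change point `T` and `lambda1` below it,
#' given the epoch event counts `I` and `J`:
#' \deqn{\log L = I \log\lambda_0 + J \log\lambda_1 + T I(\lambda_0 -
#'   \lambda_1) - \lambda_0 \sum_i t_i^0 - \lambda_1 \sum_j t_j^1.}
#' `form = "kernel"` (default) drops the data-only constant
#' \eqn{\log (I+J)!}; `form = "full"` includes it. Maximum-likelihood
#' estimates are invariant to the choice.
#'
#' @param data A [partition_ltt()] result (or LTT data plus `T`).
#' @param model A [two_epoch_model()]; for `two_epoch_loglik()` any
#'   `survival_p` is ignored (see [massext_loglik()] for the
#'   mass-extinction version).
#' @param T Change-point age, needed only if `data` is not yet
#'   partitioned.
#' @param form Include the factorial constant (`"full"`) or not
#'   (`"kernel"`).
#' @return Log-likelihood, a single double.
#' @examples
#' d <- partition_ltt(ltt_data(c(3, 2, 0.5, 0.25), stem_age = 4), T = 1)
#' two_epoch_loglik(d, two_epoch_model(2 / 3, 8 / 11, T = 1, t0 = 4))
#' @export
two_epoch_loglik <- function(data, model, T = NULL,
                             form = c("kernel", "full")) {
  form <- match.arg(form)
  d <- as_two_epoch(data, T %||% model$T)
  check_two_epoch_model(model)
  Tc <- attr(d, "change_point")
  t0 <- attr(d, "stem_age")
  old <- old_ages(d)
  young <- young_ages(d)
  if (any(young >= Tc) || any(old <= Tc) ||
      (!is.null(t0) && any(old >= t0))) {
    return(-Inf)
  }
  I <- length(old)
  J <- length(young)
  ll <- I * log(model$lambda0) + J * log(model$lambda1) +
    Tc * I * (model$lambda0 - model$lambda1) -
    model$lambda0 * sum(old) - model$lambda1 * sum(young)
  if (form == "full") ll <- ll + lgamma(I + J + 1)
  ll
}

check_two_epoch_model <- function(model) {
  if (!inherits(model, "two_epoch_model")) {
    abort("expected a `two_epoch_model`.", class = "bdltt_validation_error")
  }
}

# Analytic gradient of the kernel two-epoch log-likelihood, used by the
# MLE tests and exposed for optimizer diagnostics.
two_epoch_score <- function(data, model, T = NULL) {
  d <- as_two_epoch(data, T %||% model$T)
  Tc <- attr(d, "change_point")
  old <- old_ages(d)
  young <- young_ages(d)
  I <- length(old)
  J <- length(young)
  c(lambda0 = I / model$lambda0 + I * Tc - sum(old),
    lambda1 = J / model$lambda1 - I * Tc - sum(young))
}

#' Mass-extinction epoch model: survival probability and likelihood
#'
#' In the two-epoch pure-birth model with an instantaneous mass
#' extinction at age `T` (per-lineage survival probability `p`), a
#' lineage arising in the old epoch at age `t > T` leaves exactly one
#' sampled descendant with probability obtained by averaging over its
#' descendant count `m` just before the extinction, exactly one of which
#' survives and leaves one present-day descendant:
#' \deqn{p_1^*(t) = \sum_{m \ge 1} e^{-m\lambda_0 (t-T)}
#'   (e^{\lambda_0 (t-T)} - 1)^{m-1} \cdot m p (1-p)^{m-1} \cdot
#'   e^{-\lambda_1 T}
#'   = \frac{p\, e^{\lambda_0(t-T)} e^{-\lambda_1 T}}
#'          {[\,p\, e^{\lambda_0(t-T)} + 1 - p\,]^2}.}
#' The per-lineage tip-count probabilities inside the sum are evaluated
#' at the *elapsed old-epoch time* `t - T`; with that reading the
#' geometric series sums exactly to the closed form (the closed form is
#' also expressible with numerator \eqn{p e^{\lambda_0 (t+T) - \lambda_1 T}}
#' and denominator \eqn{[e^{\lambda_0 T}(p-1) - e^{\lambda_0 t} p]^2},
#' which is the same quantity after multiplying through by
#' \eqn{e^{-2\lambda_0 T}}). As \eqn{p \to 1} with
#' \eqn{\lambda_0 = \lambda_1 = \lambda}, \eqn{p_1^*(t) \to e^{-\lambda t}}.
#'
#' `massext_loglik()` is the corresponding log-likelihood of partitioned
#' node ages,
#' \deqn{\log L = I\log\lambda_0 + \sum_i \log p_1^*(t_i^0)
#'   + J\log\lambda_1 - \lambda_1 \sum_j t_j^1}
#' (`form = "full"` adds \eqn{\log(I+J)!}); its `p -> 1` limit is the
#' plain two-epoch likelihood.
#'
#' @param t Age(s) in the old epoch, `t > T`.
#' @param model A [two_epoch_model()] with `survival_p` set.
#' @param log Return the log probability?
#' @param method `"closed"` evaluates the closed form; `"series"` sums
#'   the defining series until the geometric tail mass is below `1e-14`
#'   (the two agree to near machine precision and the series serves as an
#'   internal cross-check).
#' @inheritParams two_epoch_loglik
#' @return `massext_p1star()`: probability vector; `massext_loglik()`:
#'   a single double.
#' @examples
#' m <- two_epoch_model(0.1, 0.1, T = 1, t0 = 3, survival_p = 0.5)
#' massext_p1star(2, m) # ~0.45129
#' @export
massext_p1star <- function(t, model, log = FALSE,
                           method = c("closed", "series")) {
  method <- match.arg(method)
  check_two_epoch_model(model)
  p <- model$survival_p
  if (is.null(p)) {
    abort("`model$survival_p` must be set for the mass-extinction model.",
      class = "bdltt_validation_error")
  }
  if (any(t <= model$T)) {
    abort("`t` must exceed `T`: the lineage must arise in the old epoch.",
      class = "bdltt_validation_error")
  }
  tau <- t - model$T
  if (method == "closed") {
    # denominator p e^{lambda0 tau} + (1 - p), in log space
    ld <- if (p == 1) {
      model$lambda0 * tau
    } else {
      log1pexp(log(p) + model$lambda0 * tau - log1p(-p)) + log1p(-p)
    }
    lp <- log(p) + model$lambda0 * tau - model$lambda1 * model$T - 2 * ld
    if (log) lp else exp(lp)
  } else {
    vapply(tau, function(tt) {
      a <- exp(-model$lambda0 * tt)
      s <- 0
      m <- 1
      repeat {
        pm <- a * (1 - a)^(m - 1)
        term <- pm * m * p * (1 - p)^(m - 1)
        s <- s + term
        # remaining geometric tail bound: sum_{k>m} k z^{k-1} * a * p
        z <- (1 - a) * (1 - p)
        tail_bound <- if (z > 0) a * p * (m + 1) * z^m / (1 - z)^2 else 0
        if (tail_bound < 1e-14 || m > 1e6) break
        m <- m + 1
      }
      out <- s * exp(-model$lambda1 * model$T)
      if (log) base::log(out) else out
    }, numeric(1))
  }
}

#' @rdname massext_p1star
#' @export
massext_loglik <- function(data, model, T = NULL,
                           form = c("kernel", "full")) {
  form <- match.arg(form)
  check_two_epoch_model(model)
  d <- as_two_epoch(data, T %||% model$T)
  Tc <- attr(d, "change_point")
  t0 <- attr(d, "stem_age")
  old <- old_ages(d)
  young <- young_ages(d)
  if (any(young >= Tc) || any(old <= Tc) ||
      (!is.null(t0) && any(old >= t0))) {
    return(-Inf)
  }
  I <- length(old)
  J <- length(young)
  ll <- I * log(model$lambda0) + J * log(model$lambda1) -
    model$lambda1 * sum(young) +
    (if (I) sum(massext_p1star(old, model, log = TRUE)) else 0)
  if (form == "full") ll <- ll + lgamma(I + J + 1)
  ll
}

#' Constant-rate BDP likelihood conditioned on the tip count
#'
#' With complete sampling, the density of node ages conditional on the
#' tip count and the stem age is
#' \deqn{f(t \mid t_0, n) = (n-1)! \prod_{i=1}^{n-1}
#'   \frac{\lambda\,p_1(t_i)}{\eta_{t_0}},}
#' using the geometric tip-count law
#' \eqn{P(n \mid t_0) = (1-p_0)(1-\eta)\eta^{n-1}}. This conditional
#' likelihood is invariant under swapping `lambda` and `mu` — a
#' label-switching non-identifiability — even though the two processes
#' are biologically very different. [label_switch_check()] returns the
#' numerical deviation \eqn{|\ell(\lambda,\mu) - \ell(\mu,\lambda)|},
#' which is zero to rounding error; the *joint* (unconditioned)
#' likelihood does not share the symmetry.
#'
#' @param data LTT data with a stem age.
#' @param lambda,mu Constant birth and death rates.
#' @return `bdp_loglik_given_stem()`: log-density;
#'   `label_switch_check()`: absolute deviation between the two
#'   parameter orders.
#' @export
bdp_loglik_given_stem <- function(data, lambda, mu) {
  data <- as_ltt(data)
  t0 <- require_stem(data)
  model <- make_constant_model(lambda, mu, 1)
  ages <- node_ages(data)
  n <- n_tips(data)
  if (any(ages >= t0)) return(-Inf)
  if (n == 1) return(0)
  if (lambda == 0) return(-Inf)
  eta0 <- gbdp_eta(t0, model)
  lgamma(n) + sum(log(lambda) + bdp_p1(ages, lambda, mu, log = TRUE)) -
    (n - 1) * log(eta0)
}

#' @rdname bdp_loglik_given_stem
#' @export
label_switch_check <- function(data, lambda, mu) {
  abs(bdp_loglik_given_stem(data, lambda, mu) -
      bdp_loglik_given_stem(data, mu, lambda))
}
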