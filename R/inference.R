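#' Closed-form maximum likelihood for the two-epoch Yule model
#'
#' With `I` speciation events at ages `t_i^0` in the old epoch and `J` at
#' ages `t_j^1` in the young epoch, the two-epoch Yule log-likelihood is
#' maximized at
#' \deqn{\hat\lambda_0 = \frac{I}{\sum_i t_i^0 - I\,T}, \qquad
#'       \hat\lambda_1 = \frac{J}{\sum_j t_j^1 + I\,T},}
#' with Fisher information
#' \eqn{F = \mathrm{diag}(I/\lambda_0^2,\; J/\lambda_1^2)} evaluated at
#' the estimates: the two rates are orthogonal and, whenever `I > 0` and
#' `J > 0`, locally identifiable. An empty epoch leaves its rate
#' locally non-identifiable: the fit is then partial and the affected
#' estimate is reported as `NA` with a flag rather than an error.
#'
#' @param data A [partition_ltt()] result, or LTT data plus `T`.
#' @param T Change-point age if `data` is not yet partitioned.
#' @return A `bdltt_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' d <- partition_ltt(ltt_data(c(3, 2, 0.5, 0.25)), T = 1)
#' two_epoch_mle(d) # lambda0 = 2/3, lambda1 = 8/11
#' @export
two_epoch_mle <- function(data, T = NULL) {
  d <- as_two_epoch(data, T)
  Tc <- attr(d, "change_point")
  old <- old_ages(d)
  young <- young_ages(d)
  I <- length(old)
  J <- length(young)
  est <- c(lambda0 = NA_real_, lambda1 = NA_real_)
  non_identifiable <- character()
  if (I > 0) {
    denom <- sum(old) - I * Tc
    if (denom <= 0) {
      abort("sum of old-epoch ages does not exceed I * T: corrupted partition.",
        class = "bdltt_validation_error")
    }
    est["lambda0"] <- I / denom
  } else {
    non_identifiable <- c(non_identifiable, "lambda0")
  }
  if (J > 0 || I > 0) {
    denom1 <- sum(young) + I * Tc
    if (J > 0) {
      est["lambda1"] <- J / denom1
    } else {
      non_identifiable <- c(non_identifiable, "lambda1")
    }
  } else {
    non_identifiable <- c(non_identifiable, "lambda1")
  }
  fisher <- diag(c(
    if (is.na(est["lambda0"])) 0 else I / est["lambda0"]^2,
    if (is.na(est["lambda1"])) 0 else J / est["lambda1"]^2
  ))
  dimnames(fisher) <- list(names(est), names(est))
  se <- ifelse(diag(fisher) > 0, sqrt(1 / diag(fisher)), NA_real_)
  ll <- if (anyNA(est)) {
    NA_real_
  } else {
    two_epoch_loglik(d, two_epoch_model(est["lambda0"], est["lambda1"],
      T = Tc, t0 = attr(d, "stem_age") %||% (max(d$age, Tc) * 2)))
  }
  new_bdltt_fit(
    estimates = est, loglik = ll, fisher = fisher, std_errors = se,
    convergence = list(status = "closed_form",
                       non_identifiable = non_identifiable),
    data_summary = list(I = I, J = J, T = Tc)
  )
}

new_bdltt_fit <- function(estimates, loglik, fisher, std_errors,
                          convergence, data_summary = list()) {
  structure(
    list(estimates = estimates, loglik = loglik, fisher = fisher,
         std_errors = setNames(std_errors, names(estimates)),
         convergence = convergence, data_summary = data_summary),
    class = "bdltt_fit"
  )
}

#' @export
print.bdltt_fit <- function(x, ...) {
  cat("<bdltt_fit>", x$convergence$status, "\n")
  df <- data.frame(estimate = x$estimates, std.error = x$std_errors)
  print(df)
  cat("log-likelihood:", format(x$loglik), "\n")
  if (length(x$convergence$non_identifiable)) {
    cat("locally non-identifiable:",
        paste(x$convergence$non_identifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Broom-style accessors for fitted models
#'
#' @param x A `bdltt_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `term`, `estimate`,
#'   `std.error`; `glance()`: a one-row tibble with the log-likelihood,
#'   epoch counts and convergence status.
#' @method tidy bdltt_fit
#' @export
tidy.bdltt_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors)
  )
}

#' @rdname tidy.bdltt_fit
#' @method glance bdltt_fit
#' @export
glance.bdltt_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    I = x$data_summary$I %||% NA_integer_,
    J = x$data_summary$J %||% NA_integer_,
    status = x$convergence$status
  )
}

#' Generic box-constrained maximum likelihood
#'
#' Quasi-Newton (`L-BFGS-B`) maximization of an arbitrary log-likelihood
#' with multi-start (log-uniform over the box, fixed sub-seeds) to cope
#' with flat ridges, and an observed-information matrix from central
#' finite differences of the objective (step
#' \eqn{\epsilon^{1/3}\max(|\theta|,1)}).
#'
#' @param loglik Function mapping a named parameter vector to a
#'   log-likelihood (may return `-Inf`).
#' @param init Named initial parameter vector; must have finite
#'   objective.
#' @param lower,upper Box constraints (vectors recycled to
#'   `length(init)`).
#' @param n_starts Number of random restarts in addition to `init`.
#' @param seed Seed for the restart draws (local to the call).
#' @return A `bdltt_fit`; non-convergence is flagged in
#'   `$convergence$status`, keeping the best point found.
#' @export
numeric_mle <- function(loglik, init, lower, upper, n_starts = 5,
                        seed = 1L) {
  npar <- length(init)
  lower <- rep_len(lower, npar)
  upper <- rep_len(upper, npar)
  f0 <- loglik(init)
  if (!is.finite(f0)) {
    abort("`loglik` must be finite at `init`.",
      class = "bdltt_validation_error")
  }
  starts <- list(init)
  if (n_starts > 1) {
    withr::with_seed(seed, {
      for (s in seq_len(n_starts - 1)) {
        lo <- pmax(lower, 1e-12)
        starts[[s + 1]] <- setNames(
          exp(runif(npar, log(lo), log(pmax(upper, lo * (1 + 1e-9))))),
          names(init)
        )
      }
    })
  }
  best <- NULL
  status <- "failed"
  for (st in starts) {
    if (!is.finite(loglik(st))) next
    res <- tryCatch(
      optim(st, loglik, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = 1000L, factr = 10,
                           pgtol = 1e-12, ndeps = rep(1e-7, npar))),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value > best$value) {
      best <- res
      status <- if (res$convergence == 0) "converged" else "not_converged"
    }
  }
  if (is.null(best)) {
    abort("optimization failed from every start.",
      class = "bdltt_optim_error")
  }
  est <- setNames(best$par, names(init))
  H <- fd_hessian(loglik, est)
  fisher <- -H
  se <- tryCatch(sqrt(diag(solve(fisher))), error = function(e) {
    rep(NA_real_, npar)
  })
  if (any(!is.finite(se))) se[!is.finite(se)] <- NA_real_
  new_bdltt_fit(
    estimates = est, loglik = best$value, fisher = fisher,
    std_errors = se,
    convergence = list(status = status, optim = best$convergence,
                       non_identifiable = character())
  )
}

# Central finite-difference Hessian.
fd_hessian <- function(f, x) {
  n <- length(x)
  h <- .Machine$double.eps^(1 / 3) * pmax(abs(x), 1)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- numeric(n)
      ei[i] <- h[i]
      ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

#' Fit the mass-extinction epoch model numerically
#'
#' Maximizes [massext_loglik()] over `(lambda0, lambda1)` with the
#' change point, stem age and survival probability held fixed (they are
#' assumed known throughout). A thin wrapper around [numeric_mle()].
#'
#' @inheritParams two_epoch_loglik
#' @param survival_p Known per-lineage survival probability at `T`.
#' @param t0 Known stem age.
#' @param lower,upper Box for both rates.
#' @inheritParams numeric_mle
#' @return A `bdltt_fit`.
#' @export
fit_massext <- function(data, T, t0, survival_p, lower = 1e-6, upper = 10,
                        n_starts = 5, seed = 1L) {
  d <- as_two_epoch(data, T)
  obj <- function(par) {
    massext_loglik(d, two_epoch_model(par[1], par[2], T = T, t0 = t0,
                                      survival_p = survival_p))
  }
  init <- two_epoch_mle(d)$estimates
  if (anyNA(init)) init[is.na(init)] <- sqrt(lower * upper)
  fit <- numeric_mle(obj, setNames(pmin(pmax(init, lower), upper),
                                   c("lambda0", "lambda1")),
                     lower = lower, upper = upper,
                     n_starts = n_starts, seed = seed)
  fit$data_summary <- list(I = attr(d, "I"), J = attr(d, "J"), T = T,
                           t0 = t0, survival_p = survival_p)
  fit
}

#' Log-likelihood surface over a rate lattice
#'
#' Evaluates the two-epoch (or, when `survival_p` is set, the
#' mass-extinction) log-likelihood on a `lambda0` by `lambda1` lattice,
#' e.g. to visualize the ridge-like uncertainty in the ancient rate. The
#' two axes typically need very different ranges: the young-epoch rate
#' is pinned down by many events while the old-epoch rate is not.
#'
#' @inheritParams fit_massext
#' @param lambda0,lambda1 Positive grid vectors for the two rates.
#' @param survival_p Optional; selects the mass-extinction likelihood.
#' @return A tibble of class `bdltt_surface` with columns `lambda0`,
#'   `lambda1`, `loglik`, and attributes recording the model setup. Use
#'   [autoplot()] for a contour view or [write_surface_tsv()] to export.
#' @export
loglik_surface <- function(data, lambda0, lambda1, T, t0,
                           survival_p = NULL) {
  d <- as_two_epoch(data, T)
  if (any(lambda0 <= 0) || any(lambda1 <= 0)) {
    abort("grid rates must be positive.", class = "bdltt_validation_error")
  }
  grid <- expand.grid(lambda0 = lambda0, lambda1 = lambda1,
                      KEEP.OUT.ATTRS = FALSE)
  ll <- purrr::map2_dbl(unname(grid$lambda0), unname(grid$lambda1),
                        function(l0, l1) {
    m <- two_epoch_model(l0, l1, T = T, t0 = t0, survival_p = survival_p)
    if (is.null(survival_p)) two_epoch_loglik(d, m) else massext_loglik(d, m)
  })
  out <- tibble(lambda0 = grid$lambda0, lambda1 = grid$lambda1, loglik = ll)
  class(out) <- c("bdltt_surface", class(out))
  attr(out, "setup") <- list(T = T, t0 = t0, survival_p = survival_p,
                             I = attr(d, "I"), J = attr(d, "J"))
  out
}

#' @rdname loglik_surface
#' @param object A `bdltt_surface`.
#' @param ... Unused.
#' @method autoplot bdltt_surface
#' @export
autoplot.bdltt_surface <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$lambda0, y = .data$lambda1, z = .data$loglik)) +
    ggplot2::geom_contour(bins = 30) +
    ggplot2::geom_point(
      data = object[which.max(object$loglik), ],
      ggplot2::aes(x = .data$lambda0, y = .data$lambda1),
      inherit.aes = FALSE, shape = 3, size = 3
    ) +
    ggplot2::labs(
      x = expression(lambda[0]), y = expression(lambda[1]),
      title = "Log-likelihood surface"
    )
}

#' Profile likelihood interval
#'
#' The set of values of one parameter whose profile log-likelihood (all
#' other parameters maximized out) lies within `cutoff` of the maximum;
#' the default `cutoff = 1.92` is the 95% chi-square(1) likelihood-ratio
#' bound. Endpoints are located by bisection; an endpoint that cannot be
#' bracketed inside the box is reported at the box edge and flagged
#' open-ended.
#'
#' @param loglik Objective as in [numeric_mle()].
#' @param mle A `bdltt_fit` for the same objective.
#' @param which Name or index of the profiled parameter.
#' @param cutoff Log-likelihood drop defining the interval.
#' @param lower,upper Box constraints for all parameters.
#' @return A one-row tibble: `term`, `estimate`, `lower`, `upper`,
#'   `open_lower`, `open_upper`.
#' @export
profile_interval <- function(loglik, mle, which, cutoff = 1.92,
                             lower = 1e-8, upper = 100) {
  est <- mle$estimates
  npar <- length(est)
  lower <- rep_len(lower, npar)
  upper <- rep_len(upper, npar)
  w <- if (is.character(which)) match(which, names(est)) else as.integer(which)
  if (is.na(w)) {
    abort("unknown parameter in `which`.", class = "bdltt_validation_error")
  }
  prof <- function(theta) {
    if (npar == 1L) return(loglik(setNames(theta, names(est))))
    others <- setdiff(seq_len(npar), w)
    obj <- function(po) {
      full <- numeric(npar)
      full[w] <- theta
      full[others] <- po
      loglik(setNames(full, names(est)))
    }
    if (length(others) == 1L) {
      optimize(obj, lower = lower[others], upper = upper[others],
               maximum = TRUE, tol = 1e-9)$objective
    } else {
      optim(est[others], obj, method = "L-BFGS-B",
            lower = lower[others], upper = upper[others],
            control = list(fnscale = -1))$value
    }
  }
  ll_max <- mle$loglik
  target <- function(theta) prof(theta) - (ll_max - cutoff)
  root_between <- function(a, b) {
    uniroot(target, lower = a, upper = b, tol = 1e-10)$root
  }
  th <- est[w]
  # lower endpoint
  open_lower <- FALSE
  if (target(lower[w]) > 0) {
    lo <- lower[w]
    open_lower <- TRUE
  } else {
    lo <- root_between(lower[w], th)
  }
  open_upper <- FALSE
  if (target(upper[w]) > 0) {
    hi <- upper[w]
    open_upper <- TRUE
  } else {
    hi <- root_between(th, upper[w])
  }
  tibble(
    term = names(est)[w] %||% as.character(w),
    estimate = unname(th), lower = lo, upper = hi,
    open_lower = open_lower, open_upper = open_upper
  )
}
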