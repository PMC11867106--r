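#' Lineage-through-time (LTT) data
#'
#' The rank-ordered internal-node (speciation) ages of an ultrametric
#' reconstructed tree, `t1 > t2 > ... > t(n-1)` for a tree with `n` tips,
#' optionally together with the stem age `t0 > t1` at which the process
#' started with a single lineage. Under all models in this package the
#' tree topology carries no information, so these ages are the sufficient
#' statistic for every likelihood.
#'
#' Stored as a tibble with columns `rank` (1 = oldest) and `age`, plus a
#' `stem_age` attribute. Ties among ages are kept in their input order
#' (they are a measure-zero event under every model here).
#'
#' @param ages Vector of positive node ages (any order; sorted descending).
#' @param stem_age Optional stem age, strictly older than all node ages.
#' @return A tibble of class `ltt` with columns `rank`, `age`.
#' @examples
#' x <- ltt_data(c(0.5, 2, 1), stem_age = 3)
#' n_tips(x)
#' @export
ltt_data <- function(ages, stem_age = NULL) {
  ages <- as.numeric(ages)
  if (anyNA(ages) || any(ages <= 0) || any(!is.finite(ages))) {
    abort("node ages must be finite and strictly positive.",
      class = "bdltt_validation_error")
  }
  ages <- sort(ages, decreasing = TRUE, method = "radix") # stable for ties
  if (!is.null(stem_age)) {
    check_number(stem_age, "stem_age", lower = 0)
    if (length(ages) && stem_age <= ages[1]) {
      abort("`stem_age` must exceed the root age (oldest node age).",
        class = "bdltt_validation_error")
    }
  }
  out <- tibble(rank = seq_along(ages), age = ages)
  class(out) <- c("ltt", class(out))
  attr(out, "stem_age") <- stem_age
  out
}

#' @rdname ltt_data
#' @param x An `ltt` object (or for `as_ltt()` anything with an `age`
#'   column or coercible to numeric ages).
#' @export
as_ltt <- function(x, stem_age = NULL) {
  if (inherits(x, "ltt")) {
    if (!is.null(stem_age)) attr(x, "stem_age") <- stem_age
    return(x)
  }
  if (is.data.frame(x)) {
    if (!"age" %in% names(x)) {
      abort("data frame input must have an `age` column.",
        class = "bdltt_validation_error")
    }
    return(ltt_data(x$age, stem_age = stem_age %||% attr(x, "stem_age")))
  }
  ltt_data(x, stem_age = stem_age)
}

#' @rdname ltt_data
#' @export
n_tips <- function(x) {
  x <- as_ltt(x)
  if (nrow(x) == 0L) 1L else nrow(x) + 1L
}

#' @rdname ltt_data
#' @export
stem_age <- function(x) attr(x, "stem_age")

node_ages <- function(x) as_ltt(x)$age

require_stem <- function(x) {
  t0 <- stem_age(x)
  if (is.null(t0)) {
    abort("this likelihood conditions on the stem age; supply `stem_age`.",
      class = "bdltt_validation_error")
  }
  t0
}

#' Partition LTT data at a change-point age
#'
#' Splits the node ages of an LTT dataset into an old epoch (`age > T`,
#' `I` events) and a young epoch (`age < T`, `J` events), the sufficient
#' partition for the two-epoch Yule and mass-extinction likelihoods. An
#' age exactly equal to `T` is assigned to the young epoch, consistent
#' with the rate at a change point taking the younger piece's value.
#'
#' @param data LTT data ([ltt_data()] or anything [as_ltt()] accepts).
#' @param T Change-point age, `T > 0`.
#' @return A tibble of class `two_epoch_ltt` with columns `age` and
#'   `epoch` (factor, `"old"`/`"young"`), and attributes `change_point`,
#'   `stem_age`, `I`, `J`.
#' @examples
#' partition_ltt(ltt_data(c(3, 2, 0.5, 0.25)), T = 1)
#' @export
partition_ltt <- function(data, T) {
  data <- as_ltt(data)
  check_number(T, "T", lower = 1e-300)
  ages <- node_ages(data)
  epoch <- factor(ifelse(ages > T, "old", "young"), levels = c("old", "young"))
  out <- tibble(age = ages, epoch = epoch)
  class(out) <- c("two_epoch_ltt", class(out))
  attr(out, "change_point") <- T
  attr(out, "stem_age") <- stem_age(data)
  attr(out, "I") <- sum(epoch == "old")
  attr(out, "J") <- sum(epoch == "young")
  out
}

old_ages <- function(x) x$age[x$epoch == "old"]
young_ages <- function(x) x$age[x$epoch == "young"]
epoch_counts <- function(x) c(I = attr(x, "I"), J = attr(x, "J"))

as_two_epoch <- function(data, T = NULL) {
  if (inherits(data, "two_epoch_ltt")) return(data)
  if (is.null(T)) {
    abort("supply `T` to partition plain LTT data into epochs.",
      class = "bdltt_validation_error")
  }
  partition_ltt(data, T)
}

#' Two-epoch Yule / mass-extinction epoch model
#'
#' A pure-birth process started with one lineage at stem age `t0`, with
#' speciation rate `lambda0` in the old epoch (`age > T`) switching to
#' `lambda1` in the young epoch (`age < T`). Optionally each lineage
#' alive at age `T` survives an instantaneous mass extinction
#' independently with probability `survival_p`; the complement of
#' `survival_p` is the fraction of standing diversity removed.
#'
#' @param lambda0 Speciation rate in the old epoch (`t > T`), positive.
#' @param lambda1 Speciation rate in the young epoch (`t < T`), positive.
#' @param T Change-point (and mass-extinction) age, `0 < T < t0`.
#' @param t0 Stem age at which the process starts with a single lineage.
#' @param survival_p Optional per-lineage survival probability in
#'   `(0, 1]` applied instantaneously at age `T`.
#' @return An object of class `two_epoch_model`.
#' @examples
#' # a K-Pg-like scenario: low ancient rate, 75% extinction, fast recovery
#' two_epoch_model(0.025, 0.125, T = 66, t0 = 170, survival_p = 0.25)
#' @export
two_epoch_model <- function(lambda0, lambda1, T, t0, survival_p = NULL) {
  check_number(lambda0, "lambda0", lower = 1e-300)
  check_number(lambda1, "lambda1", lower = 1e-300)
  check_number(T, "T", lower = 1e-300)
  check_number(t0, "t0", lower = 1e-300)
  if (t0 <= T) {
    abort("need `t0 > T > 0`.", class = "bdltt_validation_error")
  }
  if (!is.null(survival_p)) {
    check_number(survival_p, "survival_p", lower = 1e-300, upper = 1)
  }
  structure(
    list(lambda0 = unname(lambda0), lambda1 = unname(lambda1),
         T = unname(T), t0 = unname(t0),
         survival_p = if (!is.null(survival_p)) unname(survival_p)),
    class = "two_epoch_model"
  )
}

#' @export
print.two_epoch_model <- function(x, ...) {
  cat("<two_epoch_model>\n")
  cat(sprintf("  lambda0 = %g (ages > %g), lambda1 = %g (ages < %g)\n",
    x$lambda0, x$T, x$lambda1, x$T))
  cat(sprintf("  stem age t0 = %g\n", x$t0))
  if (!is.null(x$survival_p)) {
    cat(sprintf("  mass extinction at T = %g, survival probability p = %g\n",
      x$T, x$survival_p))
  }
  invisible(x)
}

# The pure-birth piecewise rate model underlying a two-epoch model
# (the mass-extinction event, if any, is handled by the simulator and
# the dedicated likelihood, not by the rate functions).
as_rate_model <- function(x) {
  if (is_rate_model(x)) return(x)
  if (inherits(x, "two_epoch_model")) {
    return(make_piecewise_model(x$T, c(x$lambda1, x$lambda0), c(0, 0)))
  }
  abort("cannot interpret object as a rate model.",
    class = "bdltt_validation_error")
}
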