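test_that("yule joint likelihood matches its term-by-term construction", {
  x <- ltt_data(c(2, 1), stem_age = 3)
  expect_equal(yule_joint_loglik(x, 0.5), log(2) + 2 * log(0.5) - 3)
  # single lineage: just the survival factor
  x1 <- ltt_data(numeric(), stem_age = 4)
  expect_equal(yule_joint_loglik(x1, 0.3), -0.3 * 4)
  # births are impossible at lambda = 0
  expect_identical(yule_joint_loglik(x, 0), -Inf)
  # the container itself refuses ages at or above the stem
  expect_error(ltt_data(c(3.5, 1), stem_age = 3),
               class = "bdltt_validation_error")
})

test_that("tip-count probabilities agree between formulations", {
  # stem-conditioned law is the transition probability itself
  for (n in c(1, 2, 7)) {
    expect_equal(yule_prob_n_given_stem(n, 2.3, 0.7), yule_pn(n, 2.3, 0.7))
  }
  # root-conditioned closed form equals the explicit convolution
  t1 <- 1.7
  lam <- 0.6
  for (n in c(2, 3, 10, 50)) {
    conv <- sum(yule_pn(1:(n - 1), t1, lam) * yule_pn(n - 1:(n - 1), t1, lam))
    expect_equal(yule_prob_n_given_root(n, t1, lam), conv, tolerance = 1e-12)
  }
  expect_equal(yule_prob_n_given_root(2, t1, lam), exp(-2 * lam * t1))
  expect_error(yule_prob_n_given_root(1, 1, 1), class = "bdltt_validation_error")
  # normalization over n >= 2
  p <- yule_prob_n_given_root(2:2000, 0.8, 0.9)
  expect_equal(sum(p), 1, tolerance = 1e-10)
})

test_that("both printed routes to the stem-conditioned density agree", {
  set.seed(23)
  for (rep in 1:25) {
    t0 <- runif(1, 1, 10)
    n <- sample(2:30, 1)
    lam <- runif(1, 0.05, 2)
    x <- ltt_data(runif(n - 1, 0, t0), stem_age = t0)
    a <- yule_loglik_given_stem(x, lam, route = "conditional")
    b <- yule_loglik_given_stem(x, lam, route = "order_stats")
    expect_equal(a, b, tolerance = 1e-12)
    # definition of conditioning
    expect_equal(a, yule_joint_loglik(x, lam) -
                   yule_prob_n_given_stem(n, t0, lam, log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("the truncated-exponential kernel is a proper density", {
  lam <- 0.8
  t0 <- 3
  total <- stats::integrate(function(x) lam * exp(-lam * x) / (1 - exp(-lam * t0)),
                            0, t0, rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("stem-conditioned density integrates to 1 (Monte-Carlo, n = 4)", {
  set.seed(29)
  t0 <- 2
  lam <- 0.9
  n <- 4
  nrep <- 20000
  u <- matrix(runif(nrep * (n - 1), 0, t0), nrep)
  vals <- apply(u, 1, function(r) {
    exp(yule_loglik_given_stem(ltt_data(r, stem_age = t0), lam))
  })
  vals <- vals * t0^(n - 1) / factorial(n - 1)
  est <- mean(vals)
  se <- sd(vals) / sqrt(nrep)
  expect_lt(abs(est - 1), 3 * se)
})

test_that("root-conditioned density follows the conditioning identity", {
  set.seed(31)
  for (rep in 1:10) {
    t1 <- runif(1, 1, 4)
    n <- sample(3:20, 1)
    lam <- runif(1, 0.2, 1.5)
    ages <- c(t1, runif(n - 2, 0, t1))
    x <- ltt_data(ages)
    joint_no_stem <- lgamma(n) + (n - 1) * log(lam) - lam * sum(ages)
    expect_equal(yule_loglik_given_root(x, lam),
                 joint_no_stem - yule_prob_n_given_root(n, t1, lam, log = TRUE),
                 tolerance = 1e-12)
  }
  # n = 2: the younger-age product is empty; only the root terms remain
  x2 <- ltt_data(1.3)
  expect_equal(yule_loglik_given_root(x2, 0.7), log(0.7) + 0.7 * 1.3)
})

test_that("younger ages under root conditioning are truncated-exponential", {
  # simulate the root-conditioned process as two independent stems of
  # age t1 and compare the pooled younger node ages with the kernel law
  set.seed(37)
  t1 <- 1
  lam <- 1
  n <- 6
  m <- make_constant_model(lam, 0, 1)
  pooled <- c()
  reps <- 0
  while (reps < 400) {
    s1 <- simulate_forward(m, t1)
    s2 <- simulate_forward(m, t1)
    if (s1$n_sampled + s2$n_sampled != n) next
    reps <- reps + 1
    ages <- c(if (s1$n_sampled > 1) ltt_from_tree(s1)$age,
              if (s2$n_sampled > 1) ltt_from_tree(s2)$age)
    pooled <- c(pooled, ages)
  }
  ks <- stats::ks.test(pooled, function(q) trunc_exp_cdf(q, lam, t1))
  expect_gt(ks$p.value, 0.01)
})

test_that("gbdp likelihood nests the Yule likelihood and handles zero rates", {
  x <- ltt_data(c(2, 1), stem_age = 3)
  m <- make_constant_model(0.5, 0, 1)
  expect_equal(gbdp_loglik(x, m), yule_joint_loglik(x, 0.5), tolerance = 1e-12)
  # a zero birth rate at an observed age kills the likelihood
  mz <- make_piecewise_model(1.5, c(0.5, 0), c(0, 0), 1)
  expect_identical(gbdp_loglik(x, mz), -Inf)
})

test_that("gyp likelihood nests the Yule likelihood and handles edge cases", {
  x <- ltt_data(c(2, 1), stem_age = 3)
  expect_equal(gyp_loglik(x, function(t) rep(0.5, length(t))),
               yule_joint_loglik(x, 0.5), tolerance = 1e-8)
  x0 <- ltt_data(numeric(), stem_age = 3)
  expect_equal(gyp_loglik(x0, function(t) rep(0.5, length(t))), -1.5,
               tolerance = 1e-8)
})

test_that("two-epoch likelihood nests the single-rate Yule kernel", {
  d <- partition_ltt(ltt_data(c(3, 2, 0.5, 0.25), stem_age = 4), T = 1)
  lam <- 0.6
  m <- two_epoch_model(lam, lam, T = 1, t0 = 4)
  # with equal rates the kernel is I+J draws from one exponential tilt
  expect_equal(two_epoch_loglik(d, m),
               4 * log(lam) - lam * sum(c(3, 2, 0.5, 0.25)),
               tolerance = 1e-12)
  # full form differs from the kernel by log (I+J)! only
  expect_equal(two_epoch_loglik(d, m, form = "full") - two_epoch_loglik(d, m),
               lgamma(5), tolerance = 1e-12)
  # epoch violations are impossible data
  bad <- partition_ltt(ltt_data(c(3, 0.5)), T = 1)
  attr(bad, "change_point") <- 4 # corrupt: old age now below T
  expect_identical(two_epoch_loglik(bad, m), -Inf)
})

test_that("analytic score vanishes at the closed-form MLE", {
  d <- partition_ltt(ltt_data(c(3, 2, 0.5, 0.25), stem_age = 4), T = 1)
  m <- two_epoch_model(2 / 3, 8 / 11, T = 1, t0 = 4)
  expect_equal(unname(bdltt:::two_epoch_score(d, m)), c(0, 0), tolerance = 1e-12)
  # finite-difference check of the score itself
  h <- 1e-6
  fd0 <- (two_epoch_loglik(d, two_epoch_model(2 / 3 + h, 8 / 11, 1, 4)) -
            two_epoch_loglik(d, two_epoch_model(2 / 3 - h, 8 / 11, 1, 4))) / (2 * h)
  expect_equal(fd0, 0, tolerance = 1e-5)
})

test_that("an empty old epoch leaves lambda0 out of the likelihood", {
  d <- partition_ltt(ltt_data(c(0.5, 0.25), stem_age = 4), T = 1)
  m1 <- two_epoch_model(0.1, 0.7, T = 1, t0 = 4)
  m2 <- two_epoch_model(5.0, 0.7, T = 1, t0 = 4)
  expect_equal(two_epoch_loglik(d, m1), two_epoch_loglik(d, m2))
})

test_that("mass-extinction survival probability: closed form equals its series", {
  grid <- expand.grid(tau = c(0.2, 1, 3, 8), T = c(0.5, 2),
                      l0 = c(0.05, 0.3), l1 = c(0.1, 0.8), p = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- two_epoch_model(g$l0, g$l1, T = g$T, t0 = g$T + 10,
                         survival_p = g$p)
    t <- g$T + g$tau
    expect_equal(massext_p1star(t, m), massext_p1star(t, m, method = "series"),
                 tolerance = 1e-10)
  }
  m <- two_epoch_model(0.1, 0.1, T = 1, t0 = 3, survival_p = 0.5)
  expect_equal(massext_p1star(2, m), 0.451290, tolerance = 1e-5)
  expect_error(massext_p1star(0.5, m), class = "bdltt_validation_error")
})

test_that("p -> 1 limits recover the pure two-epoch process", {
  m <- two_epoch_model(0.3, 0.3, T = 1, t0 = 5, survival_p = 1)
  expect_equal(massext_p1star(2, m), exp(-0.3 * 2), tolerance = 1e-12)
  d <- partition_ltt(ltt_data(c(4, 2, 0.5, 0.25), stem_age = 5), T = 1)
  m_near1 <- two_epoch_model(0.4, 0.9, T = 1, t0 = 5, survival_p = 1 - 1e-8)
  m_yule <- two_epoch_model(0.4, 0.9, T = 1, t0 = 5)
  expect_equal(massext_loglik(d, m_near1), two_epoch_loglik(d, m_yule),
               tolerance = 1e-6)
})

test_that("survival probability increases with p on a mild-rate grid", {
  # monotonicity holds whenever lambda0 * (t - T) < log 2
  ps <- seq(0.05, 1, 0.05)
  for (tau in c(0.5, 2)) {
    vals <- vapply(ps, function(p) {
      massext_p1star(1 + tau,
                     two_epoch_model(0.1, 0.2, T = 1, t0 = 10, survival_p = p))
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("with no young-epoch events lambda1 enters only through the exponent", {
  d <- partition_ltt(ltt_data(c(4, 3), stem_age = 5), T = 1)
  m1 <- two_epoch_model(0.4, 0.5, T = 1, t0 = 5, survival_p = 0.5)
  m2 <- two_epoch_model(0.4, 1.5, T = 1, t0 = 5, survival_p = 0.5)
  # I = 2 lineages each contribute e^{-lambda1 T} inside p1*
  expect_equal(massext_loglik(d, m1) - massext_loglik(d, m2),
               2 * (1.5 - 0.5) * 1, tolerance = 1e-10)
})

test_that("conditioned constant-rate likelihood is symmetric in (lambda, mu)", {
  set.seed(41)
  for (rep in 1:10) {
    t0 <- runif(1, 2, 6)
    n <- sample(3:30, 1)
    x <- ltt_data(runif(n - 1, 0, t0), stem_age = t0)
    expect_lt(label_switch_check(x, 1.0, 0.5), 1e-10)
    expect_lt(label_switch_check(x, runif(1, 0.1, 2), runif(1, 0.1, 2)), 1e-10)
    expect_identical(label_switch_check(x, 0.8, 0.8), 0)
  }
})

test_that("the unconditioned joint likelihood is not label-switch symmetric", {
  x <- ltt_data(c(2, 1, 0.3), stem_age = 3)
  m12 <- make_constant_model(1.0, 0.5, 1)
  m21 <- make_constant_model(0.5, 1.0, 1)
  dev <- abs(gbdp_loglik(x, m12, condition_on_survival = FALSE) -
               gbdp_loglik(x, m21, condition_on_survival = FALSE))
  expect_gt(dev, 0.1)
})
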