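#' Sample speciation ages conditional on tip count and stem age
#'
#' Under a constant-rate pure-birth process conditioned on `n` tips and
#' the stem age `t0`, the `n - 1` node ages are the order statistics of
#' i.i.d. draws from the truncated-exponential kernel
#' \eqn{f(x) = \lambda e^{-\lambda x} / (1 - e^{-\lambda t_0})} on
#' `[0, t0]`; `sample_yule_order_stats()` draws them by inverse CDF.
#' The same order-statistics representation holds for the constant-rate
#' birth-death process with sampling, with kernel proportional to
#' \eqn{\lambda\,p_1(x)}; `sample_bdp_order_stats()` uses the exact CDF
#' \eqn{\eta_x / \eta_{t_0}} evaluated on a 2048-point grid and inverted
#' by monotone interpolation. Both samplers are orders of magnitude
#' cheaper than rejection-conditioned forward simulation and
#' distributionally indistinguishable from it.
#'
#' @param n Tip count, `n >= 2`.
#' @param t0 Stem age, positive.
#' @param lambda,mu Birth and death rates (`lambda > 0`).
#' @param rho Sampling fraction in `(0, 1]`.
#' @param seed Optional integer seed (applied locally; the caller's RNG
#'   state is untouched).
#' @return An [ltt_data()] tibble with `n - 1` ages and `stem_age = t0`.
#' @examples
#' sample_yule_order_stats(6, 10, 0.3, seed = 1)
#' @export
sample_yule_order_stats <- function(n, t0, lambda, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(t0, "t0", lower = 1e-300)
  check_number(lambda, "lambda", lower = 1e-300)
  if (!is.null(seed)) withr::local_seed(seed)
  u <- runif(n - 1)
  x <- -log1p(u * expm1(-lambda * t0)) / lambda
  ltt_data(x, stem_age = t0)
}

#' @rdname sample_yule_order_stats
#' @export
sample_bdp_order_stats <- function(n, t0, lambda, mu, rho = 1, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(t0, "t0", lower = 1e-300)
  model <- make_constant_model(lambda, mu, rho)
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- seq(0, t0, length.out = 2048L)
  cdf <- gbdp_eta(grid, model)
  if (cdf[length(cdf)] <= 0) {
    abort("degenerate kernel: lambda * p1 vanishes on [0, t0].",
      class = "bdltt_degenerate_kernel")
  }
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n - 1)
  x <- approx(cdf, grid, xout = u, ties = "ordered", rule = 2)$y
  ltt_data(x, stem_age = t0)
}

#' Forward simulation of a (generalized) birth-death tree
#'
#' Exact stochastic simulation from a single lineage at stem age `t0`
#' down to the present. For constant and piecewise-constant rates the
#' waiting times are per-piece exponentials (no discretization error);
#' for tabulated rates, thinning against the maximum total rate. For a
#' [two_epoch_model()] with `survival_p`, every lineage alive at age `T`
#' survives the instantaneous mass extinction independently with
#' probability `survival_p`. At the present each extant lineage is
#' sampled independently with probability `rho`. Total extinction is
#' reported via the `extinct` flag, not an error.
#'
#' @param model A [rate model][make_constant_model] or a
#'   [two_epoch_model()].
#' @param t0 Stem age (defaults to the model's own `t0` for two-epoch
#'   models).
#' @param seed Optional integer seed, recorded in the result.
#' @param max_lineages Guard against runaway supercritical simulations.
#' @return An object of class `sim_tree`: the full event history as a
#'   lineage table (one row per tree edge; a birth ends a lineage and
#'   starts two daughters), plus counts and flags. Use [ltt_from_tree()]
#'   for the reconstructed node ages, [prune_to_reconstructed()] /
#'   [as.phylo()] for trees, and [as_tibble()] for the raw table.
#' @examples
#' sim <- simulate_forward(make_constant_model(1, 0.3), t0 = 2, seed = 1)
#' sim$n_sampled
#' @export
simulate_forward <- function(model, t0 = NULL, seed = NULL,
                             max_lineages = 1e6) {
  me_age <- NA_real_
  me_p <- 1
  if (inherits(model, "two_epoch_model")) {
    t0 <- t0 %||% model$t0
    if (!is.null(model$survival_p)) {
      me_age <- model$T
      me_p <- model$survival_p
    }
    rm_ <- as_rate_model(model)
  } else {
    stop_not_model(model)
    rm_ <- model
  }
  check_number(t0, "t0", lower = 1e-300)
  if (!is.null(seed)) withr::local_seed(seed)

  lin <- if (rm_$kind == "tabulated") {
    sim_core_thinning(rm_, t0, max_lineages)
  } else {
    cp <- if (rm_$kind == "constant") numeric() else rm_$change_points
    lam <- rm_$lambda
    mu <- rm_$mu
    sim_core_piecewise(cp, lam, mu, t0, me_age, me_p, max_lineages)
  }
  # sampling fraction applied at the present
  extant <- lin$fate == 4L
  lin$sampled <- extant & runif(length(extant)) < rm_$rho

  structure(
    list(
      lineages = lin, t0 = t0, model = model, seed = seed,
      n_extant = sum(extant), n_sampled = sum(lin$sampled),
      extinct = !any(lin$sampled)
    ),
    class = "sim_tree"
  )
}

# Event-driven simulation with exact per-piece exponential waiting times.
# Fate codes: 1 birth (lineage splits), 2 death, 3 killed at the mass
# extinction, 4 extant at present.
sim_core_piecewise <- function(cp, lam, mu, t0, me_age, me_p, max_lineages) {
  cap <- 256L
  par <- integer(cap)
  st <- numeric(cap)
  en <- numeric(cap)
  fate <- integer(cap)
  nlin <- 1L
  par[1] <- NA_integer_
  st[1] <- t0
  active <- integer(cap)
  active[1] <- 1L
  n_act <- 1L

  bnds <- sort(unique(c(cp[cp < t0], if (!is.na(me_age) && me_age < t0) me_age)),
               decreasing = TRUE)
  bnds <- c(bnds, 0)
  a <- t0
  for (nb in bnds) {
    k <- piece_index(a, cp)
    lamk <- lam[k]
    muk <- mu[k]
    prob_birth <- if (lamk + muk > 0) lamk / (lamk + muk) else 0
    repeat {
      if (n_act == 0L) break
      tot <- n_act * (lamk + muk)
      if (tot <= 0) {
        a <- nb
        break
      }
      dt <- rexp(1L, tot)
      if (a - dt <= nb) {
        a <- nb
        break
      }
      a <- a - dt
      slot <- sample.int(n_act, 1L)
      l <- active[slot]
      if (runif(1L) < prob_birth) {
        if (nlin + 2L > length(par)) {
          newcap <- 2L * length(par)
          if (newcap > 2 * max_lineages) {
            abort("simulation exceeded `max_lineages`.",
              class = "bdltt_simulation_overflow")
          }
          par <- c(par, integer(length(par)))
          st <- c(st, numeric(length(st)))
          en <- c(en, numeric(length(en)))
          fate <- c(fate, integer(length(fate)))
          active <- c(active, integer(length(active)))
        }
        en[l] <- a
        fate[l] <- 1L
        c1 <- nlin + 1L
        c2 <- nlin + 2L
        par[c1] <- l
        par[c2] <- l
        st[c1] <- a
        st[c2] <- a
        nlin <- nlin + 2L
        active[slot] <- c1
        n_act <- n_act + 1L
        active[n_act] <- c2
      } else {
        en[l] <- a
        fate[l] <- 2L
        active[slot] <- active[n_act]
        n_act <- n_act - 1L
      }
    }
    if (n_act > 0L && !is.na(me_age) && nb == me_age) {
      surv <- runif(n_act) < me_p
      dead <- active[seq_len(n_act)][!surv]
      en[dead] <- me_age
      fate[dead] <- 3L
      active[seq_len(sum(surv))] <- active[seq_len(n_act)][surv]
      n_act <- sum(surv)
    }
  }
  if (n_act > 0L) {
    ext <- active[seq_len(n_act)]
    en[ext] <- 0
    fate[ext] <- 4L
  }
  list(parent = par[seq_len(nlin)], start = st[seq_len(nlin)],
       end = en[seq_len(nlin)], fate = fate[seq_len(nlin)])
}

# Thinning sampler for tabulated (piecewise-linear) rates: propose with
# the maximum total rate, accept with the local ratio. Exact because the
# interpolant attains its maximum at a knot.
sim_core_thinning <- function(model, t0, max_lineages) {
  bound <- max(model$lambda + model$mu)
  if (bound <= 0) {
    lin <- list(parent = NA_integer_, start = t0, end = 0, fate = 4L)
    return(lin)
  }
  par <- integer(256L)
  st <- numeric(256L)
  en <- numeric(256L)
  fate <- integer(256L)
  nlin <- 1L
  par[1] <- NA_integer_
  st[1] <- t0
  active <- integer(256L)
  active[1] <- 1L
  n_act <- 1L
  a <- t0
  while (n_act > 0L) {
    dt <- rexp(1L, n_act * bound)
    a <- a - dt
    if (a <= 0) break
    lam_a <- birth_rate(model, a)
    mu_a <- death_rate(model, a)
    if (runif(1L) >= (lam_a + mu_a) / bound) next
    slot <- sample.int(n_act, 1L)
    l <- active[slot]
    if (runif(1L) < lam_a / (lam_a + mu_a)) {
      if (nlin + 2L > length(par)) {
        if (2L * length(par) > 2 * max_lineages) {
          abort("simulation exceeded `max_lineages`.",
            class = "bdltt_simulation_overflow")
        }
        par <- c(par, integer(length(par)))
        st <- c(st, numeric(length(st)))
        en <- c(en, numeric(length(en)))
        fate <- c(fate, integer(length(fate)))
        active <- c(active, integer(length(active)))
      }
      en[l] <- a
      fate[l] <- 1L
      par[nlin + 1L] <- l
      par[nlin + 2L] <- l
      st[nlin + 1L] <- a
      st[nlin + 2L] <- a
      active[slot] <- nlin + 1L
      n_act <- n_act + 1L
      active[n_act] <- nlin + 2L
      nlin <- nlin + 2L
    } else {
      en[l] <- a
      fate[l] <- 2L
      active[slot] <- active[n_act]
      n_act <- n_act - 1L
    }
  }
  if (n_act > 0L) {
    ext <- active[seq_len(n_act)]
    en[ext] <- 0
    fate[ext] <- 4L
  }
  list(parent = par[seq_len(nlin)], start = st[seq_len(nlin)],
       end = en[seq_len(nlin)], fate = fate[seq_len(nlin)])
}

#' @rdname simulate_forward
#' @param accept Predicate `function(sim_tree) -> logical` defining the
#'   conditioning event (e.g. a fixed sampled tip count).
#' @param max_attempts Cap on rejection attempts; exceeding it is an
#'   error reporting the acceptance rate so far.
#' @export
simulate_forward_conditional <- function(model, t0 = NULL, accept,
                                         max_attempts = 1e6, seed = NULL,
                                         max_lineages = 1e6) {
  if (!is.null(seed)) withr::local_seed(seed)
  for (attempt in seq_len(max_attempts)) {
    sim <- simulate_forward(model, t0, seed = NULL, max_lineages = max_lineages)
    if (isTRUE(accept(sim))) {
      attr(sim, "attempts") <- attempt
      attr(sim, "acceptance_rate") <- 1 / attempt
      return(sim)
    }
  }
  abort(sprintf(
    "conditioning event not met in %d attempts (acceptance rate < %.2g).",
    max_attempts, 1 / max_attempts
  ), class = "bdltt_rejection_limit")
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("<sim_tree>\n")
  cat(sprintf("  stem age t0 = %g, %d lineages simulated\n",
    x$t0, length(x$lineages$parent)))
  cat(sprintf("  extant: %d, sampled: %d%s\n", x$n_extant, x$n_sampled,
    if (x$extinct) " (no sampled survivor: reconstructed tree empty)" else ""))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

fate_labels <- c("birth", "death", "mass_extinction", "extant")

#' @method as_tibble sim_tree
#' @export
as_tibble.sim_tree <- function(x, ...) {
  l <- x$lineages
  tibble(
    id = seq_along(l$parent), parent = l$parent,
    start = l$start, end = l$end,
    fate = factor(fate_labels[l$fate], levels = fate_labels),
    sampled = l$sampled
  )
}

# Propagate "subtree contains a sampled tip" up the lineage table and
# count, for each birth event, how many of its two daughters carry
# sampled descendants. Daughters always have larger ids than parents, so
# one reverse sweep suffices.
subtree_sampled <- function(lin) {
  hs <- lin$sampled
  par <- lin$parent
  for (i in rev(seq_along(hs))) {
    if (hs[i] && !is.na(par[i])) hs[par[i]] <- TRUE
  }
  list(has_sampled = hs,
       n_sampled_children = tabulate(par[hs], nbins = length(hs)))
}

#' Extract LTT data from a simulated or imported tree
#'
#' For a [simulate_forward()] result, the reconstructed-tree node ages
#' are the birth events both of whose daughter subtrees contain a
#' sampled present-day lineage (computed directly from the event table,
#' without building the pruned tree). For an `ape::phylo` the tree must
#' be binary and ultrametric to within `tol` times its height; node ages
#' are computed from tip-to-root path lengths, and a `root.edge` is
#' interpreted as the stem.
#'
#' @param tree A `sim_tree` or `ape::phylo` object.
#' @param tol Relative ultrametricity tolerance for imported trees.
#' @return An [ltt_data()] tibble (ages descending, stem age when known).
#' @export
ltt_from_tree <- function(tree, tol = 1e-6) {
  UseMethod("ltt_from_tree")
}

#' @export
ltt_from_tree.sim_tree <- function(tree, tol = 1e-6) {
  if (tree$extinct) {
    abort("no sampled survivor: the reconstructed tree is empty.",
      class = "bdltt_extinct_tree")
  }
  ss <- subtree_sampled(tree$lineages)
  ages <- tree$lineages$end[tree$lineages$fate == 1L &
                              ss$n_sampled_children == 2L]
  ltt_data(ages, stem_age = tree$t0)
}

#' @export
ltt_from_tree.phylo <- function(tree, tol = 1e-6) {
  check_time_tree(tree, tol = tol)
  ages <- node_depths_as_ages(tree)
  stem <- if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    max(ages) + tree$root.edge
  } else {
    NULL
  }
  ltt_data(ages, stem_age = stem)
}

# Internal-node ages of an ultrametric phylo (root depth 0 at the top).
node_depths_as_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ape::Ntip(tree))])
  height - depths[(ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)]
}

check_time_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) {
    abort("expected an `ape::phylo` tree.", class = "bdltt_validation_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; time trees are required.",
      class = "bdltt_validation_error")
  }
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    abort("tree must be rooted and binary (no polytomies).",
      class = "bdltt_validation_error")
  }
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(ape::Ntip(tree))]
  height <- max(tipd)
  dev <- height - tipd
  if (any(dev > tol * height)) {
    bad <- which(dev > tol * height)
    abort(paste0(
      "tree is not ultrametric; tip-depth deviations (in tree-height units):\n",
      paste(sprintf("  %s: %.3g", tree$tip.label[bad], dev[bad] / height),
            collapse = "\n")
    ), class = "bdltt_not_ultrametric")
  }
  invisible(tree)
}

#' Prune a simulated tree to the reconstructed tree of sampled survivors
#'
#' Removes every lineage without a sampled present-day descendant and
#' suppresses the resulting unary nodes, yielding the reconstructed tree
#' as an `ape::phylo` (with `root.edge` carrying the stem). The
#' `node_map` attribute maps each internal node number to the row of the
#' originating birth event in the lineage table. Pruning is idempotent:
#' the reconstructed tree of a pruned tree is itself.
#'
#' @param tree A `sim_tree`.
#' @return An ultrametric binary `phylo`, or, when fewer than two
#'   lineages were sampled, an object of class `bdltt_empty_tree`.
#' @export
prune_to_reconstructed <- function(tree) {
  if (!inherits(tree, "sim_tree")) {
    abort("expected a `sim_tree`.", class = "bdltt_validation_error")
  }
  if (tree$n_sampled < 2L) {
    return(structure(list(n_sampled = tree$n_sampled),
                     class = "bdltt_empty_tree"))
  }
  build_phylo(tree, reconstructed = TRUE)
}

#' @export
print.bdltt_empty_tree <- function(x, ...) {
  cat("<empty reconstructed tree:", x$n_sampled, "sampled lineage(s)>\n")
  invisible(x)
}

#' Convert a simulated tree to `ape::phylo`
#'
#' @param x A `sim_tree`.
#' @param reconstructed Prune to sampled survivors (`TRUE`) or keep the
#'   complete tree including extinct lineages (`FALSE`, default)?
#' @param ... Unused.
#' @return A `phylo`; tip labels are `t<row>` keyed to the lineage table.
#' @method as.phylo sim_tree
#' @export
as.phylo.sim_tree <- function(x, reconstructed = FALSE, ...) {
  build_phylo(x, reconstructed = reconstructed)
}

build_phylo <- function(sim, reconstructed) {
  lin <- sim$lineages
  n <- length(lin$parent)
  is_split <- lin$fate == 1L
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- lin$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  if (reconstructed) {
    ss <- subtree_sampled(lin)
    has_desc <- ss$has_sampled
    keep_tip <- lin$sampled
    is_node <- is_split & ss$n_sampled_children == 2L
    # walk through unary (single-sampled-daughter) birth events
    resolve <- function(l) {
      repeat {
        if (!is_split[l] || is_node[l]) return(l)
        ch <- kids[[l]]
        l <- ch[has_desc[ch]][1]
      }
    }
  } else {
    has_desc <- rep(TRUE, n)
    keep_tip <- !is_split
    is_node <- is_split
    resolve <- identity
  }
  ntip <- sum(keep_tip)
  nnode <- sum(is_node)
  if (ntip < 2L || nnode < 1L) {
    abort("fewer than two tips: not representable as a phylo tree.",
      class = "bdltt_validation_error")
  }
  edge <- matrix(0L, 2L * ntip - 2L, 2L)
  elen <- numeric(2L * ntip - 2L)
  tip_lab <- character(ntip)
  node_map <- integer(nnode)
  root <- resolve(1L)
  node_map[1] <- root
  tipc <- 0L
  nodec <- 1L
  edgec <- 0L
  # stack of (parent node number, parent age, unresolved daughter lineage)
  stack_p <- integer(2L * ntip)
  stack_a <- numeric(2L * ntip)
  stack_l <- integer(2L * ntip)
  top <- 0L
  for (ch in rev(kids[[root]])) {
    top <- top + 1L
    stack_p[top] <- ntip + 1L
    stack_a[top] <- lin$end[root]
    stack_l[top] <- ch
  }
  while (top > 0L) {
    pnum <- stack_p[top]
    page <- stack_a[top]
    l <- stack_l[top]
    top <- top - 1L
    if (!has_desc[l]) next
    r <- resolve(l)
    edgec <- edgec + 1L
    if (is_node[r]) {
      nodec <- nodec + 1L
      num <- ntip + nodec
      node_map[nodec] <- r
      edge[edgec, ] <- c(pnum, num)
      elen[edgec] <- page - lin$end[r]
      for (ch in rev(kids[[r]])) {
        top <- top + 1L
        stack_p[top] <- num
        stack_a[top] <- lin$end[r]
        stack_l[top] <- ch
      }
    } else {
      tipc <- tipc + 1L
      edge[edgec, ] <- c(pnum, tipc)
      elen[edgec] <- page - lin$end[r]
      tip_lab[tipc] <- paste0("t", r)
    }
  }
  out <- list(
    edge = edge, edge.length = elen, tip.label = tip_lab,
    Nnode = nnode, root.edge = sim$t0 - lin$end[root]
  )
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  attr(out, "node_map") <- node_map
  out
}
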