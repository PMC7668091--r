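# ---------------------------------------------------------------------------
# The three scalability conditions.
#
# A flux function J(X) is scalable when it is (1) positive on the open
# positive quadrant and continuously differentiable away from the origin,
# (2) upstream-limited (J = 0 whenever an upstream or maintaining node is
# depleted), and (3) homogeneous of degree 1: J(cX) = cJ(X) for all c > 0.
# A network is an SRN when every flux is scalable; only then does the
# composition Y = X/N evolve autonomously on the simplex and the growth rate
# become a function of composition alone.
# ---------------------------------------------------------------------------

# log-uniform interior samples, components in [1e-3, 1e3] (spec'd ranges)
sample_states <- function(nodes, n_samples, seed) {
  set.seed(seed)
  matrix(10^stats::runif(n_samples * length(nodes), -3, 3),
         nrow = n_samples, dimnames = list(NULL, nodes))
}

flux_nodes <- function(flux) {
  unique(c(names(flux$stoich), flux$upstream, flux$downstream,
           flux$maintenance, rate_nodes(flux$rate)))
}

eval_flux_at <- function(flux, X) {
  eval_rate(flux$rate, X, sum(X))
}

#' Check degree-1 homogeneity of a flux (condition 3)
#'
#' Structured family rates (product/lincomb/ratio) are homogeneous of degree 1
#' by construction and pass analytically; custom rates are tested by sampling
#' states `X` log-uniformly in `[1e-3, 1e3]` per component and scale factors
#' `c` log-uniformly in `[1e-2, 1e2]`, requiring
#' `|J(cX) - cJ(X)| <= tol * max(|cJ(X)|, atol)` at every sample.
#'
#' @param flux an `srn_flux`.
#' @param n_samples number of random samples (default 200).
#' @param tol relative tolerance.
#' @param seed RNG seed (mandatory in spirit; defaults to 0).
#' @param nodes node universe used to build sample states; defaults to the
#'   nodes referenced by the flux.
#' @return list with `pass`, `method` ("analytic" or "numeric"), and a
#'   data.frame of `counterexamples` (empty when passing).
#' @export
check_homogeneity <- function(flux, n_samples = 200, tol = 1e-9, seed = 0,
                              nodes = NULL) {
  stopifnot(n_samples >= 1, tol > 0)
  nodes <- nodes %||% flux_nodes(flux)
  if (!is.na(rate_degree(flux$rate))) {
    return(list(pass = TRUE, method = "analytic",
                counterexamples = data.frame()))
  }
  Xs <- sample_states(nodes, n_samples, seed)
  cs <- 10^stats::runif(n_samples, -2, 2)
  bad <- list()
  for (i in seq_len(n_samples)) {
    X <- stats::setNames(Xs[i, ], nodes)
    J1 <- eval_flux_at(flux, X)
    J2 <- eval_flux_at(flux, cs[i] * X)
    if (!is.finite(J1) || !is.finite(J2))
      stop("rate not evaluable at sampled point for flux '", flux$id, "'")
    err <- abs(J2 - cs[i] * J1)
    if (err > tol * max(abs(cs[i] * J1), 1e-12))
      bad[[length(bad) + 1]] <- data.frame(c = cs[i], J_cX = J2,
                                           cJ_X = cs[i] * J1, err = err)
  }
  list(pass = length(bad) == 0, method = "numeric",
       counterexamples = do.call(rbind, bad) %||% data.frame())
}

#' Check the upstream-limited condition of a flux (condition 2)
#'
#' For every upstream node and every declared maintenance node, evaluates the
#' flux at random states with that component set to zero; passes iff the flux
#' magnitude is at most `tol` (relative to the flux at the unzeroed state) at
#' all of them. This is the property that keeps trajectories inside the
#' nonnegative quadrant: a depleted node cannot be drained further.
#'
#' @inheritParams check_homogeneity
#' @return list with `pass` and per-node verdicts.
#' @export
check_upstream_limited <- function(flux, n_samples = 200, tol = 1e-9, seed = 0,
                                   nodes = NULL) {
  stopifnot(n_samples >= 1, tol > 0)
  nodes <- nodes %||% flux_nodes(flux)
  targets <- union(flux$upstream, flux$maintenance)
  if (length(targets) == 0)
    return(list(pass = TRUE, node = character(0), node_pass = logical(0)))
  Xs <- sample_states(nodes, n_samples, seed)
  node_pass <- vapply(targets, function(nd) {
    ok <- TRUE
    for (i in seq_len(n_samples)) {
      X <- stats::setNames(Xs[i, ], nodes)
      ref <- abs(eval_flux_at(flux, X))
      X[[nd]] <- 0
      J <- eval_flux_at(flux, X)
      if (!is.finite(J)) stop("rate not evaluable with ", nd,
                              " depleted for flux '", flux$id, "'")
      if (abs(J) > tol * max(ref, 1)) { ok <- FALSE; break }
    }
    ok
  }, TRUE)
  list(pass = all(node_pass), node = targets, node_pass = unname(node_pass))
}

# condition 1: positivity on the interior, finite central-difference gradients
check_condition1 <- function(flux, n_samples = 200, tol = 1e-6, seed = 0,
                             nodes = NULL) {
  nodes <- nodes %||% flux_nodes(flux)
  Xs <- sample_states(nodes, n_samples, seed)
  positive <- TRUE
  smooth <- TRUE
  counterexample <- NULL
  for (i in seq_len(min(n_samples, nrow(Xs)))) {
    X <- stats::setNames(Xs[i, ], nodes)
    J <- eval_flux_at(flux, X)
    if (!is.finite(J) || J <= 0) {
      positive <- FALSE
      counterexample <- X
      break
    }
    # bounded central finite differences at interior samples
    for (nd in nodes) {
      h <- tol * max(X[[nd]], 1)
      Xp <- X; Xp[[nd]] <- X[[nd]] + h
      Xm <- X; Xm[[nd]] <- max(X[[nd]] - h, 0)
      g <- (eval_flux_at(flux, Xp) - eval_flux_at(flux, Xm)) / (Xp[[nd]] - Xm[[nd]])
      if (!is.finite(g)) { smooth <- FALSE; counterexample <- X; break }
    }
    if (!smooth) break
  }
  list(pass = positive && smooth, positive = positive, smooth = smooth,
       counterexample = counterexample)
}

#' Check whether a network is a scalable reaction network
#'
#' Aggregates the per-flux checks of the three scalability conditions into a
#' report; failures are reported, never raised.
#'
#' @param network an `srn_network`.
#' @param n_samples,tol,seed sampling controls shared by the per-flux checks
#'   (homogeneity uses `tol_hom`, conditions 1-2 use `tol`).
#' @param tol_hom relative tolerance for the homogeneity check.
#' @return object of class `srn_scalability_report`: per-flux verdict table
#'   and overall `is_srn` flag (`TRUE` iff every flux passes all three
#'   conditions).
#' @export
check_scalability <- function(network, n_samples = 200, tol = 1e-6,
                              tol_hom = 1e-9, seed = 0) {
  nodes <- network$nodes
  rows <- lapply(network$fluxes, function(f) {
    c1 <- check_condition1(f, n_samples, tol, seed, nodes)
    c2 <- check_upstream_limited(f, n_samples, max(tol, 1e-9), seed, nodes)
    c3 <- check_homogeneity(f, n_samples, tol_hom, seed, nodes)
    data.frame(flux = f$id, cond1 = c1$pass, cond2 = c2$pass, cond3 = c3$pass,
               scalable = c1$pass && c2$pass && c3$pass,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  structure(list(verdicts = verdicts, is_srn = all(verdicts$scalable)),
            class = "srn_scalability_report")
}

#' @export
print.srn_scalability_report <- function(x, ...) {
  cat("<srn_scalability_report> is_srn:", x$is_srn, "\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Heuristic test for asymptotic scalability
#'
#' Some flux forms (e.g. `Xj*(b0+b1*Xp+b2*Xp^2)/(a0+a1*Xp+a2*Xp^2)`) are not
#' homogeneous but become so in the large-system limit along fixed composition
#' (c to infinity with Y fixed). Detected by comparing `J(cX)/c` at two large
#' scales; such fluxes are reported but never treated as SRN-qualifying.
#'
#' @inheritParams check_homogeneity
#' @return list with `asymptotic` flag.
#' @export
check_asymptotic_scalability <- function(flux, n_samples = 50, tol = 1e-3,
                                         seed = 0, nodes = NULL) {
  nodes <- nodes %||% flux_nodes(flux)
  Xs <- sample_states(nodes, n_samples, seed)
  ok <- TRUE
  for (i in seq_len(n_samples)) {
    X <- stats::setNames(Xs[i, ], nodes)
    r1 <- eval_flux_at(flux, 1e6 * X) / 1e6
    r2 <- eval_flux_at(flux, 1e8 * X) / 1e8
    if (!is.finite(r1) || !is.finite(r2) ||
        abs(r1 - r2) > tol * max(abs(r2), 1e-12)) { ok <- FALSE; break }
  }
  list(asymptotic = ok)
}

#' Lift a unit-volume (concentration) flux law to a scalable rate
#'
#' Biochemical rate laws are usually written per unit volume as functions of
#' concentrations. Under volume-biomass scaling `V = b*N`, the total flux
#' `J(X) = b*N*junit(X/(b*N))` is homogeneous of degree 1 by construction.
#'
#' @param junit function of the concentration vector (same length/order as the
#'   biomass vector) returning flux per unit volume.
#' @param b volume per unit biomass (b > 0).
#' @param maintenance optional declared maintenance set for the lifted rate.
#' @return an `srn_rate` (custom kind) implementing `X -> b*N*junit(X/(b*N))`.
#' @export
flux_from_unit_volume <- function(junit, b = 1, maintenance = NULL) {
  stopifnot(is.function(junit), b > 0)
  rate_custom(function(X, N) {
    if (N <= 0) return(0)
    b * N * junit(X / (b * N))
  }, maintenance = maintenance)
}
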