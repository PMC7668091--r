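# Small fixture networks built in code, plus independent oracles.

# one-node birth-death: import r*X1, export d*X1; lambda = r - d analytically
birth_death_net <- function(r = 0.5, d = 0.2) {
  build_network("x1", list(
    flux_spec("Jin", rate_linear("x1", r), stoich = c(x1 = 1)),
    flux_spec("Jout", rate_linear("x1", d), stoich = c(x1 = -1))))
}

# two-node conversion-only network: N is conserved, mu = 0
conversion_net <- function(c1 = 1, c2 = 0.7) {
  build_network(c("x1", "x2"), list(
    flux_spec("Jf", rate_linear("x1", c1), stoich = c(x1 = -1, x2 = 1)),
    flux_spec("Jb", rate_linear("x2", c2), stoich = c(x2 = -1, x1 = 1))))
}

# random linear SRN together with its rate matrix M (dX/dt = M X), assembled
# independently from the drawn coefficients: the dense-eigensolver oracle.
random_linear_srn <- function(n, seed) {
  set.seed(seed)
  nodes <- paste0("x", seq_len(n))
  M <- matrix(0, n, n)
  fl <- list()
  add <- function(f) fl[[length(fl) + 1]] <<- f
  for (k in seq_len(2 * n)) { # conversions j -> kk
    j <- sample(n, 1)
    kk <- sample(setdiff(seq_len(n), j), 1)
    r <- stats::runif(1, 0.1, 1)
    add(flux_spec(paste0("c", k), rate_linear(nodes[j], r),
                  stoich = stats::setNames(c(-1, 1), nodes[c(j, kk)])))
    M[j, j] <- M[j, j] - r
    M[kk, j] <- M[kk, j] + r
  }
  for (k in seq_len(n)) { # catalyzed import into k + linear export of k
    cnode <- sample(n, 1)
    r <- stats::runif(1, 0.1, 1)
    add(flux_spec(paste0("i", k), rate_linear(nodes[cnode], r),
                  stoich = stats::setNames(1, nodes[k])))
    M[k, cnode] <- M[k, cnode] + r
    d <- stats::runif(1, 0.1, 1)
    add(flux_spec(paste0("e", k), rate_linear(nodes[k], d),
                  stoich = stats::setNames(-1, nodes[k])))
    M[k, k] <- M[k, k] - d
  }
  list(net = build_network(nodes, fl), M = M)
}

# exhaustive-oracle maximal circuit: union of all subsets satisfying Eq. the
# containment condition, found by enumerating all 2^m - 1 flux subsets with
# bitmask set algebra (independent of the pruning implementation).
brute_force_max_circuit <- function(network) {
  nodes <- network$nodes
  m <- length(network$fluxes)
  stopifnot(m <= 12)
  bit <- function(set) sum(2^(match(set, nodes) - 1))
  mt <- vapply(network$fluxes, function(f) bit(f$maintenance), 0)
  dw <- vapply(network$fluxes, function(f) bit(f$downstream), 0)
  best <- integer(0)
  for (s in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(s, 2^(seq_len(m) - 1)) > 0)
    mtu <- Reduce(bitwOr, mt[idx], 0)
    dwu <- Reduce(bitwOr, dw[idx], 0)
    if (bitwAnd(mtu, bitwNot(dwu)) == 0) best <- union(best, idx)
  }
  sort(vapply(network$fluxes, `[[`, "", "id")[best])
}

uniform_y0 <- function(net) rep(1 / length(net$nodes), length(net$nodes))

write_net_string <- function(net) {
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  write_network(net, p)
  readLines(p)
}

# asymmetric start off the repressilator's symmetric invariant manifold
rep_y0 <- c(0.1, 0.2, 0.3, 0.4)
dbl_y0 <- (1:7) / sum(1:7)
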