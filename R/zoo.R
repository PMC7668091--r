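# ---------------------------------------------------------------------------
# Model zoo: parameterized constructors for the worked model systems plus
# seeded random-network and random-parameter generators.
#
# All rate constants that the underlying studies leave unspecified are fixed
# once in the registry below (documented units: arbitrary model time, biomass
# fractions on the simplex) and were chosen to reproduce the qualitative
# regimes: balanced growth at theta = 1 and a limit cycle at theta = 3 for the
# repressilator at K = 500; quasiperiodic growth at alpha = 20 and periodic
# growth at alpha = 100 for the double repressilator (no chaotic window was
# found in this reduction -- see the methods vignette; chaotic growth is
# provided by chaotic_community_model()); majority single-species outcomes
# for random Lotka-Volterra competition without cross-feeding.
# ---------------------------------------------------------------------------

#' Default parameter registry for the model zoo
#'
#' One authoritative list of every tunable the zoo constructors use; results
#' in the package documentation and tests refer to these values. The registry
#' is hash-stamped so runs can record exactly which defaults produced them.
#'
#' @return named list of per-model default parameter lists.
#' @export
zoo_registry <- function() {
  list(
    repressilator = list(
      c_syn = 2,    # synthesis rate of repressed conversions x1 -> x2,x3,x4
      r_auto = 2,   # autocatalytic import rate (per unit repressor biomass)
      d_exp = 0.2,  # export rate of x1
      K = 500,      # repression strength
      theta = 1     # Hill coefficient
    ),
    double_repressilator = list(
      c_syn = 6, r_auto = 1, d_exp = 0.2,
      K = 2000,  # within-ring repression; larger than the single model because
                 # per-node fractions halve with two rings sharing the source
      theta = 3,
      K_cross = 0.02, # base cross-ring repression, scaled by alpha
      theta_cross = 2,
      ring_detune = 1.4 # ring B synthesis multiplier: incommensurate periods
    ),
    chaotic_community = list(
      r = c(1, 0.72, 1.53, 1.27),
      A = matrix(c(1, 1.09, 1.52, 0,
                   0, 1, 0.44, 1.36,
                   2.33, 0, 1, 0.47,
                   1.21, 0.51, 0.35, 1), 4, 4, byrow = TRUE)
    ),
    limit_cycle3 = list(v_upt = 1.2, h_upt = 0.2, g_graze = 1.3,
                        h_graze = 0.2, m_rec = 0.3, r_in = 0.5, d_exp = 0.5),
    bistable = list(r_in = 0.05, c1 = 0.0525, c2 = 0.05, K = 20, theta = 2,
                    d_exp = 0.015), # slow drift: sigma ~ 0.02 hops basins
    heteroclinic = list(r = 1, a_self = 1, a_weak = 0.8, a_strong = 1.6),
    cross_feeding = list(
      r_range = c(0.5, 1.5),   # species growth rates, uniform
      a_max = 1.5,             # competition coefficients, uniform [0, a_max]
      s_max = 0.3,             # secretion rates, uniform (0 when no CF)
      Kc = 0.1,                # Michaelis constant of cross-feeding uptake
      vu = 4                   # uptake velocity scale
    ),
    chemostat = list(
      r = c(1.0, 0.9, 0.8),
      A = matrix(c(1.0, 0.4, 1.3,
                   1.3, 1.0, 0.4,
                   0.4, 1.3, 1.0), 3, 3, byrow = TRUE),
      s = c(0.2, 0.2, 0.2),
      E = matrix(c(0, 0.4, 0.4,
                   0.4, 0, 0.4,
                   0.4, 0.4, 0), 3, 3, byrow = TRUE),
      Kc = 0.1, vu = 1, Kn = 0.5, n_in = 5, yield = 1
    ),
    biosynthesis = list(
      v_imp = 4, v_conv = 8, v_aa = 8, v_cat = 6, v_pol = 3,
      v_nuc = 2,  # nucleotide (ADP) synthesis from intermediates: without it
                  # growth would dilute the conserved adenosine pool away
      thetaR = 2, nutrient = 1, atp_yield = 20,
      Km = 0.02,  # Michaelis constant on metabolite fractions
      Ke = 0.02   # Michaelis constant on ATP/ADP fractions
    ),
    random_srn = list(n_nodes = 8, n_fluxes = 12, connectivity_exponent = 2,
                      w_import = 0.3, w_conversion = 0.35, w_export = 0.25,
                      w_catalyzed = 0.1)
  )
}

#' Hash stamp of the zoo registry
#'
#' Polynomial rolling hash of the deparsed registry, recorded in run
#' provenance logs so a result can be tied to the exact defaults that
#' produced it.
#' @return hex string.
#' @export
zoo_registry_hash <- function() {
  txt <- paste(deparse(zoo_registry()), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

merge_params <- function(defaults, extra) {
  stopifnot(all(names(extra) %in% names(defaults)))
  utils::modifyList(defaults, extra)
}

# --- repressilator growth circuits -----------------------------------------

#' Autocatalytic single-repressilator network
#'
#' Four nodes: a core resource `x1` fed by an autocatalytic import whose rate
#' is proportional to the total repressor biomass `x2 + x3 + x4`, three
#' repressed synthesis conversions `x1 -> x_i` with sigmoidal rates
#' `c*X1 / (1 + K (X_rep/N)^theta)` (x3 represses J2, x4 represses J3, x2
#' represses J4), and a linear export of `x1`. On the simplex, dilution by the
#' growth rate plays the role of degradation, so the classical repressilator
#' ring oscillates once the Hill coefficient is large enough: balanced growth
#' (fixed point) at `theta = 1` and periodic growth at `theta = 3` for
#' `K = 500` at the registry defaults, with the Hopf bifurcation in between.
#'
#' @param theta Hill coefficient (>= 0).
#' @param K repression strength (> 0).
#' @param extra named list overriding registry defaults
#'   (`c_syn`, `r_auto`, `d_exp`).
#' @return an `srn_network`.
#' @export
single_repressilator <- function(theta = 1, K = 500, extra = list()) {
  stopifnot(theta >= 0, K > 0)
  p <- merge_params(zoo_registry()$repressilator, extra)
  nodes <- c("x1", "x2", "x3", "x4")
  rep_of <- c(x2 = "x3", x3 = "x4", x4 = "x2")
  fluxes <- list(
    flux_spec("J1", rate_lincomb(c(x2 = 1, x3 = 1, x4 = 1), r = p$r_auto),
              stoich = c(x1 = 1)))
  for (i in 2:4) {
    tgt <- nodes[i]
    rp <- if (theta > 0)
      list(list(node = rep_of[[tgt]], K = K, theta = theta)) else NULL
    fluxes[[i]] <- flux_spec(paste0("J", i),
      rate_product(r = p$c_syn, mono = c(x1 = 1), rep = rp),
      stoich = stats::setNames(c(-1, 1), c("x1", tgt)))
  }
  fluxes[[5]] <- flux_spec("J5", rate_linear("x1", p$d_exp),
                           stoich = c(x1 = -1))
  build_network(nodes, fluxes)
}

#' Autocatalytic double-repressilator network
#'
#' Seven nodes: the shared resource `x1` plus two three-node repressilator
#' rings (`x2,x3,x4` and `x5,x6,x7`) that mutually inhibit each other: each
#' ring node represses the synthesis of its counterpart in the other ring with
#' strength `alpha * K_cross`, so `alpha` sets the ratio of the cross-ring
#' repression to the (fixed) within-ring repression `K`. The second ring is
#' detuned (`ring_detune` multiplies its synthesis rates) so the uncoupled
#' rings oscillate at incommensurate frequencies. At registry defaults the
#' growth modality follows the coupled-oscillator route: quasiperiodic (torus)
#' at `alpha = 20` and phase-locked periodic from `alpha = 100` on. In this
#' protein-only 7-node reduction the locked state remains stable at strong
#' coupling, so no chaotic window was found (see the methods vignette for the
#' search); a chaotic growth modality is provided by
#' [chaotic_community_model()] instead.
#'
#' @param alpha cross-repression strength ratio (> 0).
#' @param extra named list overriding registry defaults.
#' @return an `srn_network`.
#' @export
double_repressilator <- function(alpha, extra = list()) {
  stopifnot(alpha > 0)
  p <- merge_params(zoo_registry()$double_repressilator, extra)
  nodes <- c("x1", paste0("x", 2:7))
  ringA <- c("x2", "x3", "x4")
  ringB <- c("x5", "x6", "x7")
  nxt <- function(ring, i) ring[(i %% 3) + 1]
  fluxes <- list(
    flux_spec("J1",
      rate_lincomb(stats::setNames(rep(1, 6), c(ringA, ringB)), r = p$r_auto),
      stoich = c(x1 = 1)))
  id <- 2L
  for (i in 1:3) { # ring A: repressed within ring + by ring B counterpart
    fluxes[[id]] <- flux_spec(paste0("JA", i),
      rate_product(r = p$c_syn, mono = c(x1 = 1),
                   rep = list(
                     list(node = nxt(ringA, i), K = p$K, theta = p$theta),
                     list(node = ringB[i], K = alpha * p$K_cross,
                          theta = p$theta_cross))),
      stoich = stats::setNames(c(-1, 1), c("x1", ringA[i])))
    id <- id + 1L
  }
  for (i in 1:3) { # ring B: same topology, synthesis detuned
    fluxes[[id]] <- flux_spec(paste0("JB", i),
      rate_product(r = p$c_syn * p$ring_detune, mono = c(x1 = 1),
                   rep = list(
                     list(node = nxt(ringB, i), K = p$K, theta = p$theta),
                     list(node = ringA[i], K = alpha * p$K_cross,
                          theta = p$theta_cross))),
      stoich = stats::setNames(c(-1, 1), c("x1", ringB[i])))
    id <- id + 1L
  }
  fluxes[[id]] <- flux_spec("Jexp", rate_linear("x1", p$d_exp),
                            stoich = c(x1 = -1))
  build_network(nodes, fluxes)
}

# --- three-node showcase flows (limit cycle / bistable / heteroclinic) ------

#' Three-node limit-cycle network
#'
#' Nutrient-producer-grazer chain (`x1 -> x2 -> x3 -> x1`): producer uptake
#' and grazing follow saturating (Michaelis-Menten / Holling type II) rates,
#' grazer mortality recycles biomass to the nutrient pool, and an
#' autocatalytic import plus a nutrient export make the system grow. The
#' saturating grazing destabilizes the interior fixed point (the classic
#' enrichment mechanism), so the rescaled flow settles on a stable interior
#' limit cycle at registry defaults, which carries the ergodic measure.
#' Producer and grazer growth are self-catalyzed, so the model is not
#' regenerative (extinction of a trophic level is absorbing).
#'
#' @param extra registry overrides (`v_upt`, `h_upt`, `g_graze`, `h_graze`,
#'   `m_rec`, `r_in`, `d_exp`).
#' @return an `srn_network`.
#' @export
limit_cycle_model <- function(extra = list()) {
  p <- merge_params(zoo_registry()$limit_cycle3, extra)
  build_network(c("x1", "x2", "x3"), list(
    flux_spec("Jin", rate_lincomb(c(x1 = 1, x2 = 1, x3 = 1), r = p$r_in),
              stoich = c(x1 = 1)),
    flux_spec("Jupt",
      rate_product(r = p$v_upt, mono = c(x2 = 1),
                   sat = list(list(node = "x1", K = p$h_upt, theta = 1))),
      stoich = c(x1 = -1, x2 = 1)),
    flux_spec("Jgraze",
      rate_product(r = p$g_graze, mono = c(x3 = 1),
                   sat = list(list(node = "x2", K = p$h_graze, theta = 1))),
      stoich = c(x2 = -1, x3 = 1)),
    flux_spec("Jrec", rate_linear("x3", p$m_rec), stoich = c(x3 = -1, x1 = 1)),
    flux_spec("Jexp", rate_linear("x1", p$d_exp), stoich = c(x1 = -1))))
}

#' Three-node bistable (toggle) network
#'
#' A resource node `x3` is replenished by an import proportional to
#' `x1 + x2`; mutually repressing conversions `x3 -> x1` and `x3 -> x2`
#' (toggle switch) plus export of `x3`. Two stable fixed points coexist
#' (`x1`-dominant and `x2`-dominant); the synthesis rates are detuned
#' (`c1 != c2`) so the two balanced-growth states have different lambda.
#' The network is regenerative, so composition noise merges the two basins
#' into a single ergodic measure.
#'
#' @param extra registry overrides.
#' @return an `srn_network`.
#' @export
bistable_model <- function(extra = list()) {
  p <- merge_params(zoo_registry()$bistable, extra)
  build_network(c("x1", "x2", "x3"), list(
    flux_spec("Jin", rate_lincomb(c(x1 = 1, x2 = 1), r = p$r_in),
              stoich = c(x3 = 1)),
    flux_spec("Js1",
      rate_product(r = p$c1, mono = c(x3 = 1),
                   rep = list(list(node = "x2", K = p$K, theta = p$theta))),
      stoich = c(x3 = -1, x1 = 1)),
    flux_spec("Js2",
      rate_product(r = p$c2, mono = c(x3 = 1),
                   rep = list(list(node = "x1", K = p$K, theta = p$theta))),
      stoich = c(x3 = -1, x2 = 1)),
    flux_spec("Jout", rate_linear("x3", p$d_exp), stoich = c(x3 = -1))))
}

#' Three-species heteroclinic (rock-paper-scissors) community
#'
#' May-Leonard-type Lotka-Volterra competition with cyclic asymmetry
#' (`a_weak < a_self < a_strong`, `a_weak + a_strong > 2 a_self`): the
#' boundary heteroclinic cycle attracts interior trajectories, dwell times
#' near each vertex lengthen indefinitely, and the running growth-rate average
#' keeps oscillating (reported non-converged). Not regenerative (species
#' growth is self-catalyzed).
#'
#' @param extra registry overrides.
#' @return an `srn_network`.
#' @export
heteroclinic_model <- function(extra = list()) {
  p <- merge_params(zoo_registry()$heteroclinic, extra)
  A <- matrix(p$a_self, 3, 3)
  for (i in 1:3) {
    A[i, (i %% 3) + 1] <- p$a_weak     # i is weakly hurt by its prey
    A[i, ((i + 1) %% 3) + 1] <- p$a_strong # and strongly by its predator
  }
  cross_feeding_community(list(r = rep(p$r, 3), A = A,
                               s = rep(0, 3), E = matrix(0, 3, 3)))
}

#' Five-node chaotic community network
#'
#' A four-species Lotka-Volterra competition system known to have a chaotic
#' attractor, embedded exactly in a five-node scalable network via the
#' replicator correspondence: species growth fluxes are quadratic
#' autocatalytic imports `r_i X_i X_5 / N` (the fifth node is the untapped
#' background resource pool) and competition is the usual quadratic efflux
#' family `r_i a_ij X_i X_j / N`. The rescaled composition flow on the 4-
#' simplex is orbit-equivalent to the chaotic Lotka-Volterra system, so the
#' largest Lyapunov exponent is positive and the growth modality is chaotic
#' while lambda still converges (Birkhoff average over the chaotic attractor).
#' Not regenerative: species growth is self-catalyzed.
#'
#' @param extra registry overrides (`r`, `A`).
#' @return an `srn_network`.
#' @export
chaotic_community_model <- function(extra = list()) {
  p <- merge_params(zoo_registry()$chaotic_community, extra)
  r <- p$r
  A <- p$A
  nodes <- paste0("x", 1:5)
  fl <- list()
  for (i in 1:4)
    fl[[length(fl) + 1]] <- flux_spec(paste0("grow", i),
      rate_product(r = r[i], mono = stats::setNames(c(1, 1),
                                                    c(nodes[i], "x5"))),
      stoich = stats::setNames(1, nodes[i]))
  for (i in 1:4) for (j in 1:4) if (A[i, j] > 0) {
    mono <- if (i == j) stats::setNames(2, nodes[i]) else
      stats::setNames(c(1, 1), nodes[c(i, j)])
    fl[[length(fl) + 1]] <- flux_spec(sprintf("comp%d%d", i, j),
      rate_product(r = r[i] * A[i, j], mono = mono),
      stoich = stats::setNames(-1, nodes[i]))
  }
  build_network(nodes, fl)
}

#' Canonical interior start for the chaotic community
#' @return composition on the 4-simplex inside the chaotic basin.
#' @export
chaotic_community_y0 <- function() {
  x0 <- rep(0.3, 4)
  c(x0, 1) / (1 + sum(x0))
}

# --- cross-feeding Lotka-Volterra community ---------------------------------

#' Cross-feeding Lotka-Volterra community network
#'
#' Three species `x1..x3` with per-species autocatalytic growth `r_i X_i`,
#' pairwise quadratic competition effluxes `a_ij X_i X_j / N`, secretion
#' `s_i X_i` of species-specific metabolites `m1..m3`, and Michaelis-Menten
#' cross-feeding uptake `vu e_ij X_i (M_j/N) / (Kc + M_j/N)` converting
#' metabolite `m_j` into species `x_i` biomass. When the metabolite channel is
#' completely inert (all secretion and efficiencies zero) the constructor
#' returns the bare three-node competition network. Like any Lotka-Volterra
#' model, the network is not regenerative: each species' growth is
#' self-catalyzed, so extinction is absorbing.
#'
#' @param params list with `r` (length 3), `A` (3x3 competition matrix),
#'   `s` (length 3 secretion rates), `E` (3x3 cross-feeding efficiencies,
#'   diagonal ignored), optional `Kc`, `vu` (registry defaults).
#' @return an `srn_network`.
#' @export
cross_feeding_community <- function(params) {
  reg <- zoo_registry()$cross_feeding
  r <- params$r; A <- params$A; s <- params$s; E <- params$E
  Kc <- params$Kc %||% reg$Kc
  vu <- params$vu %||% reg$vu
  stopifnot(length(r) == 3, all(dim(A) == c(3, 3)), length(s) == 3,
            all(dim(E) == c(3, 3)), all(r > 0), all(A >= 0), all(s >= 0),
            all(E >= 0), Kc > 0)
  sp <- paste0("x", 1:3)
  met <- paste0("m", 1:3)
  with_met <- any(s > 0) || any(E[row(E) != col(E)] > 0)
  nodes <- if (with_met) c(sp, met) else sp
  fluxes <- list()
  for (i in 1:3)
    fluxes[[length(fluxes) + 1]] <- flux_spec(paste0("grow", i),
      rate_linear(sp[i], r[i]), stoich = stats::setNames(1, sp[i]))
  for (i in 1:3) for (j in 1:3) if (A[i, j] > 0) {
    mono <- if (i == j) stats::setNames(2, sp[i]) else
      stats::setNames(c(1, 1), c(sp[i], sp[j]))
    fluxes[[length(fluxes) + 1]] <- flux_spec(sprintf("comp%d%d", i, j),
      rate_product(r = A[i, j], mono = mono),
      stoich = stats::setNames(-1, sp[i]))
  }
  if (with_met) {
    for (i in 1:3) if (s[i] > 0)
      fluxes[[length(fluxes) + 1]] <- flux_spec(paste0("secr", i),
        rate_linear(sp[i], s[i]),
        stoich = stats::setNames(c(-1, 1), c(sp[i], met[i])))
    for (i in 1:3) for (j in 1:3) if (i != j && E[i, j] > 0)
      fluxes[[length(fluxes) + 1]] <- flux_spec(sprintf("feed%d%d", i, j),
        rate_product(r = vu * E[i, j], mono = stats::setNames(1, sp[i]),
                     sat = list(list(node = met[j], K = Kc, theta = 1))),
        stoich = stats::setNames(c(-1, 1), c(met[j], sp[i])))
  }
  build_network(nodes, fluxes)
}

#' Seeded sampler of community interaction parameters
#'
#' Uniform draws of growth rates in `r_range`, competition coefficients in
#' `[0, a_max]` (all 9 entries), secretion rates in `[0, s_max]` and
#' cross-feeding efficiencies in `[0, cross_feeding_max]` (off-diagonal).
#' `cross_feeding_max = 0` switches the metabolite channel off entirely
#' (secretion included), giving the bare competition model.
#'
#' @param cross_feeding_max upper bound of the efficiency draws (the three
#'   published datasets use 0, 0.1 and 0.5).
#' @param n_sets number of parameter sets.
#' @param seed RNG seed.
#' @return list of parameter lists suitable for [cross_feeding_community()].
#' @export
lv_parameter_sampler <- function(cross_feeding_max, n_sets, seed) {
  stopifnot(cross_feeding_max >= 0, n_sets >= 1)
  reg <- zoo_registry()$cross_feeding
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    r <- stats::runif(3, reg$r_range[1], reg$r_range[2])
    A <- matrix(stats::runif(9, 0, reg$a_max), 3, 3)
    if (cross_feeding_max > 0) {
      s <- stats::runif(3, 0, reg$s_max)
      E <- matrix(stats::runif(9, 0, cross_feeding_max), 3, 3)
      diag(E) <- 0
    } else {
      s <- rep(0, 3)
      E <- matrix(0, 3, 3)
    }
    list(r = r, A = A, s = s, E = E, Kc = reg$Kc, vu = reg$vu)
  })
}

#' Long-term survival outcome of one community
#'
#' Simulates the rescaled dynamics from the uniform composition and counts the
#' surviving species: a species survives unless its biomass fraction stays
#' below `thr` over the final `window` fraction of the run (so heteroclinic
#' communities, which revisit every vertex, count as full coexistence).
#'
#' @param params one sampler entry (see [lv_parameter_sampler()]).
#' @param t_end,nout,rtol,atol simulation controls (scan-grade defaults).
#' @param thr extinction threshold on the biomass fraction.
#' @param window final fraction of the run inspected.
#' @return list with `n_survivors`, `survivors` (logical, species 1..3),
#'   `lambda`.
#' @export
community_outcome <- function(params, t_end = 400, nout = 800, rtol = 1e-7,
                              atol = 1e-10, thr = 1e-4, window = 0.1) {
  net <- cross_feeding_community(params)
  n <- length(net$nodes)
  tr <- simulate_simplex(net, rep(1 / n, n), t_end, nout = nout,
                         rtol = rtol, atol = atol)
  keep <- tr$t >= (1 - window) * t_end
  surv <- vapply(1:3, function(k) max(tr$Y[keep, k]) >= thr, TRUE)
  list(n_survivors = sum(surv), survivors = surv,
       lambda = lambda_time_average(tr)$lam)
}

#' Survival statistics over sampled communities
#'
#' @param cross_feeding_max efficiency bound handed to the sampler.
#' @param n_sets number of communities.
#' @param seed sampler seed.
#' @param ... passed to [community_outcome()].
#' @return list with `counts` (table over 0..3 survivors), `frac_single`,
#'   `frac_coexist3`.
#' @export
community_survival_scan <- function(cross_feeding_max, n_sets, seed, ...) {
  sets <- lv_parameter_sampler(cross_feeding_max, n_sets, seed)
  ns <- vapply(sets, function(p) community_outcome(p, ...)$n_survivors, 0L)
  counts <- tabulate(ns + 1L, nbins = 4L)
  names(counts) <- 0:3
  list(counts = counts, frac_single = counts[["1"]] / n_sets,
       frac_coexist3 = counts[["3"]] / n_sets)
}

# --- chemostat wrapper (not an SRN: explicit nutrient + dilution) -----------

#' Chemostat version of the cross-feeding community
#'
#' The turbidostat-type community assumes nutrients in excess; here a limiting
#' nutrient pool `n` with inflow concentration `n_in` and dilution rate `D`
#' applied to every pool is modelled explicitly (concentration space, not a
#' scalable network):
#' growth `r_i x_i n/(Kn+n)`, quadratic competition, secretion, Michaelis-
#' Menten cross-feeding, all pools diluted at rate `D`. Returns a dynamical-
#' system wrapper usable with [simulate_chemostat()].
#'
#' @param D dilution rate (>= 0).
#' @param params optional overrides of the registry `chemostat` entry.
#' @return object of class `srn_chemostat` (fields `D`, `params`, `rhs`).
#' @export
chemostat_cross_feeding <- function(D, params = list()) {
  stopifnot(D >= 0)
  p <- merge_params(zoo_registry()$chemostat, params)
  rhs <- function(t, state) {
    x <- pmax(state[1:3], 0)
    m <- pmax(state[4:6], 0)
    nu <- max(state[7], 0)
    monod <- nu / (p$Kn + nu)
    g <- p$r * x * monod
    comp <- (p$A %*% x) * x
    upt <- p$vu * p$E * outer(x, m / (p$Kc + m)) # upt[i,j]: x_i eats m_j
    dx <- g - comp - p$s * x + rowSums(upt) - D * x
    dm <- p$s * x - colSums(upt) - D * m
    dn <- D * (p$n_in - nu) - sum(g) / p$yield
    c(dx, dm, dn)
  }
  structure(list(D = D, params = p, rhs = rhs), class = "srn_chemostat")
}

#' Integrate a chemostat system
#' @param cs an `srn_chemostat`.
#' @param state0 initial `(x1..x3, m1..m3, n)`; default small inocula in fresh
#'   medium.
#' @param t_end,nout,rtol,atol integration controls.
#' @return list with `t`, `state` matrix (columns x1..x3, m1..m3, n).
#' @export
simulate_chemostat <- function(cs, state0 = NULL, t_end = 600, nout = 1200,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cs, "srn_chemostat"))
  state0 <- state0 %||% c(rep(0.1, 3), rep(0, 3), cs$params$n_in)
  times <- seq(0, t_end, length.out = nout + 1)
  st <- rk45_r(function(t, y) cs$rhs(t, y), state0, times, rtol, atol)
  st[st < 0] <- 0
  colnames(st) <- c(paste0("x", 1:3), paste0("m", 1:3), "n")
  list(t = times, state = st)
}

#' Long-term modality of a chemostat run
#'
#' Classifies the final window of a chemostat simulation: `"extinction"` when
#' every species concentration stays below `thr`; otherwise
#' `"<k>_species_fixed_point"` or `"<k>_species_limit_cycle"` depending on
#' whether the surviving species still oscillate (relative amplitude above
#' `osc_tol`).
#'
#' @param D dilution rate.
#' @param params registry overrides.
#' @param t_end,window,thr,osc_tol controls.
#' @return label string.
#' @export
chemostat_modality <- function(D, params = list(), t_end = 600, window = 0.2,
                               thr = 1e-4, osc_tol = 0.02) {
  cs <- chemostat_cross_feeding(D, params)
  run <- simulate_chemostat(cs, t_end = t_end)
  keep <- run$t >= (1 - window) * t_end
  xs <- run$state[keep, 1:3, drop = FALSE]
  alive <- apply(xs, 2, max) >= thr
  if (!any(alive)) return("extinction")
  amp <- apply(xs[, alive, drop = FALSE], 2, function(v)
    (max(v) - min(v)) / max(mean(v), thr))
  kind <- if (any(amp > osc_tol)) "limit_cycle" else "fixed_point"
  sprintf("%d_species_%s", sum(alive), kind)
}

#' Sweep the chemostat dilution rate
#' @param D_grid dilution rates to test.
#' @param params registry overrides.
#' @param ... passed to [chemostat_modality()].
#' @return data.frame with columns `D`, `modality`.
#' @export
chemostat_sweep <- function(D_grid, params = list(), ...) {
  data.frame(D = D_grid,
             modality = vapply(D_grid, chemostat_modality, "",
                               params = params, ...))
}

# --- biosynthesis toy model --------------------------------------------------

#' 24-node autocatalytic biosynthesis network
#'
#' Metabolites `m1..m10` (m1-m3 imported, m4-m6 intermediates, m7-m10 amino
#' acids), transporters `P1..P3`, enzymes `Q1..Q8`, ribosome `R`, and the
#' energy couple `ATP`/`ADP`. Transporter-catalyzed imports bring in external
#' nutrients (environment concentrations enter as the multiplier
#' `nutrient_level`); enzyme-catalyzed Michaelis-Menten conversions make amino
#' acids (costing 2 ATP each); the ribosome polymerizes amino acids into the
#' 12 polymer species (costing 3 ATP per amino acid), with the ribosome's own
#' synthesis rate set by `thetaR`; catabolism of one amino acid regenerates
#' `atp_yield` ATP from ADP. Every energy-coupled reaction conserves the
#' adenosine moiety (equal and opposite ATP/ADP coefficients); the single
#' nucleotide-synthesis reaction creates ADP from an intermediate metabolite,
#' without which growth would dilute the adenosine pool away. Like real
#' metabolism, the model is not regenerative: losing the ribosome (or the
#' whole adenosine pool) is irrecoverable, since their synthesis is
#' self-catalyzed.
#'
#' @param thetaR ribosomal synthesis strength (> 0).
#' @param nutrient_level common external nutrient level for s1 = s2 = s3
#'   (> 0).
#' @param atp_yield ATP produced per catabolized amino acid (typically 10, 20
#'   or 30).
#' @param extra registry overrides.
#' @return an `srn_network`.
#' @export
biosynthesis_toy <- function(thetaR = NULL, nutrient_level = NULL,
                             atp_yield = NULL, extra = list()) {
  p <- merge_params(zoo_registry()$biosynthesis, extra)
  p$thetaR <- thetaR %||% p$thetaR
  p$nutrient <- nutrient_level %||% p$nutrient
  p$atp_yield <- atp_yield %||% p$atp_yield
  stopifnot(p$thetaR > 0, p$nutrient >= 0, p$atp_yield > 0)
  mets <- paste0("m", 1:10)
  trans <- paste0("P", 1:3)
  enz <- paste0("Q", 1:8)
  nodes <- c(mets, trans, enz, "R", "ATP", "ADP")
  aa <- paste0("m", 7:10)
  sat1 <- function(node, K) list(list(node = node, K = K, theta = 1))
  fluxes <- list()
  add <- function(f) fluxes[[length(fluxes) + 1]] <<- f
  for (i in 1:3) # transporter-catalyzed import of external nutrient s_i
    add(flux_spec(paste0("imp", i),
      rate_product(r = p$v_imp * p$nutrient,
                   mono = stats::setNames(1, trans[i])),
      stoich = stats::setNames(1, mets[i])))
  for (i in 1:3) # m_i -> m_{i+3}, enzyme Q_i
    add(flux_spec(paste0("conv", i),
      rate_product(r = p$v_conv, mono = stats::setNames(1, enz[i]),
                   sat = sat1(mets[i], p$Km)),
      stoich = stats::setNames(c(-1, 1), c(mets[i], mets[i + 3]))))
  aa_src <- c(m7 = "m4", m8 = "m5", m9 = "m6", m10 = "m6")
  for (k in 1:4) # amino-acid synthesis, costs 2 ATP
    add(flux_spec(paste0("aa", k),
      rate_product(r = p$v_aa, mono = stats::setNames(1, enz[3 + k]),
                   sat = c(sat1(aa_src[[aa[k]]], p$Km), sat1("ATP", p$Ke))),
      stoich = stats::setNames(c(-1, 1, -2, 2),
                               c(aa_src[[aa[k]]], aa[k], "ATP", "ADP"))))
  # nucleotide synthesis: intermediate m4 -> ADP (enzyme Q8); keeps the
  # adenosine pool from being diluted out by growth
  add(flux_spec("nuc",
    rate_product(r = p$v_nuc, mono = c(Q8 = 1), sat = sat1("m4", p$Km)),
    stoich = c(m4 = -1, ADP = 1)))
  for (k in 1:4) # catabolism via Q8: one amino acid -> atp_yield ATP
    add(flux_spec(paste0("cat", k),
      rate_product(r = p$v_cat, mono = c(Q8 = 1),
                   sat = c(sat1(aa[k], p$Km), sat1("ADP", p$Ke))),
      stoich = stats::setNames(c(-1, -p$atp_yield, p$atp_yield),
                               c(aa[k], "ADP", "ATP"))))
  polymers <- c(trans, enz, "R")
  for (pm in polymers) { # ribosome-catalyzed polymerization, 3 ATP per aa
    vr <- if (pm == "R") p$thetaR else p$v_pol
    add(flux_spec(paste0("pol_", pm),
      rate_product(r = vr, mono = c(R = 1),
                   sat = c(sat1("m7", p$Km), sat1("m8", p$Km),
                           sat1("m9", p$Km), sat1("m10", p$Km),
                           sat1("ATP", p$Ke))),
      stoich = stats::setNames(c(rep(-0.25, 4), 1, -3, 3),
                               c(aa, pm, "ATP", "ADP"))))
  }
  build_network(nodes, fluxes)
}

#' Time-averaged catabolic flux fraction of amino acids
#'
#' Fraction of total amino-acid consumption routed to catabolism (energy
#' production) rather than polymer synthesis, averaged over the post-burn-in
#' part of a trajectory of the biosynthesis model:
#' `sum(J_cat) / (sum(J_cat) + sum(J_pol))` (each unit of either flux consumes
#' one amino-acid mass unit in total).
#'
#' @param network the `srn_network` from [biosynthesis_toy()].
#' @param traj an `srn_trajectory` of that network.
#' @param burn_in transient to discard (default 20%).
#' @return fraction in `[0, 1]`.
#' @export
catabolic_flux_fraction <- function(network, traj, burn_in = NULL) {
  ids <- vapply(network$fluxes, `[[`, "", "id")
  icat <- grep("^cat", ids)
  ipol <- grep("^pol_", ids)
  if (!length(icat) || !length(ipol))
    stop("network does not look like the biosynthesis model")
  pt <- post_transient(traj, burn_in)
  J <- cpp_eval_fluxes_path(network$compiled, pt$Y)
  cat_tot <- mean(rowSums(J[, icat, drop = FALSE]))
  pol_tot <- mean(rowSums(J[, ipol, drop = FALSE]))
  if (cat_tot + pol_tot <= 0) stop("zero total amino-acid consumption")
  cat_tot / (cat_tot + pol_tot)
}

#' ATP-balance prediction of the optimal catabolic fraction
#'
#' Catabolizing one amino acid nets `atp_yield - synth_cost` ATP (its own
#' synthesis cost must be repaid); routing one amino acid to polymers costs
#' `synth_cost + polym_cost` ATP. ATP production balances consumption when the
#' catabolic fraction of amino-acid consumption equals
#' `(synth_cost + polym_cost) / ((synth_cost + polym_cost) + (atp_yield -
#' synth_cost))`; with the default stoichiometry (yield 20, costs 2 and 3)
#' this is 5/23, approximately 0.22.
#'
#' @param atp_yield ATP produced per catabolized amino acid (> `synth_cost`).
#' @param synth_cost ATP consumed per amino acid synthesized (default 2).
#' @param polym_cost ATP consumed per amino acid polymerized (default 3).
#' @return predicted optimal catabolic flux fraction in `(0, 1)`.
#' @export
predicted_optimal_fraction <- function(atp_yield, synth_cost = 2,
                                       polym_cost = 3) {
  if (atp_yield <= synth_cost)
    stop("nonpositive net ATP yield: atp_yield must exceed synth_cost")
  anab <- synth_cost + polym_cost
  anab / (anab + (atp_yield - synth_cost))
}

# --- random network generator ------------------------------------------------

#' Seeded random scalable reaction network
#'
#' Nodes participate in reactions with power-law probability
#' `p_k ~ k^(-connectivity_exponent)`; each flux is drawn from the scalable
#' families (catalyzed import, linear conversion, linear export, Hill-
#' maintained catalyzed conversion) with log-uniform rate constants, so every
#' generated network passes the scalability checks by construction.
#'
#' @param n_nodes,n_fluxes network size.
#' @param connectivity_exponent power-law exponent of the node-participation
#'   weights.
#' @param flux_family_weights named numeric weights for families
#'   `import`, `conversion`, `export`, `catalyzed`.
#' @param seed RNG seed (mandatory).
#' @return an `srn_network`.
#' @export
random_srn <- function(n_nodes = 8, n_fluxes = 12, connectivity_exponent = 2,
                       flux_family_weights = NULL, seed) {
  stopifnot(n_nodes >= 1, n_fluxes >= 1)
  reg <- zoo_registry()$random_srn
  w <- flux_family_weights %||% c(import = reg$w_import,
                                  conversion = reg$w_conversion,
                                  export = reg$w_export,
                                  catalyzed = reg$w_catalyzed)
  set.seed(seed)
  nodes <- paste0("x", seq_len(n_nodes))
  pk <- seq_len(n_nodes)^(-connectivity_exponent)
  pick <- function(exclude = NULL) {
    p <- pk
    if (!is.null(exclude)) p[match(exclude, nodes)] <- 0
    sample(nodes, 1, prob = p)
  }
  fluxes <- vector("list", n_fluxes)
  fams <- sample(names(w), n_fluxes, replace = TRUE, prob = w)
  if (n_nodes == 1) fams[fams %in% c("conversion", "catalyzed")] <- "import"
  for (a in seq_len(n_fluxes)) {
    r <- 10^stats::runif(1, -1, 0.3)
    id <- paste0("J", a)
    fluxes[[a]] <- switch(fams[a],
      import = { # catalyzed import: growth of k proportional to catalyst c
        k <- pick(); cly <- pick()
        flux_spec(id, rate_linear(cly, r), stoich = stats::setNames(1, k))
      },
      conversion = {
        j <- pick(); k <- pick(exclude = j)
        flux_spec(id, rate_linear(j, r),
                  stoich = stats::setNames(c(-1, 1), c(j, k)))
      },
      export = {
        j <- pick()
        flux_spec(id, rate_linear(j, r), stoich = stats::setNames(-1, j))
      },
      catalyzed = { # j -> k catalyzed by z, Hill-saturated in j
        j <- pick(); k <- pick(exclude = j); z <- pick()
        flux_spec(id,
          rate_product(r = r, mono = stats::setNames(1, z),
                       sat = list(list(node = j, K = stats::runif(1, 0.05, 0.5),
                                       theta = sample(1:2, 1)))),
          stoich = stats::setNames(c(-1, 1), c(j, k)))
      })
  }
  build_network(nodes, fluxes)
}
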