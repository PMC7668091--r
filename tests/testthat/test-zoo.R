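# Model zoo: constructors, registry, samplers, chemostat, biosynthesis.

test_that("every zoo constructor builds a validated scalable network", {
  nets <- list(
    single_repressilator(theta = 1, K = 500),
    single_repressilator(theta = 3, K = 500),
    double_repressilator(100),
    limit_cycle_model(),
    bistable_model(),
    heteroclinic_model(),
    chaotic_community_model(),
    cross_feeding_community(lv_parameter_sampler(0.5, 1, seed = 1)[[1]]),
    biosynthesis_toy())
  for (net in nets) {
    expect_s3_class(net, "srn_network")
    expect_true(check_scalability(net, n_samples = 40)$is_srn)
  }
  # regenerative except where documented: the Lotka-Volterra-type models and
  # the biosynthesis model have self-catalyzed growth (extinction absorbing)
  expect_true(is_regenerative(nets[[1]]))  # single repressilator
  expect_true(is_regenerative(nets[[3]]))  # double repressilator
  expect_true(is_regenerative(nets[[5]]))  # bistable toggle
  expect_false(is_regenerative(nets[[6]])) # heteroclinic LV
  expect_false(is_regenerative(nets[[7]])) # chaotic community LV
  expect_false(is_regenerative(nets[[9]])) # biosynthesis (ribosome)
})

test_that("registry is stable and hash-stamped", {
  expect_identical(zoo_registry(), zoo_registry())
  h <- zoo_registry_hash()
  expect_match(h, "^[0-9a-f]{8}$")
  expect_identical(h, zoo_registry_hash())
})

test_that("repressilator limits: K -> 0 removes repression", {
  # with vanishing repression strength the synthesis flux is c*X1 and the
  # composition reaches a fixed point for any Hill coefficient
  for (th in c(1, 3)) {
    net <- single_repressilator(theta = th, K = 1e-12)
    tr <- simulate_simplex(net, c(0.1, 0.2, 0.3, 0.4), 400)
    expect_lt(attractor_diameter(tr, burn_in = 200), 1e-6)
  }
  expect_error(single_repressilator(theta = -1), "theta")
})

test_that("network behavior is invariant under node/flux reordering", {
  net <- single_repressilator(theta = 3, K = 500)
  netr <- build_network(rev(net$nodes), rev(net$fluxes))
  y0 <- c(x1 = 0.1, x2 = 0.2, x3 = 0.3, x4 = 0.4)
  l1 <- lambda_time_average(simulate_simplex(net, y0, 400))$lam
  l2 <- lambda_time_average(simulate_simplex(netr, y0[rev(net$nodes)], 400))$lam
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("lv_parameter_sampler: seeded, documented ranges", {
  s1 <- lv_parameter_sampler(0.5, 5, seed = 42)
  s2 <- lv_parameter_sampler(0.5, 5, seed = 42)
  expect_identical(s1, s2)

  s0 <- lv_parameter_sampler(0, 10, seed = 1)
  expect_true(all(vapply(s0, function(p) all(p$E == 0) && all(p$s == 0), TRUE)))

  sw <- lv_parameter_sampler(0.1, 10, seed = 1)
  for (p in sw) {
    expect_true(all(p$E >= 0 & p$E <= 0.1))
    expect_true(all(diag(p$E) == 0))
    expect_true(all(p$r >= 0.5 & p$r <= 1.5))
    expect_true(all(p$A >= 0 & p$A <= 1.5))
  }
})

test_that("community outcomes: handpicked exclusion and coexistence cases", {
  # symmetric weak competition, no cross-feeding: interior coexistence
  co <- community_outcome(list(r = rep(1, 3),
                               A = matrix(0.2, 3, 3) + diag(0.8, 3),
                               s = rep(0, 3), E = matrix(0, 3, 3)))
  expect_identical(co$n_survivors, 3L)

  # strong asymmetric competition: single-species vertex attractor
  A <- matrix(c(1, 2.5, 2.5,
                0.2, 1, 2.5,
                0.2, 0.2, 1), 3, 3, byrow = TRUE)
  ex <- community_outcome(list(r = c(1.2, 1, 0.9), A = A,
                               s = rep(0, 3), E = matrix(0, 3, 3)))
  expect_identical(ex$n_survivors, 1L)
})

test_that("chemostat wrapper: dilution terms, washout, modality sweep", {
  cs0 <- chemostat_cross_feeding(0)
  st <- c(rep(0.1, 3), rep(0.05, 3), 2)
  # at D = 0 the rhs has no dilution: compare against D > 0 analytically
  csD <- chemostat_cross_feeding(0.3)
  d0 <- cs0$rhs(0, st)
  dD <- csD$rhs(0, st)
  expect_equal(dD[1:6], d0[1:6] - 0.3 * st[1:6], tolerance = 1e-12)
  expect_equal(dD[7], d0[7] + 0.3 * (cs0$params$n_in - st[7]),
               tolerance = 1e-12)

  # dilution above every growth rate washes the culture out
  expect_identical(chemostat_modality(1.5, t_end = 300), "extinction")
})

test_that("biosynthesis toy: structure, conservation, flux-fraction limits", {
  net <- biosynthesis_toy()
  expect_length(net$nodes, 24L)
  # adenosine moiety conserved by every energy-coupled reaction; only the
  # dedicated nucleotide-synthesis flux creates ADP
  moiety <- net$S["ATP", ] + net$S["ADP", ]
  expect_equal(unname(moiety[names(moiety) != "nuc"]),
               rep(0, ncol(net$S) - 1))
  expect_equal(unname(moiety["nuc"]), 1)

  n <- length(net$nodes)
  tr <- simulate_simplex(net, rep(1 / n, n), 400, nout = 800, rtol = 1e-8)
  ge <- lambda_time_average(tr)
  expect_true(ge$converged)
  expect_gt(ge$lam, 0)

  fr <- catabolic_flux_fraction(net, tr)
  expect_gt(fr, 0)
  expect_lt(fr, 1)

  # anabolic pathways forced off: all consumption is catabolic
  net1 <- biosynthesis_toy(extra = list(v_pol = 0, thetaR = 1e-12))
  tr1 <- simulate_simplex(net1, rep(1 / n, n), 50, nout = 100, rtol = 1e-7)
  expect_equal(catabolic_flux_fraction(net1, tr1), 1)

  # catabolic pathway forced off
  net0 <- biosynthesis_toy(extra = list(v_cat = 0))
  tr0 <- simulate_simplex(net0, rep(1 / n, n), 50, nout = 100, rtol = 1e-7)
  # evaluate from t = 0: without catabolism the ATP pool empties and both
  # pathways eventually stall, but early polymerization flux is positive
  expect_equal(catabolic_flux_fraction(net0, tr0, burn_in = 0), 0)

  # no external nutrient: no growth
  netz <- biosynthesis_toy(nutrient_level = 1e-14)
  trz <- simulate_simplex(netz, rep(1 / n, n), 200, nout = 400, rtol = 1e-7)
  expect_lte(lambda_time_average(trz)$lam, 1e-6)
})

test_that("predicted_optimal_fraction: stoichiometric balance", {
  expect_equal(predicted_optimal_fraction(20), 5 / 23)
  expect_equal(round(predicted_optimal_fraction(20), 2), 0.22)
  expect_equal(round(predicted_optimal_fraction(10), 2), 0.38)
  expect_equal(round(predicted_optimal_fraction(30), 2), 0.15)
  # symmetric balance point: net yield equals the full anabolic cost
  expect_equal(predicted_optimal_fraction(7), 0.5)
  expect_error(predicted_optimal_fraction(2), "yield")
})

test_that("random_srn: deterministic, scalable, screening edge cases", {
  expect_identical(write_net_string(random_srn(seed = 5)),
                   write_net_string(random_srn(seed = 5)))
  ok <- vapply(1:30, function(i)
    check_scalability(random_srn(seed = 9000 + i), n_samples = 30)$is_srn,
    TRUE)
  expect_true(all(ok))

  # a network with no circuit cannot grow
  set.seed(1)
  found <- FALSE
  for (i in 1:50) {
    net <- random_srn(seed = 20000 + i)
    if (!max_autocatalytic_circuit(net)$is_circuit) {
      tr <- simulate_simplex(net, uniform_y0(net), 300, nout = 600)
      expect_lte(lambda_time_average(tr)$lam, 1e-6)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
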