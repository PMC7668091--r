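# Biomass ODE, rescaled simplex dynamics, and the Birkhoff time average.

test_that("biomass_rhs matches hand results and conserves N for conversions", {
  net <- build_network("x1", list(
    flux_spec("J", rate_linear("x1", 0.3), stoich = c(x1 = 1))))
  expect_equal(unname(biomass_rhs(net, c(x1 = 2))), 0.6)

  cv <- conversion_net(c1 = 1, c2 = 0)
  v <- biomass_rhs(cv, c(x1 = 1, x2 = 1))
  expect_equal(unname(v), c(-1, 1))
  expect_equal(sum(v), 0)

  expect_error(biomass_rhs(cv, c(x1 = -1, x2 = 1)), "negative")
})

test_that("biomass_rhs equals M X for linear networks (assembled oracle)", {
  for (s in 1:5) {
    lm <- random_linear_srn(4, seed = s)
    X <- stats::setNames(stats::runif(4, 0.2, 2), lm$net$nodes)
    expect_equal(unname(biomass_rhs(lm$net, X)), drop(lm$M %*% X),
                 tolerance = 1e-12)
  }
})

test_that("mu_instantaneous: birth-death, conversions, fixed point", {
  bd <- birth_death_net(0.5, 0.2)
  expect_equal(mu_instantaneous(bd, c(x1 = 1)), 0.3)
  expect_error(mu_instantaneous(bd, c(x1 = 1.1)), "not normalized")

  cv <- conversion_net()
  expect_equal(mu_instantaneous(cv, c(x1 = 0.4, x2 = 0.6)), 0)

  # balanced-growth fixed point: mu(Y*) equals lambda from a long run
  net <- single_repressilator(theta = 1, K = 500)
  tr <- simulate_simplex(net, rep_y0, 600, nout = 1200)
  ystar <- tr$Y[nrow(tr$Y), ]
  lam <- lambda_time_average(tr, burn_in = 400)$lam
  expect_equal(mu_instantaneous(net, ystar), lam, tolerance = 1e-6)
})

test_that("simplex_rhs components sum to zero and vanish where they must", {
  one <- build_network("x1", list(
    flux_spec("J", rate_linear("x1", 1), stoich = c(x1 = 1))))
  expect_equal(unname(simplex_rhs(one, c(x1 = 1))), 0)

  set.seed(4)
  for (s in 1:20) {
    net <- random_srn(n_nodes = sample(2:6, 1), seed = 300 + s)
    n <- length(net$nodes)
    y <- stats::runif(n)
    y <- y / sum(y)
    expect_lt(abs(sum(simplex_rhs(net, y))), 1e-12)
  }
})

test_that("simulate_biomass: analytic growth, conservation, blow-up guard", {
  bd <- birth_death_net(0.5, 0.2)
  tr <- simulate_biomass(bd, c(x1 = 1), 10)
  expect_equal(tail(tr$logN, 1), 3, tolerance = 1e-6)

  cv <- conversion_net()
  trc <- simulate_biomass(cv, c(x1 = 2, x2 = 1), 10)
  expect_equal(max(abs(exp(trc$logN) - 3)), 0, tolerance = 1e-7)

  expect_warning(simulate_biomass(bd, c(x1 = 1), 40, logN_guard = 5),
                 "blow-up")
})

test_that("simulate_biomass approaches the Perron growth rate (linear SRN)", {
  lm <- random_linear_srn(4, seed = 7)
  tr <- simulate_biomass(lm$net, rep(1, 4), 60, rtol = 1e-10, logN_guard = 400)
  slope <- (tr$logN[length(tr$t)] - tr$logN[which.min(abs(tr$t - 50))]) /
    (tr$t[length(tr$t)] - tr$t[which.min(abs(tr$t - 50))])
  expect_equal(slope, max(Re(eigen(lm$M)$values)), tolerance = 1e-6)
})

test_that("simulate_simplex: invariants, equivalence with biomass space", {
  bd <- birth_death_net(0.5, 0.2)
  tr <- simulate_simplex(bd, c(x1 = 1), 10)
  expect_true(all(tr$Y == 1))
  expect_equal(range(tr$mu), c(0.3, 0.3), tolerance = 1e-12)

  # simplex conservation and positivity on random networks
  set.seed(8)
  for (s in 1:10) {
    net <- random_srn(n_nodes = sample(3:6, 1), seed = 400 + s)
    tr <- simulate_simplex(net, uniform_y0(net), 30, nout = 300)
    expect_lt(max(abs(rowSums(tr$Y) - 1)), 1e-8)
    expect_gte(min(tr$Y), 0)
  }

  # logN path equals the biomass-space one while both are finite
  for (s in 1:20) {
    net <- random_srn(n_nodes = sample(3:6, 1), n_fluxes = 8, seed = 1000 + s)
    n <- length(net$nodes)
    set.seed(s)
    X0 <- stats::setNames(stats::runif(n, 0.5, 2), net$nodes)
    tb <- simulate_biomass(net, X0, 20, nout = 400, rtol = 1e-10, atol = 1e-13)
    ts <- simulate_simplex(net, X0 / sum(X0), 20, nout = 400,
                           rtol = 1e-10, atol = 1e-13)
    keep <- is.finite(tb$logN) & tb$logN < 50
    expect_lt(max(abs(tb$logN[keep] - (ts$logN[keep] + log(sum(X0))))), 1e-5)
  }
})

test_that("limit-cycle lambda is initial-condition independent", {
  net <- limit_cycle_model()
  t1 <- simulate_simplex(net, c(0.5, 0.3, 0.2), 4000, nout = 8000)
  t2 <- simulate_simplex(net, c(0.2, 0.2, 0.6), 4000, nout = 8000)
  l1 <- lambda_time_average(t1, burn_in = 2000)
  l2 <- lambda_time_average(t2, burn_in = 2000)
  expect_true(l1$converged && l2$converged)
  expect_lt(abs(l1$lam - l2$lam), 1e-4)
})

test_that("lambda_time_average: exact and closed-form oracles", {
  # constant mu: lambda = c exactly
  t <- seq(0, 100, by = 0.1)
  traj <- structure(list(t = t, mu = rep(0.37, length(t)),
                         Y = matrix(1, length(t), 1),
                         logN = 0.37 * t, meta = list(nodes = "x1")),
                    class = "srn_trajectory")
  ge <- lambda_time_average(traj)
  expect_equal(ge$lam, 0.37, tolerance = 1e-12)
  expect_true(ge$converged)

  # mu = c + sin(t): closed-form average (c (T-b) - cos T + cos b)/(T-b)
  t <- seq(0, 1000, by = 0.05)
  mu <- 0.2 + sin(t)
  traj$t <- t; traj$mu <- mu; traj$Y <- matrix(1, length(t), 1)
  ge <- lambda_time_average(traj, burn_in = 0)
  expect_lt(abs(ge$lam - 0.2), 2e-3)

  expect_error(lambda_time_average(traj, burn_in = 2000), "burn_in")
})

test_that("running average of the double repressilator settles", {
  net <- double_repressilator(500)
  tr <- simulate_simplex(net, dbl_y0, 1500, nout = 3000)
  ge <- lambda_time_average(tr, tol = 1e-3)
  expect_true(ge$converged)
})

test_that("trajectory export is tidy CSV", {
  bd <- birth_death_net()
  tr <- simulate_simplex(bd, c(x1 = 1), 5, nout = 50)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(df), c("t", "x1", "logN", "mu"))
  expect_equal(nrow(df), 51L)
})
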