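# Attractor classification, occupation measures, Lyapunov exponents, scans.

test_that("attractor_diameter: analytic cases and invariances", {
  P <- matrix(rep(c(0.2, 0.3, 0.5), each = 10), ncol = 3)
  expect_equal(attractor_diameter(P), 0)

  verts <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(attractor_diameter(verts), sqrt(2))

  expect_error(attractor_diameter(verts[1, , drop = FALSE]), "at least 2")

  set.seed(1)
  P <- matrix(stats::runif(300), ncol = 3)
  d_full <- attractor_diameter(P)
  expect_equal(attractor_diameter(P[, c(3, 1, 2)]), d_full) # node permutation
  expect_lte(attractor_diameter(P[seq(1, 100, by = 2), ]), d_full) # subsample
})

test_that("classifier: fixed point vs limit cycle at repressilator defaults", {
  net1 <- single_repressilator(theta = 1, K = 500)
  tr1 <- simulate_simplex(net1, rep_y0, 600, nout = 2400)
  att1 <- classify_attractor(tr1, network = net1, burn_in = 300)
  expect_identical(att1$label, "fixed_point")
  expect_lte(att1$diameter, 1e-4)

  net3 <- single_repressilator(theta = 3, K = 500)
  tr3 <- simulate_simplex(net3, rep_y0, 800, nout = 3200)
  att3 <- classify_attractor(tr3, network = net3, burn_in = 400)
  expect_identical(att3$label, "limit_cycle")
  expect_gt(att3$diameter, 0.05)
  expect_true(is.finite(att3$period) && att3$period > 0)
})

test_that("classifier: heteroclinic dwell-time cascade", {
  net <- heteroclinic_model()
  tr <- simulate_simplex(net, c(0.5, 0.3, 0.2), 2000, nout = 8000)
  att <- classify_attractor(tr, network = net, burn_in = 30)
  expect_identical(att$label, "heteroclinic_suspect")
  # running lambda average keeps drifting between vertex growth rates
  expect_false(lambda_time_average(tr, window = 0.6)$converged)
})

test_that("classifier is deterministic given trajectory and options", {
  net <- single_repressilator(theta = 3, K = 500)
  tr <- simulate_simplex(net, rep_y0, 400, nout = 1600)
  a1 <- classify_attractor(tr, network = net, burn_in = 200)
  a2 <- classify_attractor(tr, network = net, burn_in = 200)
  expect_identical(a1$label, a2$label)
  expect_identical(a1$lle, a2$lle)
})

test_that("largest_lyapunov: sign structure across regimes", {
  # fixed-point regime: contraction, lle < 0, agrees with the dominant
  # eigenvalue of a finite-difference Jacobian of the simplex flow at Y*
  net <- single_repressilator(theta = 1, K = 500)
  tr <- simulate_simplex(net, rep_y0, 600, nout = 600)
  ystar <- tr$Y[nrow(tr$Y), ]
  lle <- largest_lyapunov(net, pmax(ystar, 1e-12) / sum(pmax(ystar, 1e-12)),
                          t_end = 300)
  expect_lt(lle, 0)
  # finite-difference Jacobian of the simplex flow restricted to an
  # orthonormal basis of the tangent space (zero-sum vectors)
  n <- length(ystar)
  B <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n] # orthonormal, sum-zero cols
  h <- 1e-7
  f0 <- simplex_rhs(net, ystar)
  A <- matrix(0, n - 1, n - 1)
  for (k in seq_len(n - 1)) {
    g <- (simplex_rhs(net, ystar + h * B[, k]) - f0) / h
    A[, k] <- drop(t(B) %*% g)
  }
  expect_equal(lle, max(Re(eigen(A)$values)), tolerance = 0.02)

  # limit cycle: neutral direction along the flow
  net3 <- single_repressilator(theta = 3, K = 500)
  tr3 <- simulate_simplex(net3, rep_y0, 800, nout = 800)
  y <- tr3$Y[nrow(tr3$Y), ]
  lle3 <- largest_lyapunov(net3, pmax(y, 1e-9) / sum(pmax(y, 1e-9)),
                           t_end = 600)
  expect_lt(abs(lle3), 0.01)
})

test_that("chaotic community: positive exponent, chaotic label, lambda converges", {
  net <- chaotic_community_model()
  tr <- simulate_simplex(net, chaotic_community_y0(), 1500, nout = 6000,
                         rtol = 1e-10)
  att <- classify_attractor(tr, network = net, burn_in = 750,
                            lle_t_end = 1500)
  expect_gt(att$lle, 0.005)
  expect_identical(att$label, "chaotic")
  expect_true(lambda_time_average(tr, tol = 2e-3)$converged)
})

test_that("occupation_measure: masses, degenerate and uniform cases", {
  # constant trajectory at a vertex: single occupied bin with mass 1
  t <- seq(0, 10, by = 0.1)
  traj <- structure(list(t = t, Y = matrix(rep(c(1, 0, 0), each = length(t)),
                                           ncol = 3),
                         mu = rep(0.2, length(t)), logN = 0.2 * t,
                         meta = list(nodes = c("a", "b", "c"))),
                    class = "srn_trajectory")
  om <- occupation_measure(traj, bins = 10)
  expect_equal(nrow(om$table), 1L)
  expect_equal(om$table$mass, 1)
  expect_equal(sum(om$table$mass), 1, tolerance = 1e-12)
  expect_equal(lambda_space_average(om), 0.2)

  # uniform samples on the 2-simplex: bin masses match bin areas within a
  # multinomial bound. On the (Y1, Y2) grid with 5 bins per axis, cells with
  # i + j <= 3 lie fully inside the simplex (area fraction 2/25 each) and the
  # diagonal cells i + j == 4 are half-cells (1/25).
  set.seed(5)
  ns <- 40000
  e <- matrix(stats::rexp(3 * ns), ncol = 3)
  traj$t <- seq_len(ns)
  traj$Y <- e / rowSums(e)
  traj$mu <- rep(1, ns)
  om <- occupation_measure(traj, bins = 5, burn_in = 0)
  ij <- do.call(rbind, lapply(strsplit(om$table$bin, ","), as.integer))
  p_exp <- ifelse(rowSums(ij) <= 3, 2 / 25, 1 / 25)
  se <- sqrt(p_exp * (1 - p_exp) / ns)
  expect_true(all(abs(om$table$mass - p_exp) < 5 * se))
  expect_equal(sum(om$table$mass), 1, tolerance = 1e-12)
})

test_that("lambda_space_average: weighted mean and Birkhoff agreement", {
  om <- structure(list(table = data.frame(bin = c("a", "b"),
                                          mass = c(0.25, 0.75),
                                          mu_mean = c(0.4, 0.0)),
                       bins = 2, n = 2), class = "srn_occupation")
  expect_equal(lambda_space_average(om), 0.1)

  net <- single_repressilator(theta = 3, K = 500)
  tr <- simulate_simplex(net, rep_y0, 1200, nout = 4800)
  lam_t <- lambda_time_average(tr, burn_in = 600)$lam
  lam_s <- lambda_space_average(occupation_measure(tr, burn_in = 600))
  expect_lt(abs(lam_t - lam_s), 1e-4)
})

test_that("scan_phase_diagram: single point equals direct pipeline; regimes", {
  fac <- function(prm) single_repressilator(theta = prm$theta, K = prm$K)
  sc <- scan_phase_diagram(fac, list(theta = 3, K = 500), t_end = 400,
                           Y0 = rep_y0, classify = FALSE)
  direct <- simulate_simplex(fac(list(theta = 3, K = 500)), rep_y0, 400,
                             nout = 2000, rtol = 1e-8, atol = 1e-10)
  expect_equal(sc$result$lambda, lambda_time_average(direct)$lam,
               tolerance = 1e-12)

  sc2 <- scan_phase_diagram(fac, list(theta = c(1, 3), K = 500), t_end = 600,
                            Y0 = rep_y0, classify = TRUE, burn_in = 300)
  r <- sc2$result[order(sc2$result$theta), ]
  # lambda increases across the fixed-point -> limit-cycle transition and the
  # diameter goes from zero to positive
  expect_lt(r$lambda[1], r$lambda[2])
  expect_lte(r$diameter[1], 1e-4)
  expect_gt(r$diameter[2], 0.05)
  expect_identical(r$label, c("fixed_point", "limit_cycle"))

  # per-point failures are recorded, not fatal
  bad <- scan_phase_diagram(function(prm) stop("boom"), list(a = 1))
  expect_identical(bad$result$label, "error")
})
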