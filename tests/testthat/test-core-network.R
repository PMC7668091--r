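# Data model, validation, and the three scalability conditions.

test_that("build_network validates structure and assembles S", {
  # minimal autocatalytic import: one node catalyzing its own influx
  net <- build_network("x1", list(
    flux_spec("J", rate_linear("x1", 1), stoich = c(x1 = 1))))
  expect_s3_class(net, "srn_network")
  expect_equal(dim(net$S), c(1L, 1L))
  expect_equal(net$S["x1", "J"], 1)

  expect_error(build_network(c("a", "a"), list(
    flux_spec("J", rate_linear("a", 1), stoich = c(a = 1)))), "duplicate node")
  # negative stoichiometry requires upstream declaration
  expect_error(flux_spec("J", rate_linear("x1", 1), stoich = c(x1 = -1),
                         upstream = character(0)), "not declared upstream")
  # upstream must be inside the maintenance set
  expect_error(flux_spec("J", rate_linear("x1", 1), stoich = c(x1 = -1),
                         maintenance = "x2"), "maintenance")
  # rates may only reference declared nodes
  expect_error(build_network("x1", list(
    flux_spec("J", rate_linear("x9", 1), stoich = c(x1 = 1)))),
    "undeclared node")
})

test_that("repressilator network has the documented 4x5 stoichiometry", {
  net <- single_repressilator(theta = 3, K = 500)
  expect_equal(dim(net$S), c(4L, 5L))
  # J2..J4 are pure conversions (columns sum to zero); J1 import, J5 export
  cs <- colSums(net$S)
  expect_equal(unname(cs), c(1, 0, 0, 0, -1))
})

test_that("homogeneity check: scalable families pass, others fail", {
  nodes <- c("x1", "x2")
  lin <- flux_spec("J", rate_linear("x1", 0.7), stoich = c(x1 = 1))
  expect_true(check_homogeneity(lin, nodes = nodes)$pass)

  quad <- flux_spec("J", rate_product(0.3, mono = c(x1 = 2, x2 = 1)),
                    stoich = c(x1 = 1))
  expect_true(check_homogeneity(quad, nodes = nodes)$pass)

  # same forms via the expression grammar take the numeric path
  expr_ok <- flux_spec("J",
    rate_expression("0.5 * X1 / (1 + 500 * (X2/N)^2)", maintenance = "X1"),
    stoich = c(X1 = 1))
  chk <- check_homogeneity(expr_ok, nodes = c("X1", "X2"), seed = 1)
  expect_true(chk$pass)
  expect_identical(chk$method, "numeric")

  # asymptotically scalable rational form: fails exact homogeneity
  asym <- flux_spec("J",
    rate_expression("X1 * (1 + 2*X2 + 3*X2^2) / (2 + X2 + X2^2)",
                    maintenance = "X1"),
    stoich = c(X1 = 1))
  expect_false(check_homogeneity(asym, nodes = c("X1", "X2"), seed = 1)$pass)
  expect_true(check_asymptotic_scalability(asym, nodes = c("X1", "X2"))$asymptotic)

  # constant flux: J(cX) = r != c r
  const <- flux_spec("J", rate_custom(function(X, N) 2), stoich = c(x1 = 1))
  expect_false(check_homogeneity(const, nodes = "x1", seed = 1)$pass)
})

test_that("upstream-limited check (condition 2)", {
  nodes <- c("xj", "xk", "xz")
  # two-substrate ratio family vanishes when either substrate is depleted
  ratio <- flux_spec("J", rate_ratio("xj", "xk", a = 1, b = 2, c = 0.5, r = 1),
                     stoich = c(xj = -1, xk = -1, xz = 2))
  expect_true(check_upstream_limited(ratio, nodes = nodes)$pass)

  # rate ignores xk: declaring xk upstream must fail
  bad <- flux_spec("J", rate_linear("xj", 1), stoich = c(xj = -1),
                   upstream = c("xj", "xk"), maintenance = c("xj", "xk"))
  expect_false(check_upstream_limited(bad, nodes = nodes)$pass)

  # Hill-maintained conversion: J = r Xz (Yj^th)/(K + Yj^th), mt = {xj, xz}
  hill <- flux_spec("J",
    rate_product(1, mono = c(xz = 1),
                 sat = list(list(node = "xj", K = 0.3, theta = 2))),
    stoich = c(xj = -1, xz = 1))
  expect_true("xz" %in% hill$maintenance)
  expect_true(check_upstream_limited(hill, nodes = nodes)$pass)
})

test_that("check_scalability aggregates and names offenders", {
  net <- build_network(c("x1", "x2"), list(
    flux_spec("lin", rate_linear("x1", 1), stoich = c(x1 = -1, x2 = 1)),
    flux_spec("quad", rate_product(0.5, mono = c(x1 = 1, x2 = 1)),
              stoich = c(x2 = -1)),
    flux_spec("ratio", rate_ratio("x1", "x2", 1, 1, 1, r = 2),
              stoich = c(x1 = -1, x2 = -1))))
  rep1 <- check_scalability(net, n_samples = 60)
  expect_true(rep1$is_srn)

  net2 <- build_network(c("x1", "x2"), c(net$fluxes, list(
    flux_spec("const", rate_custom(function(X, N) 1), stoich = c(x1 = 1)))))
  rep2 <- check_scalability(net2, n_samples = 60)
  expect_false(rep2$is_srn)
  expect_false(rep2$verdicts$scalable[rep2$verdicts$flux == "const"])

  # verdict is stable under node and flux reordering
  net3 <- build_network(c("x2", "x1"), rev(net$fluxes))
  expect_true(check_scalability(net3, n_samples = 60)$is_srn)
})

test_that("flux_from_unit_volume lifts concentration laws to scalable rates", {
  # Michaelis-Menten per unit volume, arbitrary volume-per-biomass b
  mm <- flux_from_unit_volume(function(conc) 2 * conc[1] / (0.5 + conc[1]),
                              b = 1.7, maintenance = "x1")
  fx <- flux_spec("J", mm, stoich = c(x1 = -1, x2 = 1))
  chk <- check_homogeneity(fx, n_samples = 100, tol = 1e-9, seed = 42,
                           nodes = c("x1", "x2"))
  expect_true(chk$pass)

  # linear case collapses to k*X1 exactly
  lin <- flux_from_unit_volume(function(conc) 3 * conc[1], b = 2.3)
  X <- c(x1 = 1.4, x2 = 0.6)
  expect_equal(eval_rate(lin, X, sum(X)), 3 * 1.4)

  # mass-action quadratic matches the Table-family form k X1 X2 / (b N)
  quad <- flux_from_unit_volume(function(conc) 4 * conc[1] * conc[2], b = 2)
  expect_equal(eval_rate(quad, X, sum(X)), 4 * 1.4 * 0.6 / (2 * sum(X)))
})

test_that("scalable rates vanish in the small-size limit", {
  # homogeneity => J(c X) -> 0 as c -> 0
  rates <- list(rate_linear("x1", 1),
                rate_product(2, mono = c(x1 = 1, x2 = 1)),
                rate_product(1, mono = c(x1 = 1),
                             sat = list(list(node = "x2", K = 0.2, theta = 2))),
                rate_ratio("x1", "x2", 1, 1, 1),
                flux_from_unit_volume(function(conc) conc[1] / (1 + conc[1])))
  X1 <- c(x1 = 0.4, x2 = 0.6)          # ||X|| = 1 scale
  for (r in rates) {
    J1 <- eval_rate(r, X1, sum(X1))
    J0 <- eval_rate(r, 1e-12 * X1, 1e-12 * sum(X1))
    expect_lte(J0, 1e-10 * J1)
  }
})

test_that("property: unit-volume lifts are homogeneous over a rate grammar", {
  set.seed(99)
  for (i in 1:20) {
    k <- stats::runif(3, 0.1, 3)
    junit <- switch(sample(3, 1),
      function(conc) k[1] * conc[1],
      function(conc) k[1] * conc[1] * conc[2],
      function(conc) k[1] * conc[1] / (k[2] + conc[1]) * conc[2] /
        (k[3] + conc[2]))
    fx <- flux_spec("J", flux_from_unit_volume(junit, b = stats::runif(1, 0.5, 2)),
                    stoich = c(x1 = 1))
    expect_true(check_homogeneity(fx, n_samples = 60, tol = 1e-9, seed = i,
                                  nodes = c("x1", "x2"))$pass)
  }
})
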