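# ---------------------------------------------------------------------------
# Deterministic dynamics.
#
# Biomass space:  dX_k/dt = sum_a S_ka J_a(X)            (the network ODE)
# System size:    N = sum_k X_k,  mu(t) = d/dt log N(t)
# Simplex space:  dY_k/dt = sum_a S_ka J_a(Y) - mu(Y) Y_k (rescaled dynamics)
#
# For an SRN the fluxes are degree-1 homogeneous, so J_a(X)/N = J_a(Y): the
# composition evolves autonomously on the unit simplex and mu is a function of
# composition alone. The long-term growth rate is the Birkhoff time average
# lambda = lim (1/t) int_0^t mu dt'.
# ---------------------------------------------------------------------------

new_trajectory <- function(t, Y, logN, mu, meta, X = NULL) {
  colnames(Y) <- meta$nodes
  structure(list(t = t, Y = Y, logN = logN, mu = mu, X = X, meta = meta),
            class = "srn_trajectory")
}

#' @export
print.srn_trajectory <- function(x, ...) {
  cat("<srn_trajectory> ", length(x$t), " samples over t = [",
      min(x$t), ", ", max(x$t), "], ", ncol(x$Y), " nodes\n", sep = "")
  cat("  final mu:", signif(tail(x$mu, 1), 6),
      " logN span:", signif(tail(x$logN, 1) - x$logN[1], 6), "\n")
  invisible(x)
}

#' Right-hand side of the biomass ODE
#' @param network an `srn_network`.
#' @param X nonnegative biomass vector.
#' @return named vector dX/dt = S J(X).
#' @export
biomass_rhs <- function(network, X) {
  X <- as_state(network, X)
  if (any(X < -1e-10)) stop("negative biomass component beyond tolerance")
  X[X < 0] <- 0
  drop(network$S %*% network_fluxes(network, X))
}

#' Instantaneous growth rate from composition
#'
#' For an SRN, summing the rescaled ODE over components gives
#' `mu(Y) = sum_k sum_a S_ka J_a(Y)`, independent of system size.
#' @param network an `srn_network`.
#' @param Y point on the unit simplex (must be normalized within 1e-8).
#' @return scalar growth rate (1/time).
#' @export
mu_instantaneous <- function(network, Y) {
  Y <- as_state(network, Y)
  if (abs(sum(Y) - 1) > 1e-8) stop("Y is not normalized: sum(Y) = ", sum(Y))
  sum(biomass_rhs(network, Y))
}

#' Right-hand side of the rescaled (simplex) dynamics
#' @inheritParams mu_instantaneous
#' @return named vector dY/dt = S J(Y) - mu(Y) Y; components sum to zero.
#' @export
simplex_rhs <- function(network, Y) {
  Y <- as_state(network, Y)
  if (abs(sum(Y) - 1) > 1e-8) stop("Y is not normalized: sum(Y) = ", sum(Y))
  v <- biomass_rhs(network, Y)
  v - sum(v) * Y
}

# --- pure-R Dormand-Prince 5(4), used for custom-rate networks and the
# chemostat wrapper; mirrors the compiled kernel ---------------------------
dp_tableau <- list(
  a = list(c(), 1 / 5, c(3 / 40, 9 / 40), c(44 / 45, -56 / 15, 32 / 9),
           c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
           c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
           c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)),
  b5 = c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0),
  b4 = c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
         187 / 2100, 1 / 40)
)

rk45_r <- function(f, y0, times, rtol = 1e-9, atol = 1e-12) {
  tb <- dp_tableau
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- diff(range(times)) / 1e4
  for (i in 2:length(times)) {
    tt <- times[i]
    repeat {
      if (t >= tt - 1e-14 * max(1, abs(tt))) break
      h <- min(h, tt - t)
      k <- matrix(0, 7, n)
      k[1, ] <- f(t, y)
      for (s in 2:7) {
        ys <- y + h * drop(tb$a[[s]] %*% k[seq_len(s - 1), , drop = FALSE])
        k[s, ] <- f(t + h * sum(tb$a[[s]]), ys)
      }
      y5 <- y + h * drop(tb$b5 %*% k)
      y4 <- y + h * drop(tb$b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err)) { h <- h / 10; next }
      if (err <= 1) {
        t <- t + h
        y <- y5
        h <- h * min(5, max(0.2, 0.9 * err^-0.2))
      } else {
        h <- h * max(0.1, 0.9 * err^-0.2)
        if (h < 1e-13 * max(1, abs(t))) stop("step size underflow at t = ", t)
      }
    }
    out[i, ] <- y
  }
  out
}

default_nout <- function(t_end) max(1000L, min(4000L, as.integer(t_end * 10)))

#' Integrate the biomass ODE
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) integration of
#' `dX/dt = S J(X)`. Components entering `[-atol, 0)` are clamped to zero
#' before flux evaluation, which is consistent because upstream-limited fluxes
#' vanish at depleted nodes. For a growing SRN the biomass blows up
#' exponentially; integration stops with a warning when `log N` exceeds
#' `logN_guard` (default 250) -- use [simulate_simplex()] beyond that.
#'
#' @param network an `srn_network`.
#' @param X0 nonnegative initial biomass vector, not all zero.
#' @param t_end end time (time units are arbitrary; all shipped models use
#'   unit-rate scaling).
#' @param nout number of output samples (uniform grid).
#' @param rtol,atol integration tolerances.
#' @param logN_guard overflow guard on log N.
#' @return an `srn_trajectory` with the biomass path `X`, composition `Y`,
#'   `logN` and `mu`.
#' @export
simulate_biomass <- function(network, X0, t_end, nout = default_nout(t_end),
                             rtol = 1e-9, atol = 1e-12, logN_guard = 250) {
  X0 <- as_state(network, X0)
  stopifnot(all(X0 >= 0), sum(X0) > 0, t_end > 0)
  if (!is.null(network$compiled)) {
    res <- cpp_simulate_biomass(network$compiled, unname(X0), t_end,
                                as.integer(nout), rtol, atol, logN_guard)
    keep <- seq_len(res$last)
    tvec <- res$t[keep]
    X <- res$X[keep, , drop = FALSE]
    mu <- res$mu[keep]
    logN <- res$logN[keep]
    if (!is.na(res$blowup_time) && res$blowup_time < t_end)
      warning("biomass blow-up guard hit at t = ", signif(res$blowup_time, 6),
              "; simulate in simplex space for long-term growth")
  } else {
    times <- seq(0, t_end, length.out = nout + 1)
    f <- function(t, x) {
      x[x < 0] <- 0
      drop(network$S %*% vapply(network$fluxes,
                                function(fl) eval_rate(fl$rate,
                                  stats::setNames(x, network$nodes), sum(x)), 0))
    }
    X <- rk45_r(f, unname(X0), times, rtol, atol)
    tvec <- times
    Ntot <- rowSums(X)
    logN <- log(Ntot)
    mu <- vapply(seq_along(tvec), function(i)
      sum(f(tvec[i], X[i, ])) / Ntot[i], 0)
  }
  X[X < 0] <- 0
  Ntot <- rowSums(X)
  Y <- X / Ntot
  meta <- list(solver = "dopri5", rtol = rtol, atol = atol,
               space = "biomass", nodes = network$nodes, X0 = X0,
               t_end = t_end)
  colnames(X) <- network$nodes
  new_trajectory(tvec, Y, logN, mu, meta, X = X)
}

#' Integrate the rescaled dynamics on the simplex
#'
#' Integrates `dY/dt = S J(Y) - mu(Y) Y`. The simplex is compact, so there is
#' no blow-up; `log N` (with `log N(0) = 0`) is carried as an additional
#' integrated state `d log N/dt = mu(Y)`, so it has full ODE accuracy. Output
#' compositions are clamped to `[0, 1]` and renormalized, keeping
#' `|sum(Y) - 1| <= 1e-8` at every sample.
#'
#' @param network an `srn_network`.
#' @param Y0 initial composition on the unit simplex.
#' @param t_end end time.
#' @inheritParams simulate_biomass
#' @return an `srn_trajectory`.
#' @export
simulate_simplex <- function(network, Y0, t_end, nout = default_nout(t_end),
                             rtol = 1e-9, atol = 1e-12) {
  Y0 <- as_state(network, Y0)
  stopifnot(all(Y0 >= 0), abs(sum(Y0) - 1) < 1e-6, t_end > 0)
  Y0 <- Y0 / sum(Y0)
  if (!is.null(network$compiled)) {
    res <- cpp_simulate_simplex(network$compiled, unname(Y0), t_end,
                                as.integer(nout), rtol, atol)
    if (!res$ok) stop("simplex integration failed (step size underflow)")
    tvec <- res$t
    Y <- res$Y
    mu <- res$mu
    logN <- res$logN
  } else {
    times <- seq(0, t_end, length.out = nout + 1)
    f <- function(t, y) {
      y[y < 0] <- 0
      v <- drop(network$S %*% vapply(network$fluxes,
            function(fl) eval_rate(fl$rate,
              stats::setNames(y, network$nodes), sum(y)), 0))
      v - sum(v) * y / sum(y)
    }
    Y <- rk45_r(f, unname(Y0), times, rtol, atol)
    Y[Y < 0] <- 0
    Y <- Y / rowSums(Y)
    tvec <- times
    mu <- vapply(seq_len(nrow(Y)), function(i)
      sum(drop(network$S %*% vapply(network$fluxes,
        function(fl) eval_rate(fl$rate,
          stats::setNames(Y[i, ], network$nodes), 1), 0))), 0)
    logN <- cumtrapz(tvec, mu)
  }
  meta <- list(solver = "dopri5", rtol = rtol, atol = atol, space = "simplex",
               nodes = network$nodes, Y0 = Y0, t_end = t_end)
  new_trajectory(tvec, Y, logN, mu, meta)
}

cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Long-term growth rate as a Birkhoff time average
#'
#' Computes `lambda = (1/T) int mu dt` over the post-burn-in part of a
#' trajectory (trapezoidal rule), together with the running average
#' `(1/t) int_0^t mu dt'` and a convergence flag: converged iff the running
#' average varies by less than `tol` over the last `window` fraction of the
#' run. A heteroclinic-type trajectory, whose running average keeps
#' oscillating, is reported as non-converged rather than silently averaged.
#'
#' @param traj an `srn_trajectory`.
#' @param burn_in transient time to discard (default: first 20% of the run).
#' @param tol convergence tolerance on the running average.
#' @param window fraction of the run used for the convergence check.
#' @return object of class `srn_growth_estimate` with elements `lam`,
#'   `running` (data.frame t, value), `converged`, `tol`, `burn_in`.
#' @export
lambda_time_average <- function(traj, burn_in = NULL, tol = 1e-3,
                                window = 0.2) {
  t <- traj$t
  mu <- traj$mu
  t_end <- max(t)
  burn_in <- burn_in %||% (0.2 * t_end)
  if (sum(t > burn_in) < 2) stop("trajectory shorter than burn_in")
  keep <- t >= burn_in
  tk <- t[keep]
  lam <- trapz(tk, mu[keep]) / (max(tk) - min(tk))
  run <- cumtrapz(t, mu) / pmax(t, .Machine$double.eps)
  run[1] <- mu[1]
  inwin <- t >= (1 - window) * t_end
  converged <- (max(run[inwin]) - min(run[inwin])) < tol
  structure(list(lam = lam, running = data.frame(t = t, value = run),
                 converged = converged, tol = tol, burn_in = burn_in),
            class = "srn_growth_estimate")
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' @export
print.srn_growth_estimate <- function(x, ...) {
  cat("<srn_growth_estimate> lambda =", signif(x$lam, 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' Columns: t, one column per node composition, logN, mu.
#' @param traj an `srn_trajectory`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$t, traj$Y, logN = traj$logN, mu = traj$mu,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
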