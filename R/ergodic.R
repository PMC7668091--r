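# ---------------------------------------------------------------------------
# Ergodic analysis of the rescaled flow.
#
# The composition dynamics live on the compact simplex, so ergodic measures
# exist and the Birkhoff theorem equates the time average of mu along a
# trajectory with the space average of mu over the occupation measure. The
# routines here estimate that measure from post-transient samples, classify
# the supporting attractor, and compute lambda both ways.
# ---------------------------------------------------------------------------

post_transient <- function(traj, burn_in = NULL) {
  t_end <- max(traj$t)
  burn_in <- burn_in %||% (0.2 * t_end)
  keep <- traj$t >= burn_in
  list(Y = traj$Y[keep, , drop = FALSE], t = traj$t[keep], mu = traj$mu[keep])
}

#' Attractor diameter
#'
#' Maximum pairwise Euclidean distance `max |Y - Y'|` over post-transient
#' samples: zero for a fixed point, positive for a limit cycle or stranger
#' attractors. Exact for up to 5000 points; larger sets are deterministically
#' thinned to 5000 evenly spaced points first (the thinned diameter is a lower
#' bound, within sampling resolution of the exact one).
#'
#' @param support_points matrix of simplex points (rows) or an
#'   `srn_trajectory` (post-transient part is used).
#' @param burn_in transient to discard when a trajectory is given.
#' @return nonnegative scalar.
#' @export
attractor_diameter <- function(support_points, burn_in = NULL) {
  if (inherits(support_points, "srn_trajectory"))
    support_points <- post_transient(support_points, burn_in)$Y
  P <- as.matrix(support_points)
  if (nrow(P) < 2) stop("need at least 2 post-transient points")
  if (nrow(P) > 5000)
    P <- P[unique(round(seq(1, nrow(P), length.out = 5000))), , drop = FALSE]
  # max pairwise distance: compare against the running hull of extremes is
  # overkill at this size; direct blocked computation is fine.
  d2max <- 0
  nrm <- rowSums(P^2)
  step <- 1000L
  for (i0 in seq(1, nrow(P), by = step)) {
    idx <- i0:min(i0 + step - 1L, nrow(P))
    G <- P[idx, , drop = FALSE] %*% t(P)
    D2 <- outer(nrm[idx], rep(1, nrow(P))) + outer(rep(1, length(idx)), nrm) - 2 * G
    d2max <- max(d2max, max(D2))
  }
  sqrt(max(d2max, 0))
}

# mean-removed periodogram averaged over components; returns freq, power
trajectory_periodogram <- function(Y, dt) {
  n <- nrow(Y)
  pw <- 0
  for (k in seq_len(ncol(Y))) {
    x <- Y[, k] - mean(Y[, k])
    sp <- Mod(stats::fft(x))^2 / n
    pw <- pw + sp
  }
  nf <- floor(n / 2)
  freq <- (seq_len(nf) - 1) / (n * dt)
  list(freq = freq[-1], power = pw[2:nf])
}

# prominent local maxima: power >= prom * median power
spectral_peaks <- function(freq, power, prominence = 10) {
  medp <- stats::median(power)
  if (medp <= 0) medp <- .Machine$double.xmin
  loc <- which(diff(sign(diff(power))) == -2) + 1
  loc <- loc[power[loc] >= prominence * medp]
  if (length(loc) == 0) return(data.frame(freq = numeric(0), power = numeric(0)))
  ord <- order(power[loc], decreasing = TRUE)
  data.frame(freq = freq[loc][ord], power = power[loc][ord])
}

# TRUE if all peak frequencies are near-integer multiples of a common base;
# df is the periodogram frequency resolution, which bounds how precisely a
# peak can sit on its harmonic.
harmonically_related <- function(freqs, df = 0, rel_tol = 0.03) {
  if (length(freqs) <= 1) return(TRUE)
  base <- min(freqs)
  k <- round(freqs / base)
  all(abs(freqs - k * base) <= pmax(2 * df, rel_tol * k * base))
}

# dwell episodes: contiguous time stretches with max(Y) > thr
vertex_dwells <- function(Y, t, thr = 0.95) {
  near <- apply(Y, 1, max) > thr
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(t_start = t[starts[keep]], t_end = t[ends[keep]],
             dwell = t[ends[keep]] - t[starts[keep]])
}

#' Classify the attractor of a trajectory
#'
#' Decision cascade over post-transient samples:
#' (i) attractor diameter at most `diam_tol` -> `fixed_point`;
#' (ii) at least `dwell_visits` near-vertex dwell episodes with strictly
#' increasing durations -> `heteroclinic_suspect` (tested before the spectral
#' steps because lengthening dwells break the stationarity that the
#' periodogram and a finite-time Lyapunov estimate assume);
#' (iii) a dominant sharp periodogram peak whose prominent companions are its
#' harmonics, with largest Lyapunov exponent (LLE) consistent with zero ->
#' `limit_cycle` (with period);
#' (iv) two or more incommensurate prominent peaks and LLE consistent with
#' zero -> `quasiperiodic`;
#' (v) LLE above `lle_tol` -> `chaotic`; otherwise `unresolved`.
#'
#' The LLE is estimated with [largest_lyapunov()] when `network` is supplied
#' (or can be passed precomputed via `lle`); without it, steps that need the
#' exponent treat it as unavailable and fall through.
#'
#' @param traj an `srn_trajectory` (uniform time grid).
#' @param network the generating network (for the LLE); optional.
#' @param burn_in transient to discard.
#' @param diam_tol fixed-point diameter tolerance (simplex units).
#' @param lle_tol chaos threshold on the LLE (1/time).
#' @param lle optional precomputed largest Lyapunov exponent.
#' @param prominence periodogram peak prominence factor (x median power).
#' @param dwell_thr,dwell_visits heteroclinic detection: composition above
#'   `dwell_thr` counts as a vertex visit; `dwell_visits` strictly lengthening
#'   visits flag a heteroclinic suspect.
#' @param lle_t_end integration time for the LLE estimate.
#' @return object of class `srn_attractor` with fields `label`, `diameter`,
#'   `period`, `lle`, `lam`, `support_points`.
#' @export
classify_attractor <- function(traj, network = NULL, burn_in = NULL,
                               diam_tol = 1e-4, lle_tol = 0.005, lle = NULL,
                               prominence = 10, dwell_thr = 0.95,
                               dwell_visits = 4, lle_t_end = 500) {
  pt <- post_transient(traj, burn_in)
  diam <- attractor_diameter(pt$Y)
  lam <- lambda_time_average(traj, burn_in = burn_in)$lam
  res <- list(label = "unresolved", diameter = diam, period = NA_real_,
              lle = lle %||% NA_real_, lam = lam, support_points = pt$Y)
  if (diam <= diam_tol) {
    res$label <- "fixed_point"
    return(structure(res, class = "srn_attractor"))
  }
  dw <- vertex_dwells(pt$Y, pt$t, dwell_thr)
  if (nrow(dw) >= dwell_visits) {
    dd <- tail(dw$dwell, dwell_visits)
    if (all(diff(dd) > 0)) {
      res$label <- "heteroclinic_suspect"
      return(structure(res, class = "srn_attractor"))
    }
  }
  dt <- stats::median(diff(pt$t))
  pg <- trajectory_periodogram(pt$Y, dt)
  df <- pg$freq[2] - pg$freq[1]
  peaks <- spectral_peaks(pg$freq, pg$power, prominence)
  if (is.null(lle) && !is.null(network)) {
    y0 <- pt$Y[nrow(pt$Y), ]
    y0 <- pmax(y0, 1e-9)
    y0 <- y0 / sum(y0)
    res$lle <- tryCatch(
      largest_lyapunov(network, y0, t_end = lle_t_end),
      error = function(e) NA_real_)
  }
  lle_zero <- !is.na(res$lle) && abs(res$lle) <= lle_tol
  lle_pos <- !is.na(res$lle) && res$lle > lle_tol
  if (nrow(peaks) >= 1 && harmonically_related(peaks$freq, df) &&
      (lle_zero || is.na(res$lle))) {
    res$label <- "limit_cycle"
    res$period <- 1 / min(peaks$freq)
    return(structure(res, class = "srn_attractor"))
  }
  if (nrow(peaks) >= 2 && !harmonically_related(peaks$freq, df) && lle_zero) {
    res$label <- "quasiperiodic"
    return(structure(res, class = "srn_attractor"))
  }
  if (lle_pos) {
    res$label <- "chaotic"
    return(structure(res, class = "srn_attractor"))
  }
  structure(res, class = "srn_attractor")
}

#' @export
print.srn_attractor <- function(x, ...) {
  cat("<srn_attractor>", x$label,
      " diam:", signif(x$diameter, 4),
      " period:", signif(x$period, 4),
      " lle:", signif(x$lle, 4),
      " lambda:", signif(x$lam, 6), "\n")
  invisible(x)
}

#' Largest Lyapunov exponent of the simplex flow
#'
#' Benettin two-trajectory estimate restricted to the simplex tangent space:
#' the reference trajectory and a companion displaced by `d0` along a zero-sum
#' direction are integrated in segments of `renorm_dt`; after each segment the
#' separation is renormalized to `d0` and its log stretch accumulated. The
#' first `discard` fraction of segments is treated as transient.
#'
#' @param network an `srn_network` (compiled fast path required for speed, but
#'   the R path works too).
#' @param Y0 interior simplex point.
#' @param t_end total integration time.
#' @param renorm_dt renormalization interval.
#' @param d0 perturbation magnitude.
#' @param seed seed for the random initial perturbation direction.
#' @param discard fraction of initial segments discarded.
#' @param rtol,atol integrator tolerances.
#' @return estimated exponent (1/time).
#' @export
largest_lyapunov <- function(network, Y0, t_end = 500, renorm_dt = 1,
                             d0 = 1e-8, seed = 0, discard = 0.1,
                             rtol = 1e-10, atol = 1e-12) {
  Y0 <- as_state(network, Y0)
  if (any(Y0 <= 0)) stop("Y0 must be interior to the simplex")
  set.seed(seed)
  n <- length(Y0)
  v <- stats::rnorm(n)
  v <- v - mean(v) # tangent to the simplex: components sum to zero
  v <- v / sqrt(sum(v^2))
  y1 <- unname(Y0 / sum(Y0))
  y2 <- y1 + d0 * v
  y2 <- pmax(y2, 0); y2 <- y2 / sum(y2)
  nseg <- ceiling(t_end / renorm_dt)
  logs <- numeric(nseg)
  cn <- network$compiled
  step <- function(y) {
    if (!is.null(cn)) {
      r <- cpp_simulate_simplex(cn, y, renorm_dt, 1L, rtol, atol)
      if (!r$ok) stop("integration failure in Lyapunov segment")
      r$Y[2, ]
    } else {
      tr <- simulate_simplex(network, y, renorm_dt, nout = 1,
                             rtol = rtol, atol = atol)
      tr$Y[2, ]
    }
  }
  for (s in seq_len(nseg)) {
    y1 <- step(y1)
    y2 <- step(y2)
    if (min(y1) < 0 || !all(is.finite(y2)))
      stop("trajectory hit the simplex boundary at segment ", s)
    d1 <- sqrt(sum((y2 - y1)^2))
    if (d1 <= 0) d1 <- .Machine$double.xmin
    logs[s] <- log(d1 / d0)
    y2 <- y1 + (y2 - y1) * (d0 / d1)
  }
  keep <- seq.int(max(1, floor(discard * nseg) + 1), nseg)
  sum(logs[keep]) / (length(keep) * renorm_dt)
}

#' Occupation measure of a trajectory on the simplex
#'
#' Normalized histogram of post-transient composition samples over a regular
#' grid in the first n-1 barycentric coordinates, recording per-bin mass and
#' per-bin mean instantaneous growth rate. The product binning is capped at
#' 1e6 bins: for networks with many nodes the per-axis resolution is coarsened
#' to `floor(1e6^(1/(n-1)))`.
#'
#' @param traj an `srn_trajectory` with uniform time sampling.
#' @param bins bins per barycentric axis (default 50).
#' @param burn_in transient to discard.
#' @return object of class `srn_occupation`: data.frame with bin index
#'   columns, `mass` (sums to 1) and `mu_mean`.
#' @export
occupation_measure <- function(traj, bins = 50, burn_in = NULL) {
  pt <- post_transient(traj, burn_in)
  if (nrow(pt$Y) == 0) stop("empty trajectory after burn-in")
  n <- ncol(pt$Y)
  if (n == 1) { # 0-simplex: the measure is a point mass
    df <- data.frame(bin = "0", mass = 1, mu_mean = mean(pt$mu),
                     stringsAsFactors = FALSE)
    return(structure(list(table = df, bins = 1L, n = 1L),
                     class = "srn_occupation"))
  }
  cap <- max(2L, floor(1e6^(1 / (n - 1))))
  bins <- min(bins, cap)
  coords <- pt$Y[, -n, drop = FALSE]
  idx <- pmin(floor(coords * bins), bins - 1L)
  key <- apply(idx, 1, paste, collapse = ",")
  mass <- tapply(rep(1, length(key)), key, sum)
  mu_mean <- tapply(pt$mu, key, mean)
  ord <- names(mass)
  df <- data.frame(bin = ord, mass = as.numeric(mass[ord]) / length(key),
                   mu_mean = as.numeric(mu_mean[ord]), stringsAsFactors = FALSE)
  structure(list(table = df, bins = bins, n = n), class = "srn_occupation")
}

#' @export
print.srn_occupation <- function(x, ...) {
  cat("<srn_occupation>", nrow(x$table), "occupied bins (", x$bins,
      "per axis ), total mass", sum(x$table$mass), "\n")
  invisible(x)
}

#' Long-term growth rate as a space average
#'
#' The discrete form of the ergodic space average `int mu(Y) omega(dY)`:
#' mass-weighted mean of the per-bin mean growth rates of an occupation
#' measure. For a converging system this agrees with the Birkhoff time
#' average computed on the same trajectory.
#'
#' @param measure an `srn_occupation`.
#' @return scalar growth rate.
#' @export
lambda_space_average <- function(measure) {
  stopifnot(inherits(measure, "srn_occupation"))
  m <- measure$table
  if (abs(sum(m$mass) - 1) > 1e-12) stop("occupation measure not normalized")
  sum(m$mass * m$mu_mean)
}

#' Parameter-scan phase diagram
#'
#' Runs simulate -> classify -> lambda over the Cartesian grid of the supplied
#' parameter axes. Per-point failures are recorded in the result (label
#' `"error"`), not raised. Deterministic given the seed: the same uniform
#' initial composition is used for every grid point unless `Y0` is given.
#'
#' @param model_factory function taking one named parameter set (as a list)
#'   and returning an `srn_network`.
#' @param axes named list of parameter grids.
#' @param t_end,nout,rtol,atol simulation controls (scan-grade defaults).
#' @param Y0 initial composition; default uniform.
#' @param classify logical: also label attractors (slower; LLE skipped).
#' @param burn_in transient for the analyses.
#' @param diam_tol fixed-point tolerance passed to the classifier.
#' @return object of class `srn_scan`: long-format data.frame with the
#'   parameter columns plus `lambda`, `diameter`, `label`, `converged`.
#' @export
scan_phase_diagram <- function(model_factory, axes, t_end = 400,
                               nout = 2000, rtol = 1e-8, atol = 1e-10,
                               Y0 = NULL, classify = TRUE, burn_in = NULL,
                               diam_tol = 1e-4) {
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prm <- as.list(grid[i, , drop = FALSE])
    rows[[i]] <- tryCatch({
      net <- model_factory(prm)
      y0 <- Y0 %||% rep(1 / length(net$nodes), length(net$nodes))
      tr <- simulate_simplex(net, y0, t_end, nout = nout,
                             rtol = rtol, atol = atol)
      ge <- lambda_time_average(tr, burn_in = burn_in)
      diam <- attractor_diameter(tr, burn_in = burn_in)
      label <- if (classify)
        classify_attractor(tr, network = net, burn_in = burn_in,
                           diam_tol = diam_tol)$label
      else NA_character_
      data.frame(grid[i, , drop = FALSE], lambda = ge$lam, diameter = diam,
                 label = label, converged = ge$converged,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(grid[i, , drop = FALSE], lambda = NA_real_,
                 diameter = NA_real_, label = "error", converged = FALSE,
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(result = res, axes = axes, t_end = t_end),
            class = "srn_scan")
}

#' @export
print.srn_scan <- function(x, ...) {
  cat("<srn_scan>", nrow(x$result), "grid points over",
      paste(names(x$axes), collapse = " x "), "\n")
  print(head(x$result, 10), row.names = FALSE)
  invisible(x)
}

#' Export a scan result as long-format CSV
#' @param scan an `srn_scan`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.csv(scan$result, path, row.names = FALSE)
  invisible(path)
}
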