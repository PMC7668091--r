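#' @useDynLib srngrowth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median rnorm runif sd setNames
#' @importFrom utils head tail write.csv
NULL

# ---------------------------------------------------------------------------
# Rate families
#
# The fast simulation path supports three structured families that together
# cover all scalable flux forms used in practice (linear, mass-action on
# fractions, Hill-saturated/maintained, Hill-repressed, and the two-substrate
# ratio form). Arbitrary rates are supported through rate_custom() /
# rate_expression() and fall back to the pure-R integrator.
# ---------------------------------------------------------------------------

new_rate <- function(kind, fields) {
  # explicit field list: `...` would partially match short field names (e.g.
  # `k`) against the `kind` parameter
  structure(c(list(kind = kind), fields), class = "srn_rate")
}

#' Product-form reaction rate
#'
#' Builds a rate of the form
#' \deqn{J(X) = r \prod_j X_j^{e_j} / N^{\sum e_j - 1}
#'       \prod_s \frac{(X_s/N)^{\theta_s}}{K_s + (X_s/N)^{\theta_s}}
#'       \prod_p \frac{1}{1 + K_p (X_p/N)^{\theta_p}}}
#' where \eqn{N = \sum_k X_k}. The monomial part is normalized by \eqn{N} so
#' that the whole expression is homogeneous of degree 1 (extensive in system
#' size) whenever the monomial exponents are supplied; saturation and
#' repression factors are functions of composition only (degree 0). This
#' family covers the scalable forms \eqn{rX_j}, \eqn{rY_j^aY_k^bN},
#' \eqn{rX_j^\theta X_z/(X_j^\theta + KN^\theta)} and Hill-repressed synthesis
#' \eqn{cX_1/(1+K(X_3/N)^\theta)}.
#'
#' @param r positive rate constant (mass/time when the monomial has degree 1).
#' @param mono named numeric vector of monomial exponents, names are node ids.
#' @param sat list of saturation factors, each `list(node=, K=, theta=)`.
#' @param rep list of repression factors, each `list(node=, K=, theta=)`.
#' @return an object of class `srn_rate`.
#' @export
rate_product <- function(r = 1, mono = NULL, sat = NULL, rep = NULL) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 0)
  if (!is.null(mono)) {
    stopifnot(is.numeric(mono), !is.null(names(mono)), all(nzchar(names(mono))))
  }
  chk_fac <- function(f) {
    stopifnot(is.list(f), all(c("node", "K", "theta") %in% names(f)),
              f$K > 0, f$theta > 0)
    f
  }
  if (!is.null(sat)) sat <- lapply(sat, chk_fac)
  if (!is.null(rep)) rep <- lapply(rep, chk_fac)
  new_rate("product", list(r = r, mono = mono, sat = sat, rep = rep))
}

#' Linear reaction rate r*X_j
#' @param node node id supplying the linear dependence.
#' @param r positive rate constant (1/time).
#' @return an `srn_rate`.
#' @export
rate_linear <- function(node, r = 1) {
  rate_product(r = r, mono = stats::setNames(1, node))
}

#' Linear-combination rate r * sum_i w_i X_i
#'
#' Scalable (degree-1 homogeneous, smooth, positive for positive weights) but
#' with an empty maintenance set when more than one term is present: no single
#' node forces the flux to zero.
#' @param weights named numeric vector of nonnegative weights.
#' @param r rate constant.
#' @return an `srn_rate`.
#' @export
rate_lincomb <- function(weights, r = 1) {
  stopifnot(is.numeric(weights), !is.null(names(weights)), all(weights >= 0))
  new_rate("lincomb", list(r = r, weights = weights))
}

#' Two-substrate ratio rate r*Xj*Xk/(a*Xj + b*Xk + c*N)
#' @param j,k upstream node ids.
#' @param a,b,c positive denominator coefficients.
#' @param r rate constant.
#' @return an `srn_rate`.
#' @export
rate_ratio <- function(j, k, a, b, c, r = 1) {
  stopifnot(a > 0, b > 0, c > 0, r >= 0)
  new_rate("ratio", list(r = r, j = j, k = k, a = a, b = b, c = c))
}

#' Arbitrary rate from an R function
#'
#' The function receives the named biomass vector `X` and the system size `N`
#' and must return a single number. Networks containing custom rates are
#' integrated by the pure-R solver (slower than the compiled path) and their
#' scalability can only be checked numerically.
#' @param fn function of `(X, N)`.
#' @param maintenance optional character vector declaring the maintenance set
#'   of the rate (nodes whose depletion forces the flux to zero); verified
#'   numerically by [check_upstream_limited()].
#' @return an `srn_rate`.
#' @export
rate_custom <- function(fn, maintenance = NULL) {
  stopifnot(is.function(fn))
  new_rate("custom", list(fn = fn, maintenance = maintenance))
}

#' Rate from a text expression
#'
#' Parses an arithmetic expression in the node symbols and `N` (reserved for
#' the system size) using R's parser; supported operators/functions are
#' `+ - * / ^ exp sin atan`. Example: `"0.5 * X1 / (1 + 500 * (X3/N)^2)"`.
#' @param text expression string.
#' @param maintenance optional declared maintenance set (see [rate_custom()]).
#' @return an `srn_rate` of kind `custom` carrying the source text.
#' @export
rate_expression <- function(text, maintenance = NULL) {
  expr <- str2lang(text)
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "sin", "atan", "tan")
  walk <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% allowed) stop("unsupported function in rate expression: ", fn)
      for (i in seq_along(e)[-1]) walk(e[[i]])
    }
  }
  walk(expr)
  fn <- function(X, N) {
    env <- c(as.list(X), list(N = N))
    eval(expr, envir = env)
  }
  r <- rate_custom(fn, maintenance = maintenance)
  r$text <- text
  r
}

# nodes referenced by a rate (for validation)
rate_nodes <- function(rate) {
  switch(rate$kind,
    product = unique(c(names(rate$mono),
                       vapply(rate$sat, `[[`, "", "node"),
                       vapply(rate$rep, `[[`, "", "node"))),
    lincomb = names(rate$weights),
    ratio = c(rate$j, rate$k),
    custom = character(0)
  )
}

# nodes whose depletion structurally forces the rate to zero
rate_maintenance <- function(rate) {
  switch(rate$kind,
    product = unique(c(names(rate$mono)[rate$mono > 0],
                       vapply(rate$sat, `[[`, "", "node"))),
    lincomb = if (length(rate$weights) == 1L && rate$weights > 0)
                names(rate$weights) else character(0),
    ratio = c(rate$j, rate$k),
    custom = rate$maintenance %||% character(0)
  )
}

# homogeneity degree known from structure; NA for custom rates.
# Family rates are degree-1 by construction: the product family divides the
# monomial by N^(sum(e)-1), lincomb and ratio are degree 1 algebraically.
rate_degree <- function(rate) {
  if (rate$kind == "custom") NA_real_ else 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a rate at a biomass state
#' @param rate an `srn_rate`.
#' @param X named nonnegative biomass vector.
#' @param N system size; defaults to `sum(X)`.
#' @return flux magnitude (scalar).
#' @export
eval_rate <- function(rate, X, N = sum(X)) {
  J <- switch(rate$kind,
    product = {
      J <- rate$r
      deg <- 0
      for (nm in names(rate$mono)) {
        e <- rate$mono[[nm]]
        deg <- deg + e
        x <- X[[nm]]
        if (x <= 0 && e > 0) return(0)
        J <- J * x^e
      }
      if (deg != 1) {
        if (N <= 0) return(0)
        J <- J * N^(1 - deg)
      }
      for (f in rate$sat) {
        y <- if (N > 0) (X[[f$node]] / N)^f$theta else 0
        J <- J * y / (f$K + y)
      }
      for (f in rate$rep) {
        y <- if (N > 0) (X[[f$node]] / N)^f$theta else 0
        J <- J / (1 + f$K * y)
      }
      J
    },
    lincomb = rate$r * sum(rate$weights * X[names(rate$weights)]),
    ratio = {
      den <- rate$a * X[[rate$j]] + rate$b * X[[rate$k]] + rate$c * N
      if (den <= 0) 0 else rate$r * X[[rate$j]] * X[[rate$k]] / den
    },
    custom = rate$fn(X, N)
  )
  unname(J)
}

# ---------------------------------------------------------------------------
# FluxSpec and ReactionNetwork
# ---------------------------------------------------------------------------

#' Specify one reaction of a network
#'
#' A reaction consumes material from its upstream nodes and produces material
#' in its downstream nodes; its signed stoichiometric coefficients form one
#' column of the network's stoichiometry matrix. The maintenance set collects
#' the nodes whose depletion forces the flux to zero (substrates, enzymes,
#' cofactors); every upstream node must be maintaining, which is what makes
#' trajectories stay in the nonnegative quadrant.
#'
#' @param id reaction id (string).
#' @param rate an `srn_rate` (see [rate_product()] and friends).
#' @param stoich named numeric vector of signed coefficients; unmentioned
#'   nodes are 0. Negative entries are consumption, positive production.
#' @param upstream,downstream optional character vectors; default to the
#'   negatively / positively signed stoichiometry keys.
#' @param maintenance optional character vector; defaults to the union of the
#'   upstream set and the nodes the rate structurally vanishes with.
#' @return object of class `srn_flux`.
#' @export
flux_spec <- function(id, rate, stoich, upstream = NULL, downstream = NULL,
                      maintenance = NULL) {
  stopifnot(is.character(id), length(id) == 1, inherits(rate, "srn_rate"),
            is.numeric(stoich))
  if (length(stoich) > 0 && (is.null(names(stoich)) || any(!nzchar(names(stoich)))))
    stop("stoich must be a named vector")
  neg <- names(stoich)[stoich < 0]
  pos <- names(stoich)[stoich > 0]
  upstream <- upstream %||% neg
  downstream <- downstream %||% pos
  if (!all(neg %in% upstream))
    stop("flux '", id, "': node(s) ", paste(setdiff(neg, upstream), collapse = ", "),
         " have negative stoichiometry but are not declared upstream")
  if (!all(pos %in% downstream))
    stop("flux '", id, "': node(s) ", paste(setdiff(pos, downstream), collapse = ", "),
         " have positive stoichiometry but are not declared downstream")
  maintenance <- maintenance %||% union(upstream, rate_maintenance(rate))
  if (!all(upstream %in% maintenance))
    stop("flux '", id, "': upstream set must be contained in the maintenance set")
  structure(list(id = id, rate = rate, stoich = stoich,
                 upstream = upstream, downstream = downstream,
                 maintenance = maintenance),
            class = "srn_flux")
}

#' @export
print.srn_flux <- function(x, ...) {
  cat("<srn_flux> ", x$id, ": ", sep = "")
  cat(paste0(names(x$stoich), ifelse(x$stoich > 0, " +", " "), x$stoich,
             collapse = ", "), "\n")
  cat("  rate kind:", x$rate$kind,
      " up: {", paste(x$upstream, collapse = ","), "}",
      " dw: {", paste(x$downstream, collapse = ","), "}",
      " mt: {", paste(x$maintenance, collapse = ","), "}\n")
  invisible(x)
}

#' Assemble and validate a reaction network
#'
#' @param nodes character vector of unique node ids (the environment is not a
#'   node: import/export reactions simply have stoichiometric support only on
#'   internal nodes).
#' @param fluxes list of [flux_spec()] objects.
#' @return object of class `srn_network` with elements `nodes`, `fluxes` and
#'   the n x m stoichiometry matrix `S`.
#' @export
build_network <- function(nodes, fluxes) {
  stopifnot(is.character(nodes), length(nodes) >= 1)
  if (anyDuplicated(nodes)) stop("duplicate node id: ",
                                 nodes[duplicated(nodes)][1])
  if (inherits(fluxes, "srn_flux")) fluxes <- list(fluxes)
  stopifnot(length(fluxes) >= 1)
  ids <- vapply(fluxes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate flux id: ", ids[duplicated(ids)][1])
  for (f in fluxes) {
    refs <- unique(c(names(f$stoich), f$upstream, f$downstream, f$maintenance,
                     rate_nodes(f$rate)))
    bad <- setdiff(refs, nodes)
    if (length(bad))
      stop("flux '", f$id, "' references undeclared node(s): ",
           paste(bad, collapse = ", "))
  }
  S <- matrix(0, length(nodes), length(fluxes),
              dimnames = list(nodes, ids))
  for (a in seq_along(fluxes)) S[names(fluxes[[a]]$stoich), a] <- fluxes[[a]]$stoich
  net <- structure(list(nodes = nodes, fluxes = fluxes, S = S),
                   class = "srn_network")
  net$compiled <- compile_network(net)
  net
}

#' @export
print.srn_network <- function(x, ...) {
  cat("<srn_network> ", length(x$nodes), " nodes, ", length(x$fluxes),
      " fluxes", if (is.null(x$compiled)) " (custom rates: R path)" else "",
      "\n", sep = "")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

# Translate a network into the index-based structure consumed by the C++
# kernels; returns NULL when any rate is custom (pure-R path used instead).
compile_network <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  fl <- vector("list", length(net$fluxes))
  for (a in seq_along(net$fluxes)) {
    r <- net$fluxes[[a]]$rate
    if (r$kind == "custom") return(NULL)
    fl[[a]] <- switch(r$kind,
      product = list(
        type = 0L, r = r$r,
        mono_i = as.integer(idx[names(r$mono)] %||% integer(0)),
        mono_e = as.numeric(r$mono %||% numeric(0)),
        sat_i = as.integer(idx[vapply(r$sat, `[[`, "", "node")]),
        sat_K = vapply(r$sat, `[[`, 0, "K"),
        sat_th = vapply(r$sat, `[[`, 0, "theta"),
        rep_i = as.integer(idx[vapply(r$rep, `[[`, "", "node")]),
        rep_K = vapply(r$rep, `[[`, 0, "K"),
        rep_th = vapply(r$rep, `[[`, 0, "theta")),
      lincomb = list(type = 1L, r = r$r,
                     lin_i = as.integer(idx[names(r$weights)]),
                     lin_w = as.numeric(r$weights)),
      ratio = list(type = 2L, r = r$r,
                   ratio = c(idx[[r$j]], idx[[r$k]], r$a, r$b, r$c))
    )
  }
  list(n = length(net$nodes), m = length(net$fluxes), S = unname(net$S),
       flux = fl)
}

#' Evaluate all flux magnitudes at a state
#' @param network an `srn_network`.
#' @param X biomass vector (named or in node order).
#' @return numeric vector of m flux magnitudes, named by flux id.
#' @export
network_fluxes <- function(network, X) {
  X <- as_state(network, X)
  if (!is.null(network$compiled)) {
    J <- cpp_eval_fluxes(network$compiled, unname(X))
  } else {
    J <- vapply(network$fluxes, function(f) eval_rate(f$rate, X, sum(X)), 0)
  }
  stats::setNames(J, colnames(network$S))
}

as_state <- function(network, X) {
  n <- length(network$nodes)
  if (length(X) != n) stop("state has length ", length(X), ", expected ", n)
  if (!is.null(names(X))) X <- X[network$nodes]
  stats::setNames(as.numeric(X), network$nodes)
}
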