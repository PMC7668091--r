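# ---------------------------------------------------------------------------
# Network schema (JSON), run configuration, and the end-to-end pipeline.
#
# Schema "srn-network/1": top-level `nodes` (array of strings) and `reactions`
# (array of objects {id, rate, stoich, upstream, downstream, maintenance}).
# Rates serialize by family: product / lincomb / ratio carry their parameters,
# expression rates carry their source text. The writer emits a canonical
# sorted form (reactions by id, sets sorted) so write(read(f)) == f on
# canonical files.
# ---------------------------------------------------------------------------

serialize_rate <- function(rate) {
  switch(rate$kind,
    product = list(kind = "product", r = rate$r,
                   mono = as.list(rate$mono %||% stats::setNames(numeric(0), character(0))),
                   sat = lapply(rate$sat %||% list(), function(f)
                     list(node = f$node, K = f$K, theta = f$theta)),
                   rep = lapply(rate$rep %||% list(), function(f)
                     list(node = f$node, K = f$K, theta = f$theta))),
    lincomb = list(kind = "lincomb", r = rate$r, weights = as.list(rate$weights)),
    ratio = list(kind = "ratio", r = rate$r, j = rate$j, k = rate$k,
                 a = rate$a, b = rate$b, c = rate$c),
    custom = {
      if (is.null(rate$text))
        stop("custom closure rates are not serializable; use rate_expression()")
      list(kind = "expression", text = rate$text,
           maintenance = as.list(rate$maintenance %||% character(0)))
    })
}

deserialize_rate <- function(obj, where) {
  kind <- obj$kind
  if (is.null(kind)) stop("reaction '", where, "': rate is missing 'kind'")
  fac <- function(f) list(node = f$node, K = as.numeric(f$K),
                          theta = as.numeric(f$theta))
  switch(kind,
    product = rate_product(r = as.numeric(obj$r),
                           mono = if (length(obj$mono))
                             unlist(obj$mono) else NULL,
                           sat = if (length(obj$sat))
                             lapply(obj$sat, fac) else NULL,
                           rep = if (length(obj$rep))
                             lapply(obj$rep, fac) else NULL),
    lincomb = rate_lincomb(unlist(obj$weights), r = as.numeric(obj$r)),
    ratio = rate_ratio(obj$j, obj$k, as.numeric(obj$a), as.numeric(obj$b),
                       as.numeric(obj$c), r = as.numeric(obj$r)),
    expression = rate_expression(obj$text,
                                 maintenance = unlist(obj$maintenance) %||% NULL),
    stop("reaction '", where, "': unknown rate kind '", kind, "'"))
}

#' Write a network to the JSON schema
#'
#' Emits the canonical sorted form: reactions ordered by id, stoichiometry
#' keys and node sets sorted, numbers at full precision. Reading the file back
#' and writing it again reproduces the bytes exactly.
#'
#' @param network an `srn_network` (custom closure rates are not
#'   serializable; expression rates are).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path) {
  rx <- lapply(network$fluxes, function(f) {
    st <- f$stoich[order(names(f$stoich))]
    list(id = f$id,
         rate = serialize_rate(f$rate),
         stoich = as.list(st),
         upstream = as.list(sort(f$upstream)),
         downstream = as.list(sort(f$downstream)),
         maintenance = as.list(sort(f$maintenance)))
  })
  rx <- rx[order(vapply(rx, `[[`, "", "id"))]
  doc <- list(schema = "srn-network/1", nodes = as.list(network$nodes),
              reactions = rx)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a network from the JSON schema
#'
#' Validation errors name the offending reaction and key.
#' @param path file in the `srn-network/1` schema.
#' @return an `srn_network`.
#' @export
read_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "srn-network/1"))
    stop("unsupported schema: ", doc$schema %||% "<missing>")
  nodes <- unlist(doc$nodes)
  fluxes <- lapply(doc$reactions, function(rx) {
    id <- rx$id
    if (is.null(id)) stop("reaction without id")
    for (key in c("rate", "stoich")) if (is.null(rx[[key]]))
      stop("reaction '", id, "': missing key '", key, "'")
    st <- unlist(rx$stoich)
    bad <- setdiff(names(st), nodes)
    if (length(bad))
      stop("reaction '", id, "' references unknown node(s): ",
           paste(bad, collapse = ", "))
    flux_spec(id, deserialize_rate(rx$rate, id), st,
              upstream = unlist(rx$upstream) %||% NULL,
              downstream = unlist(rx$downstream) %||% NULL,
              maintenance = unlist(rx$maintenance) %||% NULL)
  })
  build_network(nodes, fluxes)
}

zoo_constructors <- function() {
  list(single_repressilator = single_repressilator,
       double_repressilator = double_repressilator,
       limit_cycle_model = limit_cycle_model,
       bistable_model = bistable_model,
       heteroclinic_model = heteroclinic_model,
       cross_feeding_community = cross_feeding_community,
       biosynthesis_toy = biosynthesis_toy,
       random_srn = random_srn)
}

resolve_model <- function(model) {
  if (inherits(model, "srn_network")) return(model)
  if (!is.null(model$file)) return(read_network(model$file))
  if (!is.null(model$zoo)) {
    ctor <- zoo_constructors()[[model$zoo]]
    if (is.null(ctor)) stop("unknown zoo model: ", model$zoo)
    return(do.call(ctor, model$args %||% list()))
  }
  stop("config$model must be an srn_network, list(file=), or list(zoo=, args=)")
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: build -> scalability check -> simulate (deterministic, or SDE when
#' `noise$sigma > 0`) -> classify attractor -> lambda as time average and as
#' space average over the occupation measure -> autocatalytic circuits.
#' Deterministic given the seed; the JSON summary contains no timestamps, so
#' reruns of the same config are byte-identical.
#'
#' @param config list (or path to a JSON file) with entries: `model`
#'   (`list(zoo=, args=)`, `list(file=)` or an `srn_network`), `t_end`,
#'   optional `Y0`, `seed` (default 0), `burn_in`, `noise`
#'   (`list(sigma=, scheme=)`), `nout`, `rtol`, `atol`, and optional
#'   `out_dir` to write `summary.json` + `trajectory.csv`.
#' @return result bundle (list) with the network, scalability report,
#'   trajectory, attractor summary, growth estimates and circuit report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  for (key in c("model", "t_end")) if (is.null(config[[key]]))
    stop("pipeline config: missing '", key, "'")
  seed <- config$seed %||% 0L
  net <- resolve_model(config$model)
  report <- check_scalability(net, seed = seed)
  n <- length(net$nodes)
  Y0 <- config$Y0 %||% rep(1 / n, n)
  traj <- if (!is.null(config$noise) && (config$noise$sigma %||% 0) > 0) {
    ns <- noise_spec(config$noise$sigma,
                     config$noise$scheme %||% "tangent_additive", seed = seed)
    simulate_simplex_sde(net, Y0, config$t_end, ns,
                         dt = config$noise$dt %||% 1e-3)
  } else {
    simulate_simplex(net, Y0, config$t_end,
                     nout = config$nout %||% default_nout(config$t_end),
                     rtol = config$rtol %||% 1e-9,
                     atol = config$atol %||% 1e-12)
  }
  att <- classify_attractor(traj, network = net, burn_in = config$burn_in)
  ge <- lambda_time_average(traj, burn_in = config$burn_in)
  occ <- occupation_measure(traj, burn_in = config$burn_in)
  lam_space <- lambda_space_average(occ)
  circ <- max_autocatalytic_circuit(net)
  bundle <- list(network = net, scalability = report, trajectory = traj,
                 attractor = att, growth = ge, lambda_time = ge$lam,
                 lambda_space = lam_space, circuit = circ,
                 provenance = list(seed = seed,
                                   registry_hash = zoo_registry_hash(),
                                   is_srn = report$is_srn))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(config$out_dir, "trajectory.csv"))
    summary <- list(
      is_srn = report$is_srn,
      label = att$label,
      diameter = att$diameter,
      lambda_time = ge$lam,
      lambda_space = lam_space,
      converged = ge$converged,
      circuit = circ$reactions,
      is_autocatalytic = circ$is_circuit,
      seed = seed,
      registry_hash = zoo_registry_hash())
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(config$out_dir, "summary.json"))
  }
  invisible(bundle)
}
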