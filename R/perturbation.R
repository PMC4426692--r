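#' Simulation parameters for the communicating-vessels model
#'
#' The dynamics inject a starting energy `E` at the seed node(s), let energy
#' flow along every edge in proportion to the energy difference between its
#' endpoints, and subtract a fixed dissipation `D` from every node at each
#' step. A node is considered perturbed while its energy is at or above the
#' detection threshold `theta` (1 unit); the simulation ends when every node
#' is below it.
#'
#' @param E starting energy (energy units), split equally among the seeds.
#' @param D dissipation removed from each node per step (energy units); a
#'   node holding less than `D` loses all of it.
#' @param theta silencing/detection threshold (energy units).
#' @param k per-edge flow coefficient. `NULL` (default) means choose
#'   `1 / (max degree + 1)` for the simulated network — the explicit-Euler
#'   stability bound of the graph Laplacian, guaranteeing the flow phase
#'   never overshoots or oscillates.
#' @param max_steps hard cap on steps; `NULL` means `10 * E / theta`.
#'   Hitting the cap is reported, never silent.
#' @return an object of class `perturbation_config`.
#' @export
perturbation_config <- function(E = 1000, D = 5, theta = 1, k = NULL,
                                max_steps = NULL) {
  stopifnot(E > 0, D > 0, theta > 0)
  if (!is.null(k) && (k <= 0)) stop("flow coefficient k must be positive")
  if (is.null(max_steps)) max_steps <- ceiling(10 * E / theta)
  if (max_steps < ceiling(E / min(D, theta))) {
    stop("max_steps too small to allow silencing at this E and D")
  }
  structure(list(E = E, D = D, theta = theta, k = k,
                 max_steps = as.integer(max_steps)),
            class = "perturbation_config")
}

#' @export
print.perturbation_config <- function(x, ...) {
  cat("Communicating-vessels perturbation config\n")
  cat(sprintf("  starting energy E: %g\n", x$E))
  cat(sprintf("  dissipation D:     %g per node per step\n", x$D))
  cat(sprintf("  threshold theta:   %g\n", x$theta))
  cat(sprintf("  flow coefficient:  %s\n",
              if (is.null(x$k)) "1/(deg_max + 1) of the network" else
                format(x$k)))
  cat(sprintf("  step cap:          %d\n", x$max_steps))
  invisible(x)
}

# Resolve the flow coefficient for a concrete network and check stability.
resolve_k <- function(net, cfg) {
  dmax <- if (igraph::vcount(net)) max(igraph::degree(net)) else 0
  bound <- 1 / (dmax + 1)
  k <- if (is.null(cfg$k)) bound else cfg$k
  if (k > bound + 1e-12) {
    stop(sprintf(
      "flow coefficient k = %g exceeds the stability bound 1/(deg_max+1) = %g",
      k, bound))
  }
  k
}

#' Distribute the starting energy over seed nodes
#'
#' Each seed receives `E / (number of seeds)`; every other node starts at 0.
#'
#' @param net interaction network.
#' @param seeds nonempty character vector of seed node IDs.
#' @param E total starting energy.
#' @param theta detection threshold used to initialise the ever-reached flags.
#' @return an `energy_state`: list with per-node `energy` (named), the
#'   per-node logical `reached` flag and the `step` counter (0).
#' @export
initialize_energy <- function(net, seeds, E = 1000, theta = 1) {
  assert_network(net)
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("seed set must be nonempty")
  ids <- node_ids(net)
  missing <- setdiff(seeds, ids)
  if (length(missing)) {
    stop("seed node(s) not in network: ", paste(missing, collapse = ", "))
  }
  energy <- stats::setNames(numeric(length(ids)), ids)
  energy[seeds] <- E / length(seeds)
  structure(list(energy = energy, reached = energy >= theta, step = 0L),
            class = "energy_state")
}

#' Advance the dynamics by one step
#'
#' One step is a synchronous flow sub-phase followed by dissipation. In the
#' flow sub-phase every edge \{u, v\} carries a flow `k * (E_u - E_v)` from
#' the higher-energy endpoint to the lower, so the new energy of u is
#' `E_u + k * sum over neighbours v of (E_v - E_u)`; total energy is
#' conserved exactly. The ever-reached flags are updated after the flow
#' sub-phase. Dissipation then removes `min(energy, D)` from every node.
#'
#' @param state an `energy_state` from [initialize_energy()].
#' @param net the interaction network the state lives on.
#' @param cfg a [perturbation_config()].
#' @return the updated `energy_state`.
#' @export
perturb_step <- function(state, net, cfg = perturbation_config()) {
  assert_network(net)
  stopifnot(inherits(state, "energy_state"))
  ids <- node_ids(net)
  if (!identical(names(state$energy), ids)) {
    stop("energy state is inconsistent with the network's node set")
  }
  k <- resolve_k(net, cfg)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- igraph::degree(net)
  e <- state$energy
  e <- e + k * (as.numeric(A %*% e) - deg * e)
  reached <- state$reached | (e >= cfg$theta)
  e <- pmax(e - cfg$D, 0)
  structure(list(energy = stats::setNames(e, ids), reached = reached,
                 step = state$step + 1L),
            class = "energy_state")
}

#' Run a perturbation simulation from a seed set
#'
#' Iterates [perturb_step()] until every node's energy is below the threshold
#' (or the step cap is hit) and reports the two spreading metrics: the
#' silencing time — the number of steps until the perturbation has fully
#' dissipated — and the perturbation reach — the number of nodes whose energy
#' ever met the threshold. Small silencing times and large reach both
#' indicate efficient spreading from the seed.
#'
#' @param net interaction network.
#' @param seeds nonempty character vector of seed node IDs (a multi-target
#'   drug's target set, say); the starting energy is split equally.
#' @param cfg a [perturbation_config()].
#' @param trajectory if `TRUE`, record total energy after each step.
#' @return an object of class `perturbation_result`: `silencing_time`
#'   (steps), `perturbation_reach` (node count), `seeds`,
#'   `terminated_by_cap`, and optionally `trajectory`.
#' @export
run_perturbation <- function(net, seeds, cfg = perturbation_config(),
                             trajectory = FALSE) {
  assert_network(net)
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("seed set must be nonempty")
  st <- initialize_energy(net, seeds, E = cfg$E, theta = cfg$theta)
  k <- resolve_k(net, cfg)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- igraph::degree(net)
  e <- unname(st$energy)
  reached <- unname(st$reached)
  traj <- if (trajectory) numeric(0)
  step <- 0L
  capped <- FALSE
  while (any(e >= cfg$theta)) {
    if (step >= cfg$max_steps) {
      capped <- TRUE
      break
    }
    step <- step + 1L
    e <- e + k * (as.numeric(A %*% e) - deg * e)
    reached <- reached | (e >= cfg$theta)
    e <- pmax(e - cfg$D, 0)
    if (trajectory) traj <- c(traj, sum(e))
  }
  structure(list(
    silencing_time = step,
    perturbation_reach = sum(reached),
    seeds = seeds,
    terminated_by_cap = capped,
    trajectory = traj,
    final_energy = stats::setNames(e, node_ids(net))
  ), class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("Perturbation run from seed(s):",
      paste(utils::head(x$seeds, 5), collapse = ", "),
      if (length(x$seeds) > 5) "..." else "", "\n")
  cat(sprintf("  silencing time:     %d steps%s\n", x$silencing_time,
              if (x$terminated_by_cap) " (step cap hit)" else ""))
  cat(sprintf("  perturbation reach: %d nodes\n", x$perturbation_reach))
  invisible(x)
}

# Batched engine: each column of E0 is an independent run (the per-seed
# dynamics do not interact). Finished columns are retired as they silence.
simulate_batch <- function(A, deg, k, E0, D, theta, max_steps) {
  p <- ncol(E0)
  times <- integer(p)
  capped <- logical(p)
  reach <- integer(p)
  e <- E0
  rch <- e >= theta
  alive <- which(colSums(e >= theta) > 0)
  reach[setdiff(seq_len(p), alive)] <-
    colSums(rch[, setdiff(seq_len(p), alive), drop = FALSE])
  e <- e[, alive, drop = FALSE]
  rch <- rch[, alive, drop = FALSE]
  step <- 0L
  while (length(alive) && step < max_steps) {
    step <- step + 1L
    e <- as.matrix(A %*% e) * k + e * (1 - k * deg)
    rch <- rch | (e >= theta)
    e <- pmax(e - D, 0)
    done <- colSums(e >= theta) == 0
    if (any(done)) {
      idx <- which(done)
      times[alive[idx]] <- step
      reach[alive[idx]] <- colSums(rch[, idx, drop = FALSE])
      alive <- alive[-idx]
      e <- e[, -idx, drop = FALSE]
      rch <- rch[, -idx, drop = FALSE]
    }
  }
  if (length(alive)) {
    times[alive] <- step
    capped[alive] <- TRUE
    reach[alive] <- colSums(rch)
  }
  list(silencing_time = times, perturbation_reach = reach,
       terminated_by_cap = capped)
}

#' Silencing times and reach for many probe nodes or seed sets
#'
#' Runs one independent simulation per probe node (or per seed set, the
#' multi-target mode in which a drug's starting energy is split equally
#' among its targets) and tabulates silencing time and perturbation reach.
#' All runs share one synchronous engine, so results are identical to
#' calling [run_perturbation()] probe by probe.
#'
#' @param net interaction network.
#' @param probes character vector of probe node IDs; default all nodes.
#' @param cfg a [perturbation_config()].
#' @param seed_sets optional named list of node-ID vectors; when given it
#'   overrides `probes` and each element is simulated as one seed set.
#' @return a data frame of class `silencing_profile` with columns `probe`,
#'   `silencing_time`, `perturbation_reach`, `terminated_by_cap`.
#' @export
silencing_profile <- function(net, probes = NULL,
                              cfg = perturbation_config(),
                              seed_sets = NULL) {
  assert_network(net)
  ids <- node_ids(net)
  if (is.null(seed_sets)) {
    if (is.null(probes)) probes <- ids
    probes <- as.character(probes)
    seed_sets <- stats::setNames(as.list(probes), probes)
  } else {
    if (is.null(names(seed_sets)) || any(!nzchar(names(seed_sets)))) {
      stop("seed_sets must be a named list")
    }
  }
  if (!length(seed_sets)) stop("no probes or seed sets given")
  for (nm in names(seed_sets)) {
    bad <- setdiff(seed_sets[[nm]], ids)
    if (length(bad)) {
      stop("probe '", nm, "': seed node(s) not in network: ",
           paste(bad, collapse = ", "))
    }
    if (!length(seed_sets[[nm]])) stop("probe '", nm, "': empty seed set")
  }
  k <- resolve_k(net, cfg)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- igraph::degree(net)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  E0 <- matrix(0, n, length(seed_sets))
  for (j in seq_along(seed_sets)) {
    s <- unique(as.character(seed_sets[[j]]))
    E0[idx[s], j] <- cfg$E / length(s)
  }
  res <- simulate_batch(A, deg, k, E0, cfg$D, cfg$theta, cfg$max_steps)
  out <- data.frame(
    probe = names(seed_sets),
    silencing_time = res$silencing_time,
    perturbation_reach = res$perturbation_reach,
    terminated_by_cap = res$terminated_by_cap,
    stringsAsFactors = FALSE
  )
  class(out) <- c("silencing_profile", "data.frame")
  out
}

#' @export
print.silencing_profile <- function(x, ...) {
  cat(sprintf("Silencing profile over %d probe(s)\n", nrow(x)))
  cat(sprintf("  silencing time: median %g, range [%g, %g]\n",
              stats::median(x$silencing_time), min(x$silencing_time),
              max(x$silencing_time)))
  cat(sprintf("  reach:          median %g, range [%g, %g]\n",
              stats::median(x$perturbation_reach), min(x$perturbation_reach),
              max(x$perturbation_reach)))
  if (any(x$terminated_by_cap)) {
    cat(sprintf("  WARNING: %d run(s) hit the step cap\n",
                sum(x$terminated_by_cap)))
  }
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Plot cumulative silencing-time distributions by group
#'
#' @param x a `silencing_profile`.
#' @param groups optional named list of probe-ID vectors; one cumulative
#'   curve per group, else one curve for all probes.
#' @param metric which metric to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.silencing_profile <- function(x, groups = NULL,
                                   metric = c("silencing_time",
                                              "perturbation_reach"), ...) {
  metric <- match.arg(metric)
  if (is.null(groups)) groups <- list(all = x$probe)
  vals <- lapply(groups, function(g) x[[metric]][x$probe %in% g])
  vals <- vals[vapply(vals, length, 1L) > 0]
  xlim <- range(unlist(vals))
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1),
                 xlab = gsub("_", " ", metric),
                 ylab = "cumulative fraction of probes", ...)
  cols <- seq_along(vals)
  for (i in seq_along(vals)) {
    cd <- cumulative_distribution(vals[[i]])
    graphics::lines(stats::stepfun(cd$threshold, c(0, cd$fraction)),
                    col = cols[i], do.points = FALSE)
  }
  graphics::legend("bottomright", legend = names(vals), col = cols, lty = 1)
  invisible(x)
}
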