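#' Geodesic (shortest-path) distances between two node sets
#'
#' @param net interaction network.
#' @param sources,targets nonempty character vectors of node IDs.
#' @return integer-valued matrix of BFS path lengths (rows = sources,
#'   columns = targets); unreachable pairs are `Inf`; a node appearing in
#'   both sets has distance 0 to itself.
#' @export
geodesic_distances <- function(net, sources, targets) {
  assert_network(net)
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (!length(sources) || !length(targets)) {
    stop("source and target sets must be nonempty")
  }
  ids <- node_ids(net)
  bad <- setdiff(c(sources, targets), ids)
  if (length(bad)) {
    stop("node(s) not in network: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  d <- igraph::distances(net, v = sources, to = targets)
  dimnames(d) <- list(sources, targets)
  d
}

#' Mean geodesic distance from each target to a disease gene set
#'
#' For every target node, the arithmetic mean of its shortest-path distances
#' to the disease-set members. Members unreachable from the target are
#' either excluded from the mean and counted (`"exclude"`, the default,
#' keeping values finite) or imputed as the network size (`"penalize"`).
#' Duplicate disease listings are de-duplicated; members outside the network
#' are dropped and reported.
#'
#' @param net interaction network.
#' @param targets nonempty character vector of target node IDs (in network).
#' @param disease_set nonempty character vector of disease node IDs.
#' @param unreachable_policy `"exclude"` or `"penalize"`.
#' @return an object of class `distance_result`: `per_target` data frame
#'   (target, mean_distance, n_reachable, n_unreachable), `summary` (mean
#'   and median of per-target means), `excluded_targets` (targets reaching
#'   zero disease members) and `disease_not_in_network`.
#' @export
average_distance_to_set <- function(net, targets, disease_set,
                                    unreachable_policy = c("exclude",
                                                           "penalize")) {
  assert_network(net)
  unreachable_policy <- match.arg(unreachable_policy)
  ids <- node_ids(net)
  targets <- unique(as.character(targets))
  disease_all <- unique(as.character(disease_set))
  disease <- intersect(disease_all, ids)
  missing <- setdiff(disease_all, ids)
  targets <- intersect(targets, ids)
  if (!length(targets) || !length(disease)) {
    stop("target and disease sets must be nonempty after intersection ",
         "with the network")
  }
  d <- geodesic_distances(net, targets, disease)
  per <- data.frame(target = targets, mean_distance = NA_real_,
                    n_reachable = 0L, n_unreachable = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    row <- d[i, ]
    reach <- is.finite(row)
    per$n_reachable[i] <- sum(reach)
    per$n_unreachable[i] <- sum(!reach)
    if (unreachable_policy == "penalize") {
      row[!reach] <- igraph::vcount(net)
      per$mean_distance[i] <- mean(row)
    } else if (any(reach)) {
      per$mean_distance[i] <- mean(row[reach])
    }
  }
  defined <- !is.na(per$mean_distance)
  structure(list(
    per_target = per,
    summary = list(mean = mean(per$mean_distance[defined]),
                   median = stats::median(per$mean_distance[defined]),
                   n_targets = sum(defined)),
    excluded_targets = per$target[!defined],
    disease_not_in_network = missing,
    unreachable_policy = unreachable_policy
  ), class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("Target-to-disease-set distances (%d targets, policy: %s)\n",
              nrow(x$per_target), x$unreachable_policy))
  cat(sprintf("  mean of per-target means:   %.3f edges\n", x$summary$mean))
  cat(sprintf("  median of per-target means: %.3f edges\n", x$summary$median))
  if (length(x$excluded_targets)) {
    cat("  targets reaching no disease member (excluded):",
        paste(x$excluded_targets, collapse = ", "), "\n")
  }
  if (length(x$disease_not_in_network)) {
    cat(sprintf("  %d disease member(s) not in the network\n",
                length(x$disease_not_in_network)))
  }
  invisible(x)
}

#' Count how many of a node set sit inside the giant component
#'
#' @param net interaction network.
#' @param node_set character vector of node IDs (must be in the network).
#' @return list with `in_giant`, `out_of_giant` and `fraction_out`.
#' @export
component_membership <- function(net, node_set) {
  assert_network(net)
  node_set <- unique(as.character(node_set))
  bad <- setdiff(node_set, node_ids(net))
  if (length(bad)) {
    stop("node(s) not in network: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  giant <- node_ids(giant_component(net))
  inside <- sum(node_set %in% giant)
  outside <- length(node_set) - inside
  list(in_giant = inside, out_of_giant = outside,
       fraction_out = if (length(node_set)) outside / length(node_set) else 0)
}
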