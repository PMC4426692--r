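#' Degree, closeness and betweenness centrality per node
#'
#' Degree is the neighbour count. Closeness of node u in a component of size
#' r (out of n nodes) is `((r - 1) / sum of distances from u) * ((r - 1) /
#' (n - 1))`: the within-component inverse mean distance, scaled by the
#' fraction of the network the node can reach, so values stay comparable on
#' disconnected networks. Betweenness is the fraction of shortest paths
#' passing through the node (endpoints excluded), normalised by
#' `(n - 1)(n - 2) / 2`.
#'
#' @param net interaction network.
#' @return a data frame of class `centrality_profile` with columns `node`,
#'   `degree`, `closeness`, `betweenness`.
#' @export
compute_centralities <- function(net) {
  assert_network(net)
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  ids <- node_ids(net)
  deg <- unname(igraph::degree(net))
  comp <- igraph::components(net)
  r <- comp$csize[comp$membership]
  if (n == 1) {
    clo <- 0
    btw <- 0
  } else {
    # igraph closeness = 1 / sum(distances to reachable nodes)
    clo_raw <- suppressWarnings(unname(igraph::closeness(net, mode = "all")))
    clo <- ifelse(r > 1, (r - 1) * clo_raw * (r - 1) / (n - 1), 0)
    btw <- if (n > 2) {
      unname(igraph::betweenness(net, directed = FALSE)) / ((n - 1) * (n - 2) / 2)
    } else {
      rep(0, n)
    }
  }
  out <- data.frame(node = ids, degree = deg, closeness = clo,
                    betweenness = btw, stringsAsFactors = FALSE)
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Per-group centrality summaries with pairwise rank-sum tests
#'
#' Summarises each centrality (degree, closeness, betweenness) per node
#' group by median and mean, and compares every requested pair of groups
#' with a two-sided Mann-Whitney test per centrality.
#'
#' @param profile a `centrality_profile` from [compute_centralities()].
#' @param groups named list of node-ID vectors. Overlapping groups trigger a
#'   warning; empty groups are an error.
#' @param pairs list of length-2 character vectors naming the group pairs to
#'   test; default all pairs.
#' @return list with `summary` (data frame: group, metric, n, median, mean)
#'   and `comparisons` (data frame: group_a, group_b, metric, p_value,
#'   direction).
#' @export
group_centrality_summary <- function(profile, groups, pairs = NULL) {
  stopifnot(inherits(profile, "centrality_profile"))
  if (!length(groups) || is.null(names(groups))) {
    stop("groups must be a nonempty named list")
  }
  sizes <- vapply(groups, length, 1L)
  if (any(sizes == 0)) {
    stop("empty group(s): ", paste(names(groups)[sizes == 0], collapse = ", "))
  }
  unknown <- setdiff(unlist(groups), profile$node)
  if (length(unknown)) {
    stop("group member(s) not in profile: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        ov <- intersect(groups[[i]], groups[[j]])
        if (length(ov)) {
          warning("groups '", names(groups)[i], "' and '", names(groups)[j],
                  "' overlap in ", length(ov), " node(s)")
        }
      }
    }
  }
  metrics <- c("degree", "closeness", "betweenness")
  vals <- function(g, m) profile[[m]][match(g, profile$node)]
  summ <- do.call(rbind, lapply(names(groups), function(gn) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- vals(groups[[gn]], m)
      data.frame(group = gn, metric = m, n = length(v),
                 median = stats::median(v), mean = mean(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(pairs)) {
    pairs <- utils::combn(names(groups), min(2, length(groups)),
                          simplify = FALSE)
    if (length(groups) < 2) pairs <- list()
  }
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(metrics, function(m) {
      mw <- mann_whitney(vals(groups[[pr[1]]], m), vals(groups[[pr[2]]], m),
                         group_names = pr)
      data.frame(group_a = pr[1], group_b = pr[2], metric = m,
                 p_value = mw$p_value, direction = mw$direction,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, comparisons = comp)
}
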