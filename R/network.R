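#' @importFrom igraph graph_from_data_frame simplify vcount ecount V degree
#'   components induced_subgraph delete_vertices vertex_attr as_edgelist
#'   add_vertices is_connected gsize
NULL

#' Build an undirected interaction network from an edge table
#'
#' Constructs a simple undirected graph from a two-column table of node IDs,
#' dropping self-loops and collapsing duplicate pairs (in either order).
#' Interaction networks carry no edge weights.
#'
#' @param from,to character vectors of endpoint IDs (recycled pairwise).
#' @param isolated optional character vector of node IDs with no edges.
#' @return an undirected \code{igraph} object with vertex names, carrying a
#'   \code{cleanup_report} graph attribute: a list with \code{raw_rows},
#'   \code{loops_dropped}, \code{duplicates_collapsed} counts.
#' @export
interaction_network <- function(from, to, isolated = character()) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  raw <- length(from)
  loop <- from == to
  f <- from[!loop]
  t <- to[!loop]
  # canonical unordered order so (A,B) and (B,A) collapse
  lo <- pmin(f, t)
  hi <- pmax(f, t)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  nodes <- unique(c(from, to, as.character(isolated)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g$cleanup_report <- list(
    raw_rows = raw,
    loops_dropped = sum(loop),
    duplicates_collapsed = sum(dup)
  )
  g
}

assert_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("expected an igraph interaction network")
  if (igraph::is_directed(net)) stop("interaction networks must be undirected")
  if (is.null(igraph::V(net)$name)) stop("network vertices must be named")
  invisible(net)
}

node_ids <- function(net) igraph::V(net)$name

#' Read an interaction network from an edge-list file
#'
#' Supports tab-separated edge lists (configurable ID columns, `#`-prefixed
#' comment lines) and SIF (`node1 relation node2`). The loaded network is
#' simplified: self-loops dropped, duplicate pairs in either order collapsed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @param columns for TSV, the two 1-based indices of the node-ID columns.
#' @param header for TSV, whether the first non-comment line is a header.
#' @return an interaction network (see [interaction_network()]); the
#'   `cleanup_report` graph attribute records raw row, dropped-loop and
#'   collapsed-duplicate counts.
#' @export
load_edge_list <- function(path, format = c("tsv", "sif"), columns = c(1L, 2L),
                           header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop("empty edge-list file: ", path)
  fields <- strsplit(lines, if (format == "tsv") "\t" else "[ \t]+")
  if (format == "sif") columns <- c(1L, 3L)
  need <- max(columns)
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad)) {
    stop("malformed row at line ", lineno[bad[1]], " of ", path,
         ": fewer than ", need, " fields")
  }
  from <- vapply(fields, `[[`, "", columns[1])
  to <- vapply(fields, `[[`, "", columns[2])
  interaction_network(from, to)
}

#' Read a two-column ID-mapping table
#'
#' @param path TSV with source ID in column 1, target ID in column 2.
#' @return data frame with columns `source`, `target`.
#' @export
load_id_mapping <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("mapping file needs two columns: ", path)
  data.frame(source = tab[[1]], target = tab[[2]], stringsAsFactors = FALSE)
}

#' Rename network nodes through an ID mapping
#'
#' Nodes are renamed source -> target; nodes with no mapping are dropped
#' together with their incident edges, and edges that become self-loops or
#' duplicates after renaming are re-simplified. A source mapped to several
#' targets is resolved by `collision_policy`.
#'
#' @param net interaction network.
#' @param mapping data frame with columns `source`, `target`
#'   (see [load_id_mapping()]).
#' @param collision_policy `"lexicographic_min"` keeps the smallest target ID
#'   and logs the rest; `"error"` aborts on any ambiguous source.
#' @return the renamed network; its `mapping_report` graph attribute lists
#'   `untranslated` source IDs and `collisions` (ambiguous sources with the
#'   discarded targets).
#' @export
apply_id_mapping <- function(net, mapping,
                             collision_policy = c("lexicographic_min", "error")) {
  assert_network(net)
  collision_policy <- match.arg(collision_policy)
  stopifnot(is.data.frame(mapping), all(c("source", "target") %in% names(mapping)))

  split_t <- split(as.character(mapping$target), as.character(mapping$source))
  split_t <- lapply(split_t, function(x) sort(unique(x)))
  multi <- names(split_t)[vapply(split_t, length, 1L) > 1]
  if (length(multi) && collision_policy == "error") {
    stop("ambiguous mapping for source ID(s): ", paste(multi, collapse = ", "))
  }
  resolved <- vapply(split_t, `[[`, "", 1L)
  collisions <- lapply(split_t[multi], function(x) x[-1])

  old <- node_ids(net)
  new <- resolved[old]
  untranslated <- old[is.na(new)]

  el <- igraph::as_edgelist(net, names = TRUE)
  ef <- resolved[el[, 1]]
  et <- resolved[el[, 2]]
  ok <- !is.na(ef) & !is.na(et)
  out <- interaction_network(ef[ok], et[ok],
                             isolated = new[!is.na(new)])
  out$mapping_report <- list(
    untranslated = untranslated,
    collisions = collisions,
    nodes_before = length(old),
    nodes_after = igraph::vcount(out),
    edges_before = nrow(el),
    edges_after = igraph::ecount(out)
  )
  out
}

#' Extract the giant (largest connected) component
#'
#' Ties between equally large components are broken deterministically in
#' favour of the component containing the lexicographically smallest node ID.
#'
#' @param net interaction network.
#' @return the vertex-induced subgraph on the largest component.
#' @export
giant_component <- function(net) {
  assert_network(net)
  if (igraph::vcount(net) == 0) stop("empty network has no giant component")
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    smallest <- vapply(big, function(ci) {
      min(node_ids(net)[comp$membership == ci])
    }, "")
    big <- big[order(smallest)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Randomly delete a fraction of nodes
#'
#' Samples `floor(fraction * n)` nodes uniformly without replacement and
#' removes them with their incident edges. Nodes are put in sorted-ID order
#' before the draw, so the result depends only on the node set and the seed,
#' not on input row order.
#'
#' @param net interaction network.
#' @param fraction proportion in (0, 1) of nodes to delete.
#' @param rng_seed integer seed making the deletion reproducible.
#' @return the truncated network.
#' @export
random_node_deletion <- function(net, fraction, rng_seed) {
  assert_network(net)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must be a single number in (0, 1)")
  }
  ids <- sort(node_ids(net))
  n_del <- floor(fraction * length(ids))
  victims <- with_seed(rng_seed, sample(ids, n_del))
  igraph::delete_vertices(net, victims)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed derivation: all randomness in a scenario flows
# from one base seed; component i gets an independent reproducible seed.
sub_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}
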