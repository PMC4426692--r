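#' Describe a synthetic interactome scenario
#'
#' Bundles the parameters of a synthetic study: a scale-free
#' (preferential-attachment) network standing in for the interactome, a
#' drug-target map with multi-target drugs, a per-drug side-effect flag
#' whose targets can be placed with a degree bias (sampling weight
#' proportional to degree^beta — the planted "good spreader" ground truth),
#' and two disease gene sets: a central one drawn from the top of the degree
#' distribution (cancer-like) and a peripheral one drawn from the bottom
#' (diabetes-like).
#'
#' Defaults emulate a desk-scale study: 2000 nodes with attachment
#' parameter 2, 40 drugs drawing 1-5 targets each, side-effect prevalence
#' 0.5 (balanced groups), degree-bias strength 2, an 18-member central and a
#' 14-member peripheral disease set (the sizes of the colorectal-cancer and
#' type-2-diabetes sets the full-scale analysis used), drawn from the top 5%
#' and bottom 25% of the degree distribution.
#'
#' @param n_nodes number of nodes.
#' @param m edges added per new node in the preferential-attachment growth.
#' @param n_drugs number of drugs.
#' @param targets_per_drug length-2 integer vector (min, max) of the uniform
#'   targets-per-drug distribution.
#' @param se_prevalence probability a drug is flagged as having side effects.
#' @param degree_bias beta >= 0: side-effect drugs sample their targets with
#'   weight degree^beta; 0 means no planted effect.
#' @param disease_sizes named numeric vector `c(central = ..., peripheral = ...)`.
#' @param central_top_fraction fraction of top-degree nodes the central
#'   disease set is drawn from.
#' @param peripheral_bottom_fraction fraction of bottom-degree nodes the
#'   peripheral disease set is drawn from.
#' @param seed base RNG seed; every sub-draw derives its own reproducible
#'   stream seed from it.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_nodes = 2000, m = 2, n_drugs = 40,
                               targets_per_drug = c(1L, 5L),
                               se_prevalence = 0.5, degree_bias = 2,
                               disease_sizes = c(central = 18, peripheral = 14),
                               central_top_fraction = 0.05,
                               peripheral_bottom_fraction = 0.25,
                               seed = 1) {
  stopifnot(n_nodes > m, m >= 1, n_drugs >= 1,
            length(targets_per_drug) == 2,
            targets_per_drug[1] >= 1,
            targets_per_drug[2] >= targets_per_drug[1],
            se_prevalence >= 0, se_prevalence <= 1,
            degree_bias >= 0,
            all(disease_sizes >= 1),
            all(c("central", "peripheral") %in% names(disease_sizes)))
  structure(list(
    n_nodes = as.integer(n_nodes), m = as.integer(m),
    n_drugs = as.integer(n_drugs),
    targets_per_drug = as.integer(targets_per_drug),
    se_prevalence = se_prevalence, degree_bias = degree_bias,
    disease_sizes = disease_sizes,
    central_top_fraction = central_top_fraction,
    peripheral_bottom_fraction = peripheral_bottom_fraction,
    seed = seed
  ), class = "synthetic_scenario")
}

#' Generate a scale-free network by preferential attachment
#'
#' Starts from a complete graph on `m` seed nodes; each subsequent node
#' attaches `m` edges to distinct existing nodes drawn with probability
#' proportional to their current degree. The result is connected and simple
#' with exactly `m * (n_nodes - m) + choose(m, 2)` edges.
#'
#' @param n_nodes number of nodes (`> m`).
#' @param m edges per new node (`>= 1`).
#' @param rng_seed integer seed; the same seed yields the identical edge set.
#' @return an interaction network with node IDs `n0001`, `n0002`, ...
#' @export
generate_network <- function(n_nodes, m = 2, rng_seed = 1) {
  if (!(n_nodes > m && m >= 1)) stop("need n_nodes > m >= 1")
  n_nodes <- as.integer(n_nodes)
  m <- as.integer(m)
  with_seed(rng_seed, {
    n_edges <- m * (n_nodes - m) + m * (m - 1) %/% 2
    ef <- integer(n_edges)
    et <- integer(n_edges)
    deg <- integer(n_nodes)
    pos <- 0L
    if (m > 1) {
      clique <- utils::combn(m, 2)
      idx <- seq_len(ncol(clique))
      ef[idx] <- clique[1, ]
      et[idx] <- clique[2, ]
      pos <- ncol(clique)
      deg[1:m] <- m - 1L
    }
    for (v in seq(m + 1L, n_nodes)) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      # the m=1 start and any degree-0 corner get uniform weights
      if (all(w == 0)) w <- rep(1, length(existing))
      nb <- if (length(existing) == m) existing else
        sample(existing, m, prob = w)
      idx <- pos + seq_len(m)
      ef[idx] <- v
      et[idx] <- nb
      pos <- pos + m
      deg[nb] <- deg[nb] + 1L
      deg[v] <- m
    }
    fmt <- paste0("n%0", nchar(as.character(n_nodes)), "d")
    interaction_network(sprintf(fmt, ef), sprintf(fmt, et))
  })
}

#' Plant drug and disease annotations on a network
#'
#' Flags each drug as having side effects with probability `se_prevalence`,
#' draws its target count uniformly from the configured range, then draws
#' targets without replacement — with weight degree^beta for side-effect
#' drugs and uniformly otherwise. The central disease set is sampled from
#' the top degree quantile, the peripheral one from the bottom quantile.
#'
#' @param net interaction network (typically from [generate_network()]).
#' @param scenario a [synthetic_scenario()].
#' @return an [annotation_set()] with disease sets `central` and
#'   `peripheral`.
#' @export
plant_annotations <- function(net, scenario) {
  assert_network(net)
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ids <- node_ids(net)
  n <- length(ids)
  deg <- igraph::degree(net)
  tmax <- scenario$targets_per_drug[2]
  if (tmax > n) stop("targets_per_drug max exceeds network size")
  if (any(scenario$disease_sizes > n)) {
    stop("requested disease-set size exceeds network size")
  }
  with_seed(sub_seed(scenario$seed, 1), {
    drugs <- sprintf("drug%03d", seq_len(scenario$n_drugs))
    has_se <- stats::setNames(
      stats::runif(scenario$n_drugs) < scenario$se_prevalence, drugs)
    tcount <- sample(seq(scenario$targets_per_drug[1],
                         scenario$targets_per_drug[2]),
                     scenario$n_drugs, replace = TRUE)
    w_bias <- deg ^ scenario$degree_bias
    rows <- lapply(seq_len(scenario$n_drugs), function(i) {
      w <- if (has_se[i]) w_bias else rep(1, n)
      data.frame(drug = drugs[i],
                 node = sample(ids, tcount[i], prob = w),
                 stringsAsFactors = FALSE)
    })
    dt <- do.call(rbind, rows)

    qc <- stats::quantile(deg, 1 - scenario$central_top_fraction, type = 1)
    qp <- stats::quantile(deg, scenario$peripheral_bottom_fraction, type = 1)
    pool_c <- ids[deg >= qc]
    pool_p <- ids[deg <= qp]
    size_c <- scenario$disease_sizes[["central"]]
    size_p <- scenario$disease_sizes[["peripheral"]]
    if (size_c > length(pool_c) || size_p > length(pool_p)) {
      stop("disease-set size exceeds the available degree-quantile pool")
    }
    disease <- list(central = sample(pool_c, size_c),
                    peripheral = sample(pool_p, size_p))
    annotation_set(dt, has_se, disease)
  })
}

#' Write a synthetic scenario to disk as loadable TSV files
#'
#' Produces the same dialects the loaders consume: `edges.tsv`,
#' `drug_targets.tsv`, `side_effects.tsv` (one "adverse_event" row per
#' side-effect drug), `disease_central.tsv`, `disease_peripheral.tsv` and a
#' `manifest.json` recording every parameter and the seed, so the bundle can
#' be regenerated byte-identically.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the generated `network`, `annotations`
#'   and the file `paths`.
#' @export
generate_scenario_bundle <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- generate_network(scenario$n_nodes, scenario$m,
                          rng_seed = sub_seed(scenario$seed, 0))
  ann <- plant_annotations(net, scenario)
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    side_effects = file.path(dir, "side_effects.tsv"),
    disease_central = file.path(dir, "disease_central.tsv"),
    disease_peripheral = file.path(dir, "disease_peripheral.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ann$drug_targets, paths$drug_targets, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  se_drugs <- names(ann$side_effects)[ann$side_effects]
  utils::write.table(
    data.frame(drug = se_drugs, term = "adverse_event"),
    paths$side_effects, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (d in c("central", "peripheral")) {
    utils::write.table(
      data.frame(disease = d, node = ann$disease_sets[[d]]),
      paths[[paste0("disease_", d)]], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(parameters = unclass(scenario),
         n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = net, annotations = ann, paths = paths))
}
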