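# Replicated synthetic studies: the validation experiments the package runs
# on generated interactomes. Each driver regenerates a fresh scenario per
# replicate from a deterministic seed stream and measures one contrast.

#' Spearman correlation between seed degree and silencing time
#'
#' Simulates a perturbation from every node of a scale-free network and
#' correlates each seed's degree with its silencing time. Good spreaders
#' (hubs) silence faster, so the expected correlation is strongly negative.
#'
#' @param n_nodes,m network size and attachment parameter.
#' @param seed RNG seed for the network.
#' @param cfg a [perturbation_config()].
#' @return list with `rho` (Spearman), `profile` and the network size.
#' @export
spreading_centrality_correlation <- function(n_nodes = 1000, m = 2, seed = 1,
                                             cfg = perturbation_config()) {
  net <- generate_network(n_nodes, m, rng_seed = seed)
  prof <- silencing_profile(net, cfg = cfg)
  deg <- igraph::degree(net)[prof$probe]
  list(rho = stats::cor(deg, prof$silencing_time, method = "spearman"),
       profile = prof, n_nodes = n_nodes)
}

#' Planted-effect recovery study
#'
#' Per replicate: generate a scenario, derive the target groups, simulate a
#' perturbation from every drug-target node and compare silencing times of
#' side-effect targets vs no-side-effect targets with a Mann-Whitney test.
#' With `degree_bias > 0` side-effect targets sit on hubs and should show
#' smaller silencing times; with `degree_bias = 0` the comparison is a null
#' and should reject at the nominal rate only.
#'
#' @param n_replicates number of independent replicate scenarios.
#' @param base_seed seed from which each replicate derives its own stream.
#' @param scenario a [synthetic_scenario()] template; its `seed` field is
#'   replaced per replicate.
#' @param cfg a [perturbation_config()].
#' @return data frame with one row per replicate: group sizes, Mann-Whitney
#'   `p_value`, and `effect_direction` (`TRUE` when the side-effect group
#'   has the smaller median silencing time).
#' @export
planted_effect_study <- function(n_replicates = 50, base_seed = 1,
                                 scenario = synthetic_scenario(),
                                 cfg = perturbation_config()) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    sc <- scenario
    sc$seed <- sub_seed(base_seed, r)
    net <- generate_network(sc$n_nodes, sc$m,
                            rng_seed = sub_seed(sc$seed, 0))
    ann <- plant_annotations(net, sc)
    g <- derive_groups(net, ann)$groups
    if (length(g$targets_with_SE) < 2 || length(g$targets_without_SE) < 2) {
      return(data.frame(replicate = r, n_with_SE = length(g$targets_with_SE),
                        n_without_SE = length(g$targets_without_SE),
                        p_value = NA_real_, effect_direction = NA))
    }
    probes <- c(g$targets_with_SE, g$targets_without_SE)
    prof <- silencing_profile(net, probes, cfg)
    st <- function(x) prof$silencing_time[match(x, prof$probe)]
    mw <- mann_whitney(st(g$targets_with_SE), st(g$targets_without_SE),
                       c("targets_with_SE", "targets_without_SE"))
    data.frame(replicate = r, n_with_SE = length(g$targets_with_SE),
               n_without_SE = length(g$targets_without_SE),
               p_value = mw$p_value,
               effect_direction = grepl("^targets_with_SE <", mw$direction))
  })
  do.call(rbind, rows)
}

#' Central vs peripheral disease-set contrast study
#'
#' Per replicate: generate a scenario with a central (hub-drawn) and a
#' peripheral (low-degree) disease set, then measure (1) silencing times of
#' each disease set against a background sample, (2) degree and betweenness
#' of the central set against background, and (3) the per-target mean
#' geodesic distance from all drug targets to each disease set, contrasted
#' with a Welch test. The central set is expected to silence faster and be
#' more central; the peripheral set should show no such pattern and lie
#' farther from the drug targets.
#'
#' @param n_replicates number of replicate scenarios.
#' @param base_seed seed deriving each replicate's stream.
#' @param scenario a [synthetic_scenario()] template.
#' @param cfg a [perturbation_config()].
#' @param background_n number of background (non-disease) nodes sampled as
#'   the comparison group for the silencing-time tests.
#' @return data frame, one row per replicate, with the p-values and
#'   direction indicators of every sub-contrast.
#' @export
disease_contrast_study <- function(n_replicates = 50, base_seed = 1,
                                   scenario = synthetic_scenario(),
                                   cfg = perturbation_config(),
                                   background_n = 150) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    sc <- scenario
    sc$seed <- sub_seed(base_seed, r)
    net <- generate_network(sc$n_nodes, sc$m,
                            rng_seed = sub_seed(sc$seed, 0))
    ann <- plant_annotations(net, sc)
    der <- derive_groups(net, ann)
    ds <- der$disease
    bg_pool <- setdiff(node_ids(net), unlist(ds))
    bg <- sort(with_seed(sub_seed(sc$seed, 5),
                         sample(bg_pool, min(background_n, length(bg_pool)))))
    probes <- unique(c(ds$central, ds$peripheral, bg))
    prof <- silencing_profile(net, probes, cfg)
    st <- function(x) prof$silencing_time[match(x, prof$probe)]
    mw_c <- mann_whitney(st(ds$central), st(bg), c("central", "background"))
    mw_p <- mann_whitney(st(ds$peripheral), st(bg),
                         c("peripheral", "background"))
    cp <- compute_centralities(net)
    gv <- function(g, m) cp[[m]][match(g, cp$node)]
    mw_deg <- mann_whitney(gv(ds$central, "degree"), gv(bg_pool, "degree"))
    mw_btw <- mann_whitney(gv(ds$central, "betweenness"),
                           gv(bg_pool, "betweenness"))
    targets <- union(der$groups$targets_with_SE,
                     der$groups$targets_without_SE)
    d_c <- average_distance_to_set(net, targets, ds$central)
    d_p <- average_distance_to_set(net, targets, ds$peripheral)
    a <- d_p$per_target$mean_distance
    b <- d_c$per_target$mean_distance
    wt <- welch_t(a[!is.na(a)], b[!is.na(b)], c("peripheral", "central"))
    data.frame(
      replicate = r,
      central_time_p = mw_c$p_value,
      central_time_smaller = grepl("^central <", mw_c$direction),
      peripheral_time_p = mw_p$p_value,
      peripheral_time_smaller = grepl("^peripheral <", mw_p$direction),
      central_degree_p = mw_deg$p_value,
      central_degree_larger =
        stats::median(gv(ds$central, "degree")) >
          stats::median(gv(bg_pool, "degree")),
      central_betweenness_p = mw_btw$p_value,
      central_betweenness_larger =
        stats::median(gv(ds$central, "betweenness")) >
          stats::median(gv(bg_pool, "betweenness")),
      distance_p = wt$p_value,
      peripheral_farther = mean(a, na.rm = TRUE) > mean(b, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}

#' Robustness-to-deletion study on a planted scenario
#'
#' Generates one biased scenario, then for each replicate seed deletes the
#' given fraction of nodes, takes the giant component and re-tests the
#' side-effect vs no-side-effect silencing-time contrast (see
#' [run_robustness()]).
#'
#' @param n_replicates number of deletion replicates.
#' @param base_seed seed for the scenario and the replicate deletions.
#' @param scenario a [synthetic_scenario()] template.
#' @param fraction node fraction deleted.
#' @param cfg a [perturbation_config()].
#' @return the [run_robustness()] result.
#' @export
robustness_study <- function(n_replicates = 10, base_seed = 1,
                             scenario = synthetic_scenario(),
                             fraction = 0.5,
                             cfg = perturbation_config()) {
  sc <- scenario
  sc$seed <- sub_seed(base_seed, 0)
  net <- generate_network(sc$n_nodes, sc$m, rng_seed = sub_seed(sc$seed, 0))
  ann <- plant_annotations(net, sc)
  run_robustness(net, ann, fraction = fraction,
                 replicate_seeds = vapply(seq_len(n_replicates),
                                          function(i) sub_seed(base_seed, i),
                                          numeric(1)),
                 cfg = cfg)
}
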