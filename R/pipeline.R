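#' Run the full perturbation-spreading analysis
#'
#' Executes the complete sequence on a network plus annotations: derive the
#' three node groups (targets of drugs with side effects, targets of drugs
#' without side effects, non-targets), simulate a perturbation from every
#' group member at each point of the E/D grid, compare silencing times and
#' perturbation reach between groups with Mann-Whitney tests, summarise the
#' centralities of the disease sets against background, and measure
#' target-to-disease geodesic distances with a Welch test contrasting the
#' two disease sets.
#'
#' @param net interaction network.
#' @param ann an [annotation_set()].
#' @param ed_grid list of length-2 numeric vectors `c(E, D)`; default the
#'   grid `{1000/5, 10000/5, 10000/1}`.
#' @param multi_target_split if `TRUE`, also simulate each drug's full
#'   target set as one seed set with the starting energy split equally.
#' @param non_target_cap per grid point, at most this many non-target nodes
#'   are simulated (sampled deterministically from `seed` when the group is
#'   larger); keeps desk-scale runs fast without touching the target groups.
#' @param seed integer seed for the non-target subsample.
#' @param theta,k,max_steps forwarded to [perturbation_config()].
#' @return an object of class `perturbation_analysis`: `groups`, per-grid
#'   `profiles` and `comparisons`, `curves` (cumulative distributions),
#'   `centrality` summary, `distances`, and `provenance`.
#' @export
run_full_analysis <- function(net, ann,
                              ed_grid = list(c(1000, 5), c(10000, 5),
                                             c(10000, 1)),
                              multi_target_split = FALSE,
                              non_target_cap = 500, seed = 1,
                              theta = 1, k = NULL, max_steps = NULL) {
  assert_network(net)
  stopifnot(inherits(ann, "annotation_set"), length(ed_grid) >= 1)
  der <- derive_groups(net, ann)
  groups <- der$groups
  message(sprintf("groups: %d with-SE targets, %d without-SE targets, %d non-targets",
                  length(groups$targets_with_SE),
                  length(groups$targets_without_SE),
                  length(groups$non_targets)))

  nt <- groups$non_targets
  if (length(nt) > non_target_cap) {
    nt <- sort(with_seed(sub_seed(seed, 11), sample(nt, non_target_cap)))
  }
  probe_groups <- list(targets_with_SE = groups$targets_with_SE,
                       targets_without_SE = groups$targets_without_SE,
                       non_targets = nt)
  probes <- unique(unlist(probe_groups))

  grid_names <- vapply(ed_grid, function(ed)
    sprintf("E%g_D%g", ed[1], ed[2]), "")
  profiles <- list()
  comparisons <- list()
  curves <- list()
  for (gi in seq_along(ed_grid)) {
    ed <- ed_grid[[gi]]
    cfg <- perturbation_config(E = ed[1], D = ed[2], theta = theta, k = k,
                               max_steps = max_steps)
    prof <- if (length(probes)) silencing_profile(net, probes, cfg) else NULL
    if (multi_target_split) {
      sets <- split(ann$drug_targets$node, ann$drug_targets$drug)
      sets <- lapply(sets, function(s) intersect(unique(s), node_ids(net)))
      sets <- sets[vapply(sets, length, 1L) > 0]
      prof_drug <- silencing_profile(net, cfg = cfg, seed_sets = sets)
      prof_drug$multi_target <- TRUE
    } else {
      prof_drug <- NULL
    }
    gvals <- function(g, metric) prof[[metric]][match(g, prof$probe)]
    cmp <- list()
    crv <- list()
    for (metric in c("silencing_time", "perturbation_reach")) {
      ok1 <- length(probe_groups$targets_with_SE) >= 1 &&
        length(probe_groups$targets_without_SE) >= 1
      cmp[[paste0("withSE_vs_withoutSE.", metric)]] <- if (ok1) {
        mann_whitney(gvals(probe_groups$targets_with_SE, metric),
                     gvals(probe_groups$targets_without_SE, metric),
                     c("targets_with_SE", "targets_without_SE"))
      }
      ok2 <- length(probe_groups$targets_without_SE) >= 1 && length(nt) >= 1
      cmp[[paste0("withoutSE_vs_nontargets.", metric)]] <- if (ok2) {
        mann_whitney(gvals(probe_groups$targets_without_SE, metric),
                     gvals(nt, metric),
                     c("targets_without_SE", "non_targets"))
      }
      for (gn in names(probe_groups)) {
        if (length(probe_groups[[gn]])) {
          crv[[paste0(gn, ".", metric)]] <-
            cumulative_distribution(gvals(probe_groups[[gn]], metric))
        }
      }
    }
    profiles[[grid_names[gi]]] <- list(per_node = prof,
                                       per_drug = prof_drug)
    comparisons[[grid_names[gi]]] <- cmp
    curves[[grid_names[gi]]] <- crv
  }

  centrality <- NULL
  distances <- NULL
  if (length(der$disease) >= 1 &&
      any(vapply(der$disease, length, 1L) > 0)) {
    prof_cent <- compute_centralities(net)
    dsets <- der$disease[vapply(der$disease, length, 1L) > 0]
    background <- setdiff(node_ids(net), unlist(dsets))
    cgroups <- c(dsets, list(background = background))
    pairs <- lapply(names(dsets), function(d) c(d, "background"))
    centrality <- group_centrality_summary(prof_cent, cgroups, pairs = pairs)

    all_targets <- union(groups$targets_with_SE, groups$targets_without_SE)
    if (length(all_targets)) {
      distances <- lapply(dsets, function(ds) {
        average_distance_to_set(net, all_targets, ds)
      })
      if (length(dsets) >= 2) {
        nm <- names(dsets)[1:2]
        a <- distances[[nm[1]]]$per_target$mean_distance
        b <- distances[[nm[2]]]$per_target$mean_distance
        a <- a[!is.na(a)]
        b <- b[!is.na(b)]
        if (length(a) >= 2 && length(b) >= 2) {
          distances$comparison <- welch_t(a, b, nm)
        }
      }
    }
  }

  structure(list(
    groups = der,
    probe_groups = probe_groups,
    profiles = profiles,
    comparisons = comparisons,
    curves = curves,
    centrality = centrality,
    distances = distances,
    provenance = list(ed_grid = ed_grid, seed = seed,
                      multi_target_split = multi_target_split,
                      non_target_cap = non_target_cap,
                      n_nodes = igraph::vcount(net),
                      n_edges = igraph::ecount(net),
                      timestamp = format(Sys.time()))
  ), class = "perturbation_analysis")
}

#' @export
print.perturbation_analysis <- function(x, ...) {
  cat(sprintf("Perturbation-spreading analysis of a %d-node, %d-edge network\n",
              x$provenance$n_nodes, x$provenance$n_edges))
  cat(sprintf("  groups: %d with-SE / %d without-SE / %d non-target\n",
              length(x$groups$groups$targets_with_SE),
              length(x$groups$groups$targets_without_SE),
              length(x$groups$groups$non_targets)))
  for (gn in names(x$comparisons)) {
    cat("  grid point", gn, "\n")
    for (cn in names(x$comparisons[[gn]])) {
      cc <- x$comparisons[[gn]][[cn]]
      if (!is.null(cc)) {
        cat(sprintf("    %-40s p = %.4g (%s)\n", cn, cc$p_value, cc$direction))
      }
    }
  }
  if (!is.null(x$distances$comparison)) {
    cat(sprintf("  distance contrast: p = %.4g (%s)\n",
                x$distances$comparison$p_value,
                x$distances$comparison$direction))
  }
  invisible(x)
}

#' Summarise a perturbation analysis
#'
#' @param object a `perturbation_analysis`.
#' @param ... unused.
#' @return a data frame of all group comparisons across the E/D grid.
#' @export
summary.perturbation_analysis <- function(object, ...) {
  rows <- list()
  for (gn in names(object$comparisons)) {
    for (cn in names(object$comparisons[[gn]])) {
      cc <- object$comparisons[[gn]][[cn]]
      if (is.null(cc)) next
      rows[[length(rows) + 1]] <- data.frame(
        grid = gn, comparison = cn, n_a = cc$sizes[1], n_b = cc$sizes[2],
        statistic = cc$statistic, p_value = cc$p_value,
        direction = cc$direction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Robustness of group contrasts to random node deletion
#'
#' For each replicate: delete a fraction of nodes uniformly at random, take
#' the giant component of the truncated network, re-derive the groups among
#' surviving nodes, re-run the with-SE vs without-SE silencing-time
#' comparison, and record the direction of the median shift. Summarises how
#' often the comparison keeps the sign observed on the intact network.
#'
#' @param net interaction network.
#' @param ann an [annotation_set()].
#' @param fraction fraction of nodes deleted per replicate.
#' @param replicate_seeds integer vector, one seed per replicate.
#' @param cfg a [perturbation_config()].
#' @return list with `replicates` (data frame: seed, n_with_SE,
#'   n_without_SE, p_value, direction, skipped) and `sign_consistency`
#'   (fraction of non-skipped replicates where the with-SE group has the
#'   smaller median silencing time).
#' @export
run_robustness <- function(net, ann, fraction = 0.5,
                           replicate_seeds = 1:10,
                           cfg = perturbation_config()) {
  assert_network(net)
  rows <- lapply(replicate_seeds, function(s) {
    trunc <- random_node_deletion(net, fraction, rng_seed = s)
    trunc <- giant_component(trunc)
    der <- derive_groups(trunc, ann)
    g <- der$groups
    if (length(g$targets_with_SE) < 2 || length(g$targets_without_SE) < 2) {
      return(data.frame(seed = s, n_with_SE = length(g$targets_with_SE),
                        n_without_SE = length(g$targets_without_SE),
                        p_value = NA_real_, direction = NA_character_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    probes <- c(g$targets_with_SE, g$targets_without_SE)
    prof <- silencing_profile(trunc, probes, cfg)
    st <- function(nodes) prof$silencing_time[match(nodes, prof$probe)]
    mw <- mann_whitney(st(g$targets_with_SE), st(g$targets_without_SE),
                       c("targets_with_SE", "targets_without_SE"))
    data.frame(seed = s, n_with_SE = length(g$targets_with_SE),
               n_without_SE = length(g$targets_without_SE),
               p_value = mw$p_value, direction = mw$direction,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, rows)
  done <- reps[!reps$skipped, , drop = FALSE]
  consistent <- grepl("^targets_with_SE <", done$direction)
  list(replicates = reps,
       sign_consistency = if (nrow(done)) mean(consistent) else NA_real_)
}

#' Write an analysis report to disk
#'
#' Emits the JSON comparison report plus TSV tables: per-node profiles and
#' cumulative curves per grid point, centrality and distance summaries.
#'
#' @param analysis a `perturbation_analysis`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_analysis_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "perturbation_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (gn in names(analysis$profiles)) {
    p <- analysis$profiles[[gn]]$per_node
    if (!is.null(p)) {
      f <- file.path(dir, paste0("profile_", gn, ".tsv"))
      utils::write.table(p, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    for (cn in names(analysis$curves[[gn]])) {
      f <- file.path(dir, paste0("curve_", gn, "_", cn, ".tsv"))
      utils::write.table(analysis$curves[[gn]][[cn]], f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
  }
  cmp <- summary(analysis)
  report <- list(
    provenance = analysis$provenance,
    group_sizes = lapply(analysis$groups$groups, length),
    comparisons = cmp,
    centrality = analysis$centrality,
    distance_summary = if (!is.null(analysis$distances)) {
      lapply(analysis$distances, function(d) {
        if (inherits(d, "distance_result")) d$summary else
          list(test = d$test, p_value = d$p_value, direction = d$direction)
      })
    }
  )
  f <- file.path(dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- c(files, f)
  invisible(files)
}
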