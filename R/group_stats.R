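#' Bundle drug-target, side-effect and disease annotations
#'
#' @param drug_targets data frame with columns `drug`, `node`
#'   (many-to-many: multi-target drugs, shared targets).
#' @param side_effects named logical vector: per-drug flag, `TRUE` when the
#'   drug has at least one recorded side effect. Must cover every drug in
#'   `drug_targets`.
#' @param disease_sets named list of character vectors of disease-related
#'   node IDs.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(drug_targets, side_effects,
                           disease_sets = list()) {
  stopifnot(is.data.frame(drug_targets),
            all(c("drug", "node") %in% names(drug_targets)))
  drug_targets$drug <- as.character(drug_targets$drug)
  drug_targets$node <- as.character(drug_targets$node)
  if (is.null(names(side_effects)) || !is.logical(side_effects)) {
    stop("side_effects must be a named logical vector")
  }
  undefined <- setdiff(unique(drug_targets$drug), names(side_effects))
  if (length(undefined)) {
    stop("drug(s) with targets but no side-effect flag: ",
         paste(undefined, collapse = ", "))
  }
  stopifnot(is.list(disease_sets))
  disease_sets <- lapply(disease_sets, as.character)
  structure(list(drug_targets = drug_targets,
                 side_effects = side_effects,
                 disease_sets = disease_sets),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d drugs, %d drug-target pairs, %d unique targets\n",
              length(unique(x$drug_targets$drug)), nrow(x$drug_targets),
              length(unique(x$drug_targets$node))))
  cat(sprintf("  drugs with side effects: %d of %d flagged\n",
              sum(x$side_effects), length(x$side_effects)))
  for (d in names(x$disease_sets)) {
    cat(sprintf("  disease set '%s': %d genes\n", d,
                length(x$disease_sets[[d]])))
  }
  invisible(x)
}

#' Load annotations from TSV files
#'
#' The drug-target table has columns (drug_id, node_id); the side-effect
#' table has (drug_id, side_effect_term) rows, from which the per-drug flag
#' is "has at least one term" (drugs absent from the table are flagged
#' `FALSE`); each disease table has (disease_id, node_id) rows.
#'
#' @param drug_target_path,side_effect_path TSV paths.
#' @param disease_paths named character vector of TSV paths (names become
#'   disease-set names; unnamed paths use the disease_id column).
#' @return an [annotation_set()].
#' @export
load_annotations <- function(drug_target_path, side_effect_path = NULL,
                             disease_paths = character()) {
  read2 <- function(p) {
    tab <- utils::read.table(p, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2) stop("expected two tab-separated columns in ", p)
    tab[, 1:2]
  }
  dt <- read2(drug_target_path)
  names(dt) <- c("drug", "node")
  drugs <- unique(dt$drug)
  flags <- stats::setNames(rep(FALSE, length(drugs)), drugs)
  if (!is.null(side_effect_path)) {
    se <- read2(side_effect_path)
    flagged <- intersect(unique(se[[1]]), drugs)
    flags[flagged] <- TRUE
    extra <- setdiff(unique(se[[1]]), drugs)
    if (length(extra)) {
      flags <- c(flags, stats::setNames(rep(TRUE, length(extra)), extra))
    }
  }
  disease <- list()
  for (i in seq_along(disease_paths)) {
    tab <- read2(disease_paths[i])
    nm <- names(disease_paths)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- tab[1, 1]
    disease[[nm]] <- unique(tab[[2]])
  }
  annotation_set(dt, flags, disease)
}

#' Partition network nodes by drug-target and side-effect status
#'
#' A node targeted by at least one drug with side effects goes to
#' `targets_with_SE`; a node targeted only by drugs without side effects
#' goes to `targets_without_SE`; every other node is a `non_target`. The
#' three sets partition the network. Disease sets are intersected with the
#' network; members outside it are reported, not silently dropped.
#'
#' @param net interaction network.
#' @param ann an [annotation_set()].
#' @return list with `groups` (the three node-ID vectors), `disease`
#'   (named list of in-network disease node sets) and `report`
#'   (targets and disease members not present in the network).
#' @export
derive_groups <- function(net, ann) {
  assert_network(net)
  stopifnot(inherits(ann, "annotation_set"))
  ids <- node_ids(net)
  dt <- ann$drug_targets
  in_net <- dt$node %in% ids
  missing_targets <- unique(dt$node[!in_net])
  dt <- dt[in_net, , drop = FALSE]
  se_drug <- ann$side_effects[dt$drug]
  with_se <- sort(unique(dt$node[se_drug]))
  without_se <- sort(setdiff(unique(dt$node[!se_drug]), with_se))
  non_targets <- sort(setdiff(ids, c(with_se, without_se)))
  disease <- lapply(ann$disease_sets, function(s) {
    sort(intersect(unique(s), ids))
  })
  disease_missing <- lapply(ann$disease_sets, function(s) {
    sort(setdiff(unique(s), ids))
  })
  list(
    groups = list(targets_with_SE = with_se,
                  targets_without_SE = without_se,
                  non_targets = non_targets),
    disease = disease,
    report = list(targets_not_in_network = missing_targets,
                  disease_not_in_network = disease_missing)
  )
}

#' Cumulative distribution of a sample as a step function
#'
#' Fractions are normalised by the sample size, so the curve ends at exactly
#' 1; thresholds are the sorted unique values.
#'
#' @param values nonempty numeric vector.
#' @return data frame with columns `threshold`, `fraction` (nondecreasing,
#'   final value 1).
#' @export
cumulative_distribution <- function(values) {
  if (!length(values)) stop("empty sample")
  thr <- sort(unique(values))
  frac <- cumsum(tabulate(match(sort(values), thr))) / length(values)
  data.frame(threshold = thr, fraction = frac)
}

new_group_comparison <- function(test, names, a, b, statistic, p, degenerate = FALSE) {
  dir <- if (degenerate || stats::median(a) == stats::median(b)) "none"
  else if (stats::median(a) < stats::median(b)) paste(names[1], "<", names[2])
  else paste(names[1], ">", names[2])
  structure(list(
    test = test, groups = names, sizes = c(length(a), length(b)),
    statistic = unname(statistic), p_value = unname(p), direction = dir,
    degenerate = degenerate
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: %s (n=%d) vs %s (n=%d)\n", x$test,
              x$groups[1], x$sizes[1], x$groups[2], x$sizes[2]))
  cat(sprintf("  statistic = %g, two-sided p = %g (unadjusted)\n",
              x$statistic, x$p_value))
  cat(sprintf("  location shift: %s%s\n", x$direction,
              if (x$degenerate) " [degenerate samples]" else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Follows `stats::wilcox.test` defaults: the exact distribution when both
#' samples have fewer than 50 values and no ties are present, otherwise the
#' normal approximation with tie and continuity correction. p-values are
#' reported unadjusted.
#'
#' @param a,b nonempty numeric samples.
#' @param group_names length-2 character vector of labels.
#' @return a `group_comparison` with the U statistic, two-sided p-value,
#'   group sizes and the direction of the median shift. Identical constant
#'   samples give p = 1 with a degenerate flag.
#' @export
mann_whitney <- function(a, b, group_names = c("a", "b")) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (length(unique(c(a, b))) == 1) {
    return(new_group_comparison("Mann-Whitney", group_names, a, b,
                                statistic = length(a) * length(b) / 2,
                                p = 1, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  new_group_comparison("Mann-Whitney", group_names, a, b,
                       statistic = wt$statistic, p = wt$p.value)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b numeric samples of size at least 2.
#' @param group_names length-2 character vector of labels.
#' @return a `group_comparison`. Two zero-variance samples are flagged
#'   degenerate (p = 1 when the means agree, p = 0 otherwise).
#' @export
welch_t <- function(a, b, group_names = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need size >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_group_comparison("Welch t", group_names, a, b,
                                statistic = if (same) 0 else Inf,
                                p = if (same) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new_group_comparison("Welch t", group_names, a, b,
                       statistic = tt$statistic, p = tt$p.value)
}
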