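#' Cluster atlas samples into tissue groups
#'
#' Average-linkage hierarchical clustering of atlas samples on correlation
#' distance (1 - Pearson r of log2(signal + 0.1)), cut to exactly
#' `n_groups` groups.
#'
#' @param atlas Gene x sample signal matrix.
#' @param n_groups Number of groups to cut the tree into (<= n samples).
#' @return List of class `atlas_grouping`: `assignment` (named vector sample
#'   -> group id), `tree` (hclust over samples), `n_groups`.
#' @export
cluster_atlas_samples <- function(atlas, n_groups = 35L) {
  if (n_groups > ncol(atlas)) stop("n_groups exceeds the number of samples")
  hc <- stats::hclust(.cor_dist(atlas), method = "average")
  assignment <- stats::cutree(hc, k = n_groups)
  structure(list(assignment = assignment, tree = hc, n_groups = n_groups),
            class = "atlas_grouping")
}

#' Summarise atlas signal per tissue group
#' @param atlas Gene x sample matrix.
#' @param grouping An `atlas_grouping` (or named sample -> group vector).
#' @param fun Summary statistic within a group (default median, robust to
#'   outlier arrays).
#' @return Gene x group matrix; columns named by group id.
#' @export
group_summarise <- function(atlas, grouping, fun = stats::median) {
  assign <- if (inherits(grouping, "atlas_grouping")) grouping$assignment else grouping
  assign <- assign[colnames(atlas)]
  ids <- sort(unique(assign))
  out <- vapply(ids, function(g)
    apply(atlas[, assign == g, drop = FALSE], 1, fun), numeric(nrow(atlas)))
  colnames(out) <- as.character(ids)
  out
}

#' Dynamic step classification of tissue-restricted genes
#'
#' Per gene, group values (plus a pseudocount) are sorted in decreasing
#' order; the step at position k is value_k / value_(k+1). The gene is
#' called restricted at the k (1 <= k <= `max_groups`) maximising the step
#' among positions whose step is at least `step_fold` and whose value_k is
#' at least `floor`; ties go to the smaller k (the more restricted call).
#' Genes whose maximum group value falls below `floor` are labelled
#' "not_detected" rather than broad.
#'
#' @param group_expr Gene x group matrix of non-negative signal.
#' @param max_groups Maximum restriction breadth.
#' @param step_fold Minimum fold step separating the restricted groups from
#'   the rest.
#' @param floor Scalar detection floor on group signal; when NULL, the
#'   atlas-wide median of per-gene median group signals.
#' @param pseudocount Added to group values before ratios.
#' @return data.frame(gene_id, restricted, label, k, groups, step_ratio,
#'   max_value); `groups` holds comma-joined group ids for restricted genes.
#' @export
dynamic_step_classify <- function(group_expr, max_groups = 5L, step_fold = 1.7,
                                  floor = NULL, pseudocount = 1) {
  if (max_groups < 1) stop("max_groups must be >= 1")
  if (any(group_expr < 0)) stop("group_expr must be non-negative")
  if (is.null(floor))
    floor <- stats::median(apply(group_expr, 1, stats::median))
  gids <- colnames(group_expr)
  n <- nrow(group_expr)
  restricted <- logical(n); kk <- integer(n); ratio <- rep(NA_real_, n)
  grp <- character(n)
  mx <- apply(group_expr, 1, max)
  kmax <- min(max_groups, ncol(group_expr) - 1L)
  for (i in seq_len(n)) {
    v <- sort(group_expr[i, ], decreasing = TRUE) + pseudocount
    steps <- v[seq_len(kmax)] / v[seq_len(kmax) + 1L]
    ok <- steps >= step_fold & (v[seq_len(kmax)] - pseudocount) >= floor
    if (any(ok)) {
      cand <- which(ok)
      best <- cand[which.max(steps[cand])]  # which.max takes the first: ties to small k
      restricted[i] <- TRUE
      kk[i] <- best
      ratio[i] <- steps[best]
      top <- names(sort(group_expr[i, ], decreasing = TRUE))[seq_len(best)]
      grp[i] <- paste(sort(top), collapse = ",")
    }
  }
  label <- ifelse(restricted, "restricted",
                  ifelse(mx < floor, "not_detected", "broad"))
  data.frame(gene_id = rownames(group_expr), restricted = restricted,
             label = label, k = kk, groups = grp, step_ratio = ratio,
             max_value = mx, stringsAsFactors = FALSE)
}

#' Simple-threshold baseline for tissue restriction
#'
#' A gene is restricted when its maximum group value is at least
#' `fold_over_median` times its median group value (pseudocounted).
#'
#' @param group_expr Gene x group matrix.
#' @param fold_over_median Fold threshold over the per-gene median.
#' @param pseudocount Added before the ratio.
#' @return data.frame(gene_id, restricted, ratio).
#' @export
simple_threshold_classify <- function(group_expr, fold_over_median = 10,
                                      pseudocount = 1) {
  mx <- apply(group_expr, 1, max)
  md <- apply(group_expr, 1, stats::median)
  ratio <- (mx + pseudocount) / (md + pseudocount)
  data.frame(gene_id = rownames(group_expr),
             restricted = ratio >= fold_over_median,
             ratio = ratio, stringsAsFactors = FALSE)
}

# group-level tree implied by the sample tree above the n_groups cut:
# returns list of internal nodes, each a sorted vector of group ids,
# from narrowest to the root (plus leaf nodes as singletons)
.group_tree_nodes <- function(grouping) {
  hc <- grouping$tree
  assign <- grouping$assignment
  clades <- .hclust_clades(hc)
  nodes <- lapply(clades, function(s) sort(unique(assign[s])))
  nodes <- c(lapply(sort(unique(assign)), identity), nodes)
  keep <- !duplicated(vapply(nodes, paste, "", collapse = ","))
  nodes[keep]
}

#' Assign restricted genes to the smallest covering node of the group tree
#'
#' Each restricted gene is assigned to the narrowest clade of the sample
#' clustering (viewed at group level) that contains all of its restricted
#' groups, yielding non-overlapping gene sets per tree node. Sets with fewer
#' than `min_members` genes are flagged.
#'
#' @param calls Output of [dynamic_step_classify()].
#' @param grouping The `atlas_grouping` the calls were made on.
#' @param min_members Flag threshold for small sets.
#' @return List with `sets` (named list node -> gene ids), `nodes`
#'   (data.frame: node, n_leaves, n_genes, small).
#' @export
breadth_sets <- function(calls, grouping, min_members = 10L) {
  nodes <- .group_tree_nodes(grouping)
  keys <- vapply(nodes, paste, "", collapse = ",")
  sizes <- lengths(nodes)
  o <- order(sizes)
  nodes <- nodes[o]; keys <- keys[o]; sizes <- sizes[o]
  res <- calls[calls$restricted, , drop = FALSE]
  node_of <- vapply(res$groups, function(gs) {
    want <- as.integer(strsplit(gs, ",")[[1]])
    if (!all(want %in% unlist(nodes)))
      stop("gene groups absent from the grouping tree: ", gs)
    for (j in seq_along(nodes))
      if (all(want %in% nodes[[j]])) return(keys[j])
    stop("no covering node for groups ", gs)
  }, "", USE.NAMES = FALSE)
  sets <- split(res$gene_id, factor(node_of, levels = keys))
  sets <- sets[lengths(sets) > 0]
  info <- data.frame(node = names(sets),
                     n_leaves = vapply(names(sets), function(k)
                       length(strsplit(k, ",")[[1]]), integer(1)),
                     n_genes = lengths(sets),
                     small = lengths(sets) < min_members,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(sets = sets, nodes = info, total_leaves = grouping$n_groups)
}
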