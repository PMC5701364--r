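# Internal: weighted shortest-path distance matrix over a subset of nodes,
# using only edges with both endpoints in the subset when induced = TRUE.
subgraph_distances <- function(net, nodes_sub, induced = TRUE) {
  if (induced) {
    keep <- net$edges$excerpt_a %in% nodes_sub & net$edges$excerpt_b %in% nodes_sub
    edges <- net$edges[keep, ]
    node_set <- nodes_sub
  } else {
    edges <- net$edges
    node_set <- net$nodes
  }
  D <- dijkstra_distances(length(node_set),
                          match(edges$excerpt_a, node_set),
                          match(edges$excerpt_b, node_set),
                          edges$distance)
  dimnames(D) <- list(node_set, node_set)
  D[nodes_sub, nodes_sub, drop = FALSE]
}

# Ties at the arg-min/arg-max are resolved to the full tie set, using a
# relative tolerance to absorb floating-point noise in path sums.
tie_set <- function(values, best, mode = c("min", "max")) {
  mode <- match.arg(mode)
  tol <- 1e-9 * max(1, abs(best))
  if (mode == "min") names(values)[values <= best + tol]
  else names(values)[values >= best - tol]
}

#' Within-cluster closeness of every excerpt
#'
#' For each excerpt, the mean weighted shortest-path distance to the other
#' excerpts of its group. The group's key quote (by closeness) is the
#' excerpt minimizing this mean — the quote most representative of the
#' theme's conceptual centre. Distances are computed on the subgraph
#' induced by the group by default, so the quote competes only against the
#' other quotes of its own cluster; set `scope = "global"` to measure the
#' same means along paths of the full network.
#'
#' @param net A `similarity_network`.
#' @param clustering A `pte_clustering`; every group must have >= 2 members.
#' @param scope `"cluster"` (induced subgraph, default) or `"global"`.
#' @return A tibble with `excerpt_id`, `group`, `mean_distance` (`NA` for
#'   unassigned excerpts) and `key_closeness` (logical; ties all flagged).
#' @export
cluster_closeness <- function(net, clustering, scope = c("cluster", "global")) {
  stopifnot(inherits(net, "similarity_network"),
            inherits(clustering, "pte_clustering"))
  scope <- match.arg(scope)
  out <- clustering$assignment
  out$mean_distance <- NA_real_
  out$key_closeness <- FALSE
  for (gid in seq_along(clustering$groups)) {
    members <- clustering$groups[[gid]]
    D <- subgraph_distances(net, members, induced = (scope == "cluster"))
    if (any(!is.finite(D))) {
      ts_error("themesort_disconnected_group_error",
               paste0("group ", gid, " is internally disconnected; ",
                      "closeness within it is undefined"))
    }
    means <- rowSums(D) / (length(members) - 1)
    key <- tie_set(means, min(means), "min")
    idx <- match(members, out$excerpt_id)
    out$mean_distance[idx] <- unname(means[members])
    out$key_closeness[idx] <- members %in% key
  }
  out
}

#' Bridging betweenness of every excerpt
#'
#' Standard weighted node betweenness — the fractional count of weighted
#' shortest paths (conceptual distances as lengths, endpoints excluded)
#' passing through each excerpt. Computed on the full network by default,
#' because a bridging quote is one that links themes and subthemes *across*
#' the whole sort; `scope = "cluster"` restricts paths to each group's
#' induced subgraph instead. When a clustering is supplied, each group's
#' key bridging quote (arg-max over its members) is flagged.
#'
#' @param net A `similarity_network`.
#' @param clustering Optional `pte_clustering` used for per-group flags.
#' @param scope `"global"` (default) or `"cluster"`.
#' @return A tibble with `excerpt_id`, `betweenness`, and — when a
#'   clustering is given — `group` and `key_betweenness`.
#' @export
node_betweenness <- function(net, clustering = NULL,
                             scope = c("global", "cluster")) {
  stopifnot(inherits(net, "similarity_network"))
  scope <- match.arg(scope)
  if (scope == "global" || is.null(clustering)) {
    bt <- betweenness_core(length(net$nodes),
                           match(net$edges$excerpt_a, net$nodes),
                           match(net$edges$excerpt_b, net$nodes),
                           net$edges$distance)$node
    bt <- stats::setNames(bt, net$nodes)
  } else {
    bt <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
    for (members in clustering$groups) {
      keep <- net$edges$excerpt_a %in% members &
        net$edges$excerpt_b %in% members
      sub <- net$edges[keep, ]
      bt[members] <- betweenness_core(length(members),
                                      match(sub$excerpt_a, members),
                                      match(sub$excerpt_b, members),
                                      sub$distance)$node
    }
  }
  out <- tibble::tibble(excerpt_id = net$nodes, betweenness = unname(bt))
  if (!is.null(clustering)) {
    stopifnot(inherits(clustering, "pte_clustering"))
    out$group <- clustering$assignment$group[
      match(out$excerpt_id, clustering$assignment$excerpt_id)]
    out$key_betweenness <- FALSE
    for (members in clustering$groups) {
      vals <- bt[members]
      key <- tie_set(vals, max(vals), "max")
      out$key_betweenness[out$excerpt_id %in% key] <- TRUE
    }
    out <- out[, c("excerpt_id", "group", "betweenness", "key_betweenness")]
  }
  out
}

#' Per-excerpt centrality report
#'
#' One row per excerpt: its group (or `UNASSIGNED`), within-cluster mean
#' distance, node betweenness, key-quote flags, and — when a catalogue is
#' supplied — the excerpt text. This is the table an analyst reads to pick
#' the quotes that anchor each theme's interpretation.
#'
#' @param net A `similarity_network`.
#' @param clustering A `pte_clustering`.
#' @param catalog Optional excerpt catalogue (see [read_excerpt_catalog()]);
#'   must cover every excerpt of the network.
#' @param closeness_scope,betweenness_scope Passed to [cluster_closeness()]
#'   and [node_betweenness()].
#' @param path Optional output path; when given, the report is also written
#'   as a delimited table.
#' @return A tibble, rows in network node order.
#' @export
key_quote_report <- function(net, clustering, catalog = NULL,
                             closeness_scope = "cluster",
                             betweenness_scope = "global",
                             path = NULL) {
  cc <- cluster_closeness(net, clustering, scope = closeness_scope)
  nb <- node_betweenness(net, clustering, scope = betweenness_scope)
  out <- tibble::tibble(
    excerpt_id = net$nodes,
    group = ifelse(is.na(cc$group[match(net$nodes, cc$excerpt_id)]),
                   "UNASSIGNED",
                   as.character(cc$group[match(net$nodes, cc$excerpt_id)])),
    mean_distance = cc$mean_distance[match(net$nodes, cc$excerpt_id)],
    betweenness = nb$betweenness[match(net$nodes, nb$excerpt_id)],
    key_closeness = cc$key_closeness[match(net$nodes, cc$excerpt_id)],
    key_betweenness = nb$key_betweenness[match(net$nodes, nb$excerpt_id)]
  )
  if (!is.null(catalog)) {
    unknown <- setdiff(net$nodes, catalog$excerpt_id)
    if (length(unknown) > 0) {
      ts_error("themesort_catalog_error",
               paste0("excerpt(s) missing from catalogue: ",
                      paste(unknown, collapse = ", ")))
    }
    out$text <- catalog$text[match(out$excerpt_id, catalog$excerpt_id)]
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE,
                       qmethod = "double")
  }
  out
}
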