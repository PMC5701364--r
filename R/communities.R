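# Internal: connected-component membership from an edge list over 1..n
# (compiled union-find; ids renumbered in order of first node).
components_membership <- function(n, from, to) {
  connected_components(n, as.integer(from), as.integer(to))
}

# Internal: betweenness of the current edge set, nodes indexed 1..n.
betweenness_core <- function(n, from, to, len) {
  if (length(from) == 0) {
    return(list(node = numeric(n), edge = numeric(0)))
  }
  brandes_betweenness(n, as.integer(from), as.integer(to), as.numeric(len))
}

#' Edge betweenness of the similarity network
#'
#' For every tie, the number of weighted shortest paths between node pairs
#' that pass through it, counted once per unordered pair, with equal-length
#' alternatives sharing the count fractionally. Conceptual distances
#' (`1/score`) are the path lengths, so high values mark ties that join
#' conceptually distant parts of the network — the ties the community
#' detection removes first.
#'
#' @param net A `similarity_network` with at least one edge.
#' @return The network's edge tibble with a `betweenness` column appended.
#' @export
edge_betweenness <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  if (nrow(net$edges) == 0) {
    ts_error("themesort_format_error", "network has no edges")
  }
  bt <- betweenness_core(length(net$nodes),
                         match(net$edges$excerpt_a, net$nodes),
                         match(net$edges$excerpt_b, net$nodes),
                         net$edges$distance)
  out <- net$edges
  out$betweenness <- bt$edge
  out
}

#' Girvan-Newman dendrogram by iterative edge removal
#'
#' Repeatedly recomputes edge betweenness on the remaining network and
#' removes the single tie with the highest value, recording a new partition
#' level every time the removal splits a component. Level 0 is the
#' connected-component partition of the input network; the final level is
#' all singletons. When several ties share the maximal betweenness (within
#' relative tolerance 1e-12) the lexicographically smallest
#' (min label, max label) tie is removed, making the procedure fully
#' deterministic.
#'
#' Each level's quality is its weighted modularity on the *original*
#' network (see [partition_quality()]), used by [select_partition()] to
#' choose the cut.
#'
#' @param net A `similarity_network`.
#' @return A `pte_dendrogram`: list with `levels` (list of membership
#'   vectors named by excerpt), `n_communities`, `quality` (modularity per
#'   level), `removed_edges` (tibble of every removal with its betweenness,
#'   in order) and `nodes`.
#' @export
girvan_newman <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  n <- length(net$nodes)
  from <- match(net$edges$excerpt_a, net$nodes)
  to <- match(net$edges$excerpt_b, net$nodes)
  len <- net$edges$distance
  lab_a <- net$edges$excerpt_a
  lab_b <- net$edges$excerpt_b

  memb <- components_membership(n, from, to)
  levels <- list(stats::setNames(memb, net$nodes))
  ncomm <- max(memb)
  rem_a <- character(0); rem_b <- character(0); rem_bt <- numeric(0)

  while (length(from) > 0) {
    bt <- betweenness_core(n, from, to, len)$edge
    mx <- max(bt)
    cand <- which(bt >= mx - 1e-12 * max(1, abs(mx)))
    # edges are kept in canonical lexicographic order, so the first
    # candidate is the lexicographically smallest tie
    drop <- cand[1]
    rem_a <- c(rem_a, lab_a[drop])
    rem_b <- c(rem_b, lab_b[drop])
    rem_bt <- c(rem_bt, bt[drop])
    from <- from[-drop]; to <- to[-drop]; len <- len[-drop]
    lab_a <- lab_a[-drop]; lab_b <- lab_b[-drop]
    memb <- components_membership(n, from, to)
    k <- max(memb)
    if (k > ncomm) {
      levels[[length(levels) + 1L]] <- stats::setNames(memb, net$nodes)
      ncomm <- k
    }
  }

  quality <- vapply(levels, function(p) partition_quality(net, p), numeric(1))
  structure(
    list(levels = levels,
         n_communities = vapply(levels, max, numeric(1)),
         quality = quality,
         removed_edges = tibble::tibble(excerpt_a = rem_a, excerpt_b = rem_b,
                                        betweenness = rem_bt,
                                        step = seq_along(rem_a)),
         nodes = net$nodes),
    class = "pte_dendrogram"
  )
}

#' @export
print.pte_dendrogram <- function(x, ...) {
  cat("<pte_dendrogram> ", length(x$levels), " level(s) over ",
      length(x$nodes), " excerpts; communities ",
      paste(range(x$n_communities), collapse = ".."),
      "; best Q = ", format(max(x$quality), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity with the similarity *scores* as edge strengths:
#' `Q = sum_c [ W_in(c)/W - (S_c/(2W))^2 ]`, where `W` is the total edge
#' score, `W_in(c)` the score inside community `c`, and `S_c` the summed
#' node strengths of `c`. Scores — not distances — are used here because
#' modularity needs affinity weights: a partition is good when strong ties
#' fall within groups.
#'
#' @param net A `similarity_network`.
#' @param membership Integer vector of community ids; either named by
#'   excerpt or in `net$nodes` order.
#' @return The modularity `Q` (0 for an edgeless network, by convention).
#' @examples
#' # one all-inclusive community always scores 0
#' @export
partition_quality <- function(net, membership) {
  stopifnot(inherits(net, "similarity_network"))
  memb <- align_membership(net$nodes, membership)
  w <- as.numeric(net$edges$score)
  W <- sum(w)
  if (W == 0) return(0)
  ca <- memb[match(net$edges$excerpt_a, net$nodes)]
  cb <- memb[match(net$edges$excerpt_b, net$nodes)]
  W_in <- sum(w[ca == cb])
  # S_c: total strength of community c = sum of w over edge endpoints in c
  S_c <- vapply(split(c(w, w), c(ca, cb)), sum, numeric(1))
  W_in / W - sum((S_c / (2 * W))^2)
}

# Internal: reconcile a membership vector with the network's node order.
align_membership <- function(nodes, membership) {
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), nodes)) {
      ts_error("themesort_format_error",
               "membership names do not match network nodes")
    }
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    ts_error("themesort_format_error",
             "membership length does not match node count")
  }
  stats::setNames(as.integer(membership), nodes)
}

#' Choose the partition from a dendrogram
#'
#' By default, returns the dendrogram level with maximal weighted
#' modularity (the earliest such level on ties). Since the cut determines
#' the final themes, a fixed community count `k` can be requested instead,
#' in which case the first level with exactly `k` communities is returned.
#'
#' @param dendro A `pte_dendrogram` from [girvan_newman()].
#' @param net Optional `similarity_network`; if supplied, per-level
#'   modularity is recomputed from it rather than read from the dendrogram.
#' @param k Optional integer; request the first level with exactly `k`
#'   communities (error if no level has `k`).
#' @return Named integer membership vector over all excerpts.
#' @export
select_partition <- function(dendro, net = NULL, k = NULL) {
  stopifnot(inherits(dendro, "pte_dendrogram"))
  if (!is.null(k)) {
    hit <- which(dendro$n_communities == k)
    if (length(hit) == 0) {
      ts_error("themesort_selection_error",
               paste0("no dendrogram level has exactly ", k, " communities"))
    }
    return(dendro$levels[[hit[1]]])
  }
  quality <- dendro$quality
  if (!is.null(net)) {
    quality <- vapply(dendro$levels, function(p) partition_quality(net, p),
                      numeric(1))
  }
  dendro$levels[[which.max(quality)]]
}

#' Turn a partition into a clustering with unassigned excerpts
#'
#' Communities with at least two members become thematic groups; singleton
#' communities (including isolated nodes) are flagged as unassigned —
#' excerpts that cut across themes and belong to none. Group ids are
#' assigned in decreasing size order, ties broken by smallest member label,
#' so numbering is reproducible.
#'
#' @param membership Named integer vector (excerpt -> community id).
#' @return A `pte_clustering`: list with `assignment` (tibble `excerpt_id`,
#'   `group` — integer or `NA` for unassigned), `groups` (list of member
#'   vectors, indexed by group id) and `unassigned` (character vector).
#' @export
finalize_clustering <- function(membership) {
  if (is.null(names(membership))) {
    ts_error("themesort_format_error", "membership must be named by excerpt")
  }
  comms <- split(names(membership), membership)
  sizes <- lengths(comms)
  multi <- comms[sizes >= 2]
  if (length(multi) > 0) {
    key_min <- vapply(multi, function(g) sort(g)[1], character(1))
    ord <- order(-lengths(multi), key_min, method = "radix")
    multi <- multi[ord]
  }
  groups <- stats::setNames(unname(multi), seq_along(multi))
  unassigned <- sort(unlist(comms[sizes < 2], use.names = FALSE))
  if (is.null(unassigned)) unassigned <- character(0)
  group_of <- stats::setNames(rep(NA_integer_, length(membership)),
                              names(membership))
  for (i in seq_along(groups)) group_of[groups[[i]]] <- i
  structure(
    list(assignment = tibble::tibble(excerpt_id = names(membership),
                                     group = unname(group_of)),
         groups = groups,
         unassigned = unassigned),
    class = "pte_clustering"
  )
}

#' @export
print.pte_clustering <- function(x, ...) {
  cat("<pte_clustering> ", length(x$groups), " group(s) of sizes {",
      paste(lengths(x$groups), collapse = ", "), "}; ",
      length(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

#' Run community detection end to end
#'
#' Convenience wrapper: [girvan_newman()] then [select_partition()] then
#' [finalize_clustering()].
#'
#' @param net A `similarity_network`.
#' @param k Optional fixed community count passed to [select_partition()].
#' @return A `pte_clustering`.
#' @export
detect_themes <- function(net, k = NULL) {
  finalize_clustering(select_partition(girvan_newman(net), k = k))
}

#' Write a clustering as a delimited table
#'
#' @param clustering A `pte_clustering`.
#' @param path Output path; one row per excerpt with its group id or
#'   `UNASSIGNED`.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path, sep = ",") {
  stopifnot(inherits(clustering, "pte_clustering"))
  df <- clustering$assignment
  out <- data.frame(excerpt_id = df$excerpt_id,
                    group = ifelse(is.na(df$group), "UNASSIGNED",
                                   as.character(df$group)))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Serialize a dendrogram to JSON
#'
#' @param dendro A `pte_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_json <- function(dendro, path) {
  stopifnot(inherits(dendro, "pte_dendrogram"))
  payload <- list(
    nodes = dendro$nodes,
    levels = lapply(seq_along(dendro$levels), function(i) {
      list(level = i - 1L,
           n_communities = dendro$n_communities[i],
           quality = dendro$quality[i],
           membership = as.list(dendro$levels[[i]]))
    }),
    removed_edges = dendro$removed_edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
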