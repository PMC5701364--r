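#' Pairwise similarity scores across sorters
#'
#' For every unordered pair of excerpts, the similarity score is the number
#' of sorters who placed both excerpts in the same pile (0..m). With `n`
#' excerpts, all `n(n-1)/2` pairs are evaluated. Scores of at least 1 also
#' carry a conceptual distance of `1/score`, so a pair co-assigned by every
#' one of `m` sorters sits at distance `1/m` while a pair co-assigned once
#' sits at the maximum distance 1.
#'
#' @param ds A [sort_dataset()].
#' @return A tibble with one row per unordered pair, columns `excerpt_a`,
#'   `excerpt_b` (with `excerpt_a` < `excerpt_b` lexicographically, rows
#'   sorted by that key), `score` (integer) and `distance` (`1/score`, or
#'   `NA` for score 0).
#' @seealso [build_network()] which keeps only score >= 1 pairs as edges.
#' @export
pair_similarity <- function(ds) {
  stopifnot(inherits(ds, "sort_dataset"))
  n <- length(ds$excerpt_ids)
  S <- matrix(0L, n, n, dimnames = list(ds$excerpt_ids, ds$excerpt_ids))
  for (p in ds$participant_ids) {
    rec <- ds$records[ds$records$participant_id == p, ]
    v <- rec$pile_label[match(ds$excerpt_ids, rec$excerpt_id)]
    same <- outer(v, v, `==`)
    same[is.na(same)] <- FALSE     # incomplete sorts: unobserved pairs don't count
    S <- S + same
  }
  idx <- utils::combn(order(ds$excerpt_ids), 2)
  a <- ds$excerpt_ids[idx[1, , drop = TRUE]]
  b <- ds$excerpt_ids[idx[2, , drop = TRUE]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b, method = "radix")
  a <- a[ord]; b <- b[ord]
  score <- as.integer(S[cbind(a, b)])
  tibble::tibble(
    excerpt_a = a,
    excerpt_b = b,
    score = score,
    distance = ifelse(score >= 1L, 1 / score, NA_real_)
  )
}

#' Conceptual distance of a similarity score
#'
#' @param score Integer vector of similarity scores, all >= 1. A score of 0
#'   means no tie exists, so no distance is defined for it.
#' @return `1/score`, exactly.
#' @examples
#' to_distance(c(8, 4, 1)) # 0.125 0.25 1
#' @export
to_distance <- function(score) {
  if (any(score < 1)) {
    ts_error("themesort_undefined_distance_error",
             "distance is undefined for score 0 pairs: no tie exists to carry it")
  }
  1 / score
}

#' Construct a similarity network from hand-supplied parts
#'
#' Mostly useful for building small networks directly in examples and
#' tests; pipelines should use [build_network()].
#'
#' @param nodes Character vector of excerpt labels (isolated nodes allowed).
#' @param edges Data frame with columns `excerpt_a`, `excerpt_b`, `score`;
#'   `distance` is derived as `1/score` if absent.
#' @param n_sorters Number of sorters the scores are counted over.
#' @return A `similarity_network` object.
#' @export
similarity_network <- function(nodes, edges, n_sorters) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    ts_error("themesort_format_error", "duplicate node labels")
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("excerpt_a", "excerpt_b", "score") %in% names(edges)))
    edges$excerpt_a <- as.character(edges$excerpt_a)
    edges$excerpt_b <- as.character(edges$excerpt_b)
    if (any(edges$score < 1)) {
      ts_error("themesort_format_error", "edges must have score >= 1")
    }
    if (!all(edges$excerpt_a %in% nodes) || !all(edges$excerpt_b %in% nodes)) {
      ts_error("themesort_format_error", "edge endpoint not among nodes")
    }
    if (any(edges$excerpt_a == edges$excerpt_b)) {
      ts_error("themesort_format_error", "self-loops are not allowed")
    }
    swap <- edges$excerpt_a > edges$excerpt_b
    tmp <- edges$excerpt_a[swap]
    edges$excerpt_a[swap] <- edges$excerpt_b[swap]
    edges$excerpt_b[swap] <- tmp
    if (anyDuplicated(paste(edges$excerpt_a, edges$excerpt_b))) {
      ts_error("themesort_format_error", "duplicate edges")
    }
    edges$score <- as.integer(edges$score)
    edges$distance <- 1 / edges$score
    edges <- edges[order(edges$excerpt_a, edges$excerpt_b, method = "radix"),
                   c("excerpt_a", "excerpt_b", "score", "distance")]
  } else {
    edges <- tibble::tibble(excerpt_a = character(0), excerpt_b = character(0),
                            score = integer(0), distance = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges,
                 n_sorters = as.integer(n_sorters)),
            class = "similarity_network")
}

#' Build the weighted co-occurrence network
#'
#' Each excerpt becomes a node; an undirected tie joins two excerpts if at
#' least one sorter placed them in the same pile. Each tie carries the
#' similarity score (how many sorters co-assigned the pair) and the
#' conceptual distance `1/score` used as the tie's length in shortest-path
#' computations. Excerpts never co-piled with anything remain as isolated
#' nodes.
#'
#' @param ds A [sort_dataset()].
#' @return A `similarity_network`: list with `nodes` (all excerpt labels,
#'   first-appearance order), `edges` (tibble `excerpt_a`, `excerpt_b`,
#'   `score`, `distance`, in canonical lexicographic order) and `n_sorters`.
#' @examples
#' ds <- sort_dataset(data.frame(
#'   participant_id = rep(c("p1", "p2"), each = 4),
#'   excerpt_id     = rep(c("raspberry", "tomato", "grapes", "seaweed"), 2),
#'   pile_label     = c("a", "a", "a", "b", "x", "x", "y", "y")
#' ))
#' net <- build_network(ds)
#' net$edges
#' @export
build_network <- function(ds) {
  ps <- pair_similarity(ds)
  keep <- ps[ps$score >= 1L, ]
  names(keep) <- c("excerpt_a", "excerpt_b", "score", "distance")
  similarity_network(ds$excerpt_ids, keep,
                     n_sorters = length(ds$participant_ids))
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("<similarity_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " ties (scores over ", x$n_sorters, " sorter(s))\n", sep = "")
  invisible(x)
}

#' Convert a similarity network to an igraph object
#'
#' Used for file export and for cross-checking against independent graph
#' routines; all analysis in this package runs on its own representation.
#'
#' @param net A `similarity_network`.
#' @return An undirected `igraph` graph with edge attributes `score`,
#'   `distance` and `weight` (= distance).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$excerpt_a, net$nodes),
               match(net$edges$excerpt_b, net$nodes)),
      score = net$edges$score,
      distance = net$edges$distance,
      weight = net$edges$distance
    )
  }
  g
}
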