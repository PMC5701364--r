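#' Export a similarity network to a file
#'
#' Supported formats: `"edgelist"` — delimited table with columns
#' `excerpt_a`, `excerpt_b`, `score`, `distance` in canonical order;
#' `"graphml"` — GraphML with `score` and `distance` edge attributes
#' (written via igraph); `"dot"` — Graphviz DOT for rendering, mapping the
#' similarity score to pen width and, when a clustering is supplied, the
#' group to node colour with a neutral colour for unassigned excerpts.
#'
#' @param net A `similarity_network`.
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"graphml"`, `"dot"`.
#' @param clustering Optional `pte_clustering`, used for DOT node colours.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml", "dot"),
                           clustering = NULL) {
  stopifnot(inherits(net, "similarity_network"))
  if (length(format) == 1 && !format %in% c("edgelist", "graphml", "dot")) {
    ts_error("themesort_format_error", paste0("unknown format: ", format))
  }
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = ",", row.names = FALSE,
                       quote = TRUE, qmethod = "double")
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    writeLines(dot_lines(net, clustering), path)
  }
  invisible(path)
}

# Graphviz palette: one fill per group, neutral grey for unassigned.
dot_palette <- c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3", "#a6d854",
                 "#ffd92f", "#e5c494", "#b3b3b3", "#1b9e77", "#d95f02",
                 "#7570b3", "#e7298a")

dot_lines <- function(net, clustering = NULL) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lines <- c("graph themesort {", "  node [style=filled];")
  fill <- stats::setNames(rep("#dddddd", length(net$nodes)), net$nodes)
  if (!is.null(clustering)) {
    g <- clustering$assignment$group[
      match(net$nodes, clustering$assignment$excerpt_id)]
    ok <- !is.na(g)
    fill[ok] <- dot_palette[(g[ok] - 1) %% length(dot_palette) + 1]
  }
  lines <- c(lines, sprintf("  \"%s\" [fillcolor=\"%s\"];",
                            esc(net$nodes), fill))
  if (nrow(net$edges) > 0) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [penwidth=%d, label=\"%d\"];",
                              esc(net$edges$excerpt_a),
                              esc(net$edges$excerpt_b),
                              net$edges$score, net$edges$score))
  }
  c(lines, "}")
}
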