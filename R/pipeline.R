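#' Run the full theme-elicitation pipeline
#'
#' End to end: read (or accept) a multi-sorter dataset, build the weighted
#' co-occurrence network, detect thematic groups by iterative
#' edge-betweenness removal with a modularity cut, identify key quotes,
#' compute preservation diagnostics, and write the output bundle.
#'
#' @param sorts A [sort_dataset()], or a path to a sort table readable by
#'   [read_sort_table()].
#' @param catalog Optional excerpt catalogue (tibble or path).
#' @param out_dir Output directory (created if needed). Files written:
#'   `network_edgelist.csv`, `network.graphml`, `network.dot`,
#'   `dendrogram.json`, `clustering.csv`, `keyquotes.csv`,
#'   `preservation.csv`, `manifest.json`.
#' @param k Optional fixed community count (default: modularity maximum).
#' @param closeness_scope,betweenness_scope Centrality scopes (see
#'   [cluster_closeness()] and [node_betweenness()]).
#' @param count_singletons Preservation switch (see [preservation_table()]).
#' @return Invisibly, a list with `network`, `dendrogram`, `clustering`,
#'   `keyquotes`, `preservation` and `manifest`.
#' @export
run_pte <- function(sorts, catalog = NULL, out_dir = NULL, k = NULL,
                    closeness_scope = "cluster",
                    betweenness_scope = "global",
                    count_singletons = FALSE) {
  input_path <- NULL
  if (is.character(sorts)) {
    input_path <- sorts
    sorts <- read_sort_table(sorts)
  }
  stopifnot(inherits(sorts, "sort_dataset"))
  catalog_path <- NULL
  if (is.character(catalog)) {
    catalog_path <- catalog
    catalog <- read_excerpt_catalog(catalog)
  }

  net <- build_network(sorts)
  dendro <- girvan_newman(net)
  clustering <- finalize_clustering(select_partition(dendro, k = k))
  kq <- key_quote_report(net, clustering, catalog = catalog,
                         closeness_scope = closeness_scope,
                         betweenness_scope = betweenness_scope)
  pres <- preservation_table(sorts, clustering,
                             count_singletons = count_singletons)

  manifest <- list(
    package = "themesort",
    version = as.character(utils::packageVersion("themesort")),
    config = list(k = k, closeness_scope = closeness_scope,
                  betweenness_scope = betweenness_scope,
                  count_singletons = count_singletons),
    inputs = list(
      sorts = input_path,
      sorts_md5 = if (!is.null(input_path))
        unname(tools::md5sum(input_path)) else NULL,
      catalog = catalog_path,
      n_excerpts = length(sorts$excerpt_ids),
      n_sorters = length(sorts$participant_ids)
    ),
    result = list(n_groups = length(clustering$groups),
                  group_sizes = unname(lengths(clustering$groups)),
                  unassigned = clustering$unassigned,
                  modularity = max(dendro$quality))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_network(net, file.path(out_dir, "network_edgelist.csv"), "edgelist")
    export_network(net, file.path(out_dir, "network.graphml"), "graphml")
    export_network(net, file.path(out_dir, "network.dot"), "dot",
                   clustering = clustering)
    write_dendrogram_json(dendro, file.path(out_dir, "dendrogram.json"))
    write_clustering(clustering, file.path(out_dir, "clustering.csv"))
    key_quote_report(net, clustering, catalog = catalog,
                     closeness_scope = closeness_scope,
                     betweenness_scope = betweenness_scope,
                     path = file.path(out_dir, "keyquotes.csv"))
    utils::write.table(pres, file.path(out_dir, "preservation.csv"), sep = ",",
                       row.names = FALSE, quote = TRUE, qmethod = "double")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(network = net, dendrogram = dendro, clustering = clustering,
                 keyquotes = kq, preservation = pres, manifest = manifest))
}
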