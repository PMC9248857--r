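#' Hierarchical localization network as node/edge tables
#'
#' Builds the protein -> cluster -> neighborhood hierarchy from the final
#' assignments: proteins with a cluster call attach to their cluster,
#' proteins with only a neighborhood call attach directly to the
#' neighborhood, and clusters attach to their neighborhoods.
#'
#' @param assignments Assignment tibble ([reconcile_levels()] output).
#' @param nb_map Tibble `cluster`, `neighborhood`.
#' @return List of tibbles `nodes` (`id`, `type`) and `edges` (`from`,
#'   `to`, `type`).
#' @export
localization_network <- function(assignments, nb_map) {
  a <- assignments |> dplyr::filter(!is.na(.data$neighborhood))
  cl_nodes <- unique(a$cluster[!is.na(a$cluster)])
  nb_nodes <- unique(c(a$neighborhood, nb_map$neighborhood))
  nodes <- bind_rows(
    tibble(id = a$protein_id, type = "protein"),
    tibble(id = paste0("cluster_", cl_nodes), type = "cluster"),
    tibble(id = nb_nodes, type = "neighborhood"))
  e1 <- a |> dplyr::filter(!is.na(.data$cluster)) |>
    transmute(from = .data$protein_id,
              to = paste0("cluster_", .data$cluster),
              type = "protein-cluster")
  e2 <- a |> dplyr::filter(is.na(.data$cluster)) |>
    transmute(from = .data$protein_id, to = .data$neighborhood,
              type = "protein-neighborhood")
  e3 <- nb_map |>
    dplyr::filter(as.character(.data$cluster) %in% as.character(cl_nodes)) |>
    transmute(from = paste0("cluster_", .data$cluster),
              to = .data$neighborhood, type = "cluster-neighborhood")
  list(nodes = nodes, edges = bind_rows(e1, e2, e3))
}

#' Write a node/edge network to TSV and GraphML
#'
#' @param network List with `nodes` and `edges` ([localization_network()]
#'   or complex edge lists reshaped the same way).
#' @param path_prefix Output prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, path_prefix) {
  paths <- c(nodes = paste0(path_prefix, "_nodes.tsv"),
             edges = paste0(path_prefix, "_edges.tsv"),
             graphml = paste0(path_prefix, ".graphml"))
  readr::write_tsv(network$nodes, paths[["nodes"]])
  readr::write_tsv(network$edges, paths[["edges"]])
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes |> distinct(.data$id, .keep_all = TRUE))
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
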