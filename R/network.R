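#' Build the cross-species tissue/interaction/ortholog graph
#'
#' Nodes are (species, gene) pairs drawn from the union of the per-tissue
#' highly-enriched gene sets of both species. Physical-interaction edges
#' are kept only when both endpoints are present (same species); ortholog
#' edges are added for links whose two endpoints are present (different
#' species). The graph is undirected and unweighted; edge type is carried
#' in the `type` edge attribute, tissue membership in logical
#' `tissue_<name>` vertex attributes.
#'
#' @param gene_sets Named list (one element per species) of named lists
#'   (one element per tissue) of gene-id character vectors, as produced by
#'   [highly_enriched_gene_sets()] per species.
#' @param physical Named list (per species) of physical-interaction
#'   `pair_table`s.
#' @param orthologs Ortholog `pair_table`; `id_a` belongs to the first
#'   species in `gene_sets`, `id_b` to the second.
#' @return An `igraph` graph.
#' @export
build_network <- function(gene_sets, physical, orthologs = NULL) {
  species <- names(gene_sets)
  if (is.null(species) || length(species) < 1L)
    stop("`gene_sets` must be a named list per species")
  tissues <- sort(unique(unlist(lapply(gene_sets, names))))

  nodes <- do.call(rbind, lapply(species, function(sp) {
    genes <- sort(unique(unlist(gene_sets[[sp]])))
    if (length(genes) == 0L) return(NULL)
    data.frame(name = paste(sp, genes, sep = "|"), species = sp,
               gene = genes, stringsAsFactors = FALSE)
  }))
  if (is.null(nodes))
    return(igraph::make_empty_graph(directed = FALSE))
  for (tis in tissues)
    nodes[[paste0("tissue_", tis)]] <- mapply(function(sp, g)
      tis %in% names(gene_sets[[sp]]) && g %in% gene_sets[[sp]][[tis]],
      nodes$species, nodes$gene, USE.NAMES = FALSE)

  edges <- list()
  for (sp in intersect(names(physical), species)) {
    pt <- physical[[sp]]
    if (is.null(pt) || nrow(pt) == 0L) next
    a <- paste(sp, pt$id_a, sep = "|")
    b <- paste(sp, pt$id_b, sep = "|")
    ok <- a %in% nodes$name & b %in% nodes$name & a != b
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    key <- ifelse(a < b, paste(a, b), paste(b, a))
    dedup <- !duplicated(key)
    edges[[length(edges) + 1L]] <- data.frame(
      from = a[dedup], to = b[dedup], type = "physical",
      stringsAsFactors = FALSE)
  }
  if (!is.null(orthologs) && nrow(orthologs) > 0L && length(species) >= 2L) {
    a <- paste(species[1], orthologs$id_a, sep = "|")
    b <- paste(species[2], orthologs$id_b, sep = "|")
    ok <- a %in% nodes$name & b %in% nodes$name
    a <- a[ok]; b <- b[ok]
    key <- paste(a, b)
    dedup <- !duplicated(key)
    if (any(dedup))
      edges[[length(edges) + 1L]] <- data.frame(
        from = a[dedup], to = b[dedup], type = "ortholog",
        stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           type = character(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  has_orth <- rep(FALSE, igraph::vcount(g))
  if (any(igraph::E(g)$type == "ortholog")) {
    oe <- igraph::ends(g, igraph::E(g)[igraph::E(g)$type == "ortholog"])
    has_orth[match(unique(as.vector(oe)), igraph::V(g)$name)] <- TRUE
  }
  igraph::V(g)$has_ortholog <- has_orth
  g
}

#' Node centralities on the physical-interaction subgraph
#'
#' Degree counts physical edges only. Betweenness and closeness are
#' computed per species on the physical subgraph, within each connected
#' component: betweenness is normalized by (m-1)(m-2)/2 for component size
#' m (0 when m < 3), closeness is (m-1)/(sum of shortest-path distances)
#' so it lies in [0, 1]; isolated nodes score 0. Ortholog edges never
#' contribute to shortest paths.
#'
#' @param graph A graph from [build_network()].
#' @return Data frame with `name`, `species`, `gene`, `degree`,
#'   `betweenness`, `closeness`.
#' @export
centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L)
    return(data.frame(name = character(), species = character(),
                      gene = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      stringsAsFactors = FALSE))
  out <- data.frame(name = igraph::V(graph)$name,
                    species = igraph::V(graph)$species,
                    gene = igraph::V(graph)$gene,
                    degree = 0L, betweenness = 0, closeness = 0,
                    stringsAsFactors = FALSE)
  phys <- igraph::subgraph_from_edges(
    graph, igraph::E(graph)[igraph::E(graph)$type == "physical"],
    delete.vertices = FALSE)
  out$degree <- igraph::degree(phys)
  comps <- igraph::components(phys)
  for (cid in seq_len(comps$no)) {
    members <- which(comps$membership == cid)
    m <- length(members)
    if (m < 2L) next  # isolated: betweenness/closeness stay 0
    sub <- igraph::induced_subgraph(phys, members)
    btw <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    denom <- (m - 1) * (m - 2) / 2
    out$betweenness[members] <- if (denom > 0) btw / denom else 0
    d <- igraph::distances(sub)
    out$closeness[members] <- (m - 1) / rowSums(d)
  }
  rownames(out) <- NULL
  out
}

#' Keep hub nodes: physical degree strictly above a cutoff
#'
#' The induced subgraph on surviving nodes retains both physical and
#' ortholog edges between them. Degree exactly at the cutoff is dropped.
#'
#' @param graph A graph from [build_network()].
#' @param centrality_table Output of [centrality()] for the same graph
#'   (computed if omitted).
#' @param min_degree Degree cutoff (default 20; strict `>`).
#' @return The induced `igraph` subgraph of hubs.
#' @export
filter_hubs <- function(graph, centrality_table = NULL, min_degree = 20) {
  if (is.null(centrality_table)) centrality_table <- centrality(graph)
  keep <- centrality_table$name[centrality_table$degree > min_degree]
  igraph::induced_subgraph(graph, match(keep, igraph::V(graph)$name))
}

#' Subnetwork of ortholog-paired nodes for one tissue
#'
#' Restricts the graph to nodes that are members of the given tissue's
#' highly-enriched set and have at least one incident ortholog edge, then
#' induces the remaining physical and ortholog edges.
#'
#' @param graph A graph from [build_network()].
#' @param tissue Tissue name (must match a `tissue_<name>` vertex
#'   attribute).
#' @return The induced `igraph` subgraph, with per-species node counts in
#'   the graph attribute `node_counts`.
#' @export
ortholog_pair_subnetwork <- function(graph, tissue) {
  attr_name <- paste0("tissue_", tissue)
  if (!attr_name %in% igraph::vertex_attr_names(graph))
    stop("unknown tissue: ", tissue)
  keep <- which(igraph::vertex_attr(graph, attr_name) &
                igraph::V(graph)$has_ortholog)
  sub <- igraph::induced_subgraph(graph, keep)
  counts <- table(igraph::V(sub)$species)
  sub <- igraph::set_graph_attr(sub, "node_counts",
                                stats::setNames(as.integer(counts),
                                                names(counts)))
  sub
}

#' Export a network as GraphML plus node/edge attribute TSVs
#'
#' Writes `<stem>.graphml`, `<stem>_edges.tsv` (source, target, edge_type)
#' and `<stem>_nodes.tsv` (name, species, gene, tissue flags and, when a
#' centrality table is given, degree/betweenness/closeness) — the layout
#' Cytoscape-style tools import directly.
#'
#' @param graph An `igraph` graph from [build_network()].
#' @param stem Output path stem (no extension).
#' @param centrality_table Optional output of [centrality()].
#' @return Character vector of the files written, invisibly.
#' @export
export_network <- function(graph, stem, centrality_table = NULL) {
  files <- paste0(stem, c(".graphml", "_edges.tsv", "_nodes.tsv"))
  igraph::write_graph(graph, files[1], format = "graphml")
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[names(ed) == "type"] <- "edge_type"
  utils::write.table(ed[c("from", "to", "edge_type")], files[2],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- igraph::as_data_frame(graph, what = "vertices")
  if (!is.null(centrality_table))
    nd <- merge(nd, centrality_table[c("name", "degree", "betweenness",
                                       "closeness")],
                by = "name", sort = FALSE)
  utils::write.table(nd, files[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}
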