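#' Export a ceRNA triplet network for Cytoscape
#'
#' Writes the circRNA-miRNA-mRNA triplets as a graph. Each triplet contributes
#' two directed edges: `circ -sponges-> miRNA` and `miRNA -targets-> mRNA`;
#' repeated edges (shared across triplets) are deduplicated. Output is
#' deterministic given identical input order.
#'
#' @param triplets Data frame of ceRNA triplets as returned by
#'   [build_cerna_network()] (columns `circ_id`, `mirna_id`, `mrna_id` and the
#'   three `*_direction` columns).
#' @param format `"sif"` (Cytoscape simple interaction format), `"graphml"`
#'   (node attributes `class` and `de_direction`) or `"edge_tsv"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(triplets, format = c("sif", "graphml", "edge_tsv"), path) {
  format <- match.arg(format)
  edges <- triplet_edges(triplets)
  if (!nrow(edges)) warning("writing an empty network", call. = FALSE)
  switch(format,
    sif = {
      lines <- sprintf("%s\t%s\t%s", edges$source, edges$relation, edges$target)
      writeLines(lines, path)
    },
    edge_tsv = write_tsv(edges, path),
    graphml = {
      g <- triplet_graph(triplets, edges)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

# Deduplicated two-edges-per-triplet table.
triplet_edges <- function(triplets) {
  if (is.null(triplets) || !nrow(triplets)) {
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  edges <- rbind(
    data.frame(source = triplets$circ_id, relation = "sponges",
               target = triplets$mirna_id, stringsAsFactors = FALSE),
    data.frame(source = triplets$mirna_id, relation = "targets",
               target = triplets$mrna_id, stringsAsFactors = FALSE))
  edges[!duplicated(edges), , drop = FALSE]
}

triplet_graph <- function(triplets, edges = triplet_edges(triplets)) {
  nodes <- unique(data.frame(
    name = c(triplets$circ_id, triplets$mirna_id, triplets$mrna_id),
    class = rep(c("circRNA", "miRNA", "mRNA"), each = nrow(triplets)),
    de_direction = c(triplets$circ_direction, triplets$mirna_direction,
                     triplets$mrna_direction),
    stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$name))
    stop("inconsistent node attributes across triplets", call. = FALSE)
  igraph::graph_from_data_frame(edges[, c("source", "target", "relation")],
                                directed = TRUE, vertices = nodes)
}
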