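#' Expand multi-participant complex nodes
#'
#' A complex node with `n` molecular participants is divided into `n`
#' single-participant nodes; every edge incident to the complex is
#' replicated to each participant, and no intra-complex edges are added.
#' Participants are carried in the `src_participants` / `dst_participants`
#' columns as semicolon-separated lists (`"."` marks a simple node).
#'
#' @param edges pathway-graph edge table with columns `src_id`, `src_type`,
#'   `src_participants`, `dst_id`, `dst_type`, `dst_participants`,
#'   `edge_class` (and optionally `pathway_id`).
#' @return the edge table with all complex nodes replaced by their
#'   participants (participant columns reset to `"."`).
#' @export
expand_complex_nodes <- function(edges) {
  expand_side <- function(ed, id_col, part_col) {
    parts <- ed[[part_col]]
    parts[is.na(parts)] <- "."
    pl <- strsplit(parts, ";", fixed = TRUE)
    if (any(lengths(pl) == 0 | vapply(pl, function(p) any(!nzchar(p)), TRUE))) {
      stop("complex node with an empty participant list", call. = FALSE)
    }
    simple <- parts == "."
    pl[simple] <- as.list(ed[[id_col]][simple])
    k <- lengths(pl)
    out <- ed[rep.int(seq_len(nrow(ed)), k), , drop = FALSE]
    out[[id_col]] <- unlist(pl, use.names = FALSE)
    out[[part_col]] <- "."
    rownames(out) <- NULL
    out
  }
  edges <- expand_side(edges, "src_id", "src_participants")
  edges <- expand_side(edges, "dst_id", "dst_participants")
  edges
}

#' Merge expanded pathway graphs into one interactome
#'
#' Combines all pathway graphs on their coinciding nodes: nodes are
#' identified by `(node_type, identifier)`, the edge sets are unioned,
#' self-loops are removed, and parallel duplicate edges (the same ordered
#' node pair contributed by several pathways) collapse to one. An edge is
#' `direct` iff both endpoints are gene products and the source collection
#' marked it direct; every edge incident to a metabolite or auxiliary
#' reaction/transport node is `indirect`. The result is sorted, so merging
#' is invariant to the order of the input graphs.
#'
#' @param edges expanded edge table (see [expand_complex_nodes()]); the
#'   `pathway_id` column, if present, is ignored.
#' @return an object of class `interactome`: a list with `nodes`
#'   (`node_id`, `node_type`, `gene_id`) and `edges` (`src`, `dst`,
#'   `edge_class`).
#' @export
merge_pathway_graphs <- function(edges) {
  if (any(edges$src_participants != "." | edges$dst_participants != ".",
          na.rm = TRUE)) {
    stop("run expand_complex_nodes() before merging", call. = FALSE)
  }
  nodes <- unique(data.frame(
    node_id = c(edges$src_id, edges$dst_id),
    node_type = c(edges$src_type, edges$dst_type),
    stringsAsFactors = FALSE))
  conflicts <- unique(nodes$node_id[duplicated(nodes$node_id)])
  if (length(conflicts)) {
    stop(sprintf("conflicting node_type for identifier(s): %s",
                 paste(utils::head(conflicts, 10L), collapse = ", ")),
         call. = FALSE)
  }
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  nodes$gene_id <- ifelse(nodes$node_type == "gene_product",
                          nodes$node_id, NA_character_)
  rownames(nodes) <- NULL

  ed <- data.frame(src = edges$src_id, dst = edges$dst_id,
                   edge_class = ifelse(edges$src_type == "gene_product" &
                                         edges$dst_type == "gene_product" &
                                         edges$edge_class == "direct",
                                       "direct", "indirect"),
                   stringsAsFactors = FALSE)
  ed <- ed[ed$src != ed$dst, , drop = FALSE]
  # collapse parallel duplicates; a pair marked direct anywhere stays direct
  ed <- ed[order(ed$src, ed$dst, ed$edge_class), , drop = FALSE]
  ed <- ed[!duplicated(ed[, c("src", "dst")]), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  tt <- table(x$nodes$node_type)
  cat(sprintf("interactome: %d nodes (%s), %d edges (%d direct)\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(tt), tt), collapse = ", "),
              nrow(x$edges), sum(x$edges$edge_class == "direct")))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("src", "dst")],
                                directed = TRUE,
                                vertices = net$nodes$node_id)
}

#' Restrict the interactome to its largest connected component
#'
#' Molecular participants not connected within the overall network are
#' excluded: the largest weakly connected component (edge directions
#' ignored) is kept. The removed-node fraction is attached as attribute
#' `"removed_fraction"` (with the dropped identifiers in
#' `"removed_nodes"`); if it exceeds `max_removed_fraction` a warning is
#' raised, since a small disconnected remainder is an empirical expectation
#' rather than a guarantee. Pruning is idempotent.
#'
#' @param net an `interactome` from [merge_pathway_graphs()].
#' @param max_removed_fraction warning threshold on the removed fraction
#'   (default 0.01).
#' @return the pruned `interactome`.
#' @export
prune_unconnected <- function(net, max_removed_fraction = 0.01) {
  if (nrow(net$nodes) == 0) stop("empty graph", call. = FALSE)
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "weak")
  keep_ids <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  removed <- setdiff(net$nodes$node_id, keep_ids)
  frac <- length(removed) / nrow(net$nodes)
  if (frac > max_removed_fraction) {
    warning(sprintf("pruning removed %.2f%% of nodes (threshold %.2f%%)",
                    100 * frac, 100 * max_removed_fraction), call. = FALSE)
  }
  nodes <- net$nodes[net$nodes$node_id %in% keep_ids, , drop = FALSE]
  edges <- net$edges[net$edges$src %in% keep_ids &
                       net$edges$dst %in% keep_ids, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  out <- structure(list(nodes = nodes, edges = edges), class = "interactome")
  attr(out, "removed_fraction") <- frac
  attr(out, "removed_nodes") <- removed
  out
}

#' Per-gene connectivity in two modes
#'
#' A gene's connectivity is the number of incoming plus outgoing edges of
#' its node. `total_degree` counts all interactions, including those
#' through metabolites and auxiliary reaction/transport nodes;
#' `ppi_degree` counts only direct edges whose two endpoints are gene
#' products. Genes absent from the graph yield no record (rather than a
#' zero), so downstream gene-set intersections stay explicit.
#'
#' @param net an `interactome` (normally pruned).
#' @return data frame: `gene_id`, `ppi_degree`, `total_degree`.
#' @export
connectivity <- function(net) {
  lev <- net$nodes$node_id
  tot <- tabulate(match(c(net$edges$src, net$edges$dst), lev),
                  nbins = length(lev))
  dd <- net$edges[net$edges$edge_class == "direct", , drop = FALSE]
  ppi <- tabulate(match(c(dd$src, dd$dst), lev), nbins = length(lev))
  is_gene <- net$nodes$node_type == "gene_product"
  out <- data.frame(gene_id = net$nodes$node_id[is_gene],
                    ppi_degree = ppi[is_gene],
                    total_degree = tot[is_gene],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
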