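#' Gene-centric neighborhood pathways
#'
#' Each neighborhood pathway is defined by a central gene and its immediate
#' neighbors in the interactome, ignoring edge direction. Gene-product
#' neighbors join directly; when a neighbor is an auxiliary biochemical
#' reaction or transport node, all gene-product participants of that
#' process are included to keep the process intact. Metabolites never enter
#' the gene set. Pathways are named `nb_<central gene>`.
#'
#' @param net an `interactome` (normally pruned).
#' @param centers character vector of central gene ids; defaults to every
#'   gene-product node in the graph.
#' @return named list of member gene-id sets (each containing its center).
#' @export
neighborhood_pathways <- function(net, centers = NULL) {
  type <- setNames(net$nodes$node_type, net$nodes$node_id)
  gene_nodes <- net$nodes$node_id[net$nodes$node_type == "gene_product"]
  if (is.null(centers)) centers <- gene_nodes
  missing <- setdiff(centers, net$nodes$node_id)
  if (length(missing)) {
    stop(sprintf("gene(s) absent from graph: %s",
                 paste(utils::head(missing, 10L), collapse = ", ")),
         call. = FALSE)
  }
  und <- data.frame(a = c(net$edges$src, net$edges$dst),
                    b = c(net$edges$dst, net$edges$src),
                    stringsAsFactors = FALSE)
  nbrs <- lapply(split(und$b, und$a), unique)
  aux_nodes <- net$nodes$node_id[net$nodes$node_type == "auxiliary_process"]
  aux_members <- lapply(nbrs[intersect(aux_nodes, names(nbrs))], function(v) {
    v[type[v] == "gene_product"]
  })
  out <- lapply(centers, function(cg) {
    nb <- nbrs[[cg]]
    genes <- nb[type[nb] == "gene_product"]
    aux <- intersect(nb, aux_nodes)
    sort(unique(c(cg, genes,
                  unlist(aux_members[aux], use.names = FALSE))))
  })
  names(out) <- paste0("nb_", centers)
  out
}

#' Filtering cascade for a pathway collection
#'
#' Applies, in order: (1) a size filter keeping pathways with at least
#' `min_size` member genes; (2) a coverage filter keeping pathways in which
#' strictly more than `min_coverage` of the members belong to
#' `data_genes` (the genes with both evolution and connectivity data);
#' (3) removal of exact duplicates by gene composition, keeping one
#' representative; (4) greedy removal of pathways whose Jaccard similarity
#' with an already-kept pathway exceeds `jaccard_max`. For stages (3)-(4)
#' pathways are processed in decreasing size, ties broken by pathway id, and
#' the earlier-kept pathway wins. Every removal is recorded with its stage
#' and reason.
#'
#' @param pathways named list of member gene-id sets.
#' @param data_genes character vector of gene ids with data available.
#' @param min_size minimum member count (default 10).
#' @param min_coverage strict lower bound on the data-coverage fraction
#'   (default 0.6).
#' @param jaccard_max maximum allowed Jaccard similarity between kept
#'   pathways (default 0.7).
#' @return list with `pathways` (the surviving sets, in id order) and
#'   `audit` (data frame `pathway_id`, `stage_removed` in
#'   `size|coverage|duplicate|jaccard|kept`, `detail`).
#' @export
filter_pathways <- function(pathways, data_genes, min_size = 10,
                            min_coverage = 0.6, jaccard_max = 0.7) {
  ids <- names(pathways)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  sizes <- lengths(pathways)
  stage <- setNames(rep("kept", length(ids)), ids)
  detail <- setNames(rep("", length(ids)), ids)

  small <- sizes < min_size
  stage[small] <- "size"
  detail[small] <- sprintf("%d members < %d", sizes[small], min_size)

  cand <- ids[!small]
  cov <- vapply(pathways[cand], function(m) {
    mean(m %in% data_genes)
  }, 0)
  low <- cov <= min_coverage
  stage[cand[low]] <- "coverage"
  detail[cand[low]] <- sprintf("coverage %.3f <= %.2f", cov[low], min_coverage)
  cand <- cand[!low]

  ord <- cand[order(-sizes[cand], cand)]
  keys <- vapply(pathways[ord], function(m) {
    paste(sort(m), collapse = "\r")
  }, "")
  dup <- duplicated(keys)
  stage[ord[dup]] <- "duplicate"
  detail[ord[dup]] <- sprintf("duplicate of %s", ord[match(keys[dup], keys)])
  ord <- ord[!dup]

  if (length(ord) > 1) {
    genes <- unique(unlist(pathways[ord], use.names = FALSE))
    M <- Matrix::sparseMatrix(
      i = match(unlist(pathways[ord], use.names = FALSE), genes),
      j = rep.int(seq_along(ord), lengths(pathways[ord])),
      x = 1, dims = c(length(genes), length(ord)))
    cp <- Matrix::crossprod(M)
    sz <- sizes[ord]
    kept <- logical(length(ord))
    for (i in seq_along(ord)) {
      inter <- cp[i, ]
      prev <- which(kept & inter > 0)
      if (length(prev)) {
        jac <- inter[prev] / (sz[i] + sz[prev] - inter[prev])
        jmax <- which.max(jac)
        if (jac[jmax] > jaccard_max) {
          stage[ord[i]] <- "jaccard"
          detail[ord[i]] <- sprintf("jaccard %.3f with %s",
                                    jac[jmax], ord[prev[jmax]])
          next
        }
      }
      kept[i] <- TRUE
    }
    surv <- ord[kept]
  } else {
    surv <- ord
  }
  surv <- surv[order(surv)]
  if (!length(surv)) warning("no pathway survived filtering", call. = FALSE)
  list(pathways = pathways[surv],
       audit = data.frame(pathway_id = ids,
                          stage_removed = unname(stage[ids]),
                          detail = unname(detail[ids]),
                          stringsAsFactors = FALSE))
}

#' Pathway-level evolution and connectivity metrics
#'
#' For each pathway: `dnds_pw`, the mean dN/dS over member genes with dN/dS
#' data; `mean_conn_ppi` / `mean_conn_all`, the summed whole-interactome
#' degree of the members divided by the number of members with connectivity
#' data (degrees come from the whole interactome, not from within-pathway
#' edges); and the NPII values, the mean aggregated NGRE per biomarker
#' category over members with a defined score. Each mean is over members
#' with data only and is NA when no member has data.
#'
#' @param pathways named list of member gene-id sets (normally filtered).
#' @param dnds data frame `gene_id`, `dnds`.
#' @param conn data frame from [connectivity()].
#' @param gene_scores wide data frame from [aggregate_scores()].
#' @return data frame with one row per pathway: `pathway_id`, `n_members`,
#'   `dnds_pw`, `n_dnds`, `mean_conn_ppi`, `mean_conn_all`, `n_conn`,
#'   `npii_ac`, `npii_hc`, `npii_tfbs`, `npii_agg`, `n_score`.
#' @export
pathway_metrics <- function(pathways, dnds, conn, gene_scores) {
  pid <- rep(names(pathways), lengths(pathways))
  gene <- unlist(pathways, use.names = FALSE)
  pidf <- factor(pid, levels = names(pathways))

  pick <- function(tab, col) tab[[col]][match(gene, tab$gene_id)]
  mean_by <- function(v) {
    ok <- !is.na(v)
    s <- rowsum(ifelse(ok, v, 0), pidf)
    k <- rowsum(as.numeric(ok), pidf)
    list(mean = ifelse(k[, 1] > 0, s[, 1] / k[, 1], NA_real_),
         n = as.integer(k[, 1]))
  }
  dn <- mean_by(pick(dnds, "dnds"))
  cp <- mean_by(pick(conn, "ppi_degree"))
  ca <- mean_by(pick(conn, "total_degree"))
  s_ac <- mean_by(pick(gene_scores, "ngre_ac"))
  s_hc <- mean_by(pick(gene_scores, "ngre_hc"))
  s_tf <- mean_by(pick(gene_scores, "ngre_tfbs"))
  s_ag <- mean_by(pick(gene_scores, "ngre_agg"))

  data.frame(pathway_id = names(pathways),
             n_members = as.integer(lengths(pathways)),
             dnds_pw = dn$mean, n_dnds = dn$n,
             mean_conn_ppi = cp$mean,
             mean_conn_all = ca$mean, n_conn = ca$n,
             npii_ac = s_ac$mean, npii_hc = s_hc$mean,
             npii_tfbs = s_tf$mean, npii_agg = s_ag$mean,
             n_score = s_ag$n,
             stringsAsFactors = FALSE, row.names = NULL)
}
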