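#' Assemble the intersected gene analysis table
#'
#' Only genes present in all three inputs enter the analysis: a defined
#' dN/dS value, a defined aggregated NGRE score, and a connectivity record
#' (genes pruned from the interactome have none).
#'
#' @param dnds data frame `gene_id`, `dnds`.
#' @param gene_scores wide table from [aggregate_scores()].
#' @param conn table from [connectivity()].
#' @return merged data frame, one row per intersected gene.
#' @export
assemble_gene_table <- function(dnds, gene_scores, conn) {
  tab <- merge(merge(dnds, gene_scores, by = "gene_id"), conn, by = "gene_id")
  tab <- tab[!is.na(tab$dnds) & !is.na(tab$ngre_agg), , drop = FALSE]
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Run the full analysis pipeline on a dataset
#'
#' Chains every stage: RE annotation and window counting of the feature
#' tracks; per-profile GRE/GFE/NGRE scoring and weighted aggregation per
#' biomarker category; interactome assembly (complex expansion, merging,
#' pruning) and connectivity in both modes; assembly of the intersected
#' gene table and connectivity-outlier exclusion; neighborhood-pathway
#' construction, pooling with the classic pathways and the
#' size/coverage/duplicate/Jaccard filtering cascade; pathway metrics; the
#' Spearman correlation grid at both levels; and, when inheritance labels
#' are present, the AD-versus-AR comparison. The pipeline itself is
#' deterministic: identical inputs give identical outputs.
#'
#' @param ds a `retro_dataset` from [simulate_dataset()] or
#'   [read_dataset()].
#' @param width TSS window width in bp.
#' @param weight_rule profile weight rule, see [profile_weight()].
#' @param outlier_rule,outlier_k see [exclude_outliers()].
#' @param min_size,min_coverage,jaccard_max see [filter_pathways()].
#' @param include_pathways set `FALSE` to stop after the gene-level grid
#'   (faster when pathway-level results are not needed).
#' @return list with elements `counts`, `profile_scores`, `gene_scores`,
#'   `interactome`, `connectivity`, `gene_table`, `excluded_genes`,
#'   `pathways`, `filter_audit`, `pathway_metrics`, `grid`, `inheritance`.
#' @export
run_pipeline <- function(ds, width = 10000L,
                         weight_rule = c("complement-cubed",
                                         "one-minus-z-cubed"),
                         outlier_rule = c("fence", "topk"), outlier_k = 12L,
                         min_size = 10, min_coverage = 0.6, jaccard_max = 0.7,
                         include_pathways = TRUE) {
  weight_rule <- match.arg(weight_rule)
  outlier_rule <- match.arg(outlier_rule)

  re_flag <- annotate_re_linked(ds$hits, ds$re)
  counts <- count_features(ds$hits, re_flag, ds$tss, width = width,
                           coverage = ds$coverage)
  ps <- score_profiles(counts, weight_rule = weight_rule)
  gene_scores <- aggregate_scores(ps, ds$manifest)

  net <- prune_unconnected(
    merge_pathway_graphs(expand_complex_nodes(ds$graph_edges)))
  conn <- connectivity(net)

  tab <- assemble_gene_table(ds$dnds, gene_scores, conn)
  ex <- exclude_outliers(tab, rule = outlier_rule, k = outlier_k)
  kept <- ex$kept

  pw_metrics <- NULL
  filtered <- NULL
  audit <- NULL
  if (include_pathways) {
    nb <- neighborhood_pathways(net)
    pool <- c(nb, ds$classic)
    fl <- filter_pathways(pool, data_genes = kept$gene_id,
                          min_size = min_size, min_coverage = min_coverage,
                          jaccard_max = jaccard_max)
    filtered <- fl$pathways
    audit <- fl$audit
    keep_id <- kept$gene_id
    pw_metrics <- pathway_metrics(
      filtered,
      dnds = ds$dnds[ds$dnds$gene_id %in% keep_id, , drop = FALSE],
      conn = conn[conn$gene_id %in% keep_id, , drop = FALSE],
      gene_scores = gene_scores[gene_scores$gene_id %in% keep_id, ,
                                drop = FALSE])
  }
  grid <- correlation_grid(kept, pw_metrics)

  inh <- NULL
  if (!is.null(ds$inheritance) && nrow(ds$inheritance) > 0) {
    inh <- inheritance_comparison(kept, ds$inheritance)
  }
  list(counts = counts,
       profile_scores = ps,
       gene_scores = gene_scores,
       interactome = net,
       connectivity = conn,
       gene_table = kept,
       excluded_genes = ex$excluded,
       pathways = filtered,
       filter_audit = audit,
       pathway_metrics = pw_metrics,
       grid = grid,
       inheritance = inh)
}

#' Write pipeline results as TSV files
#'
#' Persists the tabular results of [run_pipeline()] under `dir`:
#' `counts.tsv`, `gene_scores.tsv`, `connectivity.tsv`, `gene_table.tsv`,
#' `excluded_genes.tsv`, `pathway_metrics.tsv`, `filter_audit.tsv`,
#' `pathways.gmt`, `correlation_grid.tsv` and `inheritance.tsv` (the last
#' only when labels were analyzed). Output is deterministic: rerunning the
#' pipeline on identical inputs reproduces the files byte for byte.
#'
#' @param res result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$counts, file.path(dir, "counts.tsv"))
  write_tsv(res$gene_scores, file.path(dir, "gene_scores.tsv"))
  write_tsv(res$connectivity, file.path(dir, "connectivity.tsv"))
  write_tsv(res$gene_table, file.path(dir, "gene_table.tsv"))
  write_tsv(data.frame(gene_id = res$excluded_genes),
            file.path(dir, "excluded_genes.tsv"))
  if (!is.null(res$pathway_metrics)) {
    write_tsv(res$pathway_metrics, file.path(dir, "pathway_metrics.tsv"))
    write_tsv(res$filter_audit, file.path(dir, "filter_audit.tsv"))
    write_gmt(res$pathways, file.path(dir, "pathways.gmt"))
  }
  write_tsv(res$grid, file.path(dir, "correlation_grid.tsv"))
  if (!is.null(res$inheritance)) {
    write_tsv(res$inheritance, file.path(dir, "inheritance.tsv"))
  }
  invisible(dir)
}
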