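#' Exclude connectivity outliers from the gene analysis table
#'
#' Hub artifacts can dominate rank correlations; genes with extreme total
#' degree are removed before analysis. The default `"fence"` rule drops
#' genes above the Tukey far-out fence `Q3 + 3*IQR` of `total_degree`; the
#' `"topk"` rule drops the `k` highest-degree genes (ties broken by gene
#' id). A warning is raised if more than 5% of genes would be removed.
#'
#' @param rows gene analysis table with columns `gene_id`, `total_degree`.
#' @param rule `"fence"` or `"topk"`.
#' @param k number of genes to drop under `"topk"`.
#' @return list with `kept` (the filtered table) and `excluded` (character
#'   vector of dropped gene ids).
#' @export
exclude_outliers <- function(rows, rule = c("fence", "topk"), k = 12L) {
  rule <- match.arg(rule)
  d <- rows$total_degree
  if (rule == "fence") {
    q <- quantile(d, c(0.25, 0.75), names = FALSE)
    drop <- d > q[2] + 3 * (q[2] - q[1])
  } else {
    ord <- order(-d, rows$gene_id)
    drop <- seq_len(nrow(rows)) %in% ord[seq_len(min(k, nrow(rows)))]
  }
  if (mean(drop) > 0.05) {
    warning(sprintf("outlier rule removed %.1f%% of genes", 100 * mean(drop)),
            call. = FALSE)
  }
  list(kept = rows[!drop, , drop = FALSE],
       excluded = rows$gene_id[drop])
}

#' Spearman rank correlation with mid-ranks and t approximation
#'
#' Pairs with an undefined value in either variable are dropped listwise;
#' rho is the product-moment correlation of mid-ranks (average ranks for
#' ties) and the two-sided p-value uses the large-sample t approximation
#' with `n - 2` degrees of freedom. With zero variance in either ranked
#' vector rho is undefined (NA) and flagged.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p_value`, `n`, `degenerate`.
#' @examples
#' spearman_cor(1:3, c(3, 2, 1))$rho   # -1
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = max(p, .Machine$double.xmin), n = n,
       degenerate = FALSE)
}

#' The full gene- and pathway-level correlation grid
#'
#' Computes every reported Spearman cell: at gene level, the two
#' connectivity modes (`ppi_degree`, `total_degree`) against the four NGRE
#' aggregates and dN/dS (10 cells); at pathway level, the two mean
#' connectivity modes against the four NPII aggregates and `dnds_pw`
#' (10 cells); and the structural-versus-regulatory cells, dN/dS against
#' each NGRE aggregate and `dnds_pw` against each NPII (8 cells). Pairs
#' are deleted listwise per cell, so each cell uses its maximal n.
#' P-values are reported raw; `p_adjust = "BH"` switches on
#' Benjamini-Hochberg adjustment across the grid.
#'
#' @param genes gene analysis table (columns `ppi_degree`, `total_degree`,
#'   `dnds`, `ngre_ac`, `ngre_hc`, `ngre_tfbs`, `ngre_agg`).
#' @param pathways optional pathway metrics table from [pathway_metrics()];
#'   `NULL` restricts the grid to gene level.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data frame: `level`, `x_metric`, `y_metric`, `rho`, `p_value`,
#'   `n`.
#' @export
correlation_grid <- function(genes, pathways = NULL,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  cells <- list()
  add <- function(level, tab, xs, ys) {
    for (xm in xs) for (ym in ys) {
      r <- spearman_cor(tab[[xm]], tab[[ym]])
      cells[[length(cells) + 1L]] <<- data.frame(
        level = level, x_metric = xm, y_metric = ym,
        rho = r$rho, p_value = r$p_value, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  reg_g <- c("ngre_ac", "ngre_hc", "ngre_tfbs", "ngre_agg")
  add("gene", genes, c("ppi_degree", "total_degree"), c(reg_g, "dnds"))
  add("gene", genes, "dnds", reg_g)
  if (!is.null(pathways)) {
    reg_p <- c("npii_ac", "npii_hc", "npii_tfbs", "npii_agg")
    add("pathway", pathways, c("mean_conn_ppi", "mean_conn_all"),
        c(reg_p, "dnds_pw"))
    add("pathway", pathways, "dnds_pw", reg_p)
  }
  out <- do.call(rbind, cells)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Compare autosomal-dominant and autosomal-recessive genes
#'
#' Two-sided Wilcoxon rank-sum tests comparing AD against AR genes on
#' (i) dN/dS, (ii) direct protein-protein connectivity, and (iii) a
#' combined score. The default combined score is the normalized-rank
#' difference `rank(dnds)/n - rank(ppi_degree)/n` over the labeled genes
#' (lower = more AD-like: conserved and highly connected); the alternative
#' `"z-diff"` uses the difference of z-scores.
#'
#' @param genes gene analysis table with `gene_id`, `dnds`, `ppi_degree`.
#' @param labels data frame `gene_id`, `label` with labels `"AD"`/`"AR"`.
#' @param combined `"rank-diff"` (default) or `"z-diff"`.
#' @return data frame with one row per metric: `metric`, `statistic`,
#'   `p_value`, `median_ad`, `median_ar`, `n_ad`, `n_ar`.
#' @export
inheritance_comparison <- function(genes, labels,
                                   combined = c("rank-diff", "z-diff")) {
  combined <- match.arg(combined)
  tab <- merge(genes, labels, by = "gene_id")
  tab <- tab[tab$label %in% c("AD", "AR"), , drop = FALSE]
  if (sum(tab$label == "AD") < 2 || sum(tab$label == "AR") < 2) {
    stop("need at least 2 genes per inheritance label", call. = FALSE)
  }
  n <- nrow(tab)
  tab$combined <- if (combined == "rank-diff") {
    rank(tab$dnds) / n - rank(tab$ppi_degree) / n
  } else {
    as.numeric(scale(tab$dnds)) - as.numeric(scale(tab$ppi_degree))
  }
  one <- function(metric) {
    x <- tab[[metric]][tab$label == "AD"]
    y <- tab[[metric]][tab$label == "AR"]
    wt <- wilcox.test(x, y)
    data.frame(metric = metric,
               statistic = unname(wt$statistic),
               p_value = wt$p.value,
               median_ad = median(x), median_ar = median(y),
               n_ad = length(x), n_ar = length(y),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("dnds", "ppi_degree", "combined"), one))
}
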