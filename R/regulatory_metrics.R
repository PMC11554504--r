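#' Gene RE-linked enrichment (GRE) and gene feature enrichment (GFE)
#'
#' `gre_scores()` normalizes each gene's RE-linked hit count (FES) by the
#' mean FES over the genes under analysis; `gfe_scores()` does the same for
#' the total hit count (TFS). Genes with no data (NA counts) are excluded
#' from the mean and returned as NA; by construction the mean of the
#' defined scores is exactly 1.
#'
#' @param fes,tfs numeric vectors of per-gene counts, NA for no-data genes.
#' @return numeric vector of scores, NA where the input was NA.
#' @examples
#' gre_scores(c(2, 0, 4))   # 1, 0, 2
#' @export
gre_scores <- function(fes) {
  m <- mean(fes, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate profile: mean FES over analyzed genes is zero",
         call. = FALSE)
  }
  fes / m
}

#' @rdname gre_scores
#' @export
gfe_scores <- function(tfs) {
  m <- mean(tfs, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate profile: mean TFS over analyzed genes is zero",
         call. = FALSE)
  }
  tfs / m
}

#' Normalized gene RE-linked enrichment (NGRE)
#'
#' `NGRE = GRE / GFE`: the gene's RE-linked proportion of regulatory
#' features relative to the genome-wide proportion. Undefined (NA) where
#' `GFE` is zero or either input is undefined. Satisfies the closed form
#' `NGRE = (FES/TFS) * (mean TFS / mean FES)`.
#'
#' @param gre,gfe numeric vectors from [gre_scores()] / [gfe_scores()].
#' @return numeric vector; NA encodes "undefined", not an error.
#' @export
ngre_scores <- function(gre, gfe) {
  out <- ifelse(!is.na(gfe) & gfe > 0, gre / gfe, NA_real_)
  out[is.na(gre)] <- NA_real_
  out
}

#' Informativeness weight of a feature profile
#'
#' Profiles with many zero or missing NGRE values carry less information;
#' the weight decreases from 1 (fully informative) to 0 (empty) in the
#' proportion `z` of zero/no-data values. Two monotone rules are available:
#' the default `"complement-cubed"`, `w = (1 - z)^3`, which strongly
#' down-weights sparse profiles, and the flat reading
#' `"one-minus-z-cubed"`, `w = 1 - z^3`.
#'
#' @param z proportion of zero/no-data NGRE values in the profile, in
#'   `[0, 1]`.
#' @param rule weight rule; see Details.
#' @return weight in `[0, 1]`.
#' @examples
#' profile_weight(0.5)                            # 0.125
#' profile_weight(0.5, "one-minus-z-cubed")       # 0.875
#' @export
profile_weight <- function(z, rule = c("complement-cubed",
                                       "one-minus-z-cubed")) {
  rule <- match.arg(rule)
  if (any(z < 0 | z > 1)) {
    stop("z must lie in [0, 1]", call. = FALSE)
  }
  switch(rule,
         "complement-cubed" = (1 - z)^3,
         "one-minus-z-cubed" = 1 - z^3)
}

#' Score all feature profiles of a counts table
#'
#' Computes GRE, GFE and NGRE per gene for every profile, plus the
#' per-profile proportion `z` of zero/no-data NGRE values and the resulting
#' weight `w`. The genes "under analysis" for the normalizing means of a
#' profile are those not flagged `no_data` in that profile; `z`, however,
#' is taken over the full gene universe of the table, pooling observed
#' zeros with missing values.
#'
#' @param counts long data frame from [count_features()] (`gene_id`,
#'   `profile_id`, `FES`, `TFS`, `no_data`).
#' @param weight_rule passed to [profile_weight()].
#' @return list with `scores` (long data frame `gene_id`, `profile_id`,
#'   `gre`, `gfe`, `ngre`) and `profiles` (`profile_id`, `z`, `w`).
#' @export
score_profiles <- function(counts,
                           weight_rule = c("complement-cubed",
                                           "one-minus-z-cubed")) {
  weight_rule <- match.arg(weight_rule)
  pids <- sort(unique(counts$profile_id))
  sc_list <- vector("list", length(pids))
  z <- numeric(length(pids))
  for (i in seq_along(pids)) {
    sub <- counts[counts$profile_id == pids[i], , drop = FALSE]
    fes <- ifelse(sub$no_data, NA_real_, as.numeric(sub$FES))
    tfs <- ifelse(sub$no_data, NA_real_, as.numeric(sub$TFS))
    gre <- gre_scores(fes)
    gfe <- gfe_scores(tfs)
    ngre <- ngre_scores(gre, gfe)
    bad <- is.na(ngre)
    bad[!bad] <- ngre[!bad] == 0
    z[i] <- mean(bad)
    sc_list[[i]] <- data.frame(gene_id = sub$gene_id,
                               profile_id = pids[i],
                               gre = gre, gfe = gfe, ngre = ngre,
                               stringsAsFactors = FALSE)
  }
  list(scores = do.call(rbind, sc_list),
       profiles = data.frame(profile_id = pids, z = z,
                             w = profile_weight(z, weight_rule),
                             stringsAsFactors = FALSE))
}

#' Weighted aggregation of NGRE across profiles, per biomarker category
#'
#' For each gene and category, `NGRE_AGG` is the weighted mean of the
#' gene's defined NGRE values over the member profiles,
#' `sum(w_i * NGRE_i) / sum(w_i)`; it is undefined only when the gene has
#' no defined NGRE in any member profile. The `aggregated` column pools the
#' profiles of all categories. When all profiles share the same `z` the
#' aggregation collapses to an unweighted mean.
#'
#' @param profile_scores output of [score_profiles()].
#' @param manifest data frame with columns `profile_id`, `category`
#'   (values `active_chromatin`, `inactive_chromatin`, `tfbs`).
#' @return wide data frame: `gene_id`, `ngre_ac`, `ngre_hc`, `ngre_tfbs`,
#'   `ngre_agg`.
#' @export
aggregate_scores <- function(profile_scores, manifest) {
  sc <- profile_scores$scores
  pr <- profile_scores$profiles
  genes <- sort(unique(sc$gene_id))
  pids <- pr$profile_id
  M <- matrix(NA_real_, length(genes), length(pids),
              dimnames = list(genes, pids))
  M[cbind(match(sc$gene_id, genes), match(sc$profile_id, pids))] <- sc$ngre
  w <- setNames(pr$w, pr$profile_id)

  wmean <- function(cols) {
    sub <- M[, cols, drop = FALSE]
    ww <- matrix(rep(w[cols], each = nrow(sub)), nrow(sub))
    ww[is.na(sub)] <- 0
    num <- rowSums(sub * ww, na.rm = TRUE)
    den <- rowSums(ww)
    ifelse(den > 0, num / den, NA_real_)
  }
  cat_cols <- function(cat) {
    intersect(pids, manifest$profile_id[manifest$category == cat])
  }
  cols_ac <- cat_cols("active_chromatin")
  cols_hc <- cat_cols("inactive_chromatin")
  cols_tf <- cat_cols("tfbs")
  if (!length(c(cols_ac, cols_hc, cols_tf))) {
    stop("no profiles match any biomarker category", call. = FALSE)
  }
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$ngre_ac <- if (length(cols_ac)) wmean(cols_ac) else NA_real_
  out$ngre_hc <- if (length(cols_hc)) wmean(cols_hc) else NA_real_
  out$ngre_tfbs <- if (length(cols_tf)) wmean(cols_tf) else NA_real_
  out$ngre_agg <- wmean(pids)
  rownames(out) <- NULL
  out
}

#' Pathway involvement from per-gene scores
#'
#' The (normalized) pathway involvement index is the arithmetic mean of the
#' defined per-gene values over the pathway's member genes: the mean GRE
#' gives PII, the mean NGRE (or NGRE_AGG) gives NPII. Members without data
#' cannot contribute, so the mean is over the `k` members with a defined
#' value, and `k` is reported so that coverage-based filters can judge
#' reliability.
#'
#' @param members character vector of member gene ids.
#' @param gene_values named numeric vector of per-gene scores (NA =
#'   undefined).
#' @return list with `value` (NA when no member has data) and
#'   `n_genes_with_data`.
#' @export
pathway_involvement <- function(members, gene_values) {
  v <- gene_values[match(members, names(gene_values))]
  v <- v[!is.na(v)]
  list(value = if (length(v)) mean(v) else NA_real_,
       n_genes_with_data = length(v))
}
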