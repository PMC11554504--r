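# Independent brute-force oracles and random-fixture builders used across
# the suite. Oracles are deliberately written as plain loops / direct
# formula evaluations, independent of the package implementation.

# Quadratic all-pairs half-open overlap test.
oracle_overlaps_any <- function(hits, re, min_overlap = 1L) {
  out <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(re))) {
      if (hits$chrom[i] == re$chrom[j]) {
        ov <- min(hits$end[i], re$end[j]) - max(hits$start[i], re$start[j])
        if (ov >= min_overlap) {
          out[i] <- TRUE
          break
        }
      }
    }
  }
  out
}

# Quadratic per-gene window counting oracle.
oracle_count <- function(hits, re_linked, tss, width = 10000L,
                         coverage = NULL) {
  half <- width %/% 2L
  profiles <- sort(unique(c(hits$profile_id, coverage$profile_id)))
  rows <- list()
  for (g in seq_len(nrow(tss))) {
    ws <- max(0L, tss$tss_pos[g] - half)
    we <- tss$tss_pos[g] + half
    for (p in profiles) {
      covered <- is.null(coverage) ||
        any(coverage$profile_id == p & coverage$gene_id == tss$gene_id[g])
      tfs <- 0L
      fes <- 0L
      if (covered) {
        for (h in seq_len(nrow(hits))) {
          if (hits$profile_id[h] == p && hits$chrom[h] == tss$chrom[g] &&
              min(hits$end[h], we) - max(hits$start[h], ws) >= 1) {
            tfs <- tfs + 1L
            if (re_linked[h]) fes <- fes + 1L
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tss$gene_id[g], profile_id = p,
        FES = if (covered) fes else NA_integer_,
        TFS = if (covered) tfs else NA_integer_,
        no_data = !covered, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$profile_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Explicit-loop weighted NGRE aggregation oracle for one category.
oracle_aggregate <- function(ngre_mat, w, cols) {
  vapply(seq_len(nrow(ngre_mat)), function(g) {
    num <- 0
    den <- 0
    for (p in cols) {
      v <- ngre_mat[g, p]
      if (!is.na(v)) {
        num <- num + w[p] * v
        den <- den + w[p]
      }
    }
    if (den > 0) num / den else NA_real_
  }, 0)
}

# Flood-fill (BFS) weakly-connected-components oracle on an edge table.
oracle_components <- function(nodes, edges) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$src[i]]] <- c(adj[[edges$src[i]]], edges$dst[i])
    adj[[edges$dst[i]]] <- c(adj[[edges$dst[i]]], edges$src[i])
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (v in nodes) {
    if (is.na(comp[v])) {
      k <- k + 1L
      queue <- v
      comp[v] <- k
      while (length(queue)) {
        u <- queue[1]
        queue <- queue[-1]
        for (wn in adj[[u]]) {
          if (is.na(comp[wn])) {
            comp[wn] <- k
            queue <- c(queue, wn)
          }
        }
      }
    }
  }
  comp
}

# Random typed pathway-graph edge table (expanded, no complexes).
random_typed_edges <- function(n_nodes = 60, n_edges = 120,
                               n_pathways = 5) {
  types <- c("gene_product", "metabolite", "auxiliary_process")
  node_type <- sample(types, n_nodes, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
  ids <- sprintf("%s%03d", c(gene_product = "g", metabolite = "m",
                             auxiliary_process = "r")[node_type],
                 seq_len(n_nodes))
  a <- sample.int(n_nodes, n_edges, replace = TRUE)
  b <- sample.int(n_nodes, n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  data.frame(pathway_id = sprintf("pw%02d",
                                  sample.int(n_pathways, length(a),
                                             replace = TRUE)),
             src_id = ids[a], src_type = node_type[a],
             src_participants = ".",
             dst_id = ids[b], dst_type = node_type[b],
             dst_participants = ".",
             edge_class = ifelse(node_type[a] == "gene_product" &
                                   node_type[b] == "gene_product",
                                 "direct", "indirect"),
             stringsAsFactors = FALSE)
}

# Random counts fixture: complete gene x profile grid with missingness.
random_counts <- function(n_genes, n_profiles, missing_rate = 0.1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  profiles <- sprintf("p%02d", seq_len(n_profiles))
  grid <- expand.grid(gene_id = genes, profile_id = profiles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$no_data <- runif(nrow(grid)) < missing_rate
  grid$TFS <- ifelse(grid$no_data, NA_integer_,
                     rnbinom(nrow(grid), size = 2, mu = 15))
  grid$FES <- ifelse(grid$no_data, NA_integer_,
                     rbinom(nrow(grid), ifelse(is.na(grid$TFS), 0L, grid$TFS),
                            0.35))
  grid[order(grid$gene_id, grid$profile_id), , drop = FALSE]
}
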