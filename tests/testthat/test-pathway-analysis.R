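nb_fixture <- function() {
  # center A: protein neighbor B, reaction R with participants {C, D},
  # metabolite M, plus a distant protein E attached to B only
  ed <- data.frame(
    pathway_id = "pw1",
    src_id = c("A", "R", "C", "D", "A", "B"),
    src_type = c("gene_product", "auxiliary_process", "gene_product",
                 "gene_product", "gene_product", "gene_product"),
    src_participants = ".",
    dst_id = c("B", "A", "R", "R", "M", "E"),
    dst_type = c("gene_product", "gene_product", "auxiliary_process",
                 "auxiliary_process", "metabolite", "gene_product"),
    dst_participants = ".",
    edge_class = c("direct", "indirect", "indirect", "indirect",
                   "indirect", "direct"),
    stringsAsFactors = FALSE)
  merge_pathway_graphs(ed)
}

test_that("a neighborhood pathway is the center, protein neighbors and process members", {
  net <- nb_fixture()
  pw <- neighborhood_pathways(net, centers = "A")
  expect_equal(pw[["nb_A"]], c("A", "B", "C", "D"))   # metabolite M excluded
  # direction is ignored: E neighbors B, not A
  expect_equal(neighborhood_pathways(net, "B")[["nb_B"]],
               c("A", "B", "E"))
  expect_error(neighborhood_pathways(net, "nope"), "absent")
})

test_that("neighborhood pathways equal a breadth-1 traversal oracle", {
  set.seed(23)
  ed <- random_typed_edges(120, 400, n_pathways = 6)
  net <- suppressWarnings(prune_unconnected(merge_pathway_graphs(ed)))
  type <- setNames(net$nodes$node_type, net$nodes$node_id)
  centers <- sample(net$nodes$node_id[net$nodes$node_type == "gene_product"],
                    30)
  got <- neighborhood_pathways(net, centers)
  for (cg in centers) {
    nb <- unique(c(net$edges$dst[net$edges$src == cg],
                   net$edges$src[net$edges$dst == cg]))
    members <- cg
    for (v in nb) {
      if (type[v] == "gene_product") members <- c(members, v)
      if (type[v] == "auxiliary_process") {
        pn <- unique(c(net$edges$dst[net$edges$src == v],
                       net$edges$src[net$edges$dst == v]))
        members <- c(members, pn[type[pn] == "gene_product"])
      }
    }
    expect_equal(got[[paste0("nb_", cg)]], sort(unique(members)))
  }
  # determinism: regenerating from the same graph gives identical sets
  expect_identical(got, neighborhood_pathways(net, centers))
})

test_that("the filtering cascade applies size, coverage, duplicate and Jaccard rules", {
  data_genes <- sprintf("G%02d", 1:40)
  pws <- list(
    small = sprintf("G%02d", 1:9),                        # 9 genes: size
    ok1   = sprintf("G%02d", 1:12),
    dup1  = sprintf("G%02d", 13:24),
    dup2  = sprintf("G%02d", 13:24),                      # exact duplicate
    lowcov = c(sprintf("G%02d", 25:30), sprintf("X%02d", 1:6)),  # 50% data
    jacA  = sprintf("G%02d", 1:10),                       # {A..J}
    zjacB = c(sprintf("G%02d", 1:10), "G31", "G32"))      # {A..J, X, Y}
  fl <- filter_pathways(pws, data_genes, min_size = 10,
                        min_coverage = 0.6, jaccard_max = 0.7)
  a <- setNames(fl$audit$stage_removed, fl$audit$pathway_id)
  expect_equal(unname(a["small"]), "size")
  expect_equal(unname(a["lowcov"]), "coverage")
  # ok1 = {G1..G12} is kept first among the 12-gene survivors; zjacB has
  # Jaccard 10/14 = 0.714 > 0.7 with it and falls, as does jacA (10/12)
  expect_equal(unname(a["ok1"]), "kept")
  expect_equal(unname(a["zjacB"]), "jaccard")
  expect_equal(unname(a["jacA"]), "jaccard")
  expect_equal(sum(a == "duplicate"), 1L)
  expect_equal(unname(a["dup2"]), "duplicate")   # dup1 precedes and wins
  expect_setequal(names(fl$pathways), c("ok1", "dup1"))
  # survivors are pairwise below the Jaccard bound
  ids <- names(fl$pathways)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    jac <- length(intersect(fl$pathways[[i]], fl$pathways[[j]])) /
      length(union(fl$pathways[[i]], fl$pathways[[j]]))
    expect_lte(jac, 0.7)
  }
})

test_that("coverage is a strict bound and boundary sizes survive", {
  data_genes <- sprintf("G%02d", 1:6)
  # exactly 60% coverage must be removed ("more than 60%")
  pw <- list(edge = c(sprintf("G%02d", 1:6), sprintf("X%d", 1:4)))
  expect_warning(filter_pathways(pw, data_genes, min_size = 10),
                 "no pathway survived")
  fl <- suppressWarnings(filter_pathways(pw, data_genes, min_size = 10))
  expect_equal(fl$audit$stage_removed, "coverage")
  # exactly 10 genes passes the size rule ("10 and more genes")
  pw2 <- list(ten = c(sprintf("G%02d", 1:7), "X1", "X2", "X3"))
  fl2 <- filter_pathways(pw2, data_genes = sprintf("G%02d", 1:7),
                         min_size = 10)
  expect_equal(fl2$audit$stage_removed, "kept")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(24)
  pws <- lapply(1:40, function(i) {
    sample(sprintf("G%03d", 1:120), sample(5:30, 1))
  })
  names(pws) <- sprintf("pw%02d", 1:40)
  data_genes <- sprintf("G%03d", 1:80)
  base <- names(filter_pathways(pws, data_genes)$pathways)
  stricter_size <- names(filter_pathways(pws, data_genes,
                                         min_size = 15)$pathways)
  stricter_cov <- names(filter_pathways(pws, data_genes,
                                        min_coverage = 0.8)$pathways)
  expect_true(all(stricter_size %in% base))
  expect_true(all(stricter_cov %in% base))
})

test_that("pathway metrics average member values with data", {
  pws <- list(pwA = c("g1", "g2", "g3"), pwB = c("g1", "g4"))
  dnds <- data.frame(gene_id = c("g1", "g2"), dnds = c(1.0, 0.5))
  conn <- data.frame(gene_id = c("g1", "g2", "g3"),
                     ppi_degree = c(2L, 4L, 6L),
                     total_degree = c(4L, 6L, 8L))
  scores <- data.frame(gene_id = c("g1", "g2", "g3"),
                       ngre_ac = c(1, 2, NA), ngre_hc = NA_real_,
                       ngre_tfbs = c(0.5, NA, NA), ngre_agg = c(1, 2, 3))
  pm <- pathway_metrics(pws, dnds, conn, scores)
  a <- pm[pm$pathway_id == "pwA", ]
  expect_equal(a$dnds_pw, 0.75)            # mean over the 2 genes with dN/dS
  expect_equal(a$mean_conn_all, 6)         # (4 + 6 + 8) / 3
  expect_equal(a$mean_conn_ppi, 4)
  expect_equal(a$npii_ac, 1.5)
  expect_equal(a$npii_agg, 2)
  expect_true(is.na(a$npii_hc))
  b <- pm[pm$pathway_id == "pwB", ]
  expect_equal(b$dnds_pw, 1.0)
  expect_equal(b$n_conn, 1L)               # g4 has no connectivity record
  expect_equal(b$mean_conn_all, 4)
  # members sharing one dN/dS value aggregate to exactly that value
  same <- pathway_metrics(list(p = c("g1", "g2")),
                          data.frame(gene_id = c("g1", "g2"),
                                     dnds = c(0.4, 0.4)),
                          conn, scores)
  expect_equal(same$dnds_pw, 0.4)
})

test_that("pathway metrics equal an explicit-loop oracle on a random fixture", {
  set.seed(25)
  genes <- sprintf("g%03d", 1:100)
  pws <- lapply(1:25, function(i) sample(genes, sample(5:20, 1)))
  names(pws) <- sprintf("pw%02d", 1:25)
  dnds <- data.frame(gene_id = sample(genes, 80),
                     dnds = rlnorm(80, log(0.3), 0.6))
  conn <- data.frame(gene_id = sample(genes, 90),
                     ppi_degree = rpois(90, 5), total_degree = rpois(90, 9))
  scores <- data.frame(gene_id = genes, ngre_ac = rlnorm(100),
                       ngre_hc = rlnorm(100), ngre_tfbs = rlnorm(100),
                       ngre_agg = rlnorm(100))
  scores$ngre_agg[sample(100, 20)] <- NA
  pm <- pathway_metrics(pws, dnds, conn, scores)
  for (i in sample(25, 8)) {
    m <- pws[[i]]
    dv <- dnds$dnds[match(m, dnds$gene_id)]
    expect_equal(pm$dnds_pw[i], mean(dv[!is.na(dv)]))
    tv <- conn$total_degree[match(m, conn$gene_id)]
    expect_equal(pm$mean_conn_all[i], sum(tv, na.rm = TRUE) / sum(!is.na(tv)))
    sv <- scores$ngre_agg[match(m, scores$gene_id)]
    expect_equal(pm$npii_agg[i], mean(sv, na.rm = TRUE))
  }
})
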