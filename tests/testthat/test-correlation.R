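test_that("the fence rule excludes obvious connectivity outliers only", {
  rows <- data.frame(gene_id = sprintf("g%03d", 1:21),
                     total_degree = c(1:20, 10000L))
  ex <- exclude_outliers(rows)
  expect_equal(ex$excluded, "g021")
  expect_equal(nrow(ex$kept), 20L)
  # uniform degrees exclude nothing
  flat <- data.frame(gene_id = sprintf("g%03d", 1:50), total_degree = 7L)
  expect_length(exclude_outliers(flat)$excluded, 0L)
  # the top-k rule drops exactly k, highest degree first
  exk <- suppressWarnings(exclude_outliers(rows, rule = "topk", k = 3))
  expect_setequal(exk$excluded, c("g021", "g020", "g019"))
})

test_that("fence exclusions equal direct evaluation of the far-out formula", {
  set.seed(33)
  for (rep in 1:5) {
    d <- rnbinom(500, size = 0.4, mu = 15)
    rows <- data.frame(gene_id = sprintf("g%04d", 1:500), total_degree = d)
    q <- quantile(d, c(0.25, 0.75), names = FALSE)
    want <- rows$gene_id[d > q[2] + 3 * (q[2] - q[1])]
    got <- suppressWarnings(exclude_outliers(rows))
    expect_setequal(got$excluded, want)
  }
})

test_that("spearman handles perfect monotone pairs and matches cor.test on ties", {
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  set.seed(34)
  for (rep in 1:5) {
    x <- sample.int(10, 50, replace = TRUE)   # heavy ties
    y <- 0.4 * x + rnorm(50)
    got <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    # mid-rank product-moment oracle
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(got$n, 50L)
  }
  # zero variance is flagged, not an error
  expect_true(spearman_cor(rep(1, 10), rnorm(10))$degenerate)
})

test_that("spearman is symmetric and invariant under monotone transforms", {
  set.seed(35)
  x <- rlnorm(80)
  y <- rlnorm(80)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(log(x), y)$rho)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(x, y^3)$rho)
  # listwise deletion of undefined pairs
  x[c(3, 7)] <- NA
  r <- spearman_cor(x, y)
  expect_equal(r$n, 78L)
  expect_equal(r$rho, cor(rank(x[-c(3, 7)]), rank(y[-c(3, 7)])))
})

test_that("the correlation grid enumerates the reported panel structure", {
  set.seed(36)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      dnds = rlnorm(60, log(0.3), 0.5),
                      ngre_ac = rlnorm(60), ngre_hc = rlnorm(60),
                      ngre_tfbs = rlnorm(60), ngre_agg = rlnorm(60),
                      ppi_degree = rpois(60, 6), total_degree = rpois(60, 10))
  pw <- data.frame(pathway_id = sprintf("p%02d", 1:30),
                   dnds_pw = rlnorm(30, log(0.3), 0.3),
                   npii_ac = rlnorm(30), npii_hc = rlnorm(30),
                   npii_tfbs = rlnorm(30), npii_agg = rlnorm(30),
                   mean_conn_ppi = runif(30, 2, 8),
                   mean_conn_all = runif(30, 4, 14))
  grid <- correlation_grid(genes, pw)
  conn_gene <- grid$level == "gene" &
    grid$x_metric %in% c("ppi_degree", "total_degree")
  conn_pw <- grid$level == "pathway" &
    grid$x_metric %in% c("mean_conn_ppi", "mean_conn_all")
  struct_reg <- grid$x_metric %in% c("dnds", "dnds_pw")
  expect_equal(sum(conn_gene), 10L)
  expect_equal(sum(conn_pw), 10L)
  expect_equal(sum(struct_reg), 8L)
  expect_equal(nrow(grid), 28L)
  expect_true(all(abs(grid$rho) <= 1))
  expect_true(all(grid$p_value > 0 & grid$p_value <= 1))
  # gene-level only when no pathway table is given
  expect_equal(nrow(correlation_grid(genes)), 14L)
  # BH adjustment never lowers a p-value
  adj <- correlation_grid(genes, pw, p_adjust = "BH")
  expect_true(all(adj$p_value >= grid$p_value - 1e-15))
})

test_that("identical AD and AR groups give a null inheritance comparison", {
  set.seed(37)
  vals <- rlnorm(40, log(0.3), 0.5)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:80),
                      dnds = c(vals, vals),
                      ppi_degree = rep(rpois(40, 8), 2))
  labels <- data.frame(gene_id = genes$gene_id,
                       label = rep(c("AD", "AR"), each = 40))
  rep_tab <- suppressWarnings(inheritance_comparison(genes, labels))
  expect_true(all(rep_tab$p_value > 0.9))
  expect_equal(rep_tab$median_ad, rep_tab$median_ar)
})

test_that("small fully separated groups match the exact rank-sum distribution", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      dnds = c(1:5, 101:105) / 100,
                      ppi_degree = c(101:105, 1:5))
  labels <- data.frame(gene_id = genes$gene_id,
                       label = rep(c("AD", "AR"), each = 5))
  rep_tab <- suppressWarnings(inheritance_comparison(genes, labels))
  # exact two-sided p for complete separation with n = m = 5: 2/choose(10,5)
  expect_equal(rep_tab$p_value[rep_tab$metric == "dnds"], 2 / choose(10, 5))
  expect_equal(rep_tab$p_value[rep_tab$metric == "ppi_degree"],
               2 / choose(10, 5))
  # combined rank score is even more extreme in the same direction
  expect_lte(rep_tab$p_value[rep_tab$metric == "combined"],
             rep_tab$p_value[rep_tab$metric == "dnds"])
  expect_error(inheritance_comparison(genes[1:4, ], labels[1:4, ]),
               "at least 2")
})

test_that("the combined score ranks conserved, highly connected genes as AD-like", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      dnds = c(0.1, 0.2, 0.8, 0.9),
                      ppi_degree = c(30L, 20L, 3L, 1L))
  labels <- data.frame(gene_id = genes$gene_id,
                       label = c("AD", "AD", "AR", "AR"))
  rep_tab <- inheritance_comparison(genes, labels)
  comb <- rep_tab[rep_tab$metric == "combined", ]
  expect_lt(comb$median_ad, comb$median_ar)
  zs <- inheritance_comparison(genes, labels, combined = "z-diff")
  expect_lt(zs$median_ad[zs$metric == "combined"],
            zs$median_ar[zs$metric == "combined"])
})
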