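#' Draw the latent per-gene ground truth of a simulated study
#'
#' Samples, per gene, three correlated Gaussian latents (structural rate,
#' RE-linked fraction, interactome degree) via the copula implied by the
#' configuration, and transforms them through the marginals: dN/dS is
#' lognormal (median well below 1, so purifying selection dominates and only
#' a small tail exceeds 1), the RE-linked fraction is Beta, and the target
#' degree is a shifted negative binomial (discrete heavy tail, minimum 2).
#' The expected number of window hits per gene is lognormal with a weak
#' loading on the conservation latent.
#'
#' @param config a [sim_config()].
#' @return data frame with one row per gene: `gene_id`, the three latents
#'   `z_dnds`, `z_refrac`, `z_degree`, and the realized generative
#'   parameters `dnds`, `re_fraction`, `target_degree`, `expected_hits`.
#'   The rho targets used are attached as attribute `"rho"`.
#' @export
sim_ground_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  R <- latent_correlation_matrix(config)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- matrix(rnorm(n * 3L), n, 3L) %*% L
  z_hits <- 0.3 * Z[, 1L] + sqrt(1 - 0.3^2) * rnorm(n)

  mu <- config$re_fraction_mean
  cc <- config$re_fraction_concentration
  gt <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    z_dnds = Z[, 1L],
    z_refrac = Z[, 2L],
    z_degree = Z[, 3L],
    dnds = qlnorm(pnorm(Z[, 1L]), meanlog = log(0.25), sdlog = 0.7),
    re_fraction = qbeta(pnorm(Z[, 2L]), mu * cc, (1 - mu) * cc),
    target_degree = qnbinom(pnorm(Z[, 3L]), size = config$degree_dispersion,
                            mu = config$mean_degree - 2) + 2L,
    expected_hits = qlnorm(pnorm(z_hits), meanlog = log(config$mean_hits),
                           sdlog = 0.4),
    stringsAsFactors = FALSE
  )
  attr(gt, "rho") <- c(dnds_connectivity = config$rho_dnds_connectivity,
                       dnds_ngre = config$rho_dnds_ngre,
                       ngre_connectivity = config$rho_ngre_connectivity)
  gt
}

#' Generate the synthetic genome: TSS table, feature tracks, RE annotation
#'
#' Genes are placed on synthetic chromosomes at least 20 kb apart so that
#' 10-kb TSS windows never overlap. For every feature profile the per-gene
#' window hit count is negative binomial around the gene's expected hit
#' rate; each hit is RE-linked with the gene's RE fraction. Each window is
#' internally partitioned into an RE region (left 40%) and an RE-free
#' region: RE-linked hits fall inside the RE region and an RE-annotation
#' interval is emitted exactly under each of them, while non-linked hits
#' fall in the RE-free region and can therefore never coincidentally overlap
#' an RE interval placed for another profile's hit.
#'
#' @param config a [sim_config()].
#' @param ground_truth output of [sim_ground_truth()] for the same config.
#' @return list with elements `tss` (gene_id, chrom, tss_pos, strand),
#'   `manifest` (profile_id, mark, cell_line, category), `hits` (long BED6
#'   table of all profiles with a `profile_id` column), `re` (BED6 RE
#'   annotation), `coverage` (profile_id, gene_id rows for assayed cells).
#' @export
generate_genome <- function(config, ground_truth) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  genes_per_chrom <- 500L
  half <- 5000L
  idx <- seq_len(n)
  tss <- data.frame(
    gene_id = ground_truth$gene_id,
    chrom = sprintf("chrS%02d", (idx - 1L) %/% genes_per_chrom + 1L),
    tss_pos = 20000L * ((idx - 1L) %% genes_per_chrom) + 15000L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cats <- data.frame(category = c("active_chromatin", "inactive_chromatin",
                                  "tfbs"),
                     prefix = c("ac", "hc", "tfbs"),
                     stringsAsFactors = FALSE)
  manifest <- do.call(rbind, lapply(seq_len(nrow(cats)), function(ci) {
    j <- seq_len(config$n_profiles_per_category)
    data.frame(profile_id = sprintf("%s_%02d", cats$prefix[ci], j),
               mark = sprintf("%s_mark%02d", cats$prefix[ci], j),
               cell_line = sprintf("cell%02d", j),
               category = cats$category[ci],
               stringsAsFactors = FALSE)
  }))

  w0 <- tss$tss_pos - half                     # window start (0-based)
  re_split <- 4000L                            # RE region = [w0, w0 + 4000)
  hit_len <- 100L
  hits_list <- vector("list", nrow(manifest))
  cov_list <- vector("list", nrow(manifest))
  re_list <- vector("list", nrow(manifest))
  for (pi in seq_len(nrow(manifest))) {
    pid <- manifest$profile_id[pi]
    covered <- runif(n) >= config$missing_rate
    tfs <- integer(n)
    tfs[covered] <- rnbinom(sum(covered),
                            size = 1 / config$hit_count_dispersion,
                            mu = ground_truth$expected_hits[covered])
    fes <- rbinom(n, tfs, ground_truth$re_fraction)
    g <- rep.int(idx, tfs)
    if (length(g)) {
      is_re <- sequence(tfs) <= rep.int(fes, tfs)
      base <- w0[g]
      start <- integer(length(g))
      nre <- sum(is_re)
      start[is_re] <- base[is_re] +
        as.integer(floor(runif(nre) * (re_split - hit_len + 1L)))
      start[!is_re] <- base[!is_re] + re_split +
        as.integer(floor(runif(length(g) - nre) *
                           (2L * half - re_split - hit_len + 1L)))
      hd <- data.frame(chrom = tss$chrom[g],
                       start = start,
                       end = start + hit_len,
                       name = sprintf("%s_h%06d", pid, seq_along(g)),
                       score = 0L,
                       strand = ".",
                       profile_id = pid,
                       stringsAsFactors = FALSE)
      hits_list[[pi]] <- hd
      re_list[[pi]] <- hd[is_re, c("chrom", "start", "end")]
    }
    cov_list[[pi]] <- data.frame(profile_id = pid,
                                 gene_id = tss$gene_id[covered],
                                 stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits_list)
  re <- unique(do.call(rbind, re_list))
  re <- re[order(re$chrom, re$start, re$end), , drop = FALSE]
  re$name <- sprintf("re%06d", seq_len(nrow(re)))
  re$score <- 0L
  re$strand <- "."
  rownames(re) <- NULL
  list(tss = tss, manifest = manifest, hits = hits, re = re,
       coverage = do.call(rbind, cov_list))
}

#' Emit the per-gene dN/dS table of a simulated study
#'
#' The values themselves are drawn in [sim_ground_truth()] (lognormal,
#' median 0.25, a small tail above 1); this operation exposes them in the
#' table layout the pipeline consumes.
#'
#' @inheritParams generate_genome
#' @return data frame with columns `gene_id`, `dnds`.
#' @export
generate_dnds <- function(config, ground_truth) {
  data.frame(gene_id = ground_truth$gene_id,
             dnds = ground_truth$dnds,
             stringsAsFactors = FALSE)
}

#' Generate the pathway-graph collection and classic gene sets
#'
#' Interaction stubs realize each gene's target degree exactly
#' (configuration-model pairing); a fraction of stubs attach to metabolite
#' and auxiliary reaction/transport nodes, the remainder pair into direct
#' protein-protein edges. Stub pairing is assortative on the conservation
#' latent (genes under similar selective pressure interact preferentially),
#' emulating functional modules. The edge set is partitioned into small
#' pathway graphs, a few percent of edges are duplicated across pathways
#' (exercising merge deduplication), some pairs of co-target edges are
#' re-expressed as multi-participant complex nodes (exercising expansion),
#' and a small disconnected component of genes absent from the main network
#' is appended (exercising pruning). Classic pathways are gene sets whose
#' membership clusters on the conservation latent, with one exact duplicate
#' pair and one near-duplicate pair (Jaccard > 0.7) built in when at least
#' four sets are requested.
#'
#' @inheritParams generate_genome
#' @return list with `edges` (pathway_id, src_id, src_type,
#'   src_participants, dst_id, dst_type, dst_participants, edge_class) and
#'   `classic` (named list of gene-id sets).
#' @export
generate_interactome_pathways <- function(config, ground_truth) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- config$n_genes
  gid <- ground_truth$gene_id
  d <- ground_truth$target_degree

  stub_gene <- sample(rep.int(seq_len(n), d))
  n_met <- max(1L, round(n / 40))
  n_aux <- max(1L, round(n / 50))
  met_deg <- 1L + rpois(n_met, 2)
  aux_deg <- 2L + rpois(n_aux, 2)
  cap <- floor(length(stub_gene) * 0.25)
  if (sum(met_deg) + sum(aux_deg) > cap) {
    scl <- cap / (sum(met_deg) + sum(aux_deg))
    met_deg <- pmax(1L, as.integer(floor(met_deg * scl)))
    aux_deg <- pmax(2L, as.integer(floor(aux_deg * scl)))
  }
  k1 <- sum(met_deg)
  k2 <- sum(aux_deg)
  gm <- stub_gene[seq_len(k1)]
  ga <- stub_gene[k1 + seq_len(k2)]
  rest <- stub_gene[-seq_len(k1 + k2)]

  # assortative pairing of the remaining stubs into protein-protein edges
  s <- ground_truth$z_dnds[rest] + config$assortativity_sd * rnorm(length(rest))
  rest <- rest[order(s)]
  if (length(rest) %% 2L) rest <- rest[-length(rest)]
  a <- rest[c(TRUE, FALSE)]
  b <- rest[c(FALSE, TRUE)]
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  flip <- runif(length(a)) < 0.5
  pp <- data.frame(src_id = gid[ifelse(flip, a, b)],
                   src_type = "gene_product",
                   dst_id = gid[ifelse(flip, b, a)],
                   dst_type = "gene_product",
                   edge_class = "direct",
                   stringsAsFactors = FALSE)

  met_id <- sprintf("met%04d", seq_len(n_met))
  mo <- rep.int(seq_len(n_met), met_deg)
  mf <- runif(k1) < 0.5
  me <- data.frame(src_id = ifelse(mf, met_id[mo], gid[gm]),
                   src_type = ifelse(mf, "metabolite", "gene_product"),
                   dst_id = ifelse(mf, gid[gm], met_id[mo]),
                   dst_type = ifelse(mf, "gene_product", "metabolite"),
                   edge_class = "indirect",
                   stringsAsFactors = FALSE)
  aux_id <- sprintf("rx%04d", seq_len(n_aux))
  ao <- rep.int(seq_len(n_aux), aux_deg)
  af <- runif(k2) < 0.5
  ae <- data.frame(src_id = ifelse(af, aux_id[ao], gid[ga]),
                   src_type = ifelse(af, "auxiliary_process", "gene_product"),
                   dst_id = ifelse(af, gid[ga], aux_id[ao]),
                   dst_type = ifelse(af, "gene_product", "auxiliary_process"),
                   edge_class = "indirect",
                   stringsAsFactors = FALSE)

  ed <- rbind(pp, me, ae)
  E <- nrow(ed)
  K <- max(1L, as.integer(round(E / 120)))
  pw <- sample(rep_len(seq_len(K), E))
  ed$pathway_id <- sprintf("pg%04d", pw)
  ed$src_participants <- "."
  ed$dst_participants <- "."

  # duplicate ~2% of edges into a second pathway
  ndup <- max(1L, as.integer(round(0.02 * E)))
  di <- sample.int(E, ndup)
  dup <- ed[di, , drop = FALSE]
  dup$pathway_id <- sprintf("pg%04d", (pw[di] %% K) + 1L)

  # fold pairs of direct co-target edges into complex nodes
  dd <- which(ed$edge_class == "direct")
  key <- paste(ed$pathway_id[dd], ed$dst_id[dd])
  grp <- split(dd, key)
  grp <- grp[vapply(grp, function(r) {
    length(unique(ed$src_id[r])) >= 2L
  }, TRUE)]
  grp <- grp[order(names(grp))]
  n_cx <- min(15L, length(grp))
  drop_rows <- integer(0)
  cx_rows <- vector("list", n_cx)
  for (i in seq_len(n_cx)) {
    r <- grp[[i]]
    r <- r[!duplicated(ed$src_id[r])][1:2]
    row <- ed[r[1], , drop = FALSE]
    row$src_id <- sprintf("cx%03d", i)
    row$src_participants <- paste(ed$src_id[r], collapse = ";")
    cx_rows[[i]] <- row
    drop_rows <- c(drop_rows, r)
  }
  if (length(drop_rows)) ed <- ed[-drop_rows, , drop = FALSE]
  ed <- rbind(ed, do.call(rbind, cx_rows), dup)

  # small disconnected component of genes outside the TSS universe
  orph <- sprintf("orph%d", 1:4)
  oe <- data.frame(src_id = orph,
                   src_type = "gene_product",
                   dst_id = orph[c(2:4, 1)],
                   dst_type = "gene_product",
                   edge_class = "direct",
                   pathway_id = "pg_orph",
                   src_participants = ".",
                   dst_participants = ".",
                   stringsAsFactors = FALSE)
  ed <- rbind(ed, oe)
  ed <- ed[, c("pathway_id", "src_id", "src_type", "src_participants",
               "dst_id", "dst_type", "dst_participants", "edge_class")]
  rownames(ed) <- NULL

  classic <- list()
  if (config$n_classic_pathways > 0) {
    q <- pnorm(ground_truth$z_dnds)
    lo <- config$pathway_size_range[1]
    hi <- config$pathway_size_range[2]
    sizes <- sample(seq(lo, hi), config$n_classic_pathways, replace = TRUE)
    classic <- lapply(seq_len(config$n_classic_pathways), function(p) {
      u <- runif(1)
      w <- dnorm(q, u, config$pathway_clustering_sd) + 1e-9
      sort(sample(gid, sizes[p], prob = w))
    })
    names(classic) <- sprintf("cp%04d", seq_along(classic))
    if (config$n_classic_pathways >= 4) {
      classic[[2]] <- classic[[1]]                      # exact duplicate
      s3 <- classic[[3]]
      r <- max(1L, floor(0.1 * length(s3)))             # Jaccard ~ 0.82
      repl <- sample(setdiff(gid, s3), r)
      classic[[4]] <- sort(c(s3[seq_len(length(s3) - r)], repl))
    }
  }
  list(edges = ed, classic = classic)
}

#' Generate autosomal-dominant / autosomal-recessive gene labels
#'
#' Labels a subset of genes AD or AR such that AD genes are preferentially
#' sampled from conserved (low dN/dS latent), highly connected (high degree
#' latent) genes. The separation is an exponential tilt of +/- `effect/2`
#' SD on the standardized contrast (degree latent minus conservation
#' latent), so at `effect = 0` both groups are uniform draws. Labels are
#' drawn without replacement; no gene carries both.
#'
#' @inheritParams generate_genome
#' @param n_ad,n_ar numbers of AD and AR genes (defaults from the config).
#' @param effect latent location shift in SD units (default from config).
#' @return data frame with columns `gene_id`, `label` (`"AD"` or `"AR"`).
#' @export
generate_inheritance_labels <- function(config, ground_truth,
                                        n_ad = config$n_ad,
                                        n_ar = config$n_ar,
                                        effect = config$inheritance_effect) {
  set.seed(config$seed + 3L)
  n <- config$n_genes
  if (n_ad + n_ar > n) {
    stop("requested label counts exceed the number of genes", call. = FALSE)
  }
  cs <- ground_truth$z_degree - ground_truth$z_dnds
  cs <- (cs - mean(cs)) / sd(cs)
  ad <- sample(seq_len(n), n_ad, prob = exp((effect / 2) * cs))
  pool <- setdiff(seq_len(n), ad)
  ar <- sample(pool, n_ar, prob = exp(-(effect / 2) * cs[pool]))
  out <- data.frame(gene_id = ground_truth$gene_id[c(ad, ar)],
                    label = rep(c("AD", "AR"), c(n_ad, n_ar)),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Generate a complete synthetic study
#'
#' Runs all generator stages under the configuration's seed and returns the
#' in-memory dataset consumed by [run_pipeline()]. Use [write_dataset()] /
#' [read_dataset()] for the on-disk TSV/BED/GMT representation.
#'
#' @param config a [sim_config()].
#' @return an object of class `retro_dataset`: a list with `config`,
#'   `ground_truth`, `tss`, `manifest`, `hits`, `re`, `coverage`, `dnds`,
#'   `graph_edges`, `classic`, `inheritance`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 120, seed = 7))
#' @export
simulate_dataset <- function(config) {
  gt <- sim_ground_truth(config)
  gen <- generate_genome(config, gt)
  ip <- generate_interactome_pathways(config, gt)
  ds <- list(config = config,
             ground_truth = gt,
             tss = gen$tss,
             manifest = gen$manifest,
             hits = gen$hits,
             re = gen$re,
             coverage = gen$coverage,
             dnds = generate_dnds(config, gt),
             graph_edges = ip$edges,
             classic = ip$classic,
             inheritance = generate_inheritance_labels(config, gt))
  class(ds) <- "retro_dataset"
  ds
}

#' Write or read a synthetic study as plain-text files
#'
#' The on-disk layout mirrors the formats a real study would arrive in:
#' `tss.tsv`, `manifest.tsv`, `coverage.tsv`, `dnds.tsv`,
#' `inheritance.tsv`, `ground_truth.tsv` (TSV), one BED6 file per feature
#' profile under `tracks/`, `re.bed` (BED6), `pathway_graphs.tsv` (typed
#' edge list) and `classic.gmt`.
#'
#' @param ds a `retro_dataset` from [simulate_dataset()].
#' @param dir output (input) directory.
#' @return `write_dataset()`: `dir` invisibly; `read_dataset()`: a
#'   `retro_dataset` (without config/ground truth unless present on disk).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_tsv(ds$tss, file.path(dir, "tss.tsv"))
  write_tsv(ds$manifest, file.path(dir, "manifest.tsv"))
  write_tsv(ds$coverage, file.path(dir, "coverage.tsv"))
  write_tsv(ds$dnds, file.path(dir, "dnds.tsv"))
  write_tsv(ds$inheritance, file.path(dir, "inheritance.tsv"))
  write_tsv(ds$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_tsv(ds$graph_edges, file.path(dir, "pathway_graphs.tsv"))
  for (pid in ds$manifest$profile_id) {
    sub <- ds$hits[ds$hits$profile_id == pid, , drop = FALSE]
    write_bed6(sub, file.path(dir, "tracks", paste0(pid, ".bed")))
  }
  write_bed6(ds$re, file.path(dir, "re.bed"))
  write_gmt(ds$classic, file.path(dir, "classic.gmt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  hits <- do.call(rbind, lapply(manifest$profile_id, function(pid) {
    h <- read_bed6(file.path(dir, "tracks", paste0(pid, ".bed")))
    h$profile_id <- pid
    h
  }))
  gt_path <- file.path(dir, "ground_truth.tsv")
  ds <- list(config = NULL,
             ground_truth = if (file.exists(gt_path)) read_tsv(gt_path),
             tss = read_tsv(file.path(dir, "tss.tsv")),
             manifest = manifest,
             hits = hits,
             re = read_bed6(file.path(dir, "re.bed")),
             coverage = read_tsv(file.path(dir, "coverage.tsv")),
             dnds = read_tsv(file.path(dir, "dnds.tsv")),
             graph_edges = read_tsv(file.path(dir, "pathway_graphs.tsv")),
             classic = read_gmt(file.path(dir, "classic.gmt")),
             inheritance = read_tsv(file.path(dir, "inheritance.tsv")))
  class(ds) <- "retro_dataset"
  ds
}
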