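#' Configuration for the synthetic-data generator
#'
#' Defines the conditions under which a synthetic study is generated: the
#' number of genes and regulatory-feature profiles, the target Spearman
#' correlations among the three latent gene properties (structural rate
#' dN/dS, retroelement-linked fraction of regulatory hits, interactome
#' degree), marginal-distribution parameters, missingness, and the pathway
#' collection sizes.
#'
#' Rank correlations are induced through a Gaussian copula: each target
#' Spearman rho is converted to the latent Pearson correlation
#' `2*sin(pi*rho/6)` and the three-variable latent correlation matrix must
#' be positive semi-definite, otherwise the configuration is rejected.
#'
#' @param n_genes number of simulated genes.
#' @param n_profiles_per_category number of feature profiles per biomarker
#'   category (active chromatin, inactive chromatin, TFBS).
#' @param rho_dnds_connectivity,rho_dnds_ngre,rho_ngre_connectivity target
#'   Spearman correlations in `[-1, 1]` among dN/dS, the per-gene RE-linked
#'   fraction (which drives NGRE), and total interactome degree.
#' @param hit_count_dispersion overdispersion of the per-gene window hit
#'   counts; counts are negative binomial with `size = 1/hit_count_dispersion`
#'   (larger values give more overdispersion).
#' @param re_fraction_concentration concentration of the Beta distribution of
#'   the per-gene RE-linked fraction.
#' @param re_fraction_mean mean of that Beta distribution.
#' @param mean_hits expected total hits per gene window per profile.
#' @param mean_degree expected total interactome degree per gene.
#' @param degree_dispersion negative-binomial size of the (heavy-tailed)
#'   target-degree distribution; smaller is heavier-tailed.
#' @param missing_rate fraction in `[0, 1)` of gene-by-profile cells that are
#'   not assayed (no-data, as opposed to an observed zero).
#' @param n_classic_pathways number of curated-style gene sets to emit.
#' @param pathway_size_range integer pair, inclusive size range of classic
#'   pathways; the lower bound must be at least 2.
#' @param assortativity_sd per-stub noise (in latent SD units) used when
#'   pairing interaction stubs; smaller values make genes with similar
#'   conservation latents more likely to interact.
#' @param pathway_clustering_sd width (on the latent quantile scale) of the
#'   membership window of classic pathways; smaller values group genes with
#'   more similar conservation latents.
#' @param n_ad,n_ar default numbers of autosomal-dominant and
#'   autosomal-recessive labels drawn by [generate_inheritance_labels()];
#'   `NULL` scales the reference counts 543 AD / 894 AR (out of 4505
#'   analyzed genes) to `n_genes`.
#' @param inheritance_effect default latent location shift (in SD units)
#'   separating AD from AR genes.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' @export
sim_config <- function(n_genes = 2000,
                       n_profiles_per_category = 3,
                       rho_dnds_connectivity = -0.11,
                       rho_dnds_ngre = 0.12,
                       rho_ngre_connectivity = 0,
                       hit_count_dispersion = 0.5,
                       re_fraction_concentration = 10,
                       re_fraction_mean = 0.3,
                       mean_hits = 20,
                       mean_degree = 10,
                       degree_dispersion = 0.7,
                       missing_rate = 0.1,
                       n_classic_pathways = 150,
                       pathway_size_range = c(10L, 40L),
                       assortativity_sd = 1,
                       pathway_clustering_sd = 0.12,
                       n_ad = NULL,
                       n_ar = NULL,
                       inheritance_effect = 0.8,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_profiles_per_category = as.integer(n_profiles_per_category),
              rho_dnds_connectivity = rho_dnds_connectivity,
              rho_dnds_ngre = rho_dnds_ngre,
              rho_ngre_connectivity = rho_ngre_connectivity,
              hit_count_dispersion = hit_count_dispersion,
              re_fraction_concentration = re_fraction_concentration,
              re_fraction_mean = re_fraction_mean,
              mean_hits = mean_hits,
              mean_degree = mean_degree,
              degree_dispersion = degree_dispersion,
              missing_rate = missing_rate,
              n_classic_pathways = as.integer(n_classic_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              assortativity_sd = assortativity_sd,
              pathway_clustering_sd = pathway_clustering_sd,
              n_ad = if (is.null(n_ad)) {
                max(2L, as.integer(round(n_genes * 543 / 4505)))
              } else as.integer(n_ad),
              n_ar = if (is.null(n_ar)) {
                max(2L, as.integer(round(n_genes * 894 / 4505)))
              } else as.integer(n_ar),
              inheritance_effect = inheritance_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 10,
            cfg$n_profiles_per_category >= 1,
            cfg$hit_count_dispersion > 0,
            cfg$re_fraction_concentration > 0,
            cfg$re_fraction_mean > 0, cfg$re_fraction_mean < 1,
            cfg$mean_hits > 0, cfg$mean_degree > 2,
            cfg$degree_dispersion > 0,
            cfg$n_classic_pathways >= 0,
            length(cfg$pathway_size_range) == 2)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("configuration error: missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$pathway_size_range[1] < 2) {
    stop("configuration error: pathway_size_range lower bound must be >= 2",
         call. = FALSE)
  }
  rhos <- c(cfg$rho_dnds_connectivity, cfg$rho_dnds_ngre,
            cfg$rho_ngre_connectivity)
  if (any(abs(rhos) > 1)) {
    stop("configuration error: rho targets must lie in [-1, 1]", call. = FALSE)
  }
  R <- latent_correlation_matrix(cfg)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(paste0(
      "configuration error: rank-correlation targets ",
      "(rho_dnds_connectivity = %g, rho_dnds_ngre = %g, ",
      "rho_ngre_connectivity = %g) do not form a positive semi-definite ",
      "correlation matrix"),
      cfg$rho_dnds_connectivity, cfg$rho_dnds_ngre,
      cfg$rho_ngre_connectivity), call. = FALSE)
  }
  invisible(cfg)
}

# Spearman target -> Pearson correlation of the Gaussian latents.
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# Latent correlation matrix in the variable order (dN/dS, RE fraction, degree).
latent_correlation_matrix <- function(cfg) {
  r12 <- spearman_to_pearson(cfg$rho_dnds_ngre)
  r13 <- spearman_to_pearson(cfg$rho_dnds_connectivity)
  r23 <- spearman_to_pearson(cfg$rho_ngre_connectivity)
  matrix(c(1, r12, r13,
           r12, 1, r23,
           r13, r23, 1), 3, 3)
}
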