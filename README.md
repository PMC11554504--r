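# retronet

Do highly connected proteins evolve more slowly — and does the answer
differ between *structural* evolution (amino-acid change, measured by
dN/dS) and *regulatory* evolution (turnover of the regulatory landscape
around the gene, measured by retroelement-linked enrichment of regulatory
features)? `retronet` implements, as a tested and reusable R pipeline, the
full analysis that links the connectivity of protein-coding genes in a
directed interactome model to both metrics, at gene and molecular-pathway
level. It is aimed at computational biologists studying the interplay of
network topology and molecular evolution.

## The metrics

For one regulatory-feature profile (a histone mark or transcription
factor in one cell line), with `FES_x` the number of retroelement-linked
feature hits in the 10-kb window centered at gene *x*'s TSS and `TFS_x`
the total number of hits there:

```
GRE_x  = FES_x / mean(FES)          # RE-linked enrichment
GFE_x  = TFS_x / mean(TFS)          # overall feature enrichment
NGRE_x = GRE_x / GFE_x              # RE-linked proportion vs genome average
```

NGRE is aggregated across profiles per biomarker category (active
chromatin, heterochromatin, TFBS, all) by a weighted mean with profile
weights `w_i = (1 - z_i)^3`, where `z_i` is the proportion of zero or
missing values in profile *i* (the alternative literal reading
`1 - z_i^3` is one switch away). Pathway-level analogues are means over
member genes: NPII for regulatory evolution, `dnds_pw` for structural
evolution, and summed whole-interactome degree per member with data for
connectivity. Connectivity itself is in-degree plus out-degree of a
gene's node, counted over direct protein-protein edges (`ppi_degree`) or
over all edges including metabolites and auxiliary reaction/transport
nodes (`total_degree`). All pairwise associations are Spearman rank
correlations; autosomal-dominant versus autosomal-recessive gene groups
are compared with Wilcoxon rank-sum tests.

Because the original study's inputs are unpublished precomputed datasets,
the package also ships a synthetic-data generator (`simulate_dataset()`)
that emulates every input — TSS table, per-profile BED feature tracks, RE
annotation, dN/dS table, typed pathway-graph collection, classic gene
sets in GMT, inheritance labels — with a Gaussian-copula latent structure
whose pairwise Spearman targets are set in `sim_config()`.

## A worked example

```r
library(retronet)

ds  <- simulate_dataset(sim_config(n_genes = 1000, seed = 7))
res <- run_pipeline(ds)

subset(res$grid, x_metric %in% c("total_degree", "dnds") &
                 y_metric %in% c("dnds", "ngre_agg"))
#>    level     x_metric y_metric      rho  p_value   n
#> 9   gene total_degree ngre_agg  0.00153 9.62e-01 983
#> 10  gene total_degree     dnds -0.14964 2.45e-06 983
#> 14  gene         dnds ngre_agg  0.13290 2.92e-05 983

res$inheritance
#>       metric statistic  p_value median_ad median_ar n_ad n_ar
#> 1       dnds      7117 1.87e-08     0.204     0.314  116  198
#> 2 ppi_degree     15043 4.07e-06     9.000     5.000  116  198
#> 3   combined      6359 4.12e-11    -0.269     0.127  116  198
```

Reading the output: connectivity is uncorrelated with the regulatory rate
(`ngre_agg`, rho ≈ 0.002) but negatively correlated with the structural
rate (`dnds`, rho ≈ −0.15): hubs are structurally conserved. The two
evolution metrics themselves correlate weakly (0.13). In the inheritance
table, autosomal-dominant genes are more conserved (median dN/dS 0.20 vs
0.31) and more connected (median 9 vs 5 direct interactions) than
autosomal-recessive ones, and the combined rank score separates the groups
more sharply than either metric alone. Of the 1,000 simulated genes, 983
survive the data intersection and outlier fence; `res$pathway_metrics`
holds the corresponding pathway-level table for the 538 retained pathways,
and `res$filter_audit` records why every other pathway was removed.

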