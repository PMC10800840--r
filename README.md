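# ecoassembly

Community-assembly inference for microbial ecology, in a tidyverse-native R
package. Given a sample × taxon abundance table, a rooted phylogeny, and
sample metadata (habitat group, coordinates, environmental variables),
`ecoassembly` quantifies *how* a community was assembled: how much of its
structure reflects deterministic selection by the environment, and how much
reflects the stochastic processes of dispersal and ecological drift. It was
built for marker-gene (ASV) surveys of microbial communities — the motivating
setting is fungal communities sampled across an estuarine water column and
its sediments — but applies to any community table with a phylogeny.

## What it computes

**Phylogenetic null models.** The beta mean nearest taxon distance between
samples k and l,

    βMNTD(k,l) = ½ [ Σᵢ f_ik · minⱼ d_ij + Σⱼ f_jl · minᵢ d_ij ],

weights each taxon's distance to its closest relative in the other community
by its relative abundance. Standardizing the observed βMNTD against a
taxa-shuffle null (tip labels permuted across the whole tree) gives the beta
nearest taxon index, βNTI = (obs − mean_null)/sd_null. |βNTI| ≥ 2 signals
deterministic selection (βNTI < −2 homogeneous, > +2 variable selection).

**Raup–Crick (Bray–Curtis).** For |βNTI| < 2, pairs are further classified
with RC_bray, which compares the observed Bray–Curtis dissimilarity with a
probabilistic-assembly null (null samples draw their observed richness with
probability ∝ occurrence frequency and fill reads ∝ pooled abundance):
RC < −0.95 → homogenizing dispersal, RC > +0.95 → dispersal limitation,
otherwise drift. Together these yield the five-process classification with
per-group and pooled percentages.

**Sloan neutral community model.** Occurrence frequency is predicted from
mean relative abundance p via F(p) = 1 − B(d; Nmp, Nm(1−p)); the migration
rate m is fit by least squares, and Nm (= metacommunity size × migration)
and R² are reported with a 95% prediction band and per-taxon above / within
/ below flags.

**pNST.** The phylogenetic normalized stochasticity ratio compares observed
βMNTD with its taxa-shuffle null expectation and rescales to [0, 1]; group
means above 0.5 are conventionally read as stochasticity-dominated assembly.

**Supporting stages.** Alpha diversity (richness, Chao1, ACE, Shannon,
Simpson, Pielou); Bray–Curtis / Jaccard / Euclidean / Manhattan distances;
UPGMA clustering; beta-diversity partitioning into replacement and
richness-difference components (Baselga–Sørensen and Podani–Jaccard
families); db-RDA / CPCoA with VIF screening, Spearman correlation tables
with BH correction, and LMG relative-importance decomposition;
distance–decay regression on haversine distances; and FDR-filtered Spearman
co-occurrence networks with Louvain modules, topology metrics, and Zi–Pi
keystone-taxon calling (keystone ⇔ Zi ≥ 2.5 and/or Pi ≥ 0.62).

**Synthetic communities with known regimes.** `simulate_neutral()`,
`simulate_selection()`, and `simulate_distance_decay()` generate count
tables under Sloan neutral sampling, Gaussian environmental selection with
phylogenetically conserved niches, and distance-dependent metacommunity
mixing; `simulate_estuary_survey()` assembles a full 21-station × 4-habitat
survey. Every inference stage is tested by recovering the generating regime.

## Worked example

```r
library(ecoassembly)

fx <- simulate_estuary_survey(seed = 1, n_taxa = 300, reads_per_sample = 1000)

# neutral-model fit for the surface habitat
surface <- fx$metadata$sample_id[fx$metadata$group == "surface"]
fit <- fit_ncm(as_community(comm_matrix(fx$community)[surface, ]),
               detection_limit = "multinomial")
fit
#> Sloan NCM fit: m = 0.0981, Nm = 98.1, R^2 = 0.874 (261 taxa, 21 samples)
#>
#>  above  below within
#>      9      8    244

# five-process classification across all 84 samples
z   <- bnti(fx$community, fx$tree, n_null = 199, seed = 1)
rc  <- raup_crick_bray(fx$community, n_null = 199, seed = 2)
cls <- classify_processes(z, rc, process_thresholds(), fx$metadata)
dplyr::filter(cls$fractions, group %in% c("pooled", "sediment"))
#> # A tibble: 10 x 4
#>    group    process                n_pairs percent
#>    <chr>    <chr>                    <int>   <dbl>
#>  1 pooled   homogeneous_selection       65    1.86
#>  2 pooled   variable_selection          46    1.32
#>  3 pooled   homogenizing_dispersal       0    0
#>  4 pooled   dispersal_limitation      1456   41.8
#>  5 pooled   drift                     1919   55.0
#>  6 sediment homogeneous_selection        5    2.38
#>  7 sediment variable_selection           3    1.43
#>  8 sediment homogenizing_dispersal       0    0
#>  9 sediment dispersal_limitation       175   83.3
#> 10 sediment drift                       27    12.9
```

The water-column habitats, generated under low migration, are dominated by
drift (55% of pooled pairs, with selection under 4%); the sediment habitat,
whose cooperative guild structure adds compositional variance the
Raup-Crick null cannot absorb, is read as dispersal-process-dominated, and
its guild-planted co-occurrence network is the dense one. `autoplot(fit)`, `autoplot(cls)`, and `plot_zi_pi()` draw the
standard figures; `tidy()` / `glance()` give tabular views of every fitted
object. `run_pipeline(run_config(...))` drives all stages end to end and
writes TSVs plus a manifest with seeds and checksums.

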