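# magdyn

Functional dynamics of genome-resolved gut microbiomes.

`magdyn` analyses longitudinal metagenomic studies in which the microbial
community of each host individual is resolved into metagenome-assembled
genomes (MAGs) and followed across a series of environmental disturbances
(e.g. heat exposure, cold exposure, a dietary shift). It answers the
questions such studies pose: how functionally capable and redundant is each
community, how much does it turn over between disturbances, and do the
disturbances drive *directional* (shared across individuals) rather than
stochastic change in composition and in community-level metabolic capacity.

The package covers the full downstream pipeline:

- **Genome quality and normalization** — completeness/contamination
  filtering (defaults: keep completeness ≥ 70%, contamination < 10%) and
  conversion of read counts to genome-length-corrected reads per million or
  relative abundances.
- **Functional distillation** — per-genome gene annotations are scored
  against a pathway database into genome-inferred functional traits
  (GIFTs). A pathway's score is the mean over its steps of the best
  alternative identifier combination's fraction-present (so a two-identifier
  step scores 1, 0.5 or 0), adjusted for genome completeness and averaged
  within function categories into metabolic capacity indices (MCIs) on
  [0, 1].
- **Hill-number diversity partitioning** at order *q* = 1: neutral
  (`exp` of Shannon entropy), phylogenetic (abundance-weighted effective
  lineages, `exp(-Σ_b (L_b/T) a_b ln a_b)`), and functional
  (attribute diversity on a Gower trait distance matrix,
  `exp(-½ Σ_ij (d_ij/Q) p_i p_j ln(p_i p_j))` with Rao
  `Q = Σ_ij d_ij p_i p_j`). Beta diversities are reported as Sørensen-type
  turnover, `(β−1)/(N−1)` (neutral/phylogenetic) or `(β−1)/(N²−1)`
  (functional), in [0, 1].
- **Functional redundancy** — uniqueness `U* = Q/D` (Rao over Gini-Simpson)
  and redundancy `R* = 1 − U*`.
- **Directional treatment effects** — single-factor PERMANOVA on turnover
  dissimilarities with permutations restricted to within-individual strata,
  reporting the unadjusted R²; canonical analysis of principal coordinates
  (CAP) with leave-one-out selection of the number of retained axes.
- **Functional trajectories** — community-weighted mean (CWM) capacity per
  function and treatment, with individual-level percentile bootstrap
  intervals; non-overlapping consecutive intervals flag capacity shifts.
- **Synthetic studies** — `generate_study()` simulates a complete
  two-species experiment (counts, metadata, tree, annotations, pathway
  database) with known ground truth: a high-diversity stable archetype and
  a low-diversity archetype carrying a directional responder genome.

All user-facing functions take and return tibbles, so stages chain with the
pipe; PERMANOVA and CAP fits have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` companions.

## Worked example

```r
library(magdyn)

bundle <- generate_study(synthetic_config(seed = 42))
res <- run_study(bundle, n_perm = 999, n_boot = 2000, seed = 43)

res$permanova
#> # A tibble: 6 × 7
#>   species component    pseudo_f r_squared p_value n_permutations n_samples
#>   <chr>   <chr>           <dbl>     <dbl>   <dbl>          <dbl>     <int>
#> 1 spA     neutral        0.169    0.0189    0.211            999        40
#> 2 spA     phylogenetic   0.0576   0.00654   0.594            999        40
#> 3 spA     functional     0.176    0.0197    0.173            999        40
#> 4 spB     neutral       33.0      0.791     0.001            999        40
#> 5 spB     phylogenetic  72.5      0.892     0.001            999        40
#> 6 spB     functional    38.0      0.813     0.001            999        40
```

Treatment explains a large share of compositional variance in the
low-diversity species (spB, R² ≈ 0.79–0.89 with the minimal permutation
p-value) and essentially none in the high-diversity species (spA,
R² ≤ 0.02): the disturbances move spB's community directionally while spA
drifts. The same contrast shows in the turnover between consecutive
treatments and in functional redundancy:

```r
res$turnover |>
  dplyr::filter(kind == "consecutive") |>
  dplyr::group_by(species, component) |>
  dplyr::summarise(mean_turnover = mean(turnover), .groups = "drop")
#>   species component    mean_turnover
#> 1 spA     functional          0.0229
#> 2 spA     neutral             0.0338
#> 3 spA     phylogenetic        0.0100
#> 4 spB     functional          0.174
#> 5 spB     neutral             0.203
#> 6 spB     phylogenetic        0.144

res$redundancy |>
  dplyr::group_by(species) |>
  dplyr::summarise(mean_rstar = mean(rstar))
#>   species mean_rstar
#> 1 spA          0.800
#> 2 spB          0.617
```

Shift detection recovers the generator's injected Heat→Cold collapse of the
responder genome — every injected function (F01–F04) drops, and the
surrounding community's capacities rebalance in response:

```r
dplyr::filter(res$shifts, shift, species == "spB", from == "Heat")
#>    species function_id from  to    shift direction
#>  1 spB     F01         Heat  Cold  TRUE         -1
#>  2 spB     F02         Heat  Cold  TRUE         -1
#>  3 spB     F03         Heat  Cold  TRUE         -1
#>  4 spB     F04         Heat  Cold  TRUE         -1
#>  ...
```

Individual fits print like any model object:

```r
res$permanova_fits[["spB.neutral"]]
#> PERMANOVA (strata-restricted permutations)
#>   pseudo-F = 33.0204 on (4, 35) df
#>   unadjusted R2 = 0.7905
#>   p = 0.001 (999 permutations)
```

`plot_alpha_diversity(res$alpha)`, `plot_turnover(res$turnover)`,
`plot_cwm_trajectories(res$trajectories)`,
`plot_redundancy_diversity(res$redundancy_relation$spB)` and
`autoplot(res$cap[["spB.neutral"]])` draw the standard figures.

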