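---
title: "Models and methods behind magdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`magdyn` implements the downstream analysis of longitudinal, genome-resolved
gut-microbiome experiments: host individuals, nested in cages within
species, are exposed to a series of environmental disturbances and sampled
once at the end of each; their communities are resolved into
metagenome-assembled genomes (MAGs) with read counts, genome-quality
estimates, gene annotations and a phylogeny. This vignette is the package's
own account of the models it fits, the estimators it uses, the choices made
where the design was genuinely open, and what the synthetic validation does
and does not demonstrate.

## From annotations to functional capacity

A pathway definition is an ordered list of steps; each step lists one or
more alternative identifier combinations; each combination is a set of gene
identifiers that are all required. For a genome with gene set $G$,

* a combination $c$ scores $|c \cap G| / |c|$,
* a step scores the **maximum** over its alternatives,
* the pathway's genome-inferred functional trait (GIFT) is the arithmetic
  **mean** over steps.

For a single two-identifier combination this reduces to the familiar
complete / half-complete / empty rule (1, 0.5, 0). The generalization to
fraction-present within a combination is the package's choice: it is the
unique linear extension of that rule, and `score_gift()` is tested for
exact agreement with an exhaustive scorer that enumerates every choice of
one alternative per step without the per-step maximum shortcut.

**Completeness adjustment.** An assembly that recovered a fraction $k$ of a
genome loses annotated genes roughly uniformly at random, so the observed
GIFT underestimates the true one by a factor close to $k$. We use
$\min(1, \text{GIFT}/k)$: under uniformly random gene loss the division is
an unbiased correction of the step scores, and the cap respects the scale
maximum. The adjustment is the identity at $k = 1$ and never lowers a
score. Published distillation tools apply a completeness adjustment whose
exact form is not stated with the scoring rule; the division-with-cap rule
is this package's explicit, documented choice.

GIFTs are averaged within function categories (14 by default, configurable)
into metabolic capacity indices (MCIs) in $[0,1]$ — `distill_mci()`. The
pathway→function mapping is many-to-one; a deeper pathway→trait→function
hierarchy collapses to the same averaging and is not modelled separately.

## Hill-number diversity partitioning

All diversities are Hill numbers at order $q = 1$ by default — the order
that weighs MAGs exactly by their relative abundances — with the $q \to 1$
limit taken analytically, never numerically. Other orders are available
through the `q` argument.

* **Neutral:** $^1D = \exp(-\sum_i p_i \ln p_i)$.
* **Phylogenetic:** for branch $b$ with length $L_b$ and descendant-tip
  abundance $a_b$, and $T = \sum_b L_b a_b$ the abundance-weighted mean
  depth, $^1\bar D(T) = \exp(-\sum_b (L_b/T)\, a_b \ln a_b)$ — the
  effective number of equally distinct lineages. On a star tree with equal
  branch lengths this equals the neutral value exactly (a tested identity).
  Because reference implementations differ in whether they normalize by
  $T$, `hill_phylo(..., normalized = FALSE)` also exposes the
  un-normalized effective total branch length $T \cdot {}^1\bar D(T)$.
* **Functional:** on a Gower distance matrix $d$ over MCI traits (range
  normalized, constant traits excluded), with Rao
  $Q = \sum_{ij} d_{ij} p_i p_j$, the attribute diversity
  $^1D(Q) = \exp(-\tfrac12 \sum_{ij} (d_{ij}/Q)\, p_i p_j \ln(p_i p_j))$,
  the effective number of equally abundant, equally distinct MAGs.

**Beta and turnover.** For $N$ equally weighted samples, gamma is the
diversity of the pooled mean community and alpha the Hill-framework
within-sample average (exponential of the mean Shannon entropy at $q = 1$
for the neutral and phylogenetic components; the effective-pair
attribute-diversity alpha for the functional component, computed with the
pooled $Q$). Beta $= \gamma/\alpha$ ranges over $[1, N]$ for neutral and
phylogenetic diversity and over $[1, N^2]$ for the functional component,
whose gamma and alpha count effective *pairs*. Sørensen-type turnover
rescales beta onto $[0,1]$:

$$\text{turnover} = \frac{\beta - 1}{N - 1} \quad\text{or}\quad
  \frac{\beta - 1}{N^2 - 1} \;(\text{functional}),$$

0 for identical communities and 1 at complete turnover. The $N^2 - 1$
normalization for the functional component is deliberate and worth
flagging: the functional beta genuinely ranges to $N^2$ in this framework,
and normalizing by $N - 1$ would overstate functional turnover; both the
package default and this rationale are stated here because published
analyses rarely say which normalization their software used.

Within-individual variability is summarized two ways: turnover between
consecutive time points, and an *overall* value. The overall value defaults
to the turnover of the single $N$-sample partition over all of the
individual's time points (one partition, one number); the mean of all
pairwise turnovers is reported alongside (`kind = "pairwise_mean"`) since
either convention appears in practice.

Zero-abundance MAGs are dropped per computation, never globally, so sample
supports may differ. All-zero samples are excluded from diversity
computations with a warning, not an error.

## Functional redundancy

Uniqueness is the plain ratio $U^* = Q/D$ of Rao quadratic entropy to the
Gini-Simpson index $D = 1 - \sum_i p_i^2$, and redundancy
$R^* = 1 - U^*$. With Gower distances bounded in $[0,1]$ the ratio is
bounded; the implementation clips only floating-point overshoot (tolerance
$10^{-8}$) and raises an assertion if $Q > D$ genuinely occurs, which would
indicate an invalid distance matrix. Variants of "star" uniqueness in the
literature differ subtly (e.g. abundance-reweighted forms); the plain ratio
is the definition implemented here. Single-MAG communities have $D = 0$:
they are returned flagged `defined = FALSE` rather than dropped silently.
`redundancy_diversity_relation()` pairs $\log {}^1D$ with $R^*$ per sample
and reports Pearson and Spearman correlations with seeded permutation
p-values (999 permutations by default).

## Directional treatment effects

**PERMANOVA.** A single-factor partition of the squared dissimilarities:
$SS_\text{total} = \sum_{i<j} d^2_{ij}/N$,
$SS_\text{within} = \sum_g \sum_{i<j \in g} d^2_{ij}/n_g$, pseudo-$F$ from
the usual mean squares, and the **unadjusted**
$R^2 = SS_\text{among}/SS_\text{total}$ as the effect-size measure. The
permutation scheme honours the repeated-measures design: treatment labels
are freely permuted *within each individual's sample set* (strata), sampled
with replacement from the within-block permutation group, with the observed
labelling always included in the reference set, so
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_\text{perm}) \ge 1/(n_\text{perm}+1)$.
With a single stratum this reduces exactly to free permutation (tested).
Blocks with one sample contribute no permutation. Only the single-term
model is implemented — the designs this package targets have one treatment
factor plus strata — and `vegan::adonis2` serves as an independent
cross-check in the test suite, never as the implementation.

Turnover dissimilarities are not Euclidean-embeddable in general, so the
Gower-centered matrix can carry small negative eigenvalues. PERMANOVA uses
the raw sums (negative contributions cancel in the trace identities), which
means the among-group sum of squares — and hence $R^2$ — can dip
microscopically below zero under the null; values are reported unclipped
rather than masked.

**CAP.** Principal coordinates of the centered dissimilarity matrix (axes
with negative eigenvalues are excluded with a warning, not corrected),
followed by canonical discriminant analysis of group membership on the
first $m$ coordinates. When $m$ is not supplied it is chosen to maximize
leave-one-out allocation success, ties resolved to the smallest $m$; the
number of canonical axes is at most (groups − 1).

## Community-weighted mean trajectories

Rare MAGs carry too little information for trajectory estimation, so MAGs
are kept only if they reach 0.1% relative abundance in at least one sample
(threshold configurable; rows re-closed after filtering). The
community-weighted mean capacity for function $f$ in a sample with
abundances $p$ is $\text{CWM}_f = \sum_i p_i\,\text{MCI}(i,f)$.

The reference analyses for this kind of design obtain posterior credible
intervals for CWM trajectories from a hierarchical Bayesian joint species
distribution model. `magdyn` estimates the same quantity — the mean CWM per
treatment — with a deliberately lighter inferential engine: a percentile
bootstrap that resamples **individuals** (not samples) with replacement,
honouring the nesting that the random-intercept structure
(cage/individual) induces; cage-level resampling is not offered because
with the small cage counts typical of these designs it is too coarse to
calibrate. Intervals default to 90%, and the decision rule transfers
unchanged: non-overlapping intervals for consecutive treatments are strong
evidence of a capacity shift (`detect_shifts()`, which also reports the
direction of the mean difference). Treatments observed in a single
individual yield a point estimate with an undefined interval, and such
pairs are skipped with a warning.

## The synthetic study generator

`generate_study()` simulates the complete data bundle for a two-species
experiment with known ground truth. What it emulates:

* **Two archetypes.** Species A: 60 MAGs, log-abundance dispersion 1.0,
  pathway-block sharing probability (redundancy level) 0.7 — a diverse,
  redundant, stable community. Species B: 15 MAGs, dispersion 1.5,
  redundancy level 0.15 — a small, uneven, functionally unique community.
  The 60/15 richness contrast is a desk-scale rendition of the order-of-
  magnitude contrast (hundreds vs dozens of MAGs) seen in real two-species
  comparisons; it preserves the diversity ordering while keeping test
  runtimes in seconds.
* **Nested design.** 8 individuals per species in 3 cages, sampled at five
  time points under the treatment sequence Acclimation, Heat, Cold, Diet,
  Acclimation2 (a return to baseline). Cage and individual random
  intercepts (log-scale SDs 0.3 and 0.5) and residual noise (SD 0.3).
* **A directional responder.** One randomly chosen species-B MAG receives
  multiplicative latent-abundance effects ×1, ×6, ×0.05, ×4, ×1 across the
  five treatments and a +1 baseline log-abundance boost. The effects are
  deliberately strong so that the directional signature is unambiguous at
  desk scale. The genes of the first four function categories are
  concentrated in the responder (added to it, stripped from the other
  species-B MAGs), so its Cold collapse must drag the community-weighted
  capacity of those functions down — the generator's recorded ground truth.
  Species A instead receives small per-individual, per-treatment log
  effects (SD 0.2) with no shared direction: plasticity without
  directionality.
* **Phylogenetically autocorrelated gene content.** Gene presence evolves
  along a Yule tree (exponential branch lengths) under a symmetric
  two-state Markov process with rate `1/signal` (default signal 5), so
  clades share gene blocks; completeness is drawn uniform on [0.7, 1] and
  observed gene sets are true sets thinned at rate (1 − completeness).
* **Compositional sampling.** Latent log abundances are exponentiated,
  closed to proportions and sampled multinomially at depths uniform on
  [20 000, 100 000] — the standard log-normal + multinomial compromise.
  Treatment effects are multiplicative on the latent scale, so
  relative-abundance directionality is depth-invariant.

What it does **not** emulate: zero-inflation beyond sampling zeros (the
analyses under test are abundance-weighted, $q = 1$, and insensitive to
rare-taxon handling), strain-level variation, assembly and binning
artefacts, real pathway databases, or uneven/missing sampling. Passing the
validation suite therefore demonstrates that the estimators recover the
truth under the stated statistical structure — not that they are robust to
every pathology of real sequencing data.

The generator is fully deterministic: a config (including its seed) maps to
a byte-identical bundle, with per-stage child seeds so stages can be rerun
in isolation.

## Numerical choices and degenerate inputs

* $q \to 1$ limits computed analytically; simplex sums checked to
  $10^{-9}$; the exp(Shannon) identity is tested to $10^{-12}$.
* Eigenvalue positivity threshold in CAP: $10^{-8}$ relative to the largest
  magnitude.
* Ties in the CAP axis search resolve to the smallest $m$.
* All-zero samples: retained in tables, excluded from diversity with a
  warning. Constant traits: excluded from Gower; all-constant trait tables
  are an error. Functionally uniform communities ($Q = 0$): an error for
  the functional Hill number (undefined), $U^* = 0$ for redundancy.
* Completeness and contamination are stored as fractions; readers convert
  percentage-scaled columns automatically.
* Quality filtering precedes normalization in `run_study()`; both
  operations are exposed separately, so the opposite order is a two-line
  change if a study requires it.

## Validation problem sizes

The shipped validation suite runs, per check: 100 random draws for each
analytic identity; 100 genomes × 20 pathways for the exhaustive-scorer
equivalence; 500 null simulations × 199 permutations (40 samples, 10
individuals) for PERMANOVA type-I error, plus 150 generator-null
replicates; 500 replicates of 25 independently caged individuals — chosen
to match the 22–29 individuals per species of the motivating study design —
with 2000 bootstrap draws for CWM interval coverage; and 10 independent
seeds of the full two-archetype study for ground-truth recovery. These
sizes make the whole suite run in a few minutes on one CPU while keeping
the binomial envelopes tight enough to be informative.

## Known limitations

* Single-factor PERMANOVA only; no multi-factor or marginal-SS designs, no
  dispersion test.
* The bootstrap interval is frequentist; it matches the posterior-interval
  decision rule in spirit, not in posterior probability semantics.
* Gower distances treat all MCI columns as quantitative and equally
  weighted.
* The phylogenetic Hill number assumes a rooted tree with branch lengths;
  unrooted or unlengthed trees are rejected, not guessed at.
* Linear mixed-model contrasts of alpha/beta diversity between species
  (standard off-the-shelf fits) are left to `nlme`/`lme4` on the tidy
  tables this package outputs.
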