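---
title: "Methods: differential co-expression network analysis with dcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression network analysis with dcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

# The problem

Differential expression analysis asks which genes change in *level*
between two states (say, normal and cancer tissue). Differential
co-expression analysis asks a complementary question: which gene *pairs*
change in their correlation structure — pairs tightly co-expressed in one
state and decoupled in the other. Such rewiring can expose disrupted
regulatory relationships that per-gene statistics never see, because a
gene's mean can stay flat while its partners change.

`dcnet` implements an integrated strategy for two-condition expression
matrices (log2 intensities, a genes × samples table plus a sample → state
design):

1. **DEG screening** with a SAM-type moderated statistic and balanced
   label permutations;
2. **per-condition co-expression networks** by hard-thresholding Pearson
   correlations computed on each condition's samples separately;
3. **differential links**: gene pairs weakly correlated in the normal
   state but strongly correlated in the cancer state, tested by a
   label-permutation test on the Fisher-z correlation difference;
4. **hub genes** of the resulting differential subnetwork, ranked by
   degree;
5. **module detection** by average-linkage clustering of the
   (generalized) topological overlap dissimilarity.

Everything is exercised end-to-end on synthetic data with planted ground
truth, so each stage's operating characteristics are measured rather than
assumed.

# The SAM screening statistic

For gene $i$ with group means $\bar{x}_I(i)$ (cancer) and $\bar{x}_U(i)$
(normal), the relative difference is

$$d(i) = \frac{\bar{x}_I(i) - \bar{x}_U(i)}{s(i) + s_0},$$

where the gene-specific scatter

$$s(i) = \sqrt{a \left( \sum_m [x_m(i)-\bar{x}_I(i)]^2 +
                         \sum_n [x_n(i)-\bar{x}_U(i)]^2 \right)},
\qquad a = \frac{1/n_1 + 1/n_2}{n_1 + n_2 - 2}$$

is the standard error of the mean difference based on the pooled
within-group standard deviation. With $s_0 = 0$, $d(i)$ *is* the
equal-variance two-sample t statistic; the test suite verifies this
identity numerically to $10^{-10}$. We use the square-root form
throughout because $s(i)$ is a standard deviation and $d(i)$ must be
dimensionless.

The fudge factor $s_0 > 0$ prevents genes with tiny scatter from
dominating the ranking. Its selection is the classic SAM convention:
candidate values are the percentiles $\{0, 0.05, \dots, 1\}$ of the
$s(i)$ distribution; for each, genes are windowed by $s$-quantile and the
median absolute deviation of $d$ is computed per window; the percentile
minimizing the coefficient of variation of these MADs is chosen. The
procedure is deterministic, and a fixed $s_0$ (including 0) can be
supplied instead.

## Balanced permutations and the calling rule

The null reference is built from *balanced* label permutations: sample
relabelings that preserve the group sizes $(n_1, n_2)$ and place within
0.5 of $n_1/2$ of the original cancer samples into the pseudo-cancer
group, so every pseudo-group mixes the two true states as evenly as the
sizes allow (the "within 0.5" form extends the rule to odd group sizes).
When the balanced set is small it is enumerated exactly and subsampled
without replacement; otherwise distinct balanced relabelings are drawn
uniformly under a fixed seed. For each permutation $p$ the statistics
$d_p$ are sorted in decreasing order, and the expected relative
difference $d_E(i)$ is the mean of the $i$-th largest values across
permutations.

Calling is the asymmetric displacement scan: ranks whose observed sorted
$d$ exceeds $d_E$ by more than $\Delta$ define the *up* cutoff (the
smallest such observed $d$; every gene at or above it is called up), and
symmetrically for *down*. The two cutoffs are independent, so induced and
repressed genes face different thresholds — the behaviour that
distinguishes this rule from a symmetric t-test cutoff. The estimated FDR
at a given $\Delta$ is the median, over permutations, of the count of
permuted $d_p$ values beyond the cutoffs, divided by the observed call
count (the median is robust to occasional extreme permutations; the mean
is available as an option). `sam_delta_table()` re-scans a fitted object
over a $\Delta$ grid cheaply, which is how the analysis scripts choose
the smallest $\Delta$ with estimated FDR below a target.

Ties in the $d$ ranking are broken by gene order, making every stage
deterministic given the seed.

# Per-condition networks

Each condition's Pearson correlation matrix is computed on that
condition's samples only — this is what makes the two networks describe
genuinely different states; computing both on all samples would blur
exactly the contrast being sought. A pair is connected when $r > \tau$
(default $\tau = 0.8$, strict inequality, tested at the boundary). This
*signed* rule ignores strong negative correlations; an `unsigned` mode
($|r| > \tau$) is provided because the choice is a genuine modelling
decision — with the default, anti-correlated pairs are deliberately not
edges. Genes that are constant within a condition get correlation 0 (with
a warning) rather than NaN, keeping downstream matrices total.

Topology diagnostics per network: degree, local clustering coefficient
$C_i = 2\,\mathrm{tri}(i)/(k_i(k_i-1))$, the shortest-path-length
histogram over connected pairs, mean clustering by degree, and the
topological coefficient
$TC_i = \mathrm{mean}_j\,(|N_1(i) \cap N_1(j)| + a_{ij})/k_i$ over
partners $j$ that share a neighbor with $i$ or are adjacent to it
($TC_i = 0$ for $k_i < 2$). The topological coefficient has no single
canonical definition in the literature; this is the network-viewer
convention, and the test suite pins it (and all other statistics) to an
independent brute-force implementation on random graphs.

Sample clustering (the two-class sanity check) is average-linkage
agglomeration on $1 - r$ between sample profiles, after centering each
gene. Centering removes the gene-level baseline so correlations reflect
condition-driven deviations; without it, samples from a condition with no
shared signal would be mutually uncorrelated and the two-class structure
invisible. This is the same convention expression heatmaps use.

# Differential links and their significance

A pair is a *candidate differential link* when $r_{\text{normal}} < T_1$
and $r_{\text{cancer}} > T_2$ (defaults $T_1 = 0.3$, $T_2 = 0.8$, both
strict): co-expression gained in the cancer state. The reverse
(loss-of-co-expression) direction is off by default and available via
`both_directions = TRUE`, keeping the default faithful to the
gain-direction definition while acknowledging the symmetric case exists.

The per-link statistic is the Fisher-z difference
$\Delta z = \mathrm{atanh}(r_{\text{cancer}}) -
\mathrm{atanh}(r_{\text{normal}})$ — variance-stabilized, the standard
choice for comparing correlations. The null distribution reshuffles the
condition labels globally (one relabeling per draw applied to every link,
preserving group sizes and the joint gene structure) and recomputes
$\Delta z$. Two-sided p-values use the add-one rule
$p = (\#\{|\Delta z_p| \ge |\Delta z_{\text{obs}}|\} + 1)/(B+1)$, so
$p \ge 1/(B+1)$ and never 0. When the number of distinct label splits
$\binom{n}{n_1}$ is at most $B$, all splits are enumerated instead and
$p$ is the exact exceedance fraction (the observed split is a member, so
positivity is preserved). Correlations of $\pm 1$ are clamped to
$\pm(1 - 10^{-12})$ before the atanh.

Because many pairs are tested, Benjamini–Hochberg adjustment is applied
before the subnetwork is assembled (a raw-p mode exists for comparison
with single-test reports). The significant links form the differential
subnetwork; hubs are its highest-degree nodes, default the top 6, ties
broken by gene ID with a flag when ties at the boundary were cut off, or
alternatively all nodes above a degree floor.

Two properties of this design are worth stating plainly. First, under a
true null the p-value of a *pre-specified* pair is uniform — the test
suite verifies the 5% rejection rate and Kolmogorov–Smirnov uniformity on
2000 null links at $n = 9 + 9$, $B = 499$. Second, *candidate selection
biases the raw p-values of selected pairs downward* (candidates are
selected for extreme observed correlation differences), which is exactly
why the BH step and an adequate sample size matter; with very few samples
per condition, chance candidates can survive. The analysis scripts
demonstrate this honestly at $n = 9 + 9$.

# Topological overlap and modules

On a binary symmetric adjacency $A$ with zero diagonal, the topological
overlap is

$$t_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
l_{ij} = \sum_u a_{iu} a_{uj}, \quad t_{ii} = 1,$$

and the $m$-th order generalization (GTOM$m$) replaces direct
neighborhoods with $N_m(i)$, the set of nodes reachable from $i$ within
$m$ steps (excluding $i$ itself):

$$t^{[m]}_{ij} = \frac{|N_m(i) \cap N_m(j)| + a_{ij}}
{\min(|N_m(i)|, |N_m(j)|) + 1 - a_{ij}}.$$

GTOM1 coincides with TOM exactly, and the suite verifies the
count-based matrix implementation against a set-based oracle built from
explicit per-node BFS on hundreds of random graphs. We implement the
formula literally: only the node itself is excluded from $N_m(i)$. Some
of the literature also removes the partner $j$; that variant is available
via `exclude_partner = TRUE`. TOM is computed on the *thresholded*
(binary) networks — the formula requires binary adjacency — not on the
raw correlation matrix.

Modules are detected on the dissimilarity $1 - t$ by average-linkage
hierarchical clustering with a static cut (default height 0.95), clusters
below `min_size` (default 5) left unassigned, and surviving modules
renumbered by decreasing size (ties by smallest member ID). A static cut
was chosen over dynamic tree cutting for determinism and transparency;
both thresholds are exposed. `module_heatmap_data()` orders genes by
module and dendrogram leaf order and returns block boundaries for heatmap
display.

# The synthetic-data generator

The generator emulates the shape of a small single-channel microarray
study: two balanced groups (default-scale scenarios use 9 samples per
condition), a few hundred genes, log2 intensities around a common
baseline with i.i.d. Gaussian noise of SD $\sigma$.

- **Differential expression** is an additive shift of
  `de_effect`$\cdot\sigma$ in the cancer samples, signs alternating
  up/down so both calling cutoffs are exercised.
- **Co-expression modules** follow a single-factor model: in the
  condition where a module is active, its genes share a per-sample latent
  factor $f \sim N(0,1)$ with loading $\lambda$, giving population
  within-module correlation $\lambda^2/(\lambda^2 + \sigma^2)$; the
  loading is solved from the target $r$, so planted effect sizes are
  exact. A Monte-Carlo test confirms the empirical within-module
  correlation lands within ±0.03 of the target at $n = 200$.
- **Ground truth** records the shifted genes with signs, the module
  membership, and the within-module pairs whose *population* correlations
  satisfy the default differential-link rule ($r_{\text{cancer}} > 0.8$,
  $r_{\text{normal}} < 0.3$).
- Module descriptors accept an optional `de_effect` so module genes can
  also be mean-shifted — necessary when the downstream networks are built
  over the DEG universe and the module must survive the screen.

What the generator does **not** emulate: probe-level artifacts
(background, cross-hybridization, saturation), batch effects, heavy-tailed
or intensity-dependent noise, correlated background structure, and —
importantly — a realistic spread of baseline abundances across genes (all
genes share one baseline mean). Consequences worth knowing: the
median-quantile gene filter, aimed at low-abundance genes on real arrays,
would act on condition shifts here and is therefore disabled in the
simulated workflows; and passing tests demonstrate correctness of the
machinery and calibration under the stated model, not robustness to
microarray pathology. The latent-factor noise model is this package's
stand-in for an unspecified data-generating process, not an empirical
claim about any particular dataset.

One subtlety of the factor model: the module's shared factor has a
nonzero sample mean in any finite sample, so the whole module's observed
mean shift fluctuates around its planted value by roughly
$\lambda/\sqrt{n}$ *jointly* across member genes. At $n = 9$ and high
target correlations this module-level wobble is about one noise SD, which
is why demonstration scenarios that need module genes to pass the DEG
screen plant generous shifts for them.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `nperms` | 100 | balanced label permutations for $d_E$ and the FDR |
| `delta`  | 2.5 | SAM displacement cutoff (dimensionless, in $d$ units); scan with `sam_delta_table()` |
| `s0` | auto | fudge factor (expression units); percentile search unless fixed |
| `tau` | 0.8 | correlation threshold for condition networks |
| `mode` | signed | edge rule: $r > \tau$ vs $|r| > \tau$ |
| `t1`, `t2` | 0.3, 0.8 | differential-link bounds (normal below `t1`, cancer above `t2`) |
| `B` | 1000 | label permutations per differential-link test |
| `alpha` | 0.05 | BH-adjusted significance level for the subnetwork |
| `top_k` | 6 | hubs reported from the differential subnetwork |
| `gtom_order` | 1 | neighborhood order for topological overlap |
| `cut_height` | 0.95 | static cut on the $1 - t$ dendrogram |
| `min_size` | 5 | smallest reported module |

# Numerical and degenerate-input policy

- Missing values are rejected at read time; correlation and permutation
  machinery assume complete matrices.
- Constant genes: correlation 0 with a warning (not NaN); a constant gene
  with $s_0 = 0$ raises an error naming the gene.
- Threshold comparisons ($\tau$, $T_1$, $T_2$, $\Delta$ displacement) are
  strict everywhere, tested at the boundaries.
- `atanh` arguments are clamped to $\pm(1-10^{-12})$.
- Empty results are legal values, not errors: an empty differential
  subnetwork, an all-unassigned module labeling, zero SAM calls (with
  FDR defined as 0).
- All stochastic stages take explicit seeds; identical seeds give
  bit-identical results, and the pipeline derives per-stage seeds from
  one top-level seed.

# Problem sizes used by the tests and acceptance script

The suite measures operating characteristics at deliberately moderate
sizes chosen to make the properties sharp while keeping runs quick: DEG
recovery on 500 genes with 50 planted 2$\sigma$ shifts at $n = 9 + 9$
(sensitivity ≥ 0.9 at an FDR-controlled $\Delta$); differential-link
recovery on 500 genes with one 10-gene module ($r = 0.9$ vs 0) at
$n = 30 + 30$, $B = 999$ (sensitivity ≥ 0.8, false-link proportion
≤ 0.1, hubs inside the module); null calibration on 2000 independent
null links at $n = 9 + 9$, $B = 499$; exact-oracle comparisons on a few
hundred random graphs of up to 40 nodes. The 30-sample link scenario
reflects what the permutation test needs for stable correlation
estimates; at $n = 9 + 9$ (the scale of the motivating study design)
link detection is markedly noisier, as the bundled analysis scripts
show.

# Known limitations

- Hard thresholding discards the correlation magnitude structure below
  $\tau$; soft-threshold (weighted) networks are out of scope.
- The permutation test treats links marginally; no global
  family-wise statement beyond BH is made.
- Candidate selection before testing biases raw p-values of selected
  pairs; interpret raw p only together with the selection rule.
- Gene filtering by median quantile presumes an abundance gradient;
  with data lacking one it selects on condition effects instead.
- Multi-class, paired and survival designs, q-values per gene, module
  eigengenes, dynamic tree cut, and enrichment analysis against external
  annotation services are all out of scope.
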