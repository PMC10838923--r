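---
title: "Identifying parent–child dyads from functional connectomes: methods"
author: "cbident"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying parent–child dyads from functional connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbident)
```

## The problem and the data model

An individual's functional connectome is summarised as an FC profile: the
symmetric $r \times r$ matrix of Pearson correlations between the fMRI time
series of $r$ regions of interest. The package works with *two index-aligned
sets* of such profiles — $n$ parents and $n$ children, where couple $i$
occupies index $i$ in both sets — and asks whether biological couples can be
identified from connectivity alone. In every parents-by-children matrix the
diagonal therefore encodes the biological dyads.

Profiles are handled in deduplicated vector form: the strict upper triangle
in row-major order (`edge_index()`), $r(r-1)/2$ entries. The diagonal of an
FC profile is constantly 1 and carries no information, and the symmetric
duplicates would merely weight every edge twice uniformly — which leaves
Pearson correlations unchanged, a fact the test suite asserts rather than
assumes. Validation tolerances are 1e-12 (absolute) for symmetry and the
unit diagonal. No Fisher z-transform is applied by default; `fc_profile()`
has an opt-in flag, but all downstream decisions are rank- or
correlation-based and unaffected by monotone transforms.

## Fingerprint identification

`fingerprint()` correlates whole-connectome vectors across the two sets and
matches each target to its most similar database profile; a couple is
identified when the match is on the diagonal. Both directions
(parents as targets, children as targets) are reported, and
`fingerprint_permutation()` attaches an empirical p-value by shuffling
database identities. This model is the baseline the CBI model is designed
to beat: it has no access to cross-set structure.

## The CBI model

`cbi()` runs four steps:

1. **Feature selection** (`edgewise_spearman()`). For each edge, the
   parents' values across the $n$ dyads are Spearman-correlated with the
   children's values. Edges with two-sided $p < \alpha$ (default 0.05)
   split into a positive ($\rho > 0$) and a negative ($\rho < 0$) mask.
   Edges constant across dyads in either set have undefined rank
   correlation; they are excluded from both masks and counted, with a
   warning.
2. **Representation** (`feature_vectors()`). Every subject is reduced to
   their own FC values at the masked edges, giving $n \times m$ matrices
   per set and sub-model.
3. **Distance matrices** (`cbi_distance()`). Parents by children, under the
   Euclidean metric and under Spearman correlation of the feature vectors.
4. **Identification** (`cbi_identify()`). Positive sub-model: a parent is
   paired with the child at minimum distance / maximum correlation;
   negative sub-model: maximum distance / minimum correlation. A couple
   scores one when the extremum is on the diagonal; the rate is the mean
   score. Extrema are not required to be strict: ties are broken to the
   lowest column index, deterministically, with a warning.

No multiple-comparison correction is applied to the $r(r-1)/2$ edgewise
tests. This is a deliberate, prominent property of the design: validity is
delegated to the permutation tests below, where an abundance of
false-positive features is expected to surface. The limitations section
explains why that delegation is only partially effective.

### Spearman p-values

No single convention is mandated for rank-correlation p-values at this
sample size. The package uses the dominant one: the two-sided $t$
approximation with $df = n - 2$,
vectorised over all edges (at $r = 264$ there are 34,716 of them, and the
feature-level permutation test re-runs the scan thousands of times). Ties
receive average ranks. An exact option (`p_method = "exact"`, $n \le 9$)
enumerates all $n!$ rank pairings; both routes are tested against
independent oracles (`stats::cor.test` and a brute-force enumeration).

### Permutation tests

**Label shuffling** (`cbi_label_permutation()`, default 5,000 iterations)
holds the masks fixed and re-pairs the couples uniformly at random,
recomputing the identification rate each time. Shuffling both sets
independently and shuffling only the child order induce the same uniform
distribution over diagonal pairings; the simpler scheme is implemented and
the equivalence is unit-tested. Whenever each row has a unique extremum the
number of identified couples under a uniform shuffle is the fixed-point
count of a random permutation, whose expectation is exactly 1 — rate
$1/n$, i.e. $7.69\%$ at $n = 13$ — for *any* data. Chance levels reported
for such shuffles sometimes differ between sub-models (e.g., $2/13$ for
positive and $1/13$ for negative features), which cannot arise under
per-row unique extrema; the package implements the analytic rule, one
expected identification per shuffle for every sub-model and metric.
The p-value is $\#\{\text{rate} \ge \text{observed}\}/B$ without the $+1$
correction, so a perfect observed rate can legitimately report $p = 0$; a
`conservative` flag switches to $(k+1)/(B+1)$.

**Feature re-selection** (`cbi_feature_permutation()`) re-pairs the dyads,
re-runs the edgewise scan on the shuffled pairing, represents the
*original* sets by the resulting masks, and scores the true diagonal. The
report includes the mean rate, the maximum rate and how often it recurred.
Permutations with an empty mask — or a single-feature mask, for which the
Spearman metric is undefined — score rate 0 for the affected rules and are
counted; dropping them would bias the null.

A single top-level seed drives each test's permutation stream, and the
pipeline spawns per-stage seeds deterministically, so whole runs are
byte-reproducible.

## Network-to-network accounting

With an ROI-to-network labeling (e.g. the 14 functional networks of the
Power parcellation), `network_contribution()` counts the selected features
in each network-pair block. Because masks live on the deduplicated upper
triangle, no symmetric double counting can occur. Two normalizations are
reported: by the sub-model's total feature count (unique nodes sum to 1)
and by node size — $n_A n_B$ distinct edges for an off-diagonal node,
$n_A(n_A-1)/2$ for a within-network node. Self-connections are excluded
from node sizes: they are constantly 1 in an FC profile and can never be
selected, so including them would only deflate within-network
contributions. The "uncertain" network, when present, is an ordinary label.

## Diffusion maps

`diffusion_map()` embeds $N$ profiles through the Gaussian kernel
$K_\varepsilon(i,j) = \exp(-d(i,j)^2/\varepsilon)$, row-normalized to a
Markov transition matrix $P$, followed by an eigendecomposition performed
on the symmetric conjugate $D^{-1/2} K D^{-1/2}$ for numerical stability.
Feature-vector profiles use the Euclidean metric; whole-brain profiles are
symmetric positive-definite (after shrinkage) and use the affine-invariant
Riemannian metric $d(A,B) = \|\log(A^{-1/2} B A^{-1/2})\|_F$
(log-Euclidean is available as a cheaper option).

Numerical choices worth recording:

* **Kernel scale.** The requirement is only that $\varepsilon$ be large
  enough to connect all nodes; any positive value satisfies it for a
  Gaussian kernel. The default is the scale-free median heuristic,
  $\varepsilon$ = median squared off-diagonal distance, with a multiplier
  (`epsilon_scale`).
* **Trivial eigenpair.** A row-stochastic matrix has leading eigenvalue
  exactly 1 with a constant right eigenvector (a strict ordering such as
  $1 > \lambda_0$ is not attainable). The constant pair is discarded and
  coordinate $k$ of profile $i$ is $\lambda_k \phi_k(i)$ for the next $l$
  pairs ($l = 2$ by default). Eigenvectors are unit-normalized and signs
  are fixed so each vector's first maximal-magnitude component is positive,
  making embeddings reproducible up to that convention.
* **Shrinkage.** Correlation matrices estimated from fewer time points than
  ROIs are rank deficient, so `ensure_spd()` applies
  $(1-\gamma)M + \gamma I$ before the Riemannian metric. True correlation
  matrices are positive semi-definite and any $\gamma > 0$ suffices; the
  pipeline default is $\gamma = 0.1$. Directly simulated profiles
  (`mode = "fc-direct"`) are symmetric with unit diagonal but need not be
  PSD, so the pipeline raises $\gamma$ automatically to the smallest value
  that floors every profile's spectrum at 0.01.

`dyad_distance_stats()` compares the $n$ embedded biological parent–child
distances with all $n^2 - n$ unrelated parent–child pairings: means,
standard errors ($sd/\sqrt{m}$), and a two-sided Mann–Whitney test under
the normal approximation with tie correction (`stats::wilcox.test`,
`exact = FALSE, correct = FALSE`). The unrelated pairings share subjects
and are not independent observations; the test treats them as such by
construction of the procedure, and the p-value should be read accordingly.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions for every test in the
package. Defaults mirror the reference design: 13 dyads, 264 ROIs, 150 time
points. For each edge $e$, a cohort-level baseline
$\mu_e \sim N(0.1, 0.2^2)$ truncated to $(-0.8, 0.8)$; for dyad $d$ a
latent $u_{d,e} \sim N(0,1)$; then

$$\text{parent} = \tanh(\mu_e + c\,u_{d,e} + a\,g_{d,e} + \sigma\epsilon),
\qquad
\text{child} = \tanh(\mu_e + s_e\,c\,u_{d,e} + a\,g_{d,e} + \sigma\epsilon')$$

with $s_e = +1$ on the planted positive edges (5% of edges by default),
$-1$ on the planted negative edges (5%), 0 elsewhere; coupling $c = 1$,
noise $\sigma = 0.3$. The $\tanh$ squashing keeps entries inside $(-1,1)$
without clipping artifacts. The dyad-shared whole-connectome component
$g_{d,e}$ (scale $a$, `individual_strength`, default 0) is what a
whole-brain fingerprint can exploit: in a two-set parent/child design only
a signal shared by both members of a dyad across the whole connectome can
make whole-connectome matching succeed, so at $a = 0$ the fingerprint model
sits at chance while the planted edge coupling still drives the CBI model.
In `mode = "timeseries"` the same construction defines a per-subject target
correlation matrix, floored to positive definiteness (eigenvalue floor
1e-4, rescaled to unit diagonal) and sampled for $T \times r$ Gaussian
series, so the planted structure is additionally blurred by estimation
error — closer to real data, at higher cost.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation, motion or physiological artifacts, site effects, and the
heavy spatial dependence of real parcellations. Passing tests therefore
demonstrate correctness of the statistical machinery under a controlled
generative model, not performance claims about real cohorts.

The test suite exercises cohorts at $n = 13$, $r = 50$ (1,225 edges) for
the full-scale statistical checks and $r \le 20$ for oracle comparisons;
these sizes were chosen so the complete suite, including two
5,000-iteration permutation tests, runs in well under a minute while
keeping every rate estimate's Monte Carlo error far below the asserted
tolerances. The strongly coupled regime used for end-to-end checks is
$c = 1.5$, $\sigma = 0.1$ at $r = 50$.

## A known and important limitation: in-sample selection circularity

Selecting features by cross-set correlation and then scoring identification
*on the same sample* is circular. An edge that passes $p < 0.05$ at
$n = 13$ has in-sample $|\rho| \gtrsim 0.55$: by construction the two
sets' orderings agree (or anti-agree) at the selected edges, and since
parent and child edge values share marginal distributions, parent $i$'s
selected-feature vector is close to child $i$'s even when the underlying
data are pure noise. On uncoupled synthetic cohorts the in-sample CBI
identification rate accordingly runs far above the $1/n$ chance level —
the acceptance suite keeps a chance-level check at its nominal value and
treats its failure as informative, and an independent re-implementation
(rank correlation plus nearest-child matching, outside this package)
reproduces the same inflation.

The label-shuffling permutation test does not detect this: it compares an
inflated observed rate against a genuinely chance-level shuffled null, so
on null data it reports $p \approx 0$ rather than a broadly distributed
p-value. The feature re-selection test is the sharper instrument — its null
keeps the selection step — but it scores the *original* diagonal under
masks selected on a shuffled pairing, which breaks the selection–scoring
link and therefore also sits at chance under both the null and the
alternative. The only fully clean designs are out-of-sample: select
features on one subset of dyads and score identification on held-out
couples, or validate on an independent cohort. The package implements the
in-sample procedure as defined above and documents this property rather
than silently altering the method; users should treat in-sample CBI rates
as descriptive
and lean on the feature-level permutation test plus external validation
for inference.

## Other limitations

* Spearman p-values at $n = 13$ rely on the $t$ approximation; its true
  level is slightly above nominal (the suite measures the selected-edge
  fraction at roughly 0.054 for $\alpha = 0.05$).
* The diffusion embedding uses the plain (isotropic) Markov normalization;
  density-normalized variants and out-of-sample extension are out of scope.
* No NIfTI ingestion or preprocessing: inputs are plain-text ROI
  time-series tables or precomputed profiles, with a CSV manifest.
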