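---
title: "Sparse discriminative latent characteristics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse discriminative latent characteristics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lcsens)
```

## The model

`lcsens` is a discriminative, Bayesian nonparametric, sparse factor
analysis for multitask drug-sensitivity prediction. Sensitivity scores
`Y` (drugs x cell lines) are explained by latent characteristics (LCs)
`X` (LCs x cell lines), which are themselves sparse linear functions of
genomic features `F` (features x cell lines):

$$Y = G X + \epsilon, \qquad X = B F + w.$$

The construction is close to reduced-rank regression, with the important
difference that `X` carries its own noise `w`: the LCs are primarily asked
to explain the sensitivity patterns, and only secondarily constrained to be
predictable from features. Both coefficient matrices are sparse through
spike-and-slab priors with unit-variance slabs:

$$G_{dk} \mid Z_{dk} \sim Z_{dk}\,\mathcal N(0,1) + (1-Z_{dk})\,\delta_0,$$

and analogously for `B` with indicators `V` and per-feature inclusion rates
$\pi_p \sim \mathrm{Beta}(\beta/P, 1)$. The binary drug-LC membership
matrix `Z` receives a finite-truncation Indian buffet process prior:

$$v_k \sim \mathrm{Beta}(\alpha/K, 1), \qquad Z_{dk} \sim
\mathrm{Bernoulli}(v_k), \qquad k = 1, \dots, K = k_{\max}.$$

As $K \to \infty$ this converges to the Indian buffet process, under which
the expected number of non-empty columns is $\alpha \sum_{d=1}^D 1/d$; the
package verifies this limit by Monte Carlo in its test suite. We use the
uncollapsed finite form because the Markov-random-field extension below
needs an explicit rate $v_k$ per column. Empty columns are retained as
cheap truncation slots and can be re-born; the fit warns if the active
count reaches $k_{\max}$.

Noise is diagonal and hierarchical, one precision per drug (and per LC):

$$\epsilon_{dn} \sim \mathcal N(0, 1/\lambda_d), \quad
\lambda_d \mid b \sim \mathrm{Gamma}(1, \text{scale } 1/b), \quad
b \sim \mathrm{Gamma}(1, 1),$$

i.e. $\lambda_d \mid b$ is exponential with rate $b$. The shape/scale
reading makes every noise-level conditional conjugate, so the entire model
is amenable to plain Gibbs sampling. Per-drug precisions matter because
some drugs' sensitivity profiles are intrinsically easier to predict than
others'; diagonal noise also lets the likelihood factorize over entries,
which is how missing measurements are handled (masked entries simply
contribute nothing to any sufficient statistic).

### Markov random field coupling

Prior knowledge that two drugs share an inhibition target (or that two
features describe the same gene) enters as a weighted undirected graph.
The prior probability of an LC membership column is modified to

$$P(Z_{:k}) \propto \exp\Big(\sum_{d'<d} w_{d'd} Z_{d'k} Z_{dk}\Big)
\prod_d v_k^{Z_{dk}} (1-v_k)^{1-Z_{dk}},$$

an unnormalized pairwise MRF: linked drugs are encouraged, not forced, to
use the same LCs. The partition function is never computed — Gibbs flips
only need differences — and, because the MRF term involves neither $v$ nor
$\pi$, their Beta updates stay conjugate. This tractability choice has a
real consequence discussed under *Limitations*.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 2 | IBP concentration; prior scale of the number of active LCs (dimensionless) |
| `beta` | `0.01 * P` | feature-sparsity concentration; keeps the prior expected number of features per LC small regardless of `P` |
| `k_max` | 50 | truncation level; needs only headroom above the active-LC count, and the fit warns on saturation |
| `mrf_weight` | 1 | edge weight on relation graphs (log-odds units per active neighbor) |
| `n_iter` / `burn_in` / `thin` | 10000 / 5000 / 10 | sweep budget; 10,000 sweeps is the reference budget for screen-sized data |
| `noise_prec_y`, `noise_prec_x` (simulator) | 25 | generative noise precisions, i.e. noise s.d. 0.2 against unit-scale signal |

Sensitivity rows and continuous feature rows are z-scored per row before
fitting (training statistics are stored in the trace and re-applied to
held-out data); mutation rows stay 0/1. With both sides standardized, the
unit slab variances are a scale convention rather than a restriction.

## Gibbs sampler

One sweep updates, in fixed order: the latent values `X` (exact
multivariate Gaussian conditional per cell line, one shared Cholesky when
no entries are missing), the drug loadings `(Z, G)`, the feature
regression `(V, B)`, the sparsity rates `(v, pi)` (conjugate Beta), and
the noise precisions and their hyperparameters (conjugate Gamma). Any
fixed scan order is a valid Gibbs sampler; fixing one guarantees
bit-reproducibility for a given seed.

Indicator flips integrate the slab coefficient out analytically: the flip
log-odds are the prior log-odds (including the MRF neighbor term) plus the
log Bayes factor $-\tfrac12\log q + s^2/(2q)$ with $q = 1 + \lambda\,\sum
x^2$ and $s = \lambda \sum x r$ against the partial residual $r$; active
coefficients are then redrawn from $\mathcal N(s/q, 1/q)$. The test suite
checks every conditional against independent dense-grid/quadrature oracles
(tolerance 1e-6) and the whole sampler against a Geweke-style
joint-consistency experiment (sweeps alternating with data re-simulation
must leave prior moments invariant).

### Initialization

Rates `v`, `pi` are drawn from their priors, precisions start at 1, `X`
starts at `B F` plus unit noise — and the supports `Z`, `V` start *empty*,
so LCs are born one at a time when evidence supports them. We initially
used a full prior draw as an over-dispersed start, but at realistic sizes
a junk-initialized start reliably locks the chain into states where one
real LC is split across several initialized columns with mutually
correlated `X` rows; because `v_k` tracks column occupancy
(rich-get-richer), single-site flips dissolve such splits extremely
slowly. The empty start removes this failure mode without affecting the
stationary distribution; a prior-drawn start remains available via
`init_state(support = "prior")` and is what the Geweke validation uses.

### Numerical choices

- Rates are clamped to `[1e-12, 1 - 1e-12]` so log-odds stay finite when a
  Beta draw underflows.
- Flip probabilities use one uniform per site in a fixed order; zero-weight
  graphs therefore reproduce the no-graph chain bit for bit (a tested
  invariant).
- Constant data rows standardize by centering only (scale 1), so division
  is always defined; fully masked rows are rejected at container
  construction.
- The feature-side update keeps the cross products current through the
  feature gram matrix when `P <= max(N, 512)` and through a running
  length-`N` residual otherwise; both paths draw identically distributed
  variates in the same order.
- The sampler is vectorized base R. At the problem sizes this package
  targets (tens of drugs, hundreds of cell lines) a full sweep takes a few
  milliseconds, so a compiled back end would add build complexity without
  changing any result reported here.

## What the simulator emulates — and what it does not

`simulate_lc_data()` runs the generative process forward: i.i.d. standard
normal features with a configurable fraction thresholded at the 90th
percentile into rare 0/1 mutation indicators; fixed-size LC supports drawn
without replacement (identifiable ground truth for recovery experiments;
Bernoulli-density supports are available); unit-normal slabs; Gaussian
noise at the configured precisions. It also returns the relation graphs a
practitioner could build from annotations: drugs sharing a true LC, and
features grouped into synthetic genes of 1-3 features.

The defaults (20 drugs, 300 cell lines, 40 features, 3 true LCs, noise
precisions 25) define the package's reference recovery experiment: strong
but not degenerate signal at a size where a 2000-sweep fit takes seconds.
Real screens differ in ways the simulator deliberately ignores: features
are heavily correlated (co-expression), expression is not Gaussian after
normalization, missingness is structured rather than absent, and
dose-response summaries share technical noise across drugs. Passing
recovery tests therefore demonstrates correctness of the machinery, not
expected accuracy on a real screen.

Recovery is scored by `support_f1()`: estimated LC columns are greedily
matched to true columns by pairwise F1 and the binary supports are pooled
into one score; LC labels are arbitrary, so any metric must be
permutation-invariant. Interpretation tables summarize a trace by its
maximum-log-joint state for the same reason, while predictions average
`G B F_new` over the whole trace (label-invariant).

## Evaluation protocol

Cross-validation holds out cell lines (columns): folds are a seeded
shuffle with sizes differing by at most one, standardization statistics
are computed on training columns only, and predictions are scored by

- **PVE**, $1 - SS_{res}/SS_{tot}$ pooled over observed held-out entries
  with per-drug *training* means as the null model (per-drug averaging is
  available too; pooling is the default because fold-level variance
  weights drugs by how much heldout variance they actually have);
- **concordance index** per drug over held-out pairs with distinct
  observations (prediction ties score 1/2), averaged over drugs for which
  it is defined.

Spearman association p-values use the t approximation
$t = \rho\sqrt{(M-2)/(1-\rho^2)}$; for small samples this tracks the
mid-p of the exact permutation null. Association tables report raw
p-values with optional Benjamini-Hochberg adjustment.

The package's own acceptance run (`scripts/acceptance.R`) uses 2000-sweep
chains at truncation `k_max = 10` for the reference experiment — ample
headroom over the three true LCs while keeping a full 10-fold
cross-validation in minutes on one core. The API default stays
`k_max = 50` for data whose LC count is unknown.

## Limitations

- **MRF strength interacts with graph density.** Because the MRF column
  prior is unnormalized (the choice that keeps `v` conjugate), a column
  whose members form many graph edges receives a prior bonus
  $\exp(\sum w)$ that grows with the number of within-column edges, at no
  likelihood cost — membership with near-zero loadings is free. On dense
  graphs at `mrf_weight = 1` this subsidizes spurious dense or duplicated
  columns and can *hurt* support recovery, and longer chains drift further
  toward such states (it is the model's equilibrium, not a mixing
  artifact). In our experiments, weak coupling (weights around 0.2 on a
  dense truth-derived graph) helps or is neutral. Practical guidance:
  scale `mrf_weight` down as typical node degree grows (roughly weight
  x degree of order 1), and inspect the active-LC trace when enabling
  graphs. Normalizing the column prior would remove the subsidy but makes
  the rate updates non-conjugate and requires an Ising partition function
  per column, which is intractable beyond small drug panels.
- The model has no intercept; row standardization absorbs per-drug
  offsets, but uncentered binary mutation features can still induce small
  mean offsets in `X` that are soaked up by the noise or by an extra LC.
- Point predictions only: the trace supports posterior uncertainty in
  principle, but the evaluation protocol scores means.
- Per-drug (not per-cell-line) noise precisions; non-Gaussian likelihoods
  are out of scope.
- LC labels are not aligned across sweeps; all cross-sweep summaries must
  be (and here are) label-invariant or single-state.
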