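---
title: "Genomic prediction with biologically annotated neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with biologically annotated neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

banngp implements genomic prediction for dairy-cattle style data with a
two-layer sparse Bayesian neural network over SNP-sets, alongside the
standard comparators of the field (GBLUP with reliability-weighted
residuals, BayesB, BayesCπ, random forests) and a replicated
cross-validation harness with the accuracy, dispersion and mean-squared-error
metrics customary in animal breeding. This vignette documents the model, the
priors, the inference algorithms and the numerical choices; the README shows
a worked example.

## The prediction target: de-regressed proofs

Dairy evaluation pipelines rarely model raw phenotypes directly. The
pseudo-phenotype is a de-regressed proof (DRP), an estimated breeding value
with parent-average information removed, carrying a per-animal reliability
$r^2_i \in (0,1)$. Given an EBV reliability and a trait heritability $h^2$,
`derive_trait_weights()` computes

$$\lambda = \frac{1-h^2}{h^2}, \qquad
  \mathrm{ERC}_i = \lambda\,\frac{r^2_{\mathrm{EBV},i}}{1-r^2_{\mathrm{EBV},i}}, \qquad
  r^2_{\mathrm{DRP},i} = \frac{\mathrm{ERC}_i}{\mathrm{ERC}_i + \lambda}.$$

The DRP reliabilities drive two things downstream: the diagonal residual
weights $d_{ii} = (1-r^2_i)/r^2_i$ of the mixed model, and the mean DRP
accuracy $\bar r$ that scales the cross-validation accuracy.

## SNP-sets

Each hidden neuron of the network is a SNP-set. Two partitioning strategies
are provided, both producing disjoint, exhaustive covers of the panel:

* `partition_by_gene()`: a SNP inside an annotated gene joins that gene's
  set; a SNP under several overlapping genes goes to the gene with the
  nearest midpoint (ties to the lexicographically smaller identifier); SNPs
  in no gene are pooled per inter-gene interval into intergenic sets.
* `partition_by_window()`: non-overlapping windows of fixed width (default
  100 kb) tile each chromosome from coordinate 1, so position $p$ maps to
  window $\lfloor (p-1)/w \rfloor$; empty windows are not emitted.

## The two-layer network

Writing $X$ for the column-standardized dosage matrix and $y$ for the
standardized trait, the network is

$$y = h(X\Theta + b_1)\,w + b_2, \qquad h(u) = \max(u, 0) + 0.01\,\min(u, 0),$$

with one column of $\Theta$ per SNP-set (supported only on the member SNPs)
and a leaky-ReLU activation of slope 0.01. Biases are absorbed by
centering, so $b_1 = 0$ and $b_2 = 0$ on the standardized scale.

**SNP layer.** Each inner weight $\theta_j$ carries a sparse K-mixture
normal prior (default $K = 3$, interpreted as large, moderate and small
effects):

$$\theta_j \sim \pi_\theta \sum_{k=1}^{K} \eta_{\theta k}\,
  N(0, \sigma^2_{\theta k}) + (1-\pi_\theta)\,\delta_0.$$

**Set layer.** Each outer weight $w_g$ carries a single-slab
spike-and-slab prior $w_g \sim \pi_w N(0, \sigma^2_w) + (1-\pi_w)\delta_0$,
whose posterior inclusion probability $\gamma_g$ is the SNP-set PIP.

### Variational EM

Both layers are fitted by mean-field coordinate-ascent variational
inference. For each SNP the factor is
$q(\theta_j) = \sum_k \alpha_{jk} N(\mu_{jk}, s^2_{jk}) +
(1-\sum_k \alpha_{jk})\,\delta_0$, updated in closed form; after every sweep
the mixture proportions $\eta_\theta$, the slab variances
$\sigma^2_{\theta k}$ and the residual variance $\tau^2_\theta$ get exact EM
(M-step) updates from the responsibilities. Every block update maximizes the
evidence lower bound, so the ELBO trace is non-decreasing; iteration stops
when successive ELBOs change by less than `elbo_tol` (default `1e-4`) or at
`max_iter` (default 10000).

The inclusion probability $\pi_\theta$ is not a point estimate. Honouring a
uniform prior on $\log \pi_\theta$, it is handled by an $L$-point grid
(default $L = 20$) uniform in $\log \pi$ on $[-\log J,\, 0]$
($[-\log G,\, 0]$ for the set layer). The grid is swept in ascending order
with warm starts, and grid points are combined by ELBO importance weights —
a multi-model average in which $L$ plays the role of the number of candidate
models. Averaged marginals keep the decomposition
$\beta_{\theta j} = \sum_k \bar\alpha_{jk}\bar\mu_{jk}$.

The two layers are trained in sequence: the SNP layer on $y$, then the
hidden inputs $H_{\cdot g} = h(X_g \beta_{\theta g})$ are formed from the
SNP-layer marginal posterior means, re-standardized, and the set layer is
fitted on the same $y$. Hidden columns with zero variance (sets whose
SNP-layer means are exactly zero) are dropped with a warning and get weight
zero and PIP zero.

### Defaults and numerical choices

* `sigma0_sq = 0.01` seeds the variance hyperparameters: the $K$ slab
  variances start at $\sigma^2_0 \cdot 10^{(-1, \dots, 1)}$ and the random
  initialization draws weights from the corresponding priors under
  `cfg$seed` (a deterministic all-zero start is available via
  `init = "zero"`).
* The residual variance $\tau^2$ is initialized at $\mathrm{var}(y)$ rather
  than at $\sigma^2_0$: on standardized data the residual variance is near 1
  at the start of training, and initializing it at 0.01 makes the first
  sweeps badly mis-scaled without changing the optimum.
* The EM update of each slab variance is floored at `sigma0_sq / 10`, the
  smallest initialization value. Without the floor the slab can collapse
  towards the spike on weak data, making inclusion free: all grid points
  then tie in ELBO and the averaged PIPs inflate towards the grid mean.
  A fixed floor keeps the update a constrained block maximization, so ELBO
  monotonicity is preserved.
* Coordinate updates use precomputed $X^\top X$ bookkeeping when
  $J \le 2000$ and $J \le 2n$ (with periodic exact residual refreshes), and
  residual bookkeeping otherwise.

### Variance explained

Following the two-level decomposition of the network,

$$\mathrm{PVE}_{\mathrm{snp}} =
  \frac{V[X\beta_\theta]}{V[X\beta_\theta] + \tau^2_\theta}, \qquad
  \mathrm{PVE}_{\mathrm{set}} =
  \frac{V[H\beta_w]}{V[H\beta_w] + \tau^2_w},$$

with $V$ the sample variance. The SNP-level estimate sees only additive
signal; the set-level estimate runs through the activation, so within-set
non-additive signal contributes to it.

## Comparators

**GBLUP.** `fit_gblup()` fits $y = 1\mu + g + e$ with
$g \sim N(0, G\sigma^2_g)$, $e \sim N(0, D\sigma^2_e)$, where $G$ is the
VanRaden method-1 genomic relationship matrix and $D$ holds the DRP
weights $d_{ii} = (1-r^2_i)/r^2_i$. After whitening by $D^{-1/2}$ a single
eigendecomposition turns the restricted likelihood into a cheap 1-D function
of the variance ratio, maximized numerically (profiled REML). Validation
animals are predicted by the relationship-based BLUP extension
$\hat g_{\mathrm{test}} = G_{\mathrm{test,train}}
(G_{\mathrm{train,train}} + \lambda D_{\mathrm{train}})^{-1}
(y - 1\hat\mu)$ with $\lambda = \hat\sigma^2_e/\hat\sigma^2_g$.

**BayesB and BayesCπ.** Single-site Gibbs samplers over inclusion
indicators and effects. BayesB gives each marker its own effect variance
with a scaled inverse chi-square prior (marginally t-distributed effects,
default $\nu = 4.2$) and holds the no-effect proportion fixed at
$\pi = 0.95$; BayesCπ shares one slab variance and samples $\pi$ from
$\mathrm{Beta}(\#\mathrm{null}+1, \#\mathrm{nonnull}+1)$ under a uniform
prior. The default prior scale solves for a prior mean genetic variance of
`h2_prior` (0.3) of the phenotypic variance. Default chains are
50000/20000/50 (length/burn-in/thinning); the tests and the experiment
harness scale these down.

**Random forest.** `fit_rf()` grid-searches the forest size and maximum
depth by mean squared error over an inner 5-fold cross-validation run
entirely inside the training fold, then refits the best pair.

## Evaluation protocol

`run_experiment()` simulates a panel, a gene map, a trait and DRPs, then
evaluates all requested methods under one shared plan of `cv_reps`
replicates of `cv_k`-fold cross-validation (default 5 × 5; the fold plan is
hashed so fold identity across methods is checkable). DRP standardization
constants come from the training fold only. Per fold,

* accuracy $= \mathrm{cor}(\mathrm{sDRP}, \mathrm{PV})/\bar r$ with
  $\bar r$ the mean $\sqrt{r^2_{\mathrm{DRP}}}$ of the validation animals,
* dispersion $=$ the regression slope of sDRP on PV (1 = no over- or
  under-dispersion),
* MSE $=$ mean squared difference.

Fold values are averaged to replicate means, replicate means to the
reported value; `compare_methods()` runs two-sided paired t-tests on the
replicate means (df = replicates − 1) with Bonferroni correction over the
method pairs within a trait.

## The simulator

`simulate_genotypes()` draws biallelic dosages as sums of two haplotypes
whose latent Gaussians follow a first-order autoregressive process along
each chromosome (`ld_rho` controls adjacent-marker LD; it is a
controllable-knob model, not a coalescent). `sim_architecture()` +
`simulate_phenotypes()` draw sparse additive effects from a three-component
normal mixture — either a `pi_causal` fraction panel-wide or confined to
`n_enriched_sets` SNP-sets — optionally add one within-set product-term
interaction per chosen set, and calibrate the residual so the realized
sample heritability equals `h2_target` exactly. `simulate_drp()` adds
per-animal noise with variance $\mathrm{var}(\mathrm{tbv})(1-r^2)/r^2$ for
reliabilities drawn uniformly on `rel_range`, matching the reliability
algebra above.

## Problem sizes and limitations

The package is exercised at desk scale: thousands of individuals and around
a thousand markers, where a network fit takes well under a minute on one
CPU. The code paths scale beyond that (the VB updates switch bookkeeping
automatically), but the defaults and the test tolerances are chosen for
these sizes. Known limitations:

* The SNP-layer and set-layer fits are sequential, not jointly variational;
  uncertainty in $\beta_\theta$ is not propagated into the hidden inputs.
* Grid averaging targets marginal summaries (PIPs, posterior means);
  joint posterior draws are not available from the variational fits.
* The HWE filter uses the 1-df chi-square goodness-of-fit test, an
  approximation to the exact test that is adequate at simulated sample
  sizes.
* The simulator's LD model is geometric by marker adjacency and does not
  reproduce long-range pedigree structure.
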