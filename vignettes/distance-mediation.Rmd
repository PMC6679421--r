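---
title: "Distance-based mediation analysis: model, design choices, and simulation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based mediation analysis: model, design choices, and simulation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modima)
```

## The problem

Mediation analysis asks whether an exposure $X$ influences a response $Y$
*through* an intermediate variable $M$, over and above any direct $X \to Y$
effect. The classical single-mediator model (SMM) writes three linear
regressions,

$$M = i_3 + \alpha X + \varepsilon_3, \qquad
  Y = i_2 + \gamma X + \beta M + \varepsilon_2,$$

and mediation is present exactly when both the exposure-to-mediator path
$\alpha$ and the mediator-to-response path $\beta$ are nonzero. A
correlation-based test statistic for this hypothesis is the product

$$S(X, M, Y) = \rho_{X,M}\,\rho_{r_{M|X},\, r_{Y|X}},$$

the Pearson correlation of exposure and mediator times the correlation of
the residuals of the $M$-on-$X$ and $Y$-on-$X$ regressions, assessed by
permutation (`smm_test()`).

Microbiome data break the univariate framework: the candidate mediator is an
entire community profile — high-dimensional, compositional, overdispersed —
that practitioners summarize through pairwise beta-diversity
dissimilarities. This package extends the product statistic to that setting
using energy statistics. With $d_{XX}$, $d_{MM}$, $d_{YY}$ the pairwise
distance matrices of the three variables (each under a metric appropriate to
its data type), the multivariate omnibus distance mediation statistic is

$$S_d = \mathrm{dCor}(d_{XX}, d_{MM}) \times \mathrm{pdCor}(M, Y; X),$$

the distance correlation between exposure and mediator times the partial
distance correlation between mediator and response after removing the
exposure. Each factor mirrors one link of the mediation chain; the product
is large only when both links are present.

## Energy-statistics primitives

Distance correlation is built by centering the distance matrices. The
V-statistic version double-centers ($A_{jk} = d_{jk} - \bar d_{j\cdot} -
\bar d_{\cdot k} + \bar d_{\cdot\cdot}$) and takes
$\mathrm{dCov}^2 = \operatorname{mean}(A \circ B)$; `dcor()` is the
normalized version in $[0, 1]$. The bias-corrected version `bcdcor()`
("$R^*$") U-centers with $n-1$, $n-2$ denominators and a zeroed diagonal,
and uses the unbiased inner product
$\langle A, B\rangle = \sum_{ij} A_{ij}B_{ij} / (n(n-3))$; it can be
negative in finite samples and requires $n \ge 4$. Partial distance
correlation follows the first-order partial-correlation recursion on
$R^*$ values:

$$\mathrm{pdCor}(X, Y; Z) =
  \frac{R^*_{XY} - R^*_{XZ}R^*_{YZ}}
       {\sqrt{(1 - R^{*2}_{XZ})(1 - R^{*2}_{YZ})}}.$$

**Denominator choice.** A variant of this formula circulates in print with
$(1 - r_{x,y}^2)$ as the second denominator factor. That form is not the
partial-correlation recursion (it is asymmetric in a way that breaks the
residual-correlation identity), so the package implements the standard
$\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}$ denominator throughout — which is
also what the reference energy-statistics literature and software define —
and exposes the other form behind `denominator = "printed"` purely for
audit. The same choice applies to `pearson_partial()`, whose equality with
the correlate-the-OLS-residuals construction is enforced in the test suite
to 1e-10.

**Degenerate denominators** (a factor within 1e-12 of $\pm 1$, or a
vanishing marginal distance covariance) return 0 with a warning rather than
raising: permutation loops must never abort mid-stream. Tiny negative
mean-products in `dcor()` — pure floating-point artifacts — are clamped to
zero before the square root.

**Which first factor?** The statistic's first factor defaults to the
bias-corrected $R^*$ (`variant = "bias-corrected"`), matching the scale of
the partial factor, which is necessarily built from $R^*$. The plain
V-statistic `dcor()` is available as `variant = "v-statistic"` for users
who want the literal dCor–pdCor product; the permutation test is valid
either way because the null distribution is generated by the same statistic
that produced the observed value.

## The adaptive permutation test

Under the mediation null at least one link of the chain is absent, and the
honest null to simulate is the one that scrambles the *weaker* observed
link: if $|\mathrm{dCor}(X,M)| < |\mathrm{pdCor}(M,Y;X)|$ the rows and
columns of $d_{XX}$ are permuted jointly, otherwise $d_{YY}$ is
(`modima_test()`; ties go to the response branch). Magnitudes are compared
in absolute value because bias-corrected factors may be negative. The full
statistic is recomputed for each of $q$ permutations and

$$p = \frac{1}{q}\sum_{i=1}^{q} 1\{S_d \le S_d^{(i)}\}.$$

This estimator has resolution $1/q$ and can return exactly 0; the add-one
variant $(1 + \#)/(1 + q)$ is available as `positive_p = TRUE` but is off
by default, matching the frequency formula above. The identity permutation
is not excluded from the draw — excluding it would bias the null for a
negligible gain. Permuting a distance matrix moves values, not labels:
entry $(i,j)$ becomes $(\pi(i), \pi(j))$ while ids stay with positions,
which is precisely what severs the linkage to the other two matrices.

U-centering commutes with joint row/column permutation, so the test
pre-centers all three matrices once and re-indexes inside the permutation
loop; self inner products are permutation-invariant and are cached. This
makes the per-permutation cost two $O(n^2)$ elementwise products.

## Dissimilarities

Euclidean, Bray–Curtis, presence/absence Jaccard, Jensen–Shannon
divergence, and UniFrac (unweighted, weighted, generalized) cover the
metric choices a microbiome mediation analysis typically needs. Design
points worth stating:

* JSD is returned as the divergence itself, natural-log base, bounded by
  $\ln 2$; the square-root metric form is `sqrt = TRUE`, off by default.
  Samples are normalized to proportions internally, so per-sample count
  scaling is irrelevant.
* Jaccard is computed on supports only, consistent with its grouping among
  presence/absence metrics; an abundance-weighted Jaccard is out of scope.
* UniFrac accumulates per-branch: with $A_e$, $B_e$ the summed proportions
  of tips under branch $e$, the weighted-normalized form is
  $\sum_e b_e |A_e - B_e| / \sum_e b_e (A_e + B_e)$ and the generalized
  form weights branches by $(A_e + B_e)^\alpha$ with $\alpha = 0.5$ by
  default, the customary compromise between presence/absence and
  proportional weighting; $\alpha = 1$ recovers the weighted-normalized
  form identically. The raw (unnormalized) weighted form is available via
  `normalized = FALSE`; the default is the normalized form bounded by
  $[0, 1]$. Zero-length branches contribute nothing to either sum; a tree
  whose branch lengths are all zero is rejected as degenerate.
* Trees are `ape` "phylo" objects; `parse_newick()` adds the validation
  the pipeline needs (rootedness, unique tips, branch lengths).

The test suite cross-checks Bray–Curtis and Jaccard against `vegan`, JSD
and both UniFrac variants against `phyloseq`, and generalized UniFrac
against its own $\alpha = 1$ identity plus a branch-by-branch hand
computation on a printed 4-tip tree.

## The synthetic-data generators

`simulate_smm()` draws from the SMM equations with all noise SDs and the
exposure SD fixed at 1 and intercepts at 0 — intercepts do not move any
correlation-based statistic, and unit SDs are the standard simulation
condition for this design. Closed-form moments
($\operatorname{Cov}(x, m) = \alpha$,
$\operatorname{Var}(m) = \alpha^2 + 1$) are verified at $n = 10^5$ in the
tests.

`simulate_multimediator()` emulates a two-population microbiome mixture:
two Dirichlet-multinomial parameter sets (mean proportions $\pi$,
overdispersion $\theta$) stand for two related body-site communities, and
each subject's composition sits between them according to a weight $w_i$
coupled to the exposure. The bundled 21-taxon parameter sets
(`synthetic_oral_params()`) are *synthetic* stand-ins for a saliva/tonsil
pair — overlapping taxa, shifted rank abundances, $\theta \approx 0.01$,
the overdispersion magnitude typical of 16S surveys — generated once with
a fixed seed and shipped as plain text. They are not estimates from any
real survey.

**The mixing rule.** How the mixture weight depends on the exposure is the
largest open interpretive decision in this design. The default draws a
population label per subject, $w_i \sim \mathrm{Bernoulli}(
\mathrm{logistic}(\alpha x_i))$: each subject's community comes from one of
the two populations, and $\alpha$ controls how strongly the exposure tilts
that assignment. This keeps $\beta$ a real mediator-to-response path even
at $\alpha = 0$ (labels still vary across subjects), exactly mirroring the
role of $\beta$ in the single-mediator design, and it makes the $\alpha =
0$ cells proper mediation nulls with a live $M$–$Y$ association — the
regime in which the adaptive permutation test is calibrated. The
deterministic alternative $w_i = \mathrm{logistic}(\alpha x_i)$
(`mixing = "logistic"`) is also provided; note that at $\alpha = 0$ it
collapses every subject to $w = 1/2$, severing the $\beta$ path and
producing the *complete* null, under which the adaptive scheme is
structurally conservative (the permuted-factor draws dominate an observed
statistic built from the selected-smaller factor). Any
`function(alpha, x)` returning weights in $[0,1]$ can be swapped in.
Per-subject overdispersion is interpolated with the same weight as the
mean composition, the simplest rule consistent with the mixture reading;
under the default Bernoulli rule each subject simply carries its source
population's $\theta$. The response is
$y_i = \gamma x_i + \beta w_i + \varepsilon_i$ with
$\mathrm{SD}(\varepsilon) = 0.01$, tying $\beta$ to the latent composition
signal rather than to multinomial sampling noise.

`fit_dm()` estimates $(\pi, \theta)$ by method of moments — pooled
proportions for $\pi$, the excess of between-sample proportion variance
over the multinomial expectation for $\theta$, clamped to $[0, 1)$.
Parameter recovery (200 samples at depth 5000: $\pi$ within $L_1 \le
0.05$, $\theta$ within $\pm 0.05$) is part of the acceptance suite.
`random_rooted_tree()` produces random rooted bifurcating topologies with
Exponential(1) branch lengths, the construction used for the 21-tip
UniFrac simulations.

## The simulation grid

`run_grid()` crosses $\alpha, \beta, \gamma, n$, simulates `n_datasets`
datasets per cell, applies the requested tests with `q` permutations, and
reports the fraction of p-values below the threshold (0.05 by default) as
a tidy tibble; `autoplot()` draws the rejection-rate curves. All
randomness descends from one master seed through a two-level stream
(per-cell seeds, then per-dataset seeds), so any cell reproduces
independently of which other cells run. The package's working scales —
chosen so that a full calibration check runs in minutes on one CPU — are
a few hundred datasets per cell with $q = 99$ for grid work and $q = 199$
for single-cell calibration runs; the full published-scale grid
($5 \times 5 \times 4$ parameter points, five sample sizes, 1000 datasets,
$q = 999$) is available through the command-line `grid --preset full`.

```{r grid-example}
g <- run_grid(alpha = c(0, 1), beta = 1, gamma = 0, n = c(20, 50),
              n_datasets = 30, q = 49, seed = 1)
g
```

## What the simulations do and do not show

The generators reproduce the *structure* the method targets — linear
Gaussian paths in the univariate design; compositional, overdispersed,
phylogenetically structured counts whose composition drifts with the
exposure in the mixture design. They do not reproduce several features of
real surveys: rarefaction and uneven depths, sparsity far beyond what a
21-taxon table exhibits, taxon-specific dynamics that a single global
$\theta$ cannot capture, or measured confounders. A calibrated type-I
error on these designs therefore supports, but does not prove, calibration
on a particular real dataset; metric choice remains the analyst's
responsibility, and the package deliberately accepts any precomputed
distance matrix.

Two caveats are inherent to the statistic itself and are reproduced by the
acceptance suite rather than hidden. First, zero partial distance
correlation is not conditional independence: with $M$ and $Y$ independent
linear combinations of a shared $X$, $\mathrm{pdCor}(M, Y; X)$ is
strictly positive even asymptotically. Second, and as a consequence, under
$\beta = 0$ with a strong direct path ($\alpha = 1$, $\gamma = 0.5$) the
test over-rejects at large $n$ in the univariate design — a known
inflation regime, not a bug; the mixture design does not exhibit it.

## Numerical and degenerate-input conventions

* Distance matrices are validated on construction (symmetry to 1e-12 on
  build, 1e-8 on file read with an opt-in symmetrize-by-averaging), the
  diagonal is forced to exact zeros, and sample ids must align exactly
  across the three matrices of a test — `align_samples()` reorders inputs
  to the sorted common id set so results never depend on file order.
* U-centering requires $n \ge 4$ (its denominators degenerate below that);
  the V-statistic centering requires $n \ge 2$.
* All-zero samples are rejected by the proportion-based metrics; a pair of
  empty samples is rejected by Jaccard.
* `sample_dm()` at $\theta = 0$ takes the exact multinomial branch rather
  than a limit of the Dirichlet draw.
* Every user-facing stochastic function takes an explicit integer seed;
  fixed seed plus fixed inputs give byte-identical results, and the test
  suite asserts this for the tests, the generators, and the CLI reports.

## Known limitations

The statistic operates on one distance metric at a time; pooling evidence
across metrics (test-and-adjust is the interim workaround) is out of
scope, as are small-p refinements by extreme-value fits to the permutation
trace, effect decomposition into natural direct/indirect effects, and
per-taxon attribution of an omnibus mediation signal — a significant
omnibus result belongs to the joint composition, not to any single taxon.
The $O(n^2)$ memory of the centered matrices makes $n$ in the low
thousands the practical ceiling.
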