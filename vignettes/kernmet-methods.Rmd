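---
title: "Models, kernels and design choices in kernmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, kernels and design choices in kernmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kernmet` implements kernel-based whole-genome prediction for
multi-environment trials (MET): additive and dominance marker effects,
environmental main effects derived from envirotyping data, and their
interactions, fitted in a hierarchical Bayesian framework. This vignette
is the package's own account of the science: the model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## 1. The model family

For `p` hybrids evaluated in `q` environments (at most one record per
hybrid-environment pair), the most complete structure is

$$
\mathbf{y} = \mathbf{1}\mu + \mathbf{Z_E\beta} + \mathbf{Z_G u_A} +
\mathbf{Z_G u_D} + \mathbf{u_W} + \mathbf{u_{AW}} + \mathbf{u_{DW}} +
\boldsymbol\varepsilon ,
$$

with environment effects $\beta$ fixed (reference-coded indicators, first
environment as reference, flat prior) and every $\mathbf{u}$ a zero-mean
Gaussian whose covariance is an observation-level expansion of an
entity-level kernel:

| term | covariance (observation level) | meaning |
|------|-------------------------------|---------|
| A    | $Z_G K_A Z_G'$ (equivalently $J_q \otimes K_A$ for balanced data) | additive main effects |
| D    | $Z_G K_D Z_G'$ | dominance deviations |
| W    | $Z_E K_W Z_E'$ | environmental main effect from envirotype similarity |
| AE, DE | $(Z_E I_q Z_E') \odot (Z_G K Z_G')$ | genotype-by-environment interaction, environments unrelated |
| AW, DW | $(Z_E K_W Z_E') \odot (Z_G K Z_G')$ | reaction norm: interaction weighted by envirotype similarity |

The five model names expose nested subsets: `EA`, `EAD`, `EAD+GE`
(A, D, AE, DE), `EADW` (A, D, W), `EADW+GW` (A, D, W, AW, DW).

Incidence-matrix expansions are used instead of Kronecker forms so that
unbalanced and sparse data (required by CV2) are handled uniformly;
internally every term is stored in factored form (a $q \times q$
environmental part and a $p \times p$ genomic part), which the constructors
`main_effect_cov()`, `env_main_cov()` and `interaction_cov()` materialize
on demand.

## 2. Marker codings

Additive design: dosages 0/1/2 of the counted allele, column-centered by
$2f_l$ (VanRaden-style). Centering does not change the trace-normalized
linear kernel's ranking behaviour, but it makes scales comparable across
markers; a `center = FALSE` switch returns raw dosages.

Dominance design: the orthogonal coding of Vitezica et al. (2013),
$\{0 \mapsto -2f^2,\; 1 \mapsto 2f(1-f),\; 2 \mapsto -2(1-f)^2\}$, which
has zero mean under Hardy-Weinberg weights for every $f$. Some published
restatements of this coding contain sign/exponent typos that break the
zero-mean identity; the package tests the identity explicitly on a grid of
allele frequencies.

Markers with minor allele frequency at or below 0.05 are removed
(`maf_filter()`, strict "less than or equal"); missing dosages must be
mean-imputed explicitly (`impute_dosages()`), with the imputation count
logged.

## 3. The three kernel methods

**GB** (benchmark linear kernel): $K = XX' / (\mathrm{trace}(XX')/n)$, so
$\mathrm{trace}(K) = n$ and the kernel is invariant to rescaling of $X$.

**GK** (Gaussian): $K_{ii'} = \exp(-h\, D^2_{ii'} / Q)$ where $D^2$ is the
squared Euclidean distance and $Q$ the median of its strictly off-diagonal
entries. Two decisions deserve note. First, the exponent is negative:
covariance must decay with distance and the unit diagonal must be the
maximum; the occasionally printed positive-exponent form contradicts both.
Second, $Q$ excludes the diagonal zeros, so $Q > 0$ whenever at least two
rows differ; identical-row inputs (zero median distance) are an error
rather than a silent division by zero.

**DK** (arc-cosine / "Deep"): the base kernel
$DK^1(x, x') = \frac{1}{\pi}\lVert x\rVert\,\lVert x'\rVert\, J(\theta)$,
$J(\theta) = \sin\theta + (\pi - \theta)\cos\theta$, is the covariance of
an infinitely wide one-hidden-layer ReLU network; it preserves norms
($DK(x,x) = \lVert x\rVert^2$) and maps antipodal vectors to zero. Layers
are added by the standard recursion, which preserves the diagonal exactly.
The inner-product ratio is clamped to $[-1, 1]$ before `acos` to absorb
floating-point drift.

### Kernel scale and the prior

The raw arc-cosine diagonal is on the scale of $\lVert x \rVert^2$, i.e.
roughly the number of markers, whereas GB and GK have mean diagonal 1.
Because the sampler's default prior scale is shared across terms (see
section 5), `run_grid()` rescales DK kernels to mean diagonal 1. Dividing
a kernel by a scalar is an exact reparameterization (the variance
component absorbs it) and preserves the relative diagonal heterogeneity
that distinguishes DK from GK; `normalize_kernel()` itself is never
applied automatically elsewhere.

### Hyperparameter selection

The bandwidth $h$ (default grid $\{0.1, 0.25, 0.5, 1, 2, 5\}$) and the
layer count $l$ (1..`l_max`) are selected by maximizing the restricted
likelihood of the single-kernel model $y = 1\mu + u + e$,
$u \sim N(0, K\sigma^2_u)$, profiled over $\mu$ and the total variance and
maximized over a wide grid of variance ratios via the kernel
eigendecomposition. Ties break toward the smaller hyperparameter (smoother
kernel). In cross-validation the selection uses training records only
(hybrid means for genomic kernels, environment means for $K_W$);
`run_grid(tune = )` chooses between per-fold re-selection (default),
one-time selection, and none. Two caveats found while validating the
procedure: selection needs structured (related) rows — on exchangeable
iid-noise inputs all bandwidths give nearly affine-equivalent kernels and
the likelihood is flat — and it needs a few hundred entities before the
mode concentrates on the generating value.

## 4. Envirotyping

Daily per-environment series (16 weather and derived ecophysiological
variables in the bundled schema; any pre-computed variable set is
accepted) are summarized per phenology interval. The default intervals,
in days after emergence (DAE), are 0–14, 15–35, 36–65, 66–90, 91–120,
matching tropical-maize phenology from emergence to physiological
maturity. The day convention is explicit: 1-based and inclusive, so
"0–14" covers day-of-cycle indices 1–14. For each variable-interval
combination the 25th, 50th and 75th percentiles (type-7, the common
linear-interpolation estimator) become candidate covariables; management
descriptors (e.g. nitrogen applied) can be appended as single extra
columns per variable.

Quality control then (i) drops zero-variance columns, (ii) centers and
scales the rest to unit SD across environments, and (iii) drops any
column containing a standardized entry with $|z| > 3$. One consequence
worth knowing: with $n$ environments the largest attainable standardized
value is $(n-1)/\sqrt{n}$, so the outlier screen cannot fire at all for
$n \le 9$ and is weak for typical MET sizes — it matters for large
environment networks. The package's tests construct the analytic spike
cases accordingly (a single spike among 26 environments standardizes to
4.9).

## 5. The eigen-reparameterized Gibbs sampler

Every term covariance restricted to the training records is
eigendecomposed, $K = USU'$, keeping eigenvalues above `1e-8` times the
largest. With coefficients $b = U'u$ the full conditionals factorize:

* fixed effects: multivariate normal (flat prior), via a Cholesky solve of
  $X'X$;
* eigenbasis coefficients of each term: independent normals with prior
  variance $\sigma^2_t s_i$ against the current partial residual;
* each $\sigma^2_t$ and $\sigma^2_\varepsilon$: scaled-inverse-$\chi^2$
  with $\nu = 5$ and scale $\mathrm{Sc} = \mathrm{var}(y_{\text{train}})/2$
  by default (weakly informative, overridable; `fix_variances` holds chosen
  components constant, which is how the package is validated against the
  closed-form ridge solution).

Defaults: 10 000 iterations, 1 000 burn-in, thinning 2 (saved iterations
are `burn_in + thin, burn_in + 2*thin, ...`); the chain is bit-reproducible
under a fixed seed. Split-half means and autocorrelation-based effective
sample sizes per variance chain are reported in `fit$diagnostics`.

When the training set is a complete environment-by-hybrid grid (always
true for CV1 and CV0 folds of balanced trials), each factored term's
observation covariance is exactly a Kronecker product, and its eigenpairs
are Kronecker products of the factor eigenpairs. The solver detects this
and eigendecomposes the small factors instead of the $n \times n$
expansion — an exact shortcut, asserted against the dense path in the
tests, that dominates the speed of the full evaluation grid.

Masked records contribute nothing to the likelihood. Their predictions are
$\hat\mu + \hat\beta_{env} + \sum_t K_t[\text{target},\text{train}]\,
U_t S_t^{-1} \bar b_t$ — the conditional-mean propagation of each term
through its covariance, evaluated at posterior means (the predictions are
linear in $b$, so averaging $b$ over draws is exact). For an environment
absent from training (CV0), $\beta$ for that environment is inestimable;
the package uses the average of the training environments' fixed values,
so that only W/AW/DW terms carry environment-specific signal into a new
environment. This averaging rule is a documented assumption, not forced
by the model.

### What is and is not identified

Two soft spots of this model family, established empirically with the
package's own generator (truth simulated from `EADW+GW`, `p = 200`,
`q = 6`, GB kernels) and worth understanding before interpreting variance
partitions:

* $\sigma^2_W$ is structurally non-identified whenever fixed environment
  effects are in the model: $u_W$ varies only across the $q$ environments
  and the flat-prior fixed effects already span that space, so the
  likelihood carries no information about the split and the $\sigma^2_W$
  posterior tracks its prior. The model family itself pairs fixed
  environment effects with the W term, so this is inherited, not
  introduced; predictions are unaffected (the sum of the two parts is
  identified).
* The interaction variances (especially DW at small $q$) are only weakly
  separated from residual noise when the genomic kernel has weak
  off-diagonal structure: $K_W \otimes K_D$ then looks like heterogeneous
  white noise on each environment block. Posterior means of
  $\sigma^2_{DW}$ were inflated by roughly +0.15 to +0.2 (absolute) at
  truth 0.25 in the recovery experiments, with the residual compensating
  downward. The sampler itself is unbiased on well-identified single-term
  worlds (verified against ridge and naive-Gibbs oracles); this is
  collinearity of the covariance structures, not a sampler defect. The
  corresponding acceptance assertion is left red with this analysis
  rather than loosened.

## 6. The synthetic-data generator

The generator states a world resembling a tropical single-cross MET
program:

* Parents are fully inbred lines, so F1 hybrid dosages are deterministic
  parental-allele sums in {0, 1, 2}. Per-marker allele frequencies are
  drawn from `maf_range` (default 0.1–0.5); markers monomorphic across
  the sampled hybrids are redrawn, mimicking a post-QC panel.
* Weather is a seasonal sinusoid plus environment offsets plus Gaussian
  noise per variable — just enough structure to give environments
  distinguishable envirotypes. It does not emulate storms, autocorrelated
  dry spells, or cross-variable physical constraints; downstream math only
  sees centered/scaled interval percentiles, so a green test establishes
  pipeline correctness, not meteorological realism.
* Phenotypes are drawn exactly from the model above, restricted to terms
  with positive configured variance (defaults: A = 1, D = 0.5, W = 0.5,
  AE = 0.5, DE = 0.25, AW = 0.25, DW = 0.25, residual = 1, grand mean
  7 t/ha, environment offsets evenly spaced on [-1, 1] t/ha — a
  moderately heritable yield-like trait with meaningful GxE). The ground
  truth (every term's effect vector) is returned for oracle-style
  checks.
* An optional `nonlinear` switch adds pairwise multiplicative marker
  interactions (target variance `nonlinear_variance`) to the genetic
  value, for exercising the claim that nonlinear kernels capture
  non-additive signal; it is off by default.
* No linkage disequilibrium beyond parent-sharing, no multi-generation
  pedigree, no trait networks.

Generator determinism: the genotype, weather and phenotype stages use the
configured seed plus fixed offsets (0, 1, 2), so stages are individually
reproducible and mutually decorrelated.

For the directional comparison of kernel methods (nonlinear kernels
should beat the linear benchmark when the architecture is nonlinear), the
stated world draws the genetic covariances from a Gaussian kernel with
`h = 5` — a sharply local similarity that the linear kernel cannot
represent — with substantial AE+DE variance. Under that world, both GK
and DK exceed GB in mean CV2 predictive ability across ten seeds.

## 7. Cross-validation and statistics

* **CV1** (new hybrids): samples $\lceil 0.7\,p\rceil$ hybrids per
  repetition; all their records train, every record of the remaining
  hybrids tests. The common phrasing "70% of phenotypic information"
  conflicts with hybrid exclusivity for unbalanced data; sampling hybrids
  is the reading that keeps test hybrids fully unseen.
* **CV2** (sparse testing): samples $\lceil 0.7\,n\rceil$ records.
* **CV0** (new environments): deterministic leave-one-environment-out.

Predictive ability is the Pearson correlation between observed and
predicted test values, per fold (CV1/CV2) or per left-out environment and
then averaged (CV0). Undefined correlations (constant vectors, fewer than
three pairs) are excluded from averages and logged, never coerced to
zero. The standard error applies the train/test-size correction
$SE = SD \sqrt{1/n + n_2/n_1}$. Genotype-level resolution (per-hybrid
correlation across environments, CV0) is summarized by a typology
histogram over the bins
$\le 0,\ (0,.25],\ (.25,.50],\ (.50,.75],\ (.75,1]$.

## 8. Known limitations

* Homogeneous residual variance across environments; single trait.
* No epistasis-specific kernels; the nonlinear generator switch is a
  stress test, not a model term.
* CV0's fixed effect for the unseen environment is an averaging
  convention (above).
* The 3-SD covariable screen is inert for small environment networks
  (section 4).
* Variance partitions involving W and small-$q$ interactions should be
  read qualitatively (section 5).
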