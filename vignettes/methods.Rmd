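---
title: "Feature-engineered environmental covariates in multi-kernel genomic prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

A multi-environment trial observes trait values $Y_{ij}$ for genotype $j$ in
environment $i$; leave-one-environment-out (LOEO) cross-validation asks the
model to predict a *whole environment* from the others. Under the base model

$$Y_{ij} = \mu + E_i + g_j + (gE)_{ij} + \varepsilon_{ij},$$

the environment main effect $E_i$ of the held-out environment is the crux.
With an identity environment kernel (the NoEC strategy) the held-out
environment shares no covariance with training environments, so its main
effect is unpredictable and shrinks to zero. Environmental covariates —
weather and soil summaries measured once per environment, available for the
test environment because they do not involve the response — give the kernel
off-diagonal structure that lets $E_{test}$ borrow from similar environments.
This package implements and evaluates three variants of that kernel: NoEC,
EC (selected raw covariates), and FE (selected covariates after a
feature-engineering expansion).

## Kernels

* Genomic: $G = MM^\top/p$ with each marker column centered and divided by
  its **sample** standard deviation (denominator $J-1$). The diagonal of $G$
  then averages $(J-1)/J \approx 1$. Monomorphic columns cannot be
  standardized and are dropped, adjusting $p$. Observation-level expansion:
  $K_g = Z_g G Z_g^\top$.
* NoEC: $K_E = X_E X_E^\top / I$, entries $1/I$ for observations sharing an
  environment.
* EC / FE: $K_{EC} = W_{sel} W_{sel}^\top / q_{sel}$ on the standardized
  selected covariates, expanded as $X_E K_{EC} X_E^\top / I$. The divisor
  $q_{sel}$ is chosen by analogy with the marker divisor $p$ in $G$; only
  the $/I$ on the expansion is prescribed by the method description, so the
  inner normalization is this package's documented choice. Any positive
  divisor rescales $\sigma_E^2$ without changing the fitted predictions.
* Genotype-by-environment: the Hadamard product $K_g \circ K_E$, positive
  semidefinite by the Schur product theorem.

Numerical conventions: kernels must be symmetric to $10^{-10}$ (relative)
and eigenvalues above $-10^{-8}\lambda_{max}$; anything in
$(-10^{-8}\lambda_{max}, 0)$ is treated as rounding noise, anything lower is
an error. Rank truncation inside the sampler drops eigenvalues below
$10^{-10}\lambda_{max}$.

## Feature engineering

For original covariates $x_1,\dots,x_q$ the FE candidate set concatenates,
in a deterministic order (originals, pairwise blocks in pair × operation
order, unary blocks in column × operation order):

* for every unordered pair $\{a,b\}$ (one direction per pair): $a+b$, $a-b$,
  $a\cdot b$, and $a/b$ when every $|b| >$ `zero_tolerance` ($10^{-12}$);
* per covariate: $x^2$ always; $1/x$ when bounded away from zero;
  $\sqrt{x}$, $\ln x$, and Box-Cox $(x^\lambda - 1)/\lambda$ when $x > 0$.

Ineligible transforms are skipped, never shifted: a data-dependent shift
would have to be estimated per training set and is a leakage risk, while a
skipped column is simply absent from the candidate set. The default Box-Cox
set is $\lambda \in \{0.25, 0.75, 1.5\}$ (configurable): $\lambda \in
\{-1, 0.5, 2\}$ duplicate the inverse/sqrt/square transforms up to an affine
map, and Pearson-based selection is invariant to affine maps, so including
them would only create exact-duplicate candidates. The upper bound on the
candidate count is $q + 4\binom{q}{2} + q(4 + |\lambda|)$.

## Covariate selection

Selection is re-run independently for every fold and trait. Each candidate
column is paired with the trait at the observation level (every training
observation carries its environment's covariate value) and scored by Pearson
correlation; environment-mean correlation on $I-1 \le 4$ points would be
near-degenerate for the smallest trials, which is why the observation level
was chosen. Thresholds are walked in order $0.5 \to 0.4 \to 0.3$: the first
threshold met by at least one column (on $|r|$, ties inclusive) wins, and
all columns meeting it are selected; a strongly negative covariate is as
informative as a positive one for a linear kernel, hence $|r|$ rather than
signed $r$. If nothing reaches 0.3 the fold degrades to NoEC. The held-out
environment is excluded from every correlation, so selection is invariant to
arbitrary changes of test-environment responses (a property the test suite
checks directly). Scaling statistics (mean, sample sd) use all $I$
environments: covariates are known for the test environment and its kernel
row must be built, and no response value is involved.

## The Gibbs sampler

The model $y = \mu + \sum_k u_k + X\beta + \varepsilon$, $u_k \sim N(0,
\sigma_k^2 K_k)$, $\beta \sim N(0, \sigma_\beta^2 I)$, is sampled by
rotating each kernel term: with $K_k = V D V^\top$, set $\Gamma_k =
V D^{1/2}$, so $u_k = \Gamma_k \delta_k$ with $\delta_k \sim N(0, \sigma_k^2
I)$ and $\Gamma_k^\top \Gamma_k = D$ diagonal — the whole block's Gaussian
full conditional factorizes into independent coordinates and is sampled
jointly and exactly. The ridge block $\beta$ is sampled jointly via the
Cholesky factor of its full-conditional precision. Variance components get
scaled-inverse-$\chi^2$ full conditionals with prior df 5 and prior scales
set so the prior mode equals $R^2 \cdot var(y_{obs})/n_{terms}$ per model
term and $(1-R^2)\cdot var(y_{obs})$ for the residual, with $R^2 = 0.5$ —
the standard weakly-informative default in Bayesian whole-genome regression
software. The intercept has a flat prior. Although the covariates enter the
BRR block under the name "fixed effects" in common usage, they carry a
Gaussian prior with their own variance $\sigma_\beta^2$ — that is what
Bayesian ridge regression means, and it is what is implemented.

Missing responses (including every held-out observation) are data-augmented:
sampled each iteration from $N(\eta, \sigma^2)$, so they participate in the
kernel rotations but contribute no likelihood information. Predictions are
posterior means of the linear predictor $\eta$ over kept samples. Defaults:
10000 iterations, 1000 burn-in, thinning 5; the test suite and examples use
shorter chains (200–2000 iterations) because the factorized updates mix
quickly at the problem sizes involved; convergence of $\sigma^2$ is
monitored by a split-chain potential scale reduction factor with a warning
above 1.1. Fits are bit-reproducible given the seed; cross-validation
derives fold seeds as `seed + fold`.

With all variances fixed, the posterior mean of each $u_k$ has the closed
form $\sigma_k^2 K_k \tilde P y$ ($\tilde P$ the GLS projection that profiles
out $\mu$); the test suite uses this as an independent oracle for the
sampler at $n \le 50$ and 20000 iterations.

Degenerate inputs: a constant response collapses to its mean with variances
at their prior scale; a covariate with zero variance is dropped from
selection; a fold whose test environment has fewer than 3 observations still
yields an MSE but logs a warning.

## Evaluation

One fold per environment with data; test MSE per (predictor, strategy,
trait, fold); relative efficiencies $RE_{A\,vs\,B} = MSE(A)/MSE(B)$ per
fold, so the chain identity $RE_{NoEC\,vs\,FE} = RE_{NoEC\,vs\,EC} \cdot
RE_{EC\,vs\,FE}$ holds exactly row by row. `Across` rows are arithmetic
means of per-environment REs — the aggregation that reproduces the published
summary tables bundled in `reference_re_tables()` (the package's acceptance
checks verify this cell by cell; five of 108 printed cells differ by one
unit in the third decimal because the source averaged REs before rounding).
The per-predictor summary averages Across REs over traits unweighted, then
appends an `Average` row over predictors; when several datasets are
summarized together the same unweighted mean is applied dataset-wise — a
documented convention, since the published across-dataset aggregation does
not state its trait weighting. Pearson correlation is deliberately not
offered as an accuracy metric; the evaluation design is MSE-based
throughout.

## The synthetic generator and what the tests show

`simulate_met()` draws binomial marker dosages (allele frequencies uniform
on 0.1–0.5), additive genotype effects $g = \tilde M \alpha$ with $\alpha
\sim N(0, \sigma_g^2/p)$, i.i.d. standard-normal covariates, environment
effects equal to a configured signal (linear combination, pairwise product,
or independent noise) plus ~10%-variance noise rescaled so the sample
variance hits `var_env` exactly, i.i.d. interaction and residual effects,
and an optional fraction of deleted cells for unbalance. It emulates the
*statistical* structure the method assumes — it does not emulate linkage
disequilibrium, pedigree structure, weather autocorrelation, or covariate
collinearity. Passing tests therefore demonstrate correctness of the
machinery and the designed qualitative contrasts, not field performance.

Scenario conditions used by the test suite (chosen once as realistic signal
shares, not tuned):

* **Product scenario** (FE benefit): $I = 8$, $J = 30$, $q = 6$, variances
  (env, geno, ge, resid) = (1.5, 0.5, 0.25, 0.75), so the environment share
  of variance is 0.5 and the true product column's observation-level
  correlation is ~0.65. Note that for a self-product signal $E \propto
  w_1 w_2$, the sample correlation of $w_1$ itself with $y$ has sd
  $\approx\sqrt{3/I}$ — it is bounded away from zero at any realistic $I$ —
  so the meaningful property is that the engineered product column dominates
  every raw covariate, not that raw correlations vanish.
* **Null scenario** (calibration): $I = 8$, $J = 20$, env share 0.18 and no
  covariate signal; all three strategies should agree within sampling noise.
* **Variance recovery**: $J = 100$, $I = 5$, components drawn from the model
  kernels themselves. The recovery study uses 50 markers so the genomic
  relationship has off-diagonal dispersion ~0.14, comparable to related
  breeding germplasm. This matters: at one observation per (environment,
  genotype) cell the GE variance is identified *only* through genomic
  covariance among lines within an environment. In the unrelated limit
  (thousands of i.i.d. markers, $G$ off-diagonals $\sim N(0, 1/p)$) the
  GE/residual decomposition is likelihood-flat and the posterior follows the
  prior — a genuine non-identifiability of the design, not a sampler defect,
  and a caveat for interpreting GE variance components from sparse real
  trials as well.

Heritability is reported on the line-mean basis $h^2 = \sigma_g^2 /
(\sigma_g^2 + \sigma_{gE}^2/\bar n_E + \sigma^2/\bar n_E)$ with $\bar n_E$
the mean number of environments per line, using posterior means of the
*realized* (observation-level) variance of each effect vector; realized
variances are also what the recovery tests compare, since they are the
estimands the data constrain.

## Known limitations

* Ratios and differences are built in one direction per pair; a reversed
  ratio is a distinct nonlinear candidate that is deliberately not included
  to keep the candidate count at the documented bound.
* Selection controls no multiplicity; with thousands of engineered
  candidates and few environments, spurious selections at the 0.3 threshold
  are expected, and the LOEO comparison — not the selection — is the
  safeguard.
* The sampler is single-chain; the split-chain PSRF is a coarse diagnostic.
* Marker QC and imputation are out of scope; dosages must be complete 0/1/2.
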