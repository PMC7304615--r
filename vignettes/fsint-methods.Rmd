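---
title: "Rank-based inverse normal transformation tests for quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based inverse normal transformation tests for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsint)
```

## The problem

Single-variant tests for quantitative traits are usually run in the linear
model

$$ y = X\alpha + g\beta + \varepsilon, \qquad H_0{:}\ \beta = 0, $$

with $y$ the trait, $X$ an $n \times p$ covariate design (intercept
included), and $g$ an additive dosage in $\{0, 1, 2\}$. The Wald, partial-F
and score tests for $\beta$ all assume approximately normal errors. Real
traits are skewed and outlier-prone, and the resulting miscalibration is
worst exactly where sequencing studies care most: rare variants, where the
test statistic is driven by a handful of carriers.

The rank-based inverse normal transformation (INT)

$$ \mathrm{RN}(v_i) = \Phi^{-1}\!\left(\frac{\mathrm{rank}(v_i) - c}{n}\right),
\qquad c \in (0, 1/2], $$

replaces values by the normal quantiles of their ranks. `fsint` implements
it with the conventional offset $c = 1/2$ and denominator $n$, so the
probabilities live in $[0.5/n,\, 1 - 0.5/n]$ and the output is always
finite. (The Blom-style denominator $n - 2c + 1$ is available through
`denominator = "blom"` for comparison, but the default follows the form
above.) Ranks are ascending and 1-based; ties — impossible for continuous
residuals but common in real data — get average ranks by default so equal
inputs map to equal outputs.

## The test families

Eight procedures share the `sample_data` $\to$ `assoc_result` interface and
are dispatched by key (`assoc_methods()`):

* **d-int** — *direct*: INT the trait itself, then Wald-test $\beta$ in a
  joint regression on $[X, g]$.
* **pts-int** — *partly adjusted two-stage*: INT the residuals of $y$ on
  $X$, then score-test $g$ adjusting only the intercept. Under
  genotype–covariate correlation this deflates type I error and loses
  power; it is included as the historical baseline.
* **ts-int** — *fully adjusted two-stage*: as above but the second-stage
  score test re-adjusts the same $X$.
* **i-int** — *indirect*: INT the stage-1 residuals, residualize $g$ on
  $X$, and score-test the transformed residuals against the genotype
  residuals.
* **o-int** — *omnibus*: combine the direct and indirect p-values.
* **fs-int** — *fully adjusted full-stage*: the centrepiece, described
  below.
* **skat-score** — the plain covariate-adjusted score test
  $U = g^\top\hat\varepsilon$, $V = \hat\sigma^2 g^\top(I - H)g$,
  $U^2/V \sim \chi^2_1$. For a single variant this is exactly the p-value a
  kernel (SKAT-type) test produces, whatever the per-variant weight, so it
  stands in for that column of the comparison.
* **mr** — median ($\tau = 0.5$ quantile) regression of $y$ on $[X, g]$.
* **yjpt** — Yeo-Johnson power-transform regression: $\lambda$ by profile
  maximum likelihood under the full model, then a Wald test on the
  transformed scale.

### The full-stage procedure

The two-stage test implicitly assumes that the INT-transformed residuals
are (close to) normal with mean zero. After the rank transform they are
marginally normal by construction, but they need not be *independent of the
covariates*: transforming residuals re-introduces covariate structure
whenever the raw residual distribution is far from normal (heavy outliers,
strong skew). The full-stage procedure iterates the correction away:

1. Residualize $y$ on $X$, apply the INT.
2. Regress the transformed residuals on $X$ and look at the covariate
   p-values (the *screen*).
3. While any screened p-value is below `screen_alpha` (default 0.05):
   re-residualize on $X$, re-apply the INT, and re-screen; stop early when
   the covariate coefficient vector changes by less than `coef_tolerance`
   (sup-norm, default $10^{-6}$) between successive transforms, or when
   `max_iterations` (default 100) is reached (the result is then flagged
   `converged = FALSE`; the cap exists only to guarantee termination and is
   not reached in practice — one to three iterations are typical).
4. Score-test the final transformed residuals against $g$, adjusting $X$.

When the first screen already passes, the procedure *is* the fully adjusted
two-stage test, bit for bit, with `iterations = 0` — the reduction the
package asserts in its tests.

Two details of the screen were genuinely open and are package decisions,
both switchable. First, the intercept is excluded by default
(`include_intercept_in_screen = FALSE`): the transformed residuals are
symmetric about zero by construction, so its p-value carries no signal.
Second, multiple covariates are screened at an unadjusted 0.05 each
(any-one rule), with no multiplicity correction — the rule as stated, not
an omission.

### Omnibus combination

The combination rule for **o-int** is the Cauchy (ACAT) combination with
equal weights: $T = \tfrac12\sum_j \tan\{(1/2 - p_j)\pi\}$ and
$p = 1/2 - \arctan(T)/\pi$. It is exact under the null for arbitrary
dependence between the two component tests, needs no resampling, and has a
closed form the tests can verify by independent arithmetic. The reference
description of the omnibus test does not pin down its combination rule, so
this is the single most likely point of divergence from reference numbers
for the omnibus column; none of the package's quantitative checks depend
on it.

### Median regression

No quantile-regression fitter ships with the package's dependency stack,
so the LAD fit is implemented in-package: iteratively reweighted least
squares on the smoothed $|r|$ objective (coefficient sup-norm tolerance
$10^{-6}$, well below any usable standard error). Default inference is the
classical iid route: sparsity $s(\tau) = 1/f(F^{-1}(\tau))$ estimated by a
difference quotient of the residual quantile function at the Hall–Sheather
bandwidth, $\mathrm{var}(\hat\beta) = \tau(1-\tau)s^2 (Z^\top Z)^{-1}$. For
sparse designs — fewer than `min_carriers = 20` carriers, or a degenerate
sparsity estimate — the fit switches to a pairs bootstrap (`B = 1000`),
the switch quantile-regression practitioners make when the default
standard errors cannot be trusted at ultra-sparse designs.
Resamples that lose the carriers entirely are rank-deficient and are
dropped; if fewer than half survive, the result is flagged rather than
trusted.

### Yeo-Johnson regression

The four-branch transform $\psi(y; \lambda)$ is exact at the identity
($\psi(y; 1) = y$) and log branches. $\lambda$ is profiled over $[-5, 5]$
by golden-section search on the Gaussian profile log-likelihood
$-\tfrac n2 \log(\mathrm{RSS}(\lambda)/n) + (\lambda - 1)\sum_i
\mathrm{sign}(y_i)\log(1 + |y_i|)$, with the design QR factorized once.
Estimating $\lambda$ under the *full* model (including $g$) is the
default; under $\beta = 0$ the difference from null-model estimation is
negligible, and the alternative is exposed as `null_model = TRUE`. The
implementation agrees with `car::powerTransform(..., family = "yjPower")`
to at least five decimals on identical data, which the test suite checks.

## Numerical choices

* All least squares go through QR factorizations; no $X^\top X$ inverse is
  formed except the $p \times p$ diagonal needed for covariate standard
  errors, taken from the R factor with pivoting honoured. Designs with
  condition number above $10^8$ warn; rank-deficient designs fail naming
  the collinear columns.
* $\hat\sigma^2$ uses the unbiased denominator $n - p$. The score statistic
  scale depends on this choice, so it is stated rather than implied.
* A monomorphic or fully covariate-explained genotype
  ($g^\top(I-H)g \approx 0$) cannot carry association signal: every method
  returns $p = 1$ with a `degenerate_genotype` flag instead of erroring.
  In simulations these replicates stay in the denominator as
  non-rejections — conservative, and it keeps replicate counts fixed — and
  the tally is reported so the exclusion policy can be recomputed from the
  same output.
* The score test uses the large-sample $\chi^2_1$ reference (the
  rare-variant convention); Wald and partial-F use their finite-sample
  $t$/$F$ references. The identity $t^2 = F$ is asserted to $10^{-10}$
  relative in the tests.
* The INT with $c = 1/2$ needs no probability clamping; $c = 0$ would send
  the top rank to $\Phi^{-1}(1) = \infty$ and is rejected loudly rather
  than clamped.

## The simulation engine

`sim_scenario()` encodes one cell of the study design:

$$ y_i = 0.5\,x_{i1} + 0.5\,x_{i2} + g_i\beta + \varepsilon_i, $$

with $x_{i1} \sim N(0,1)$, $x_{i2} \sim \mathrm{Bernoulli}(1/2)$, and
$g_i \sim \mathrm{Binomial}(2, p_i)$ where
$p_i = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 x_{i1})$. $\gamma_0 \in
\{-7, -4.5, -2\}$ spans minor allele frequencies from 0.0009 to 0.1192;
$\gamma_1 \in \{0, 1, 2\}$ spans none-to-strong genotype–covariate
confounding. Four error regimes: normal with sd 1 or 0.01; a 99:1 mixture
of $N(0, 0.01^2)$ and $N(0, 3^2)$ (the outlier regime); $\chi^2_2$; and
$\mathrm{Gamma}(0.1, 0.1)$. Skewed errors enter *uncentred* — the analysis
intercept absorbs their mean — and the generative model has no intercept
while the analysis design $[1, x_1, x_2]$ always includes one.

Type I error is the rejection fraction at `nominal_alpha` over replicates
with $\beta = 0$; power uses $\beta = 0.0012$. Each replicate draws fresh
covariates, genotype and errors, and runs on its own L'Ecuyer-CMRG RNG
substream derived from the scenario seed, so estimates are reproducible and
identical for any worker count or sharding. Within a replicate, all
requested methods see the *same* dataset (and share one factorization of
$X$), which makes method contrasts paired and considerably tightens the
comparisons.

What the generator deliberately does not emulate: linkage disequilibrium
(one variant at a time), population structure beyond the single confounded
covariate, missing data, and correlated traits. Calibration results here
therefore speak to distributional robustness, not to those complications.

### Problem sizes

Rejection rates of order $10^{-4}$ need $10^6$ replicates to pin down to
printed precision — an overnight computation. The package's checks instead
run at sizes chosen to resolve each magnitude on a single CPU in minutes:
2,000 replicates for rates of order $0.05$–$1$ (gross-inflation cells),
10,000 for the 5%-level calibration suite and power contrasts, and 30,000
for rare-variant cells of order $10^{-3}$, where the check is on
confidence-interval position rather than a point match. Monte-Carlo
standard errors accompany every estimate.

### A reproducibility caveat worth knowing about

For *well-calibrated* methods these scaled-down runs land on the reference
values comfortably. For the gross-inflation cells of an *invalid* method
(e.g. the direct INT test under near-degenerate errors with strong
confounding), the rejection rate conditional on one covariate-and-genotype
draw is nearly 0 or 1: whether the test explodes depends on which extreme
covariate values acquired carriers, not on the error draw. Averaging over
fresh draws each replicate — as the engine does, following the generative
description — gives a strictly-between rate (about 0.64 at the
n = 10000 cell, where a full-scale reference value of exactly 1.00000
circulates). A design that draws covariates once per scenario and redraws
only errors prints a 0-or-1-like value for such cells. The package follows the per-replicate redraw design throughout;
the affected quantities are exactly the ones whose magnitude announces "this
method is broken here", and the qualitative conclusion is identical either
way.

## Worked example

```{r example}
set.seed(7)
n <- 800
pheno <- data.frame(bmi = rchisq(n, 3) + 0.4 * rnorm(n),
                    age = rnorm(n, 50, 8),
                    sex = rbinom(n, 1, 0.5))
G <- cbind(snp1 = rbinom(n, 2, 0.25), snp2 = rbinom(n, 2, 0.02))
fit <- int_assoc(bmi ~ age + sex, pheno, genotype = G, method = "fs-int")
fit
```

```{r sim-example}
sc <- sim_scenario(n = 1000, gamma0 = -2, gamma1 = 0,
                   error_model = "chisq", nominal_alpha = 0.05,
                   n_replicates = 300, seed = 1)
estimate_rejection_rate(c("ts-int", "fs-int", "skat-score"), sc)
```

## Known limitations

* Quantitative traits only; the procedure is not defined for binary or
  ordinal outcomes.
* Heavily skewed errors *combined with* genotype–covariate correlation
  defeat all the INT-based procedures, the full-stage one included; the
  gamma(0.1, 0.1) error regime is provided so that failure mode can be
  reproduced.
* Single-variant only: no region/kernel multi-variant tests, though the
  full-stage residuals could feed one.
* Independent samples; no relatedness or repeated measures.
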