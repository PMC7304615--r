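# fsint

Single-variant association tests for quantitative traits whose residuals
are anything but normal — skewed, spiky, outlier-ridden — with particular
care for rare variants, where a handful of carriers drives the test
statistic and distributional misbehaviour hurts most. The intended users
are statistical geneticists and biostatisticians running trait–genotype
scans with covariate adjustment.

## The method

The trait model is the usual linear one,

    y = X α + g β + ε,        H0: β = 0,

with `X` an n×p covariate design (intercept included) and `g` an additive
dosage in {0, 1, 2}. The package centres on the **fully adjusted
full-stage rank-based inverse normal transformation (FS-INT)** test:

1. residualize `y` on `X` and apply the INT,
   `RN(v_i) = Φ⁻¹((rank(v_i) − c)/n)` with `c = 1/2`;
2. regress the transformed residuals on `X` and screen the covariate
   p-values at 0.05;
3. while any screened p-value is below 0.05, re-residualize and
   re-transform (stopping also when the covariate coefficients change by
   less than 10⁻⁶, or at an iteration cap);
4. score-test the final transformed residuals against `g`, adjusting `X`:
   `U = gᵀε̂`, `V = σ̂² gᵀ(I−H)g`, `U²/V ~ χ²₁`.

When the first screen passes, FS-INT *is* the fully adjusted two-stage
test (TS-INT), bit for bit. The point of the extra iterations is that
rank-normalized residuals of a badly non-normal trait are not independent
of the covariates, and that leftover structure inflates the two-stage test
exactly in the rare-variant, outlier-laden settings it is meant to rescue.

Seven comparators ship alongside, selectable by key: `mr` (median/LAD
regression), `yjpt` (Yeo-Johnson power-transform regression), `skat-score`
(the plain covariate-adjusted score test — identical to a single-variant
kernel-test p-value), `d-int`, `i-int`, `o-int` (direct / indirect /
Cauchy-combined omnibus INT tests), `pts-int` and `ts-int` (partly / fully
adjusted two-stage INT). A Monte-Carlo engine estimates type I error and
power over scenario grids with logistic genotype–covariate confounding
(`p_i = logistic(γ0 + γ1 x_i1)`), and file readers handle delimited
phenotype/dosage tables and VCF genotypes.

## Worked example

```r
library(fsint)
set.seed(7)
n <- 800
pheno <- data.frame(bmi = rchisq(n, 3) + 0.4 * rnorm(n),   # skewed trait
                    age = rnorm(n, 50, 8),
                    sex = rbinom(n, 1, 0.5))
G <- cbind(snp1 = rbinom(n, 2, 0.25),    # common variant
           snp2 = rbinom(n, 2, 0.02))    # rare variant
fit <- int_assoc(bmi ~ age + sex, pheno, genotype = G, method = "fs-int")
fit
#> Quantitative-trait association tests
#> Call: int_assoc(formula = bmi ~ age + sex, data = pheno, genotype = G,     method = "fs-int")
#> 800 sample(s), 2 variant(s), method(s): fs-int
#>
#>  variant method n_used    beta_hat p_value iterations converged
#>     snp1 fs-int    800 0.005184606  0.9261          0      TRUE
#>     snp2 fs-int    800 0.079796522  0.6740          0      TRUE
```

`beta_hat` is the score-test effect estimate on the transformed-residual
scale (so its magnitude is in SD-of-INT-residual units, not raw trait
units); `iterations = 0` says the first covariate screen passed, i.e. the
full-stage test reduced to the two-stage one for both variants; neither
variant shows association (`p_value` column).

Simulated calibration of three methods under skewed (chi-squared) errors,
sharing the same replicates:

```r
sc <- sim_scenario(n = 1000, gamma0 = -2, gamma1 = 0,
                   error_model = "chisq", nominal_alpha = 0.05,
                   n_replicates = 300, seed = 1)
estimate_rejection_rate(c("ts-int", "fs-int", "skat-score"), sc)
#> Empirical rejection rates: n=1000, gamma0=-2, gamma1=0, beta=0,
#>   errors=chisq, alpha=0.05, 300 replicates (seed 1)
#>      method rejections evaluated degenerate failures    rate   mc_se
#>      ts-int         16       300          0        0 0.05333 0.01297
#>      fs-int         16       300          0        0 0.05333 0.01297
#>  skat-score         18       300          0        0 0.06000 0.01371
```

All three sit within Monte-Carlo error of the nominal 0.05 — at a common
variant with no confounding, skewness alone barely perturbs these tests.
The interesting regimes (rare variants, outlier mixtures, strong
confounding) are explored in the methods vignette
(`vignettes/fsint-methods.Rmd`).

There is also a thin CLI over the same functions:

```sh
Rscript exec/fsint assoc --pheno pheno.csv --trait bmi --covar age,sex \
    --geno variants.vcf --method fs-int --out results.tsv
Rscript exec/fsint simulate --config grid.yaml --out rates.csv
```

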