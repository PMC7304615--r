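# Brute-force compositional oracles use lm()/pchisq directly rather than the
# package's own primitives.

brute_score_p <- function(r, g, X) {
  fit <- lm(r ~ X - 1)
  res <- residuals(fit)
  s2 <- sum(res^2) / (length(r) - ncol(X))
  gres <- residuals(lm(g ~ X - 1))
  stat <- sum(g * res)^2 / (s2 * sum(gres^2))
  pchisq(stat, 1, lower.tail = FALSE)
}

test_that("two-stage variants match brute-force compositions", {
  d <- make_cov_data(seed = 4, errors = "chisq")
  X <- d$covariates
  r <- qnorm((rank(residuals(lm(d$trait ~ X - 1))) - 0.5) / d$n)

  expect_equal(ts_int(d)$p_value, brute_score_p(r, d$genotype, X))
  gres <- residuals(lm(d$genotype ~ X - 1))
  expect_equal(i_int(d)$p_value,
               brute_score_p(r, gres, matrix(1, d$n, 1)))
  expect_equal(pts_int(d)$p_value,
               brute_score_p(r, d$genotype, matrix(1, d$n, 1)))

  z <- qnorm((rank(d$trait) - 0.5) / d$n)
  fit <- lm(z ~ X - 1 + d$genotype)
  expect_equal(d_int(d)$p_value,
               unname(summary(fit)$coefficients["d$genotype", 4]))
})

test_that("with an intercept-only design the adjusted and unadjusted variants coincide", {
  set.seed(8)
  n <- 150
  d <- sample_data(rchisq(n, 2), rbinom(n, 2, 0.3))
  expect_equal(pts_int(d)$p_value, ts_int(d)$p_value)
  expect_equal(i_int(d)$p_value, ts_int(d)$p_value)
})

test_that("rank-based tests are invariant under strictly increasing trait transforms", {
  set.seed(9)
  n <- 200
  d <- sample_data(rnorm(n), rbinom(n, 2, 0.3))
  d_t <- sample_data(exp(d$trait), d$genotype)
  for (f in list(d_int, i_int, ts_int, fs_int)) {
    a <- f(d); b <- f(d_t)
    expect_identical(a$p_value, b$p_value)
  }
  # d-int is rank-invariant even with covariates
  dc <- make_cov_data(seed = 10)
  dc_t <- sample_data(exp(dc$trait / 3), dc$genotype, dc$covariates)
  expect_identical(d_int(dc)$p_value, d_int(dc_t)$p_value)
})

test_that("omnibus combination follows the closed-form tangent average", {
  expect_equal(cauchy_combine(c(0.3, 0.3)), 0.3)
  p_pair <- c(0.01, 0.5)
  oracle <- 0.5 - atan(mean(tan((0.5 - p_pair) * pi))) / pi
  expect_equal(cauchy_combine(p_pair), oracle)
  expect_equal(cauchy_combine(c(1e-20, 1)), 0.5e-20 * 2, tolerance = 1e-3)

  d <- make_cov_data(seed = 12, errors = "mixture")
  pd <- d_int(d)$p_value
  pi_ <- i_int(d)$p_value
  expect_equal(o_int(d)$p_value,
               0.5 - atan(mean(tan((0.5 - c(pd, pi_)) * pi))) / pi)
})

test_that("full-stage reduces bitwise to two-stage when the first screen passes", {
  found <- 0L
  for (seed in 1:10) {
    d <- make_cov_data(seed = seed, errors = "normal")
    res <- fs_int(d)
    if (res$iterations == 0L) {
      found <- found + 1L
      expect_identical(res$p_value, ts_int(d)$p_value)
      expect_identical(res$statistic, ts_int(d)$statistic)
    }
  }
  expect_gt(found, 0L)
})

test_that("full-stage iteration matches a step-by-step brute-force trace", {
  # heavy-tailed mixture errors force at least one re-transform
  d <- make_cov_data(n = 600, seed = 42, errors = "mixture")
  X <- d$covariates
  n <- d$n
  int_ <- function(v) qnorm((rank(v) - 0.5) / n)
  screen_p <- function(r) {
    s <- summary(lm(r ~ X - 1))$coefficients
    s[2:3, 4]
  }
  r <- int_(residuals(lm(d$trait ~ X - 1)))
  iters <- 0L
  repeat {
    if (all(screen_p(r) >= 0.05)) break
    a_tilde <- coef(lm(r ~ X - 1))
    r_new <- int_(residuals(lm(r ~ X - 1)))
    a_star <- coef(lm(r_new ~ X - 1))
    iters <- iters + 1L
    r <- r_new
    if (max(abs((a_tilde - a_star)[2:3])) < 1e-6) break
  }
  expected_p <- brute_score_p(r, d$genotype, X)

  res <- fs_int(d)
  expect_gte(res$iterations, 1L)
  expect_identical(res$iterations, iters)
  expect_equal(res$p_value, expected_p)
  expect_true(res$converged)
})

test_that("full-stage termination is capped and the stopping rule is self-consistent", {
  # seed 6 mixture data needs two re-transforms, so a cap of one must trip
  d2 <- make_cov_data(n = 600, seed = 6, errors = "mixture")
  expect_gte(fs_int(d2)$iterations, 2L)
  expect_warning(res1 <- fs_int(d2, max_iterations = 1L), "cap")
  expect_false(res1$converged)
  expect_true(is.finite(res1$p_value))
  expect_equal(res1$iterations, 1L)

  # on convergence, either the final screen passes or the last two covariate
  # coefficient vectors agree to the stopping tolerance
  for (seed in c(6, 13, 42, 1)) {
    d <- make_cov_data(n = 600, seed = seed, errors = "mixture")
    res <- fs_int(d)
    expect_true(res$converged)
    expect_lte(res$iterations, 100L)
    X <- d$covariates
    int_ <- function(v) qnorm((rank(v) - 0.5) / d$n)
    r_prev <- int_(residuals(lm(d$trait ~ X - 1)))
    r <- r_prev
    for (i in seq_len(res$iterations)) {
      r_prev <- r
      r <- int_(residuals(lm(r ~ X - 1)))
    }
    pv <- summary(lm(r ~ X - 1))$coefficients[2:3, 4]
    coef_diff <- max(abs((coef(lm(r_prev ~ X - 1)) -
                            coef(lm(r ~ X - 1)))[2:3]))
    expect_true(all(pv >= 0.05) ||
                  (res$iterations >= 1L && coef_diff < 1e-6))
  }
})

test_that("every method returns a valid p-value and handles degenerate genotypes", {
  d_rare <- make_cov_data(n = 400, seed = 3, maf = 0.01)
  for (m in names(assoc_methods())) {
    res <- assoc_test(d_rare, m)
    expect_true(res$p_value >= 0 && res$p_value <= 1, label = m)
  }
  d_mono <- sample_data(rnorm(50), rep(0, 50),
                        cbind(1, rnorm(50)))
  for (m in names(assoc_methods())) {
    res <- assoc_test(d_mono, m)
    expect_equal(res$p_value, 1, label = m)
    expect_true("degenerate_genotype" %in% res$flags, label = m)
  }
})

test_that("Yeo-Johnson transform and profile likelihood behave as specified", {
  y <- c(-3.2, -0.5, 0, 1.7, 8)
  expect_identical(yj_transform(y, 1), y)
  expect_equal(yj_transform(2, 0), log(3))
  expect_equal(yj_transform(-2, 2), -log(3))
  # lambda recovery on already-linear normal data
  set.seed(14)
  n <- 1e4
  x1 <- rnorm(n); g <- rbinom(n, 2, 0.3)
  y <- 1 + 0.5 * x1 + 0.2 * g + rnorm(n)
  res <- yjpt_test(y, g, cbind(1, x1))
  expect_lt(abs(attr(res, "lambda") - 1), 0.1)
})

test_that("profile-ML lambda and p-value agree with the car implementation", {
  set.seed(15)
  n <- 1500
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 2, 0.2)
  y <- 0.5 * x1 + 0.5 * x2 + rchisq(n, 2)
  mine <- yjpt_test(y, g, cbind(1, x1, x2))
  pt <- car::powerTransform(lm(y ~ x1 + x2 + g), family = "yjPower")
  expect_equal(attr(mine, "lambda"), unname(coef(pt)), tolerance = 1e-3)
  z <- car::yjPower(y, coef(pt))
  ref <- summary(lm(z ~ x1 + x2 + g))$coefficients["g", 4]
  expect_equal(mine$p_value, unname(ref), tolerance = 1e-4)
})

test_that("median regression recovers the effect and switches to the bootstrap when sparse", {
  set.seed(16)
  n <- 3000
  x1 <- rnorm(n)
  g <- rbinom(n, 2, 0.3)
  y <- 0.3 * x1 + 0.5 * g + rnorm(n)
  res <- mr_test(y, g, cbind(1, x1))
  expect_lt(abs(res$beta_hat - 0.5), 3 * res$se)
  expect_false("bootstrap" %in% res$flags)
  expect_lt(res$p_value, 1e-6)

  # sparse design: a handful of carriers engages the bootstrap
  set.seed(17)
  n <- 300
  g_sparse <- c(rep(1, 5), rep(0, n - 5))
  res_sp <- mr_test(rnorm(n), g_sparse, matrix(1, n, 1), B = 200L)
  expect_true("bootstrap" %in% res_sp$flags)
  expect_true(res_sp$p_value >= 0 && res_sp$p_value <= 1)

  # intercept-only toy null
  set.seed(18)
  res0 <- mr_test(rnorm(60), rbinom(60, 2, 0.4), matrix(1, 60, 1))
  expect_gt(res0$p_value, 0.05)
})
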