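#' Genotype frequency under logistic covariate confounding
#'
#' \eqn{p_i = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 x_{i1})}: the
#' per-individual ALT-allele probability from which the dosage is drawn as
#' Binomial(2, \eqn{p_i}). \eqn{\gamma_1 = 0} gives a constant minor allele
#' frequency; \eqn{\gamma_1 > 0} correlates the genotype with the continuous
#' covariate.
#'
#' @param gamma0,gamma1 Logistic intercept and covariate loading.
#' @param x1 Continuous covariate value(s).
#' @return Probability in (0, 1), vectorized over `x1`.
#' @examples
#' genotype_prob(-7, 0, 0)   # rare: MAF 0.0009
#' genotype_prob(-2, 0, 0)   # common: MAF 0.1192
#' @export
genotype_prob <- function(gamma0, gamma1, x1 = 0) {
  stats::plogis(gamma0 + gamma1 * x1)
}

#' Define one simulation scenario
#'
#' One cell of the study grid: trait
#' \eqn{y_i = 0.5 x_{i1} + 0.5 x_{i2} + g_i\beta + \varepsilon_i} with
#' \eqn{x_{i1} \sim N(0,1)}, \eqn{x_{i2} \sim} Bernoulli(1/2),
#' \eqn{g_i \sim} Binomial(2, [genotype_prob()]) and one of four error
#' regimes. Errors are used as drawn (not mean-centred); the analysis design
#' is always `[1, x1, x2]` even though the generative model has no
#' intercept.
#'
#' @param n Sample size.
#' @param gamma0,gamma1 Genotype-frequency model parameters.
#' @param beta Genetic effect (0 under the null).
#' @param error_model `"normal"`, `"outlier_mixture"`, `"chisq"` or
#'   `"gamma"`.
#' @param error_sd Normal-error standard deviation (error_model "normal").
#' @param alpha1,alpha2 Covariate effects.
#' @param nominal_alpha Nominal test level for rejection-rate estimation.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed Scenario seed (per-replicate substreams are derived from it).
#' @param mixture Outlier-mixture parameters
#'   (`p_out`, `sd_main`, `sd_out`).
#' @param chisq_df Chi-squared error degrees of freedom.
#' @param gamma_shape,gamma_scale Gamma error parameters.
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(n, gamma0, gamma1, beta = 0,
                         error_model = c("normal", "outlier_mixture",
                                         "chisq", "gamma"),
                         error_sd = 1, alpha1 = 0.5, alpha2 = 0.5,
                         nominal_alpha = 1e-4, n_replicates = 1000L,
                         seed = 1L,
                         mixture = list(p_out = 0.01, sd_main = 0.01,
                                        sd_out = 3),
                         chisq_df = 2, gamma_shape = 0.1, gamma_scale = 0.1) {
  error_model <- match.arg(error_model)
  stopifnot(n >= 10, nominal_alpha > 0, nominal_alpha < 1, n_replicates >= 1)
  structure(list(n = as.integer(n), gamma0 = gamma0, gamma1 = gamma1,
                 beta = beta, error_model = error_model, error_sd = error_sd,
                 alpha1 = alpha1, alpha2 = alpha2,
                 nominal_alpha = nominal_alpha,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), mixture = mixture,
                 chisq_df = chisq_df, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale),
            class = "sim_scenario")
}

draw_errors <- function(sc) {
  n <- sc$n
  switch(sc$error_model,
    normal = stats::rnorm(n, 0, sc$error_sd),
    outlier_mixture = {
      out <- stats::runif(n) < sc$mixture$p_out
      e <- stats::rnorm(n, 0, sc$mixture$sd_main)
      e[out] <- stats::rnorm(sum(out), 0, sc$mixture$sd_out)
      e
    },
    chisq = stats::rchisq(n, df = sc$chisq_df),
    gamma = stats::rgamma(n, shape = sc$gamma_shape, scale = sc$gamma_scale))
}

#' Draw one dataset from a scenario
#'
#' Uses the current RNG state (callers control seeding; the rejection-rate
#' estimator assigns one RNG substream per replicate).
#'
#' @param scenario A [sim_scenario()] object.
#' @return A [sample_data()] object with analysis design `[1, x1, x2]`.
#' @export
simulate_dataset <- function(scenario) {
  n <- scenario$n
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.5)
  g <- stats::rbinom(n, 2, genotype_prob(scenario$gamma0, scenario$gamma1, x1))
  eps <- draw_errors(scenario)
  y <- scenario$alpha1 * x1 + scenario$alpha2 * x2 + scenario$beta * g + eps
  sample_data(y, g, cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
}

# one L'Ecuyer-CMRG stream per replicate, derived from the scenario seed:
# deterministic and independent of how replicates are sharded over workers
replicate_streams <- function(seed, k) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", .GlobalEnv)
  streams <- vector("list", k)
  for (r in seq_len(k)) {
    s <- parallel::nextRNGStream(s)
    streams[[r]] <- s
  }
  streams
}

#' Estimate empirical rejection rates by Monte Carlo
#'
#' Draws `n_replicates` datasets from the scenario and applies each requested
#' method to every dataset (replicates are shared across methods, so the
#' methods are compared on identical data). Replicates with a degenerate
#' (monomorphic or covariate-explained) genotype are counted as
#' non-rejections and tallied; a method error on a replicate is logged,
#' counted as a non-rejection, and the run aborts if errors exceed 1% of
#' replicates.
#'
#' @param methods Character vector of method keys (see [assoc_methods()]).
#' @param scenario A [sim_scenario()] object.
#' @param workers Parallel forks (`parallel::mclapply`); results are
#'   identical for any worker count.
#' @param ... Extra arguments passed to each method.
#' @return A data frame of class `rejection_rate`, one row per method:
#'   rejections, evaluated, degenerate, failures, rate and Monte-Carlo
#'   standard error, with the scenario attached as an attribute.
#' @export
estimate_rejection_rate <- function(methods, scenario, workers = 1L, ...) {
  stopifnot(inherits(scenario, "sim_scenario"))
  funs <- assoc_methods()
  bad <- setdiff(methods, names(funs))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  R <- scenario$n_replicates
  streams <- replicate_streams(scenario$seed, R)
  alpha <- scenario$nominal_alpha

  one_rep <- function(r) {
    assign(".Random.seed", streams[[r]], .GlobalEnv)
    dat <- simulate_dataset(scenario)
    dat$qx <- qr(dat$covariates)   # factorize X once for all methods
    rej <- logical(length(methods))
    deg <- FALSE
    fail <- logical(length(methods))
    for (m in seq_along(methods)) {
      res <- tryCatch(funs[[methods[m]]](dat, ...),
                      error = function(e) NULL)
      if (is.null(res)) { fail[m] <- TRUE; next }
      if ("degenerate_genotype" %in% res$flags) deg <- TRUE
      rej[m] <- is.finite(res$p_value) && res$p_value < alpha
    }
    c(rej, deg, fail)
  }

  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(R), one_rep, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else lapply(seq_len(R), one_rep)
  tab <- do.call(rbind, rows)
  nm <- length(methods)
  rej <- colSums(tab[, seq_len(nm), drop = FALSE])
  degenerate <- sum(tab[, nm + 1L])
  failures <- colSums(tab[, nm + 1L + seq_len(nm), drop = FALSE])
  if (any(failures > 0.01 * R))
    stop("method failure rate above 1% for: ",
         paste(methods[failures > 0.01 * R], collapse = ", "))
  rate <- rej / R
  out <- data.frame(method = methods, rejections = as.integer(rej),
                    evaluated = R, degenerate = as.integer(degenerate),
                    failures = as.integer(failures), rate = rate,
                    mc_se = sqrt(rate * (1 - rate) / R),
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario
  class(out) <- c("rejection_rate", "data.frame")
  out
}

#' Run a grid of scenarios and methods
#'
#' Cartesian product of scenarios and methods, optionally checkpointed: with
#' `checkpoint_dir` set, each scenario's rows are written to a CSV after
#' completion and already-checkpointed scenarios are loaded instead of re-run.
#'
#' @param scenarios List of [sim_scenario()] objects.
#' @param methods Character vector of method keys.
#' @param workers Forked workers per scenario.
#' @param checkpoint_dir Directory for per-scenario checkpoints (`NULL` to
#'   disable).
#' @return A tidy data frame: method, n, gamma0, gamma1, beta, error_model,
#'   nominal_alpha, n_replicates, rejections, evaluated, degenerate,
#'   failures, rate, mc_se, seed.
#' @export
run_grid <- function(scenarios, methods, workers = 1L,
                     checkpoint_dir = NULL) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    tag <- sprintf("scen_%03d_n%d_g0%g_g1%g_b%g_%s_seed%d.csv", i, sc$n,
                   sc$gamma0, sc$gamma1, sc$beta, sc$error_model, sc$seed)
    ckpt <- if (!is.null(checkpoint_dir)) file.path(checkpoint_dir, tag)
    if (!is.null(ckpt) && file.exists(ckpt)) {
      out[[i]] <- utils::read.csv(ckpt, stringsAsFactors = FALSE)
      next
    }
    est <- estimate_rejection_rate(methods, sc, workers = workers)
    rows <- cbind(method = est$method,
                  data.frame(n = sc$n, gamma0 = sc$gamma0,
                             gamma1 = sc$gamma1, beta = sc$beta,
                             error_model = sc$error_model,
                             nominal_alpha = sc$nominal_alpha,
                             n_replicates = sc$n_replicates),
                  est[, c("rejections", "evaluated", "degenerate",
                          "failures", "rate", "mc_se")],
                  seed = sc$seed)
    if (!is.null(ckpt)) utils::write.csv(rows, ckpt, row.names = FALSE)
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

#' @export
print.rejection_rate <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Empirical rejection rates: n=%d, gamma0=%g, gamma1=%g, beta=%g,\n  errors=%s, alpha=%g, %d replicates (seed %d)\n",
    sc$n, sc$gamma0, sc$gamma1, sc$beta, sc$error_model, sc$nominal_alpha,
    sc$n_replicates, sc$seed))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read a simulation grid from a YAML configuration
#'
#' Keys mirror the [sim_scenario()] fields; any of `n`, `gamma0`, `gamma1`,
#' `beta`, `error_model`, `error_sd`, `nominal_alpha` may be a list, and the
#' grid is their cartesian product. A top-level `methods` key selects the
#' methods.
#'
#' @param path YAML file.
#' @return List with elements `scenarios` (list of `sim_scenario`) and
#'   `methods`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare "n" key as boolean FALSE; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "n"
  methods <- unlist(cfg$methods) %||% names(assoc_methods())
  for (k in c("n", "gamma0", "gamma1"))
    if (is.null(cfg[[k]])) stop("config is missing required key '", k, "'")
  defaults <- list(beta = 0, error_model = "normal", error_sd = 1,
                   nominal_alpha = 1e-4)
  grid_keys <- c("n", "gamma0", "gamma1", names(defaults))
  axes <- lapply(grid_keys,
                 function(k) unlist(cfg[[k]]) %||% defaults[[k]])
  names(axes) <- grid_keys
  grid <- expand.grid(axes, stringsAsFactors = FALSE)
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, ])
    args$n_replicates <- cfg$n_replicates %||% 1000L
    args$seed <- (cfg$seed %||% 1L) + i - 1L
    do.call(sim_scenario, args)
  })
  list(scenarios = scenarios, methods = methods)
}

#' Run a YAML-configured simulation and write tidy CSV results
#'
#' @param config_path YAML scenario-grid configuration.
#' @param out Output CSV path.
#' @param workers Forked workers.
#' @return The results data frame, invisibly.
#' @export
run_simulation_config <- function(config_path, out, workers = 1L) {
  cfg <- read_sim_config(config_path)
  res <- run_grid(cfg$scenarios, cfg$methods, workers = workers)
  utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
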