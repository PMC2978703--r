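#' Generative scenario for the power study
#'
#' The per-variant phenotype effect is generated as
#' \code{beta_j = alpha + gamma * T(s_j) + eps_j}, where \code{s_j} is the
#' variant's true selection coefficient, \code{T} an optional robustness
#' transform (identity by default), and \code{eps_j} a mean-zero deviation
#' with standard deviation \code{sigma_beta}.  Phenotypes are then
#' \code{y = X b + G beta + e} with residual standard deviation
#' \code{resid_sd}.
#'
#' @param gamma fitness-phenotype scaling (phenotype units per unit of
#'   selection coefficient).
#' @param sigma_beta SD of the fitness-independent effect deviations.
#' @param alpha mean derived-allele effect.
#' @param resid_sd residual SD of the phenotype; positive.
#' @param label scenario name.
#' @return An object of class \code{emmpat_scenario}.
#' @export
scenario <- function(gamma, sigma_beta, alpha, resid_sd, label = "scenario") {
  if (sigma_beta < 0) stop("'sigma_beta' must be >= 0", call. = FALSE)
  if (resid_sd <= 0) stop("'resid_sd' must be > 0", call. = FALSE)
  structure(list(gamma = gamma, sigma_beta = sigma_beta, alpha = alpha,
                 resid_sd = resid_sd, label = label),
            class = "emmpat_scenario")
}

#' The six generative scenarios of the power study
#'
#' Parameter values (gamma, sigma_beta, alpha, residual SD) chosen so the
#' gene explains a comparable share of phenotypic variance throughout:
#' a baseline with equal fitness-related and fitness-independent shares,
#' strong and very strong fitness scaling, a strong fitness-independent
#' component, a weak mean allele effect, and no fitness-phenotype
#' correlation at all.  A pure null (all effects zero) is obtained by
#' \code{scenario(0, 0, 0, resid_sd)}.
#'
#' @return Named list of \code{\link{scenario}} objects.
#' @export
power_scenarios <- function() {
  list(
    base            = scenario(-7.0,  0.012, 0.007, 0.22, "base"),
    high_gamma      = scenario(-21.0, 0.012, 0.007, 0.50, "high_gamma"),
    high_sigma_beta = scenario(-7.0,  0.018, 0.007, 0.28, "high_sigma_beta"),
    low_alpha       = scenario(-6.4,  0.012, 0.003, 0.21, "low_alpha"),
    very_high_gamma = scenario(-63.1, 0.012, 0.003, 1.43, "very_high_gamma"),
    zero_gamma      = scenario(0.0,   0.012, 0.007, 0.16, "zero_gamma"),
    null            = scenario(0.0,   0.0,   0.0,   0.22, "null")
  )
}

#' Robustness violations of the generative model
#'
#' Knobs that deliberately break the analysis model's assumptions while
#' the analysis stays the same: nonlinear fitness transforms (variance
#' rescaled to match the linear case), a sign-randomized mixture, skewed
#' (standardized log-normal) effect deviations, a fraction of completely
#' null variants, and misspecification of the analysis-side DFE scale.
#'
#' @param fitness_transform \code{"identity"}, \code{"square"},
#'   \code{"sqrt"} (sign-preserving powers of |s|), or
#'   \code{"random_sign_mixture"} (a 50/50 random sign flip of the linear
#'   term).
#' @param effect_dist \code{"normal"} or \code{"lognormal"} (standardized
#'   to mean zero, SD \code{sigma_beta}).
#' @param zero_fraction proportion of variants whose whole effect is forced
#'   to exactly zero.
#' @param dfe_scale_misspec multiplier applied to the analysis DFE scale
#'   only (the generating truth is untouched).
#' @param extra_growth add 100-fold exponential growth over the last 11\%
#'   of post-ancestral generations to the generating demography.
#' @return An object of class \code{robustness_knobs}.
#' @export
robustness_knobs <- function(fitness_transform = c("identity", "square", "sqrt",
                                                   "random_sign_mixture"),
                             effect_dist = c("normal", "lognormal"),
                             zero_fraction = 0,
                             dfe_scale_misspec = 1,
                             extra_growth = FALSE) {
  if (zero_fraction < 0 || zero_fraction > 1)
    stop("'zero_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(fitness_transform = match.arg(fitness_transform),
                 effect_dist = match.arg(effect_dist),
                 zero_fraction = zero_fraction,
                 dfe_scale_misspec = dfe_scale_misspec,
                 extra_growth = extra_growth),
            class = "robustness_knobs")
}

# apply the fitness transform, rescaled so Var(T(s)) = Var(s) across the
# variant set (sign-preserving |s|-power transforms)
transform_fitness <- function(s, transform) {
  if (transform == "identity") return(s)
  t0 <- switch(transform,
               square = -abs(s)^2,
               sqrt = -sqrt(abs(s)),
               random_sign_mixture = s * sample(c(-1, 1), length(s), replace = TRUE))
  sd0 <- stats::sd(t0)
  if (is.na(sd0) || sd0 == 0) return(t0)
  t0 * stats::sd(s) / sd0
}

#' Generate per-variant phenotype effects
#'
#' @param s_true true selection coefficients of the variants.
#' @param scenario a \code{\link{scenario}}.
#' @param knobs a \code{\link{robustness_knobs}} (identity defaults).
#' @param seed optional integer seed.
#' @return Numeric vector of effects \code{beta}.
#' @export
generate_effects <- function(s_true, scenario, knobs = robustness_knobs(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(s_true)
  Ts <- transform_fitness(s_true, knobs$fitness_transform)
  eps <- switch(knobs$effect_dist,
                normal = rnorm(m, 0, scenario$sigma_beta),
                lognormal = {
                  z <- rlnorm(m, 0, 1)
                  scenario$sigma_beta * (z - exp(0.5)) / sqrt(exp(1) * (exp(1) - 1))
                })
  beta <- scenario$alpha + scenario$gamma * Ts + eps
  if (knobs$zero_fraction > 0) {
    nz <- round(knobs$zero_fraction * m)
    beta[sample.int(m, nz)] <- 0
  }
  beta
}

#' Sample a cohort's genotypes from a simulated population
#'
#' Each individual draws two alleles per site independently from the
#' population frequency (Hardy-Weinberg sampling); sites monomorphic in the
#' sample are dropped, and the true selection coefficients are returned
#' aligned with the retained columns.
#'
#' @param pop a \code{\link{simulate_population}} result.
#' @param n number of diploid individuals.
#' @param seed optional integer seed.
#' @return List with \code{G} (n x m' matrix), \code{s_true}, \code{q}
#'   (population frequencies of retained sites), and \code{kept} (index of
#'   retained population variants).
#' @export
sample_cohort <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pseudo_population"))
  if (nrow(pop$variants) == 0) stop("population has no variants", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- pop$variants$q
  m <- length(q)
  G <- matrix(rbinom(n * m, 2L, rep(q, each = n)), nrow = n)
  keep <- colSums(G) > 0 & colSums(G) < 2 * n
  G <- G[, keep, drop = FALSE]
  colnames(G) <- paste0("v", which(keep))
  list(G = G, s_true = pop$variants$s[keep], q = q[keep], kept = which(keep))
}

#' Generate phenotypes from genotypes and effects
#'
#' @param G genotype matrix.
#' @param beta per-variant effects.
#' @param scenario a \code{\link{scenario}} (supplies the residual SD).
#' @param X optional covariate matrix with coefficients \code{b}.
#' @param b covariate coefficients.
#' @param seed optional integer seed.
#' @return Numeric phenotype vector.
#' @export
generate_phenotypes <- function(G, beta, scenario, X = NULL, b = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G)
  mu <- drop(G %*% beta)
  if (!is.null(X)) mu <- mu + drop(as.matrix(X) %*% b)
  mu + rnorm(n, 0, scenario$resid_sd)
}

#' Expected generative variance shares
#'
#' The construction behind the simulation design's expected percent of
#' variance explained: for cohorts sampled from the population, the
#' variance across individuals of the fitness-related effect component
#' (\code{gamma * T(s)} part of beta) and of the fitness-independent
#' component (\code{alpha + eps} part), each divided by the total
#' \code{V_fit + V_nonfit + resid_sd^2}, averaged over replicate cohorts
#' and expressed in percent.
#'
#' @param pop a \code{\link{simulate_population}} result.
#' @param scenario a \code{\link{scenario}}.
#' @param knobs a \code{\link{robustness_knobs}}.
#' @param n cohort size per replicate.
#' @param reps number of replicate cohorts.
#' @param seed optional integer seed.
#' @return Named vector \code{c(fitness, nonfitness)} in percent.
#' @export
expected_variance_shares <- function(pop, scenario, knobs = robustness_knobs(),
                                     n = 1000, reps = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shares <- vapply(seq_len(reps), function(r) {
    coh <- sample_cohort(pop, n)
    Ts <- transform_fitness(coh$s_true, knobs$fitness_transform)
    m <- length(Ts)
    eps <- switch(knobs$effect_dist,
                  normal = rnorm(m, 0, scenario$sigma_beta),
                  lognormal = {
                    z <- rlnorm(m, 0, 1)
                    scenario$sigma_beta * (z - exp(0.5)) /
                      sqrt(exp(1) * (exp(1) - 1))
                  })
    zero <- if (knobs$zero_fraction > 0)
      sample.int(m, round(knobs$zero_fraction * m)) else integer(0)
    bfit <- scenario$gamma * Ts
    bnon <- scenario$alpha + eps
    bfit[zero] <- 0
    bnon[zero] <- 0
    v_fit <- stats::var(drop(coh$G %*% bfit))
    v_non <- stats::var(drop(coh$G %*% bnon))
    tot <- v_fit + v_non + scenario$resid_sd^2
    c(v_fit / tot, v_non / tot)
  }, numeric(2))
  100 * c(fitness = mean(shares[1, ]), nonfitness = mean(shares[2, ]))
}

#' Run the power / type-I-error study
#'
#' For each scenario and method, the fraction of replicate cohorts with
#' p < 0.05.  Replicates share one simulated population per scenario batch
#' (cohorts, effects, and phenotypes are re-drawn each replicate); a fresh
#' population per replicate is available via \code{fresh_populations}.  The
#' analysis-side fitness prior is built from an independently simulated
#' pseudo-population (optionally with a misspecified DFE or demography via
#' \code{knobs}), exactly as an analyst without access to the truth would.
#'
#' @param pop generating population (a \code{pseudo_population}).
#' @param analysis_pop pseudo-population used to build the analysis prior.
#' @param scenarios named list of \code{\link{scenario}}s.
#' @param methods character vector of method identifiers among
#'   \code{"minp_1"}, \code{"minp_5"}, \code{"cast_1"}, \code{"cast_5"},
#'   \code{"cmc_1"}, \code{"cmc_5"}, \code{"wsum_all"}, \code{"wsum_5"},
#'   \code{"optmean_all"}, \code{"optmean_5"}, \code{"emmpat_split"},
#'   \code{"emmpat_one"}.
#' @param R replicates per scenario.
#' @param B permutations for the mixed-model tests.
#' @param n cohort size.
#' @param seed master seed.
#' @param knobs a \code{\link{robustness_knobs}} applied to the generating
#'   side (transform, effect distribution, zero fraction).
#' @param fresh_populations simulate a new generating population per
#'   replicate (requires \code{pop_config}).
#' @param pop_config configuration list (as from
#'   \code{\link{default_popgen_config}}) used when
#'   \code{fresh_populations = TRUE}.
#' @return Data frame with scenario, method, power, Monte-Carlo standard
#'   error, and replicate count.  A method failure in a replicate counts as
#'   a non-rejection.
#' @export
run_power_study <- function(pop, analysis_pop, scenarios,
                            methods = c("cast_1", "wsum_all", "emmpat_one"),
                            R = 100, B = 99, n = 1000, seed = 1,
                            knobs = robustness_knobs(),
                            fresh_populations = FALSE, pop_config = NULL) {
  set.seed(seed)
  scen_seeds <- sample.int(2^30, length(scenarios))
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    set.seed(scen_seeds[si])
    rep_seeds <- sample.int(2^30, R)
    hits <- matrix(FALSE, R, length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(R)) {
      set.seed(rep_seeds[r])
      gen_pop <- if (fresh_populations) {
        cfg <- pop_config
        simulate_population(cfg$demography, cfg$dfe, cfg$locus_length,
                            cfg$mutation_rate,
                            seed = sample.int(2^30, 1),
                            rescale_factor = cfg$rescale_factor)
      } else pop
      coh <- sample_cohort(gen_pop, n)
      beta <- generate_effects(coh$s_true, sc, knobs)
      y <- generate_phenotypes(coh$G, beta, sc)
      cohort <- cohort_data(y, matrix(1, n, 1), coh$G, drop_monomorphic = FALSE)
      prior <- build_prior(cohort, list(pooled = analysis_pop))
      for (meth in methods) {
        p <- tryCatch(run_method(meth, cohort, prior, B),
                      error = function(e) {
                        message("method ", meth, " failed in a replicate: ",
                                conditionMessage(e))
                        1
                      })
        hits[r, meth] <- p < 0.05
      }
    }
    pw <- colMeans(hits)
    rows[[si]] <- data.frame(scenario = sc$label, method = methods,
                             power = pw,
                             mc_se = sqrt(pw * (1 - pw) / R),
                             replicates = R, row.names = NULL)
  }
  do.call(rbind, rows)
}

run_method <- function(method, cohort, prior, B) {
  switch(method,
    minp_1 = minp_test(cohort, 0.01)$p.value,
    minp_5 = minp_test(cohort, 0.05)$p.value,
    cast_1 = cast_test(cohort, 0.01)$p.value,
    cast_5 = cast_test(cohort, 0.05)$p.value,
    cmc_1 = cmc_test(cohort, 0.01)$p.value,
    cmc_5 = cmc_test(cohort, 0.05)$p.value,
    wsum_all = weighted_sum_test(cohort)$p.value,
    wsum_5 = weighted_sum_test(cohort, 0.05)$p.value,
    optmean_all = optimal_mean_test(cohort, prior)$p.value,
    optmean_5 = optimal_mean_test(cohort, prior, 0.05)$p.value,
    emmpat_split = permutation_test(cohort, prior,
                                    model_spec(delta_mode = "split",
                                               include_alpha = TRUE),
                                    B = B, seed = sample.int(2^30, 1))$p_perm,
    emmpat_one = permutation_test(cohort, prior,
                                  model_spec(delta_mode = "single",
                                             include_alpha = TRUE),
                                  B = B, seed = sample.int(2^30, 1))$p_perm,
    stop("unknown method: ", method, call. = FALSE))
}
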