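test_that("the scenario table carries the study's generative parameters", {
  sc <- power_scenarios()
  tab <- t(vapply(sc, function(s) c(s$gamma, s$sigma_beta, s$alpha, s$resid_sd),
                  numeric(4)))
  expect_equal(unname(tab["base", ]), c(-7.0, 0.012, 0.007, 0.22))
  expect_equal(unname(tab["zero_gamma", ]), c(0.0, 0.012, 0.007, 0.16))
  expect_equal(unname(tab["very_high_gamma", ]), c(-63.1, 0.012, 0.003, 1.43))
  expect_equal(unname(tab["high_gamma", ]), c(-21.0, 0.012, 0.007, 0.50))
  expect_equal(unname(tab["high_sigma_beta", ]), c(-7.0, 0.018, 0.007, 0.28))
  expect_equal(unname(tab["low_alpha", ]), c(-6.4, 0.012, 0.003, 0.21))
  expect_error(scenario(1, -0.1, 0, 1), "sigma_beta")
  expect_error(scenario(1, 0.1, 0, 0), "resid_sd")
})

test_that("effect generation follows beta = alpha + gamma T(s) + eps", {
  s <- -c(0.001, 0.01, 0.05, 0, 0.002)
  # no noise, no fitness scaling: all effects are alpha
  sc0 <- scenario(0, 0, 0.3, 1)
  expect_equal(generate_effects(s, sc0, seed = 1), rep(0.3, 5))
  # identity transform, no noise: exact linear map
  sc1 <- scenario(-7, 0, 0.007, 0.22)
  expect_equal(generate_effects(s, sc1, seed = 1), 0.007 - 7 * s)
  # zero_fraction forces whole effects (including alpha) to zero
  kn <- robustness_knobs(zero_fraction = 0.8)
  beta <- generate_effects(rep(-0.01, 50), scenario(-7, 0, 0.1, 1), kn,
                           seed = 2)
  expect_equal(sum(beta == 0), 40)
})

test_that("nonlinear fitness transforms are variance-rescaled", {
  set.seed(3)
  s <- -rgamma(500, 0.3, scale = 0.05)
  for (tr in c("square", "sqrt", "random_sign_mixture")) {
    Ts <- emmpat:::transform_fitness(s, tr)
    expect_equal(stats::sd(Ts), stats::sd(s), tolerance = 1e-10)
    if (tr != "random_sign_mixture") expect_true(all(Ts <= 0))
  }
  expect_identical(emmpat:::transform_fitness(s, "identity"), s)
})

test_that("standardized log-normal effect deviations have the right moments", {
  sc <- scenario(0, 0.012, 0, 1)
  kn <- robustness_knobs(effect_dist = "lognormal")
  beta <- generate_effects(rep(0, 1e5), sc, kn, seed = 4)
  expect_lt(abs(mean(beta)), 4 * 0.012 / sqrt(1e5) * 3)  # skew-inflated SE
  expect_equal(stats::sd(beta), 0.012, tolerance = 0.02)
  expect_gt(moments_skew <- mean(((beta - mean(beta)) / sd(beta))^3), 2)
})

test_that("cohort sampling is Hardy-Weinberg with sample-monomorphic dropout", {
  pop <- tiny_population(s = c(0, -0.01, 0), q = c(0.5, 1e-6, 0.2))
  coh <- sample_cohort(pop, 2000, seed = 5)
  # ultra-rare site almost surely dropped; dropout accounted by `kept`
  expect_true(all(coh$kept %in% c(1L, 3L)))
  expect_equal(ncol(coh$G), length(coh$s_true))
  j <- which(coh$kept == 1)
  expect_equal(mean(coh$G[, j]), 1, tolerance = 0.05)
  # genotype counts at a site ~ Binomial(2, q)
  tab <- tabulate(coh$G[, j] + 1, 3)
  expected <- 2000 * dbinom(0:2, 2, 0.5)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, 2))
})

test_that("phenotype generation is reproducible with the stated variance split", {
  set.seed(6)
  pop <- tiny_population(s = rep(-0.01, 30), q = rep(0.05, 30))
  coh <- sample_cohort(pop, 400, seed = 7)
  sc <- scenario(-7, 0.012, 0.007, 0.3)
  beta <- generate_effects(coh$s_true, sc, seed = 8)
  y1 <- generate_phenotypes(coh$G, beta, sc, seed = 9)
  y2 <- generate_phenotypes(coh$G, beta, sc, seed = 9)
  expect_identical(y1, y2)
  # residual-free limit
  sc0 <- scenario(-7, 0.012, 0.007, 1e-9)
  y0 <- generate_phenotypes(coh$G, beta, sc0, seed = 10)
  expect_equal(y0, drop(coh$G %*% beta), tolerance = 1e-6)
  # covariates enter the mean
  X <- cbind(1, rnorm(400))
  yx <- generate_phenotypes(coh$G, beta, sc0, X = X, b = c(2, 1), seed = 11)
  expect_equal(yx, drop(coh$G %*% beta) + drop(X %*% c(2, 1)),
               tolerance = 1e-6)
  # variance decomposition over replicates: Var(y) ~ Var(G beta) + resid^2
  ys <- replicate(200, generate_phenotypes(coh$G, beta, sc))
  expect_equal(mean(apply(ys, 2, var)),
               var(drop(coh$G %*% beta)) + 0.09, tolerance = 0.02)
})

test_that("expected variance shares recover an analytic case", {
  # many moderately common variants: empirical shares over cohorts agree
  # with the closed-form 2q(1-q) sums
  pop <- tiny_population(s = rep(-0.01, 40), q = rep(0.1, 40))
  sc <- scenario(-7, 0.012, 0.007, 0.22)
  sh <- expected_variance_shares(pop, sc, n = 800, reps = 30, seed = 12)
  C <- 40 * 2 * 0.1 * 0.9
  v_fit <- 49 * 1e-4 * C
  v_non <- (0.007^2 + 0.012^2) * C
  tot <- v_fit + v_non + 0.22^2
  expect_equal(unname(sh["fitness"]), 100 * v_fit / tot, tolerance = 0.08)
  expect_equal(unname(sh["nonfitness"]), 100 * v_non / tot, tolerance = 0.1)
})

test_that("a one-replicate power study emits a complete table", {
  pop <- tiny_population(s = -rexp(60, 100), q = rbeta(60, 0.4, 8))
  res <- run_power_study(pop, pop, power_scenarios()["null"],
                         methods = c("cast_5", "wsum_all"),
                         R = 1, B = 9, n = 200, seed = 13)
  expect_equal(nrow(res), 2)
  expect_true(all(res$power %in% c(0, 1)))
  expect_equal(unique(res$replicates), 1)
})

test_that("power is monotone in the signal scale", {
  # paired seeds: scaling all effects up never loses rejections beyond noise
  set.seed(14)
  pop <- tiny_population(s = -rexp(50, 150), q = rbeta(50, 0.4, 6))
  nrep <- 60
  p_small <- p_big <- numeric(nrep)
  for (r in seq_len(nrep)) {
    coh <- sample_cohort(pop, 400, seed = 1000 + r)
    sc <- scenario(-7, 0.012, 0.007, 0.22)
    beta <- generate_effects(coh$s_true, sc, seed = 2000 + r)
    e <- rnorm(400, 0, 0.22)
    y1 <- drop(coh$G %*% beta) + e
    y2 <- drop(coh$G %*% (2 * beta)) + e
    c1 <- cohort_data(y1, matrix(1, 400, 1), coh$G, drop_monomorphic = FALSE)
    c2 <- cohort_data(y2, matrix(1, 400, 1), coh$G, drop_monomorphic = FALSE)
    p_small[r] <- cast_test(c1, 0.05)$p.value
    p_big[r] <- cast_test(c2, 0.05)$p.value
  }
  expect_gte(mean(p_big < 0.05), mean(p_small < 0.05))
})
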