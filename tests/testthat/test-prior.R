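test_that("conditional moments handle degenerate pseudo-populations", {
  # all-neutral: (0, 0) for every count
  neutral <- tiny_population(s = rep(0, 50), q = runif(50, 0.01, 0.5))
  for (k in c(1, 5, 40))
    expect_equal(conditional_moments(neutral, 100, k), c(shat = 0, vhat = 0))
  # single pseudo-variant: its s with zero variance, for any count
  single <- tiny_population(s = -0.01, q = 0.5)
  for (k in c(1, 50, 100))
    expect_equal(conditional_moments(single, 100, k),
                 c(shat = -0.01, vhat = 0))
  expect_error(conditional_moments(tiny_population(numeric(0), numeric(0)),
                                   100, 1), "empty")
  expect_error(conditional_moments(single, 100, 0), "k")
})

test_that("binomial weighting concentrates on frequency-compatible variants", {
  # two variants: rare-deleterious and common-neutral; a singleton count
  # should be attributed mostly to the rare one, a high count to the common
  pop <- tiny_population(s = c(-0.02, 0), q = c(0.005, 0.3))
  lo <- conditional_moments(pop, 200, 1)
  hi <- conditional_moments(pop, 200, 60)
  expect_gt(abs(lo["shat"]), abs(hi["shat"]))
  expect_lt(hi["shat"], 0)  # still a mixture, but barely
  expect_true(lo["vhat"] >= 0 && hi["vhat"] >= 0)
  # no pseudo-variant can plausibly yield the count -> explicit error
  tightpop <- tiny_population(s = c(-0.01), q = 1e-6)
  expect_error(conditional_moments(tightpop, 2000, 1900), "support")
})

test_that("exact count matching agrees with the binomial shortcut", {
  set.seed(33)
  pop <- tiny_population(s = -rexp(4000, 200) * rbinom(4000, 1, 0.7),
                         q = rbeta(4000, 0.3, 3))
  bw <- conditional_moments(pop, 100, 3)
  ex <- conditional_moments(pop, 100, 3, exact = TRUE, seed = 9)
  expect_lt(abs(bw["shat"] - ex["shat"]), 3 * sqrt(bw["vhat"] / 50))
})

test_that("simulated conditional moments agree with the PRF oracle at equilibrium", {
  # constant-size equilibrium: the forward simulator and the analytic
  # Poisson Random Field posterior must give the same (shat, vhat)
  N <- 400
  dfe <- dfe_config(neutral_mass = 0.3, gamma_shape = 1, gamma_scale = 0.004)
  pop <- equilibrium_population(N, dfe, muL = 0.03, seed = 77, n_sims = 25,
                                burn_mult = 8)
  expect_gt(nrow(pop$variants), 2000)
  n_chrom <- 200
  for (k in c(1, 10)) {
    sim <- conditional_moments(pop, n_chrom, k)
    prf <- prf_conditional_moments(dfe, N, n_chrom, k)
    # Monte-Carlo tolerance: binomial-weighted effective sample size
    w <- dbinom(k, n_chrom, pop$variants$q)
    n_eff <- sum(w)^2 / sum(w^2)
    mc_se <- sqrt(prf["vhat"] / n_eff)
    expect_lt(abs(sim["shat"] - prf["shat"]), 4 * mc_se + 1e-5)
  }
  # monotone burden on the simulator side as well
  s1 <- conditional_moments(pop, n_chrom, 1)["shat"]
  s20 <- conditional_moments(pop, n_chrom, 20)["shat"]
  expect_gt(abs(s1), abs(s20))
})

test_that("ethnicity of origin is the group with the highest frequency", {
  expect_identical(assign_origin(c(A = 0.012, B = 0.003)), "A")
  expect_identical(assign_origin(c(A = 0.05)), "A")
  # ties broken by declared order
  expect_identical(assign_origin(c(B = 0.01, A = 0.01)), "B")
  expect_error(assign_origin(c(A = 0, B = 0)), "monomorphic")
  expect_error(assign_origin(numeric(0)), "named")
})

test_that("build_prior uses the origin group's pseudo-data at its count", {
  set.seed(8)
  n <- 40
  strata <- rep(c("grpA", "grpB"), each = n / 2)
  G <- matrix(0L, n, 3)
  G[1:6, 1] <- 1L            # variant 1: more common in grpA
  G[21:22, 1] <- 1L
  G[23:30, 2] <- 1L          # variant 2: private to grpB
  G[c(1, 21), 3] <- 1L       # variant 3: tie -> first group level
  cohort <- cohort_data(rnorm(n), matrix(1, n, 1), G, strata = strata)
  # distinguishable pseudo-populations: grpA all -0.01, grpB all -0.03
  pops <- list(grpA = tiny_population(rep(-0.01, 30), rep(0.1, 30)),
               grpB = tiny_population(rep(-0.03, 30), rep(0.1, 30)))
  pr <- build_prior(cohort, pops)
  expect_s3_class(pr, "fitness_prior")
  expect_equal(pr$origin, c("grpA", "grpB", "grpA"))
  expect_equal(pr$shat, c(-0.01, -0.03, -0.01))
  expect_equal(pr$vhat, rep(0, 3))
  expect_equal(pr$count, c(6L, 8L, 1L))
  expect_equal(pr$n_chrom, rep(40L, 3))
  # missing group simulation is a configuration error
  expect_error(build_prior(cohort, pops["grpA"]), "missing pseudo-population")
})

test_that("build_prior collapses to zero under a fully neutral DFE", {
  cohort <- toy_cohort(n = 30, m = 5, seed = 2)
  pops <- list(pooled = tiny_population(rep(0, 100), rbeta(100, 0.5, 2)))
  pr <- build_prior(cohort, pops)
  expect_true(all(pr$shat == 0) && all(pr$vhat == 0))
})

test_that("counts without pseudo-variant support fall back to the nearest count", {
  n <- 50
  G <- matrix(0L, n, 1)
  G[1:49, 1] <- 2L   # count 98 of 100
  cohort <- cohort_data(rnorm(n), matrix(1, n, 1), G)
  # pseudo-variants so rare that the binomial weight underflows to zero
  pops <- list(pooled = tiny_population(c(-0.01, -0.02), c(1e-9, 2e-9)))
  expect_warning(pr <- build_prior(cohort, pops), "nearest")
  expect_true(is.finite(pr$shat) && pr$shat < 0)
})
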