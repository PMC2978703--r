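test_that("marginal moments collapse correctly in the degenerate corners", {
  cohort <- toy_cohort(n = 20, m = 4, seed = 3)
  spec1 <- model_spec(class_partition = FALSE)
  # null collapse: no genetic parameters -> mean Xb, covariance sigma_e2 I
  p0 <- parameter_set(b = 0.7, alpha = 0, delta_mean = 0, delta_var = 0,
                      sigma_beta2 = 0, sigma_e2 = 1.3, classes = "all")
  mm <- marginal_moments(p0, cohort, flat_prior(4, -0.01, 1e-4), spec1)
  expect_equal(mm$mean, rep(0.7, 20))
  expect_equal(mm$cov, diag(1.3, 20))
  # vhat = 0: homoscedastic random-effect (equal-weight) covariance
  p1 <- parameter_set(b = 0, alpha = 0.1, delta_mean = 2, delta_var = 5,
                      sigma_beta2 = 0.4, sigma_e2 = 0.9, classes = "all")
  mm1 <- marginal_moments(p1, cohort, flat_prior(4, -0.02, 0), spec1)
  G <- cohort$G
  expect_equal(mm1$cov, 0.4 * tcrossprod(G) + diag(0.9, 20))
  expect_equal(mm1$mean, drop(G %*% rep(0.1 + 2 * -0.02, 4)))
})

test_that("marginal moments match a Monte-Carlo simulation of the generative model", {
  set.seed(11)
  n <- 6; m <- 3
  G <- matrix(rbinom(n * m, 2, 0.4), n, m)
  X <- cbind(1, rnorm(n))
  cohort <- cohort_data(rnorm(n), X, G, drop_monomorphic = FALSE)
  prior <- data.frame(shat = c(-0.01, -0.003, 0), vhat = c(2e-3, 5e-4, 0))
  spec <- model_spec(class_partition = FALSE, delta_mode = "split")
  params <- parameter_set(b = c(0.5, -0.8), alpha = 0.15, delta_mean = 3,
                          delta_var = 4, sigma_beta2 = 0.05, sigma_e2 = 0.3,
                          classes = "all")
  mm <- marginal_moments(params, cohort, prior, spec)
  nrep <- 1e5
  mu_b <- 0.15 + 3 * prior$shat
  sd_b <- sqrt(16 * prior$vhat + 0.05)
  Y <- replicate(nrep, {
    beta <- rnorm(m, mu_b, sd_b)
    drop(X %*% c(0.5, -0.8)) + drop(G %*% beta) + rnorm(n, 0, sqrt(0.3))
  })
  emp_mean <- rowMeans(Y)
  emp_cov <- stats::cov(t(Y))
  se_mean <- sqrt(diag(mm$cov) / nrep)
  expect_true(all(abs(emp_mean - mm$mean) < 5 * se_mean))
  expect_lt(max(abs(emp_cov - mm$cov)), 0.03 * max(diag(mm$cov)))
})

test_that("Woodbury and dense likelihood paths agree to 1e-8", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 5 + 5 * seed; m <- seed + 2
    G <- matrix(rbinom(n * m, 2, 0.3), n, m)
    cohort <- cohort_data(rnorm(n), cbind(1, rnorm(n)), G,
                          drop_monomorphic = FALSE)
    prior <- data.frame(shat = -abs(rnorm(m, 0.01, 0.004)),
                        vhat = abs(rnorm(m, 1e-4, 3e-5)))
    params <- parameter_set(b = c(0.2, 1), alpha = 0.05, delta_mean = 2,
                            delta_var = 3, sigma_beta2 = 0.2, sigma_e2 = 0.7,
                            classes = "all")
    spec <- model_spec(class_partition = FALSE)
    expect_equal(
      emmpat_loglik(params, cohort, prior, spec, method = "dense"),
      emmpat_loglik(params, cohort, prior, spec, method = "woodbury"),
      tolerance = 1e-8)
  }
})

test_that("the likelihood has the expected analytic special cases", {
  set.seed(5)
  n <- 40
  y <- rnorm(n)
  y <- (y - mean(y)) / sd(y) * sqrt((n - 1) / n)   # MLE-standardized
  G <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  cohort <- cohort_data(y, matrix(1, n, 1), G, drop_monomorphic = FALSE)
  null_params <- parameter_set(b = 0, sigma_e2 = 1, classes = "all")
  spec <- model_spec(class_partition = FALSE)
  expect_equal(emmpat_loglik(null_params, cohort, flat_prior(2), spec),
               sum(dnorm(y, log = TRUE)), tolerance = 1e-10)
  # translation invariance: shift y and the intercept coefficient together
  shifted <- cohort_data(y + 5, matrix(1, n, 1), G, drop_monomorphic = FALSE)
  p5 <- parameter_set(b = 5, sigma_e2 = 1, classes = "all")
  expect_equal(emmpat_loglik(p5, shifted, flat_prior(2), spec),
               emmpat_loglik(null_params, cohort, flat_prior(2), spec),
               tolerance = 1e-10)
})

test_that("analytic gradients of the profiled likelihood match finite differences", {
  set.seed(21)
  n <- 80; m <- 10
  cohort <- toy_cohort(n = n, m = m, seed = 21,
                       classes = rep(c("ns", "nc"), 5),
                       X = cbind(1, rnorm(n)))
  prior <- data.frame(shat = -abs(rnorm(m, 0.005, 0.003)),
                      vhat = abs(rnorm(m, 2e-5, 1e-5)))
  for (mode in c("single", "split")) {
    spec <- model_spec(delta_mode = mode)
    cache <- emmpat:::make_model_cache(cohort, prior, spec)
    vp <- c(-1.5, emmpat:::softplus_inv(0.2), 2.2,
            emmpat:::softplus_inv(0.03), log(0.9))
    got <- emmpat:::profiled_eval(vp, cache, spec, want_grad = TRUE)$grad
    num <- vapply(seq_along(vp), function(i) {
      h <- 1e-6
      up <- dn <- vp; up[i] <- up[i] + h; dn[i] <- dn[i] - h
      (emmpat:::profiled_eval(up, cache, spec) -
         emmpat:::profiled_eval(dn, cache, spec)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(got - num)), 1e-5 * (1 + max(abs(num))))
  }
})

test_that("fitting with an uninformative prior equals the equal-weight random-effect model", {
  # all shat = vhat = 0: the model must coincide with the homoscedastic
  # variance-component (equal weight) fit; polishing our optimum with a
  # high-precision independent optimizer cannot improve it materially
  set.seed(31)
  n <- 150; m <- 12
  cohort <- toy_cohort(n = n, m = m, seed = 31)
  beta <- rnorm(m, 0.1, 0.3)
  cohort$y <- drop(cohort$G %*% beta) + rnorm(n, 0, 0.8)
  prior <- flat_prior(m)
  fit <- fit_emmpat(cohort, prior, model_spec(class_partition = FALSE))
  expect_true(fit$converged)
  # independent dense-matrix implementation of the equal-weight model
  kwee_negll <- function(par) {
    sb2 <- exp(par[1]); s2 <- exp(par[2]); a <- par[3]
    V <- sb2 * tcrossprod(cohort$G) + diag(s2, n)
    ch <- chol(V)
    r0 <- cohort$y - a * rowSums(cohort$G)
    xtv <- backsolve(ch, cbind(cohort$X, r0), transpose = TRUE)
    bhat <- solve(crossprod(xtv[, 1, drop = FALSE]),
                  crossprod(xtv[, 1, drop = FALSE], xtv[, 2]))
    r <- r0 - cohort$X %*% bhat
    z <- backsolve(ch, r, transpose = TRUE)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  start <- c(log(fit$params$sigma_beta2 + 1e-8), log(fit$params$sigma_e2),
             fit$params$alpha)
  polish <- optim(start, kwee_negll, control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(-polish$value - fit$loglik, 1e-4)
  expect_equal(fit$loglik, -kwee_negll(start), tolerance = 1e-6)
})

test_that("the likelihood is invariant to row and column reordering", {
  set.seed(41)
  cohort <- toy_cohort(n = 100, m = 9, seed = 41)
  cohort$y <- drop(cohort$G %*% rnorm(9, 0, 0.2)) + rnorm(100)
  prior <- data.frame(shat = -abs(rnorm(9, 0.005, 0.002)),
                      vhat = abs(rnorm(9, 2e-5, 1e-5)))
  spec <- model_spec(class_partition = FALSE)
  f0 <- fit_emmpat(cohort, prior, spec)
  pc <- sample(9); pr <- sample(100)
  cohort2 <- cohort_data(cohort$y[pr], cohort$X[pr, , drop = FALSE],
                         cohort$G[pr, pc], drop_monomorphic = FALSE)
  f1 <- fit_emmpat(cohort2, prior[pc, ], spec)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-5)
})

test_that("the split-delta fit is never worse than the single-delta fit", {
  for (seed in c(51, 52)) {
    cohort <- toy_cohort(n = 120, m = 10, seed = seed)
    prior <- data.frame(shat = -abs(rnorm(10, 0.005, 0.002)),
                        vhat = abs(rnorm(10, 2e-5, 1e-5)))
    cohort$y <- drop(cohort$G %*% (0.05 - 3 * prior$shat)) + rnorm(120, 0, 0.7)
    single <- fit_emmpat(cohort, prior, model_spec(delta_mode = "single",
                                                   class_partition = FALSE))
    split <- fit_emmpat(cohort, prior, model_spec(delta_mode = "split",
                                                  class_partition = FALSE))
    expect_gte(split$loglik, single$loglik - 1e-4)
  }
})

test_that("BLUPs shrink correctly and match the conditional-Gaussian oracle", {
  set.seed(61)
  n <- 12; m <- 4
  G <- matrix(rbinom(n * m, 2, 0.35), n, m)
  X <- cbind(rep(1, n))
  y <- rnorm(n)
  cohort <- cohort_data(y, X, G, drop_monomorphic = FALSE)
  prior <- data.frame(shat = c(-0.02, -0.005, -0.001, 0),
                      vhat = c(4e-3, 1e-3, 1e-4, 0))
  spec <- model_spec(class_partition = FALSE)
  params <- parameter_set(b = 0.2, alpha = 0.1, delta_mean = 2, delta_var = 3,
                          sigma_beta2 = 0.15, sigma_e2 = 0.5, classes = "all")
  fit <- fixed_fit(params, cohort, prior, spec)
  # dense-matrix conditional expectation E[beta | y] of the joint normal
  mu <- 0.1 + 2 * prior$shat
  D <- diag(9 * prior$vhat + 0.15)
  V <- G %*% D %*% t(G) + diag(0.5, n)
  oracle <- mu + drop(D %*% t(G) %*% solve(V, y - drop(X %*% 0.2) - G %*% mu))
  expect_equal(fit$blup$blup, oracle, tolerance = 1e-8)
  expect_true(all(fit$blup$se >= 0))
  expect_true(all(fit$blup$lower <= fit$blup$blup & fit$blup$blup <= fit$blup$upper))

  # no data shrinkage when the effect variance is zero
  p0 <- parameter_set(b = 0.2, alpha = 0.1, delta_mean = 2, delta_var = 0,
                      sigma_beta2 = 0, sigma_e2 = 0.5, classes = "all")
  f0 <- fixed_fit(p0, cohort, prior, spec)
  expect_equal(f0$blup$blup, 0.1 + 2 * prior$shat, tolerance = 1e-12)
})

test_that("perfectly correlated variants split their joint effect evenly", {
  set.seed(71)
  n <- 200
  g <- rbinom(n, 2, 0.05)
  g[1] <- max(g[1], 1)
  G2 <- cbind(a = g, b = g)             # duplicated column
  y <- 0.8 * g + rnorm(n, 0, 0.5)
  cohort2 <- cohort_data(y, matrix(1, n, 1), G2, drop_monomorphic = FALSE)
  cohort1 <- cohort_data(y, matrix(1, n, 1), cbind(a = g),
                         drop_monomorphic = FALSE)
  spec <- model_spec(class_partition = FALSE, include_alpha = FALSE)
  mkp <- function(m) parameter_set(b = 0, alpha = 0, delta_mean = 0,
                                   delta_var = 0, sigma_beta2 = 0.5,
                                   sigma_e2 = 0.25, classes = "all")
  f2 <- fixed_fit(mkp(2), cohort2, flat_prior(2), spec)
  f1 <- fixed_fit(mkp(1), cohort1, flat_prior(1), spec)
  expect_equal(f2$blup$blup[1], f2$blup$blup[2], tolerance = 1e-10)
  # the pair's combined fitted signal equals the single variant's:
  # 2 * beta_dup ~ beta_single requires doubling the effective variance;
  # with equal D the duplicated effect is close to half
  expect_lt(abs(2 * f2$blup$blup[1] / f1$blup$blup[1] - 1), 0.35)
})

test_that("single-variant OLS matches closed-form least squares", {
  # hand-checkable 5-row instance
  g <- c(0, 1, 2, 0, 1)
  y <- c(0.1, 2.2, 3.9, -0.1, 2.0)
  cohort <- cohort_data(y, matrix(1, 5, 1), cbind(v = g),
                        drop_monomorphic = FALSE)
  ols <- ols_single_variant(cohort)
  Xf <- cbind(1, g)
  cf <- solve(crossprod(Xf), crossprod(Xf, y))
  expect_equal(ols$estimate, cf[2], tolerance = 1e-12)
  resid <- y - Xf %*% cf
  s2 <- sum(resid^2) / (5 - 2)
  expect_equal(ols$se, sqrt(s2 * solve(crossprod(Xf))[2, 2]), tolerance = 1e-12)

  # exact signal recovers the slope; centering covariates changes nothing
  set.seed(81)
  n <- 50
  g2 <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 50, 8)
  y2 <- 2 * g2 + 0.1 * age
  c1 <- cohort_data(y2, cbind(1, age), cbind(v = g2), drop_monomorphic = FALSE)
  c2 <- cohort_data(y2, cbind(1, age - mean(age)), cbind(v = g2),
                    drop_monomorphic = FALSE)
  expect_equal(ols_single_variant(c1)$estimate, 2, tolerance = 1e-10)
  expect_equal(ols_single_variant(c1)$estimate,
               ols_single_variant(c2)$estimate, tolerance = 1e-10)
  # collinear variant flagged
  c3 <- cohort_data(y2, cbind(1, g2), cbind(v = g2), drop_monomorphic = FALSE)
  expect_false(ols_single_variant(c3)$ok)
})
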