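# shared fixture builders; everything is generated in code at test time

# wrap explicit (s, q) pairs as a pseudo-population
tiny_population <- function(s, q, pop_size = 1000) {
  structure(list(variants = data.frame(s = s, q = q), pop_size = pop_size,
                 meta = list(seed = NA, mutation_rate = NA, locus_length = NA,
                             rescale_factor = 1)),
            class = "pseudo_population")
}

# a small cohort with random genotypes and a null phenotype
toy_cohort <- function(n = 60, m = 8, seed = 1, strata = NULL,
                       classes = NULL, q = NULL, X = NULL, y = NULL) {
  set.seed(seed)
  if (is.null(q)) q <- runif(m, 0.05, 0.4)
  G <- matrix(rbinom(n * m, 2, rep(q, each = n)), n, m)
  # regenerate monomorphic columns deterministically
  for (j in which(apply(G, 2, function(g) length(unique(g)) == 1))) {
    G[1, j] <- if (G[1, j] == 0) 1 else G[1, j] - 1
  }
  if (is.null(X)) X <- cbind(intercept = rep(1, n))
  if (is.null(y)) y <- rnorm(n)
  cohort_data(y, X, G, strata = strata, classes = classes,
              drop_monomorphic = FALSE)
}

# a prior data frame with given moments (defaults: uninformative)
flat_prior <- function(m, shat = 0, vhat = 0) {
  data.frame(shat = rep(shat, length.out = m), vhat = rep(vhat, length.out = m))
}

# fabricate a fit object around known parameters, for exercising blup /
# decomposition formulas without running the optimizer
fixed_fit <- function(params, cohort, prior, spec = model_spec()) {
  cls <- emmpat:::model_classes(cohort, spec)
  fit <- structure(list(params = params, spec = spec, cls = cls,
                        converged = TRUE, loglik = NA_real_,
                        n = length(cohort$y), m = ncol(cohort$G)),
                   class = "emmpat_fit")
  fit$blup <- blup(fit, cohort, prior)
  fit
}

# constant-size equilibrium simulation (shared across prior/PRF tests)
equilibrium_population <- function(N, dfe, muL, seed, n_sims = 1,
                                   burn_mult = 10) {
  dem <- demography_model(data.frame(duration = 2 * N, size = N, growth = 0))
  pops <- lapply(seq_len(n_sims), function(i)
    simulate_population(dem, dfe, locus_length = 1, mu = muL,
                        seed = seed + i, burn_mult = burn_mult))
  tiny_population(s = unlist(lapply(pops, function(p) p$variants$s)),
                  q = unlist(lapply(pops, function(p) p$variants$q)),
                  pop_size = N)
}

# independent brute-force oracle: plain Riemann sums, a log-spaced panel for
# the 1/q singularity plus a dense linear panel
brute_prf_moments <- function(dfe, N, n_chrom, k, n_q = 30000, n_s = 400) {
  u <- seq(log(1e-9), log(0.01), length.out = n_q)
  q1 <- exp(u)
  w1 <- q1 * (u[2] - u[1])
  q2 <- seq(0.01, 1 - 1e-9, length.out = n_q)
  w2 <- rep(q2[2] - q2[1], n_q)
  qs <- c(q1, q2)
  wq <- c(w1, w2)
  sgrid <- -qgamma((seq_len(n_s) - 0.5) / n_s,
                   shape = dfe$gamma_shape, scale = dfe$gamma_scale)
  w_s <- rep((1 - dfe$neutral_mass) / n_s, n_s)
  sgrid <- c(0, sgrid)
  w_s <- c(dfe$neutral_mass, w_s)
  lik <- dbinom(k, n_chrom, qs)
  m0 <- m1 <- m2 <- 0
  for (i in seq_along(sgrid)) {
    sig <- 4 * N * sgrid[i]
    dens <- if (abs(sig) < 1e-12) 1 / qs
            else exp(sig * qs) * (-expm1(sig * (1 - qs))) /
                   (qs * (1 - qs) * (-expm1(sig)))
    wk <- w_s[i] * sum(dens * lik * wq)
    m0 <- m0 + wk
    m1 <- m1 + wk * sgrid[i]
    m2 <- m2 + wk * sgrid[i]^2
  }
  shat <- m1 / m0
  c(shat = shat, vhat = m2 / m0 - shat^2)
}

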