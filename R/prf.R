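# Equilibrium Poisson Random Field moments of the selection coefficient
# given a sampled allele count.  Serves as the analytic oracle for the
# forward simulator at constant population size.

# Wright's sojourn density for genic selection at population-scaled
# sigma = 4Ns, up to the mutation-rate constant (which cancels in the
# posterior):  t(q; sigma) = (1 - exp(-sigma(1-q))) / (q(1-q)(1 - exp(-sigma)))
# with the neutral limit 1/q at sigma = 0.
sojourn_density <- function(q, sigma) {
  if (abs(sigma) < 1e-12) return(1 / q)
  if (sigma < 0) {
    # factor out exp(|sigma|) so strongly deleterious coefficients cannot
    # overflow: (e^{a(1-q)} - 1)/(e^a - 1) = e^{-aq} (1 - e^{-a(1-q)})/(1 - e^{-a})
    a <- -sigma
    return(exp(-a * q) * (-expm1(-a * (1 - q))) /
             (q * (1 - q) * (-expm1(-a))))
  }
  expm1(-sigma * (1 - q)) / (q * (1 - q) * expm1(-sigma))
}

#' Conditional fitness moments under equilibrium PRF theory
#'
#' Computes the posterior mean and variance of the selection coefficient
#' \code{s} of a variant observed \code{k} times among \code{n_chrom}
#' sampled chromosomes, in a constant-size equilibrium population.  The
#' frequency density for a variant with coefficient \code{s} is Wright's
#' sojourn density at \code{sigma = 4Ns}; this is mixed over the DFE and
#' combined with \code{Binomial(k; n_chrom, q)} sampling, and the moments
#' are evaluated by deterministic Gauss-Legendre quadrature (log-warped in
#' \code{q} near zero, equal-probability gamma bins in \code{s}).
#'
#' @param dfe a \code{\link{dfe_config}}.
#' @param N constant diploid population size.
#' @param n_chrom number of sampled chromosomes.
#' @param k observed derived-allele count, \code{1 <= k <= n_chrom}.
#' @param quad quadrature settings: \code{n_s} gamma bins for the
#'   deleterious component, \code{n_q} nodes per frequency panel.
#' @return Named numeric vector \code{c(shat, vhat)}.
#' @examples
#' prf_conditional_moments(dfe_config(0.5, 0.5, 0.002), N = 1000,
#'                         n_chrom = 200, k = 1)
#' @export
prf_conditional_moments <- function(dfe, N, n_chrom, k,
                                    quad = list(n_s = 400, n_q = 240)) {
  stopifnot(inherits(dfe, "dfe_config"))
  if (k < 1 || k > n_chrom) stop("'k' must satisfy 1 <= k <= n_chrom", call. = FALSE)
  if (dfe$neutral_mass == 1) return(c(shat = 0, vhat = 0))

  # s grid: equal-probability bins of the gamma component, bin medians
  n_s <- quad$n_s
  p_mid <- (seq_len(n_s) - 0.5) / n_s
  s_grid <- -qgamma(p_mid, shape = dfe$gamma_shape, scale = dfe$gamma_scale)
  w_s <- rep((1 - dfe$neutral_mass) / n_s, n_s)
  s_grid <- c(0, s_grid)
  w_s <- c(dfe$neutral_mass, w_s)

  # q quadrature: log panel (0, 0.5] handles the 1/q singularity, linear
  # panel [0.5, 1)
  n_q <- quad$n_q
  lo <- log(min(1e-9, 0.01 / n_chrom))
  gl1 <- pracma::gaussLegendre(n_q, lo, log(0.5))
  q1 <- exp(gl1$x)
  wq1 <- gl1$w * q1                      # Jacobian of q = exp(u)
  gl2 <- pracma::gaussLegendre(n_q, 0.5, 1 - 1e-9)
  qs <- c(q1, gl2$x)
  wqs <- c(wq1, gl2$w)

  lik <- dbinom(k, n_chrom, qs)
  m0 <- m1 <- m2 <- 0
  for (i in seq_along(s_grid)) {
    s <- s_grid[i]
    dens <- sojourn_density(qs, 4 * N * s)
    wk <- w_s[i] * sum(wqs * dens * lik)
    if (!is.finite(wk))
      stop("PRF quadrature produced a non-finite weight (s = ", s,
           ", sigma = ", 4 * N * s, ")", call. = FALSE)
    m0 <- m0 + wk
    m1 <- m1 + wk * s
    m2 <- m2 + wk * s^2
  }
  if (m0 <= 0)
    stop("PRF quadrature has no posterior mass for k = ", k, call. = FALSE)
  shat <- m1 / m0
  vhat <- max(m2 / m0 - shat^2, 0)
  c(shat = shat, vhat = vhat)
}
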