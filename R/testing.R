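#' Maximum-likelihood fit of the covariates-only null model
#'
#' The global null -- no relationship between any genotype and any aspect
#' of the phenotype -- is the Gaussian regression of the phenotype on the
#' covariates alone, fit in closed form by maximum likelihood (residual
#' variance divided by n, not n - p).
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @return A list of class \code{emmpat_null} with \code{b},
#'   \code{sigma_e2}, \code{loglik}, and a \code{degenerate} flag raised
#'   when the covariates fit the phenotype exactly.
#' @export
fit_null <- function(cohort) {
  X <- cohort$X
  y <- cohort$y
  n <- length(y)
  ls <- stats::lm.fit(X, y)
  s2 <- mean(ls$residuals^2)
  degenerate <- s2 < 1e-12 * max(1, mean(y^2))
  ll <- if (degenerate) Inf else -0.5 * n * (log(2 * pi * s2) + 1)
  structure(list(b = ls$coefficients, sigma_e2 = s2, loglik = ll,
                 degenerate = degenerate, n = n),
            class = "emmpat_null")
}

# a random permutation of individuals that only moves members within the
# same stratum; strata of size one are fixed points
strata_permutation <- function(strata) {
  idx <- seq_along(strata)
  for (g in levels(strata)) {
    rows <- which(strata == g)
    if (length(rows) > 1) idx[rows] <- rows[sample.int(length(rows))]
  }
  idx
}

# permute genotype rows within strata
permute_within_strata <- function(G, strata) {
  G[strata_permutation(strata), , drop = FALSE]
}

#' Permutation-calibrated likelihood-ratio test of the global null
#'
#' The observed statistic is twice the gap between the maximized mixed-model
#' log-likelihood and the covariates-only null log-likelihood.  Its null
#' distribution is obtained by randomly swapping genotype vectors between
#' members of the same stratum (ethnicity) and refitting: permutation keeps
#' each variant's per-stratum allele counts -- and therefore the fitness
#' prior -- exactly fixed, while breaking any genotype-phenotype link.  The
#' p-value uses the add-one convention \code{(1 + #\{perm >= obs\}) /
#' (B + 1)} and so never returns zero.  Permutation refits are warm-started
#' at the observed optimum (with the standard starts as backup), which does
#' not change the maximized values.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param prior a \code{\link{build_prior}} result.
#' @param spec a \code{\link{model_spec}}.
#' @param B number of permutations (>= 1); 500 is the power-study default
#'   and 10000 is typical for a single-gene analysis.
#' @param seed master seed; per-permutation seeds are derived from it so
#'   results are reproducible.
#' @param control passed to \code{\link{fit_emmpat}}.
#' @return An object of class \code{emmpat_test}: \code{lrt_stat},
#'   \code{p_perm}, \code{n_perm}, \code{perm_stats}, plus the observed
#'   \code{fit} and \code{null} fits.
#' @export
permutation_test <- function(cohort, prior, spec = model_spec(), B = 500,
                             seed = NULL, control = list()) {
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  sizes <- tabulate(cohort$strata)
  if (any(sizes == 1))
    warning("stratum of size 1: that individual is a fixed point of the permutations",
            call. = FALSE)
  null <- fit_null(cohort)
  fit <- fit_emmpat(cohort, prior, spec, control)
  lrt <- 2 * (fit$loglik - null$loglik)

  if (!is.null(seed)) set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, B)
  perm_stats <- numeric(B)
  # swapping genotype vectors within a stratum is carried out as the
  # inverse permutation of the phenotype/covariate rows, which lets the
  # genotype cross-products be cached across permutations
  ctl <- utils::modifyList(list(maxit = 200, reltol = 1e-8, gtol = 0.05),
                           control)
  cache <- make_model_cache(cohort, prior, spec)
  for (b in seq_len(B)) {
    set.seed(perm_seeds[b])
    perm <- strata_permutation(cohort$strata)
    fb <- refit_permuted(cache, perm, spec, ctl, warm = fit$vpar)
    perm_stats[b] <- if (is.null(fb)) NA_real_
                     else 2 * (fb$loglik - null$loglik)
  }
  perm_stats <- perm_stats[!is.na(perm_stats)]
  p <- (1 + sum(perm_stats >= lrt)) / (length(perm_stats) + 1)
  structure(list(lrt_stat = lrt, p_perm = p, n_perm = length(perm_stats),
                 perm_stats = perm_stats, fit = fit, null = null,
                 seed = seed),
            class = "emmpat_test")
}

#' @export
print.emmpat_test <- function(x, ...) {
  cat(sprintf("Permutation likelihood-ratio test: LRT = %.4f, p = %.4g (%d permutations)\n",
              x$lrt_stat, x$p_perm, x$n_perm))
  invisible(x)
}
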