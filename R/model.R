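#' Model specification
#'
#' Controls which parts of the evolutionary mixed model are estimated.
#'
#' @param include_alpha estimate the mean derived-allele offset (otherwise
#'   fixed at zero).
#' @param delta_mode \code{"single"} ties the fitness-scaling parameter in
#'   the mean and the variance models; \code{"split"} fits them separately
#'   as a robustness check (the split fit is never worse in likelihood).
#' @param class_partition estimate (alpha, delta, sigma_beta2) separately
#'   per variant class; residual variance and covariate effects are always
#'   shared.
#' @param rare_threshold frequency cutoff used by diagnostics and
#'   rare-variant subsets (not by the model itself).
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(include_alpha = TRUE,
                       delta_mode = c("single", "split"),
                       class_partition = TRUE,
                       rare_threshold = 0.01) {
  delta_mode <- match.arg(delta_mode)
  structure(list(include_alpha = include_alpha, delta_mode = delta_mode,
                 class_partition = class_partition,
                 rare_threshold = rare_threshold),
            class = "model_spec")
}

# variant class factor actually used by the model
model_classes <- function(cohort, spec) {
  if (isTRUE(spec$class_partition)) factor(cohort$classes)
  else factor(rep("all", ncol(cohort$G)))
}

#' Parameter set of the evolutionary mixed model
#'
#' @param b fixed-effect (covariate) coefficients.
#' @param alpha per-class mean derived-allele effect (phenotype units per
#'   allele).
#' @param delta_mean per-class fitness-phenotype scaling in the mean model.
#' @param delta_var per-class fitness-phenotype scaling in the variance
#'   model (equal to \code{delta_mean} when the single-delta model is fit).
#' @param sigma_beta2 per-class fitness-independent effect variance
#'   (phenotype squared); non-negative.
#' @param sigma_e2 residual variance; positive.
#' @param classes class labels the per-class parameters refer to.
#' @return An object of class \code{parameter_set}.
#' @export
parameter_set <- function(b, alpha = 0, delta_mean = 0, delta_var = delta_mean,
                          sigma_beta2 = 0, sigma_e2 = 1, classes = "variant") {
  k <- length(classes)
  rec <- function(x) {
    if (length(x) == 1) x <- rep(x, k)
    if (length(x) != k) stop("per-class parameter of wrong length", call. = FALSE)
    stats::setNames(as.numeric(x), classes)
  }
  if (any(sigma_beta2 < 0)) stop("'sigma_beta2' must be >= 0", call. = FALSE)
  if (sigma_e2 <= 0) stop("'sigma_e2' must be > 0", call. = FALSE)
  structure(list(b = as.numeric(b), alpha = rec(alpha),
                 delta_mean = rec(delta_mean), delta_var = rec(delta_var),
                 sigma_beta2 = rec(sigma_beta2), sigma_e2 = sigma_e2,
                 classes = classes),
            class = "parameter_set")
}

# per-variant prior mean of the effect and effect variance implied by params
variant_prior_mean <- function(params, prior, cls) {
  params$alpha[as.character(cls)] +
    params$delta_mean[as.character(cls)] * prior$shat
}
variant_prior_var <- function(params, prior, cls) {
  params$delta_var[as.character(cls)]^2 * prior$vhat +
    params$sigma_beta2[as.character(cls)]
}

#' Marginal mean and covariance of the phenotype
#'
#' The two-moment model: integrating the per-variant effects out of the
#' regression gives marginal mean \code{X b + G (alpha + delta_mean shat)}
#' and covariance \code{G D G' + sigma_e2 I} with
#' \code{D = diag(delta_var^2 vhat + sigma_beta2)} -- individuals carrying
#' a burden of rare alleles drift in mean and gain variability.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param cohort a \code{\link{cohort_data}}.
#' @param prior a \code{\link{build_prior}} result aligned with the cohort's
#'   variants.
#' @param spec a \code{\link{model_spec}} (controls the class partition).
#' @return A list with \code{mean} (length n) and \code{cov} (n x n).
#' @export
marginal_moments <- function(params, cohort, prior, spec = model_spec()) {
  cls <- model_classes(cohort, spec)
  mu <- variant_prior_mean(params, prior, cls)
  D <- variant_prior_var(params, prior, cls)
  mean <- drop(cohort$X %*% params$b + cohort$G %*% mu)
  GD <- sweep(cohort$G, 2, D, `*`)
  cov <- tcrossprod(GD, cohort$G)
  diag(cov) <- diag(cov) + params$sigma_e2
  list(mean = mean, cov = cov)
}

#' Gaussian quasi-log-likelihood of the marginal model
#'
#' Evaluates the Gaussian log-density of the phenotype at the marginal
#' moments.  The \code{"woodbury"} path works in the m-dimensional inner
#' form (matrix-determinant lemma), so the cost scales with the number of
#' variants rather than n^3; the \code{"dense"} path factorizes the full
#' n x n covariance.  Both agree to numerical precision.
#'
#' @inheritParams marginal_moments
#' @param method evaluation path; \code{"auto"} picks woodbury when m < n.
#' @return The log-likelihood (a scalar).
#' @export
emmpat_loglik <- function(params, cohort, prior, spec = model_spec(),
                          method = c("auto", "woodbury", "dense")) {
  method <- match.arg(method)
  n <- length(cohort$y)
  m <- ncol(cohort$G)
  if (method == "auto") method <- if (m < n) "woodbury" else "dense"
  cls <- model_classes(cohort, spec)
  mu <- variant_prior_mean(params, prior, cls)
  r <- cohort$y - drop(cohort$X %*% params$b) - drop(cohort$G %*% mu)
  D <- variant_prior_var(params, prior, cls)
  s2 <- params$sigma_e2
  if (method == "dense") {
    GD <- sweep(cohort$G, 2, D, `*`)
    V <- tcrossprod(GD, cohort$G)
    diag(V) <- diag(V) + s2
    ch <- chol(V)
    z <- backsolve(ch, r, transpose = TRUE)
    return(-0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)))
  }
  d <- sqrt(D)
  A <- crossprod(cohort$G)
  B <- A * tcrossprod(d)
  diag(B) <- diag(B) + s2
  ch <- chol(B)
  gr <- d * drop(crossprod(cohort$G, r))
  z <- backsolve(ch, gr, transpose = TRUE)
  quad <- (sum(r^2) - sum(z^2)) / s2
  logdet <- (n - m) * log(s2) + 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

## ------------------------------------------------------------------
## fast profiled evaluator
##
## All inner products under V^{-1} are reduced to the m x m system
##   B = D^{1/2} G'G D^{1/2} + sigma_e2 I,
##   a' V^{-1} b = (a'b - (D^{1/2}G'a)' B^{-1} (D^{1/2}G'b)) / sigma_e2,
## with G'[X, u_c, w_c, y] cached once per dataset.  The linear mean
## parameters (covariates b, per-class alpha, and in the split model the
## per-class delta_mean) are profiled out by generalized least squares at
## each variance evaluation.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-300))))

make_model_cache <- function(cohort, prior, spec) {
  cls <- model_classes(cohort, spec)
  lev <- levels(cls)
  G <- cohort$G
  X <- cohort$X
  y <- cohort$y
  n <- length(y)
  m <- ncol(G)
  p <- ncol(X)
  ind <- vapply(lev, function(l) as.numeric(cls == l), numeric(m))
  ind <- matrix(ind, nrow = m)
  U <- G %*% ind                                   # n x C burden per class
  W <- G %*% (ind * prior$shat)                    # n x C shat-weighted burden
  F_ <- cbind(X, U, W, y)
  ix <- list(X = seq_len(p), u = p + seq_along(lev),
             w = p + length(lev) + seq_along(lev),
             y = p + 2 * length(lev) + 1L)
  # mean design columns for each mode, pruned once for collinearity
  zc_split <- c(ix$X, if (spec$include_alpha) ix$u, ix$w)
  zc_single <- c(ix$X, if (spec$include_alpha) ix$u)
  prune <- function(cols) {
    qrz <- qr(F_[, cols, drop = FALSE])
    cols[qrz$pivot[seq_len(qrz$rank)]]
  }
  list(M = crossprod(F_), GtF = crossprod(G, F_), A = crossprod(G),
       F_ = F_, G = G, X = X, y = y,
       n = n, m = m, p = p, lev = lev, cls = cls,
       shat = prior$shat, vhat = prior$vhat, ix = ix,
       zcols = if (spec$delta_mode == "split") prune(zc_split) else prune(zc_single))
}

# unpack the optimizer's variance-parameter vector
# layout: per class (delta_raw, theta_sb), then theta_e
unpack_vpar <- function(vp, cache) {
  C <- length(cache$lev)
  delta_raw <- vp[seq(1, 2 * C, by = 2)]
  sigma_beta2 <- softplus(vp[seq(2, 2 * C, by = 2)])
  sigma_e2 <- exp(vp[2 * C + 1])
  list(delta_raw = delta_raw, sigma_beta2 = sigma_beta2, sigma_e2 = sigma_e2)
}

profiled_eval <- function(vp, cache, spec, want_coef = FALSE,
                          want_grad = FALSE) {
  bad <- if (want_coef) list(ll = -Inf) else
    if (want_grad) list(ll = -Inf, grad = rep(0, length(vp))) else -Inf
  vpar <- unpack_vpar(vp, cache)
  if (!all(is.finite(c(vpar$delta_raw, vpar$sigma_beta2, vpar$sigma_e2))))
    return(bad)
  ci <- as.integer(cache$cls)
  D <- vpar$delta_raw[ci]^2 * cache$vhat + vpar$sigma_beta2[ci]
  s2 <- vpar$sigma_e2
  m <- cache$m
  d <- sqrt(D)
  B <- d * cache$A * rep(d, each = m)
  diag(B) <- diag(B) + s2
  ch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(ch)) return(bad)
  E <- d * cache$GtF
  W1 <- backsolve(ch, E, transpose = TRUE)          # L^{-1} D^{1/2} G'F
  GramV <- (cache$M - crossprod(W1)) / s2
  logdet <- (cache$n - m) * log(s2) + 2 * sum(log(diag(ch)))

  ix <- cache$ix
  zc <- cache$zcols
  # single-delta mode: delta enters the mean as a known-coefficient offset
  co <- if (spec$delta_mode == "single") vpar$delta_raw else numeric(length(ix$w))
  Gzy <- GramV[zc, ix$y] - GramV[zc, ix$w, drop = FALSE] %*% co
  yy <- GramV[ix$y, ix$y] -
    2 * sum(co * GramV[ix$w, ix$y]) +
    drop(t(co) %*% GramV[ix$w, ix$w, drop = FALSE] %*% co)
  Gzz <- GramV[zc, zc, drop = FALSE]
  theta <- tryCatch(solve(Gzz, Gzy), error = function(e) NULL)
  if (is.null(theta)) {
    theta <- tryCatch(qr.solve(Gzz, Gzy, tol = 1e-12), error = function(e) NULL)
    if (is.null(theta)) return(bad)
  }
  theta <- drop(theta)
  rss <- drop(yy - 2 * sum(theta * Gzy) + t(theta) %*% Gzz %*% theta)
  ll <- -0.5 * (cache$n * log(2 * pi) + logdet + rss)
  if (!is.finite(ll)) ll <- -Inf
  if (want_coef && !want_grad)
    return(list(ll = ll, theta = theta, vpar = vpar, D = D))
  if (!want_grad) return(ll)
  if (!is.finite(ll)) return(bad)

  ## analytic gradient.  The linear coefficients are profiled exactly, so
  ## by the envelope theorem only the explicit dependence on the variance
  ## parameters contributes (plus, in the single-delta model, the mean
  ## offset's direct dependence on delta).
  k <- ncol(cache$M)
  comb <- numeric(k)                              # r = F %*% comb
  comb[ix$y] <- 1
  comb[zc] <- comb[zc] - theta
  if (spec$delta_mode == "single") comb[ix$w] <- comb[ix$w] - co
  gr_v <- drop(cache$GtF %*% comb)                # G'r
  rr <- drop(crossprod(comb, cache$M %*% comb))   # r'r
  u1 <- backsolve(ch, backsolve(ch, d * gr_v, transpose = TRUE))  # B^{-1} d G'r
  t_vec <- (gr_v - drop(cache$A %*% (d * u1))) / s2               # G'V^{-1}r
  du1 <- d * u1
  norm_Vr2 <- (rr - 2 * sum(gr_v * du1) +
               drop(crossprod(du1, cache$A %*% du1))) / s2^2
  Y <- backsolve(ch, d * cache$A, transpose = TRUE)
  diagQ <- (diag(cache$A) - colSums(Y^2)) / s2    # diag of G'V^{-1}G
  # s2 V^{-1} = I - V^{-1} G D G'  =>  tr(V^{-1}) = (n - sum(D diagQ)) / s2
  trVinv <- (cache$n - sum(D * diagQ)) / s2

  C <- length(cache$lev)
  grad <- numeric(2 * C + 1)
  t2 <- t_vec^2
  for (cc in seq_len(C)) {
    jc <- ci == cc
    S_c <- sum(diagQ[jc]);  T_c <- sum(t2[jc])
    Sv_c <- sum(cache$vhat[jc] * diagQ[jc])
    Tv_c <- sum(cache$vhat[jc] * t2[jc])
    g_delta <- -vpar$delta_raw[cc] * (Sv_c - Tv_c)
    if (spec$delta_mode == "single") {
      # mean-offset term: w_c' V^{-1} r
      wcol <- ix$w[cc]
      wVr <- (cache$M[wcol, ] %*% comb -
              sum((d * cache$GtF[, wcol]) * u1)) / s2
      g_delta <- g_delta + drop(wVr)
    }
    grad[2 * cc - 1] <- g_delta
    grad[2 * cc] <- -0.5 * (S_c - T_c) * stats::plogis(vp[2 * cc])
  }
  grad[2 * C + 1] <- -0.5 * (trVinv - norm_Vr2) * s2
  list(ll = ll, grad = grad, theta = theta, vpar = vpar, D = D)
}

# reassemble a full parameter_set from optimizer + profiled coefficients
assemble_params <- function(vp, cache, spec) {
  ev <- profiled_eval(vp, cache, spec, want_coef = TRUE)
  C <- length(cache$lev)
  theta_full <- stats::setNames(numeric(ncol(cache$M)), NULL)
  theta_full[cache$zcols] <- ev$theta
  b <- theta_full[cache$ix$X]
  alpha <- theta_full[cache$ix$u]
  if (spec$delta_mode == "split") {
    delta_mean <- theta_full[cache$ix$w]
    delta_var <- ev$vpar$delta_raw
  } else {
    delta_mean <- delta_var <- ev$vpar$delta_raw
  }
  params <- parameter_set(b = b, alpha = alpha, delta_mean = delta_mean,
                          delta_var = delta_var,
                          sigma_beta2 = ev$vpar$sigma_beta2,
                          sigma_e2 = ev$vpar$sigma_e2, classes = cache$lev)
  list(params = params, loglik = ev$ll)
}

## ------------------------------------------------------------------

# standard starting points for the variance-parameter vector: a null start,
# a start from the ordinary least-squares fit of the full mean model, and a
# deterministically perturbed copy
make_starts <- function(cache) {
  C <- length(cache$lev)
  Xcols <- cache$F_[, cache$ix$X, drop = FALSE]
  y <- cache$F_[, cache$ix$y]
  s2_0 <- mean(stats::lm.fit(Xcols, y)$residuals^2)
  ls1 <- stats::lm.fit(cache$F_[, -cache$ix$y, drop = FALSE], y)
  cf1 <- ls1$coefficients
  cf1[is.na(cf1)] <- 0
  delta0 <- cf1[cache$ix$w]
  s2_1 <- mean(ls1$residuals^2)
  mk <- function(delta, sb2, s2) {
    vp <- numeric(2 * C + 1)
    vp[seq(1, 2 * C, 2)] <- delta
    vp[seq(2, 2 * C, 2)] <- softplus_inv(sb2)
    vp[2 * C + 1] <- log(s2)
    vp
  }
  list(null = mk(rep(0, C), rep(1e-4 * s2_0, C), s2_0),
       mean_model = mk(delta0, rep(0.01 * s2_0, C), s2_1),
       perturbed = mk(delta0 * 1.5 + 0.02, rep(0.1 * s2_0, C), s2_1 * 1.2))
}

# BFGS (analytic gradient) from each start; returns the best optimum and
# the gradient norm there.  The likelihood is evaluated often during line
# searches, the gradient only once per accepted step, so the two are
# computed separately.
optimize_from_starts <- function(cache, spec, ctl, starts) {
  negll <- function(vp) -profiled_eval(vp, cache, spec)
  neggr <- function(vp) -profiled_eval(vp, cache, spec, want_grad = TRUE)$grad
  best <- NULL
  info <- list()
  for (nm in names(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[nm]], negll, neggr, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    info[[nm]] <- c(value = -opt$value, convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(list(opt = NULL))
  list(opt = best, gnorm = sqrt(sum(neggr(best$par)^2)), info = info)
}

# refit on data with permuted phenotype/covariate rows, reusing the heavy
# genotype cross-products: G'G and the genotype-only blocks of the Gram
# matrix are invariant under row permutation, so only the X- and y-involved
# blocks are rebuilt.  Warm-started at `warm`; falls back to the standard
# multi-start search if the warm run does not converge.
refit_permuted <- function(cache, perm, spec, ctl, warm) {
  k <- ncol(cache$F_)
  xy <- c(cache$ix$X, cache$ix$y)
  Fp <- cache$F_
  Fp[, xy] <- Fp[perm, xy]
  cache$F_ <- Fp
  cache$M[xy, ] <- crossprod(Fp[, xy, drop = FALSE], Fp)
  cache$M[, xy] <- t(cache$M[xy, , drop = FALSE])
  cache$GtF[, xy] <- crossprod(cache$G, Fp[, xy, drop = FALSE])
  best <- optimize_from_starts(cache, spec, ctl, list(warm = warm))
  if (is.null(best$opt) || best$opt$convergence != 0) {
    more <- optimize_from_starts(cache, spec, ctl, make_starts(cache))
    if (is.null(best$opt) ||
        (!is.null(more$opt) && more$opt$value < best$opt$value))
      best <- more
  }
  if (is.null(best$opt)) return(NULL)
  list(loglik = -best$opt$value, vpar = best$opt$par)
}

#' Fit the evolutionary mixed model
#'
#' Maximizes the Gaussian quasi-log-likelihood over the fitness-scaling and
#' variance parameters, with the linear mean parameters (covariate effects,
#' per-class allele offsets and, in the split model, the mean-model
#' fitness scaling) profiled out by generalized least squares at every
#' variance evaluation.  Variance parameters are transformed so the
#' covariance stays positive definite (log residual variance, softplus for
#' the fitness-independent effect variance); optimization is quasi-Newton
#' (BFGS) from several starting points -- a null start, a start from the
#' mean-model least-squares fit, and a perturbed copy -- and the best
#' converged optimum is returned.
#'
#' @inheritParams marginal_moments
#' @param spec a \code{\link{model_spec}}.
#' @param control list with \code{maxit} (default 200), \code{reltol}
#'   (default 1e-10) and \code{gtol} (gradient-norm tolerance for the
#'   convergence flag, default 1e-3).
#' @param warm_start optional variance-parameter vector used as an
#'   additional (first) starting point, e.g. the optimum from a previous
#'   fit of the same model on permuted data.
#' @return An object of class \code{emmpat_fit}: parameter estimates,
#'   maximized log-likelihood, per-variant BLUPs with prediction standard
#'   errors, fitted means, and convergence diagnostics.  Non-convergence is
#'   flagged via \code{converged}, never an error.
#' @export
fit_emmpat <- function(cohort, prior, spec = model_spec(), control = list(),
                       warm_start = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  ctl <- utils::modifyList(list(maxit = 200, reltol = 1e-9, gtol = 0.05),
                           control)
  if (length(cohort$y) <= qr(cohort$X)$rank)
    stop("need more individuals than covariate rank", call. = FALSE)
  cache <- make_model_cache(cohort, prior, spec)

  starts <- make_starts(cache)
  if (!is.null(warm_start)) starts <- c(list(warm = warm_start), starts)
  best <- optimize_from_starts(cache, spec, ctl, starts)
  if (is.null(best$opt))
    return(structure(list(converged = FALSE, loglik = -Inf,
                          message = "all optimizer starts failed"),
                     class = "emmpat_fit"))
  gnorm <- best$gnorm
  asm <- assemble_params(best$opt$par, cache, spec)
  opt_info <- best$info
  best <- best$opt
  fit <- structure(list(
    params = asm$params, loglik = asm$loglik, spec = spec,
    vpar = best$par, cache_classes = cache$lev, cls = cache$cls,
    converged = best$convergence == 0 && is.finite(gnorm) && gnorm < ctl$gtol,
    gnorm = gnorm, starts = opt_info,
    n = cache$n, m = cache$m
  ), class = "emmpat_fit")
  if (!isTRUE(ctl$light)) {
    fit$blup <- blup(fit, cohort, prior)
    fit$fitted_mean <- drop(cohort$X %*% asm$params$b) +
      drop(cohort$G %*% variant_prior_mean(asm$params, prior, cache$cls))
  }
  fit
}

#' @export
print.emmpat_fit <- function(x, ...) {
  cat("Evolutionary mixed model fit (", x$spec$delta_mode, "-delta)\n", sep = "")
  cat(sprintf("  n = %d individuals, m = %d variants; loglik = %.4f; %s\n",
              x$n, x$m, x$loglik,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  p <- x$params
  for (cl in p$classes)
    cat(sprintf("  [%s] alpha = %.4g  delta_mean = %.4g  delta_var = %.4g  sigma_beta2 = %.4g\n",
                cl, p$alpha[cl], p$delta_mean[cl], p$delta_var[cl],
                p$sigma_beta2[cl]))
  cat(sprintf("  sigma_e2 = %.4g\n", p$sigma_e2))
  invisible(x)
}

#' Best linear unbiased prediction of per-variant effects
#'
#' Effect estimates \code{betahat = mu_beta + D G' V^{-1} (y - X bhat -
#' G mu_beta)} with \code{mu_beta = alpha + delta_mean shat}, computed via
#' the inner-form identities (no n x n factorization).  Prediction standard
#' errors use the standard mixed-model formula
#' \code{D - D G' P G D} with \code{P} the projection that also accounts
#' for estimation of the covariate coefficients; the scaling and variance
#' parameters are treated as fixed at their estimates (elementwise
#' Wald-type intervals).  95\% prediction intervals are
#' \code{betahat +/- 1.96 SE}.
#'
#' @param fit a converged \code{\link{fit_emmpat}} result.
#' @inheritParams marginal_moments
#' @return Data frame with columns \code{variant}, \code{blup}, \code{se},
#'   \code{lower}, \code{upper}.
#' @export
blup <- function(fit, cohort, prior) {
  params <- fit$params
  cls <- fit$cls
  G <- cohort$G
  mu <- variant_prior_mean(params, prior, cls)
  D <- variant_prior_var(params, prior, cls)
  s2 <- params$sigma_e2
  d <- sqrt(D)
  A <- crossprod(G)
  B <- A * tcrossprod(d)
  diag(B) <- diag(B) + s2
  ch <- chol(B)
  solveB <- function(Z) backsolve(ch, backsolve(ch, Z, transpose = TRUE))

  r <- cohort$y - drop(cohort$X %*% params$b) - drop(G %*% mu)
  gr <- drop(crossprod(G, r))
  Vinv_r <- (r - G %*% (d * solveB(d * gr))) / s2
  beta_hat <- mu + D * drop(crossprod(G, Vinv_r))

  # prediction variance: D - D [Q - S Phi S'] D,
  # Q = G'V^{-1}G, S = G'V^{-1}X, Phi = (X'V^{-1}X)^{-1}
  Ad <- A * rep(d, each = nrow(A))          # A %*% diag(d)
  Q <- (A - crossprod(d * A, solveB(d * A))) / s2
  U <- crossprod(G, cohort$X)
  S <- (U - crossprod(Ad, solveB(d * U))) / s2
  XtViX <- (crossprod(cohort$X) - crossprod(d * U, solveB(d * U))) / s2
  Phi <- solve(XtViX)
  Cdiag <- D - D^2 * (diag(Q) - rowSums((S %*% Phi) * S))
  se <- sqrt(pmax(Cdiag, 0))
  data.frame(variant = colnames(G), blup = beta_hat, se = se,
             lower = beta_hat - 1.96 * se, upper = beta_hat + 1.96 * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-variant-at-a-time least squares
#'
#' The per-variant OLS slope of the phenotype on each genotype column,
#' adjusted for the covariates in \code{X}; used for the diagnostic plot
#' overlay and the minimum-p competitor.  Variants collinear with the
#' covariates get \code{NA} estimates and are flagged.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @return Data frame with \code{variant}, \code{estimate}, \code{se},
#'   \code{statistic}, \code{p.value}, \code{ok}.
#' @export
ols_single_variant <- function(cohort) {
  qx <- qr(cohort$X)
  ry <- qr.resid(qx, cohort$y)
  RG <- qr.resid(qx, cohort$G)
  n <- length(cohort$y)
  df <- n - qx$rank - 1L
  sxx <- colSums(RG^2)
  ok <- sxx > 1e-10 * n
  slope <- ifelse(ok, colSums(RG * ry) / sxx, NA_real_)
  rss <- sum(ry^2) - ifelse(ok, slope^2 * sxx, 0)
  se <- sqrt(pmax(rss / df, 0) / sxx)
  se[!ok] <- NA_real_
  tval <- slope / se
  data.frame(variant = colnames(cohort$G), estimate = slope, se = se,
             statistic = tval,
             p.value = 2 * stats::pt(-abs(tval), df),
             ok = ok, row.names = NULL, stringsAsFactors = FALSE)
}
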