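#' Per-individual genetic values
#'
#' The model-predicted contribution of the sequenced region to each
#' individual's phenotype: the sum over selected variants of genotype times
#' BLUP effect estimate.  This is the expected difference between the
#' individual's phenotype and what it would be were there no effect of the
#' gene.
#'
#' @param fit a converged \code{\link{fit_emmpat}} result (with its BLUP
#'   table).
#' @param cohort the \code{\link{cohort_data}} the model was fit on.
#' @param subset which variants to include: \code{"all"}, \code{"rare"}
#'   (sample frequency below the spec's \code{rare_threshold}), a class
#'   label, or a logical/integer variant selector.
#' @return Numeric vector, one value per individual.
#' @export
genetic_values <- function(fit, cohort, subset = "all") {
  sel <- variant_subset(fit, cohort, subset)
  if (!any(sel)) return(numeric(length(cohort$y)))
  drop(cohort$G[, sel, drop = FALSE] %*% fit$blup$blup[sel])
}

variant_subset <- function(fit, cohort, subset) {
  m <- ncol(cohort$G)
  if (is.logical(subset) || is.numeric(subset)) {
    sel <- logical(m)
    sel[subset] <- TRUE
    return(sel)
  }
  if (identical(subset, "all")) return(rep(TRUE, m))
  if (identical(subset, "rare")) {
    q <- colMeans(cohort$G) / 2
    return(pmin(q, 1 - q) < fit$spec$rare_threshold)
  }
  if (subset %in% cohort$classes) return(cohort$classes == subset)
  stop("unknown variant subset: ", subset, call. = FALSE)
}

#' Attributable phenotypic variance
#'
#' The sample variance across individuals of their genetic values, as a
#' fraction of the covariate-adjusted phenotypic variance (the variance of
#' the phenotype after removing the fixed-effect fitted values; with
#' stratum terms in the covariates this is a within-stratum measure).
#'
#' @inheritParams genetic_values
#' @return A single fraction.
#' @export
attributable_variance <- function(fit, cohort, subset = "all") {
  tot <- total_adjusted_variance(fit, cohort)
  stats::var(genetic_values(fit, cohort, subset)) / tot
}

total_adjusted_variance <- function(fit, cohort) {
  resid_fixed <- cohort$y - drop(cohort$X %*% fit$params$b)
  tot <- stats::var(resid_fixed)
  if (tot < 1e-12) stop("covariate-adjusted phenotypic variance is zero", call. = FALSE)
  tot
}

#' Fitness-related and fitness-independent variance fractions
#'
#' Decomposes each class's contribution into a portion tied to the fitness
#' prediction and an independent portion.  With genotypes centered within
#' strata (so stratum mean shifts do not enter), the fitness portion
#' combines the variance across individuals of the delta-scaled prior-mean
#' burden with the prediction-error variance propagated through the
#' variance-model scaling:
#' \deqn{V_{fit} = Var_i(\sum_j g_{ij} \hat\delta_m \hat s_j) +
#'       \hat\delta_v^2 \, mean_i(\sum_j g_{ij}^2 v_j)}
#' and the fitness-independent portion is
#' \deqn{V_{nonfit} = Var_i(\sum_j g_{ij} \hat\alpha) +
#'       \hat\sigma_\beta^2 \, mean_i(\sum_j g_{ij}^2).}
#' Both are divided by the covariate-adjusted phenotypic variance.  This
#' parameter-based split is reported alongside (never conflated with) the
#' BLUP-based \code{\link{attributable_variance}}.
#'
#' @inheritParams genetic_values
#' @param prior the \code{\link{build_prior}} result used in the fit.
#' @return Data frame with one row per class: \code{fitness} and
#'   \code{nonfitness} variance fractions.
#' @export
fitness_split <- function(fit, cohort, prior) {
  tot <- total_adjusted_variance(fit, cohort)
  Gt <- center_within_strata(cohort$G, cohort$strata)
  p <- fit$params
  cls <- fit$cls
  out <- lapply(p$classes, function(cl) {
    j <- cls == cl
    Gc <- Gt[, j, drop = FALSE]
    v_fit <- stats::var(drop(Gc %*% (p$delta_mean[cl] * prior$shat[j]))) +
      p$delta_var[cl]^2 * mean(drop(Gc^2 %*% prior$vhat[j]))
    v_non <- stats::var(drop(Gc %*% rep(p$alpha[cl], sum(j)))) +
      p$sigma_beta2[cl] * mean(rowSums(Gc^2))
    data.frame(class = cl, fitness = v_fit / tot, nonfitness = v_non / tot,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

center_within_strata <- function(G, strata) {
  for (g in levels(strata)) {
    rows <- strata == g
    G[rows, ] <- sweep(G[rows, , drop = FALSE], 2,
                       colMeans(G[rows, , drop = FALSE]))
  }
  G
}

#' Per-variant diagnostic table
#'
#' One row per variant, rank-ordered by observed count with ties broken by
#' estimated effect size -- the layout of the frequency-versus-effect
#' diagnostic plot (model BLUPs with 95\% prediction intervals, the
#' one-variant-at-a-time OLS overlay, and the fitness prior).
#'
#' @inheritParams fitness_split
#' @return Data frame ordered for plotting, with columns \code{rank},
#'   \code{variant}, \code{count}, \code{class}, \code{ols},
#'   \code{ols_se}, \code{blup}, \code{se}, \code{lower}, \code{upper},
#'   \code{shat}, \code{vhat}.
#' @export
diagnostic_table <- function(fit, cohort, prior) {
  ols <- ols_single_variant(cohort)
  counts <- colSums(cohort$G)
  tab <- data.frame(variant = colnames(cohort$G), count = counts,
                    class = cohort$classes,
                    ols = ols$estimate, ols_se = ols$se,
                    blup = fit$blup$blup, se = fit$blup$se,
                    lower = fit$blup$lower, upper = fit$blup$upper,
                    shat = prior$shat, vhat = prior$vhat,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$count, tab$blup), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", setdiff(names(tab), "rank"))]
}
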