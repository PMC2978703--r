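# Comparison methods, in the forms appropriate for a quantitative trait
# measured on a prospective cohort: single-variant minimum p, allele-count
# regressions (CAST/CMC style), the Madsen-Browning weighted sum, and the
# optimal-mean regression that uses the fitness prior in the mean only.

competitor_result <- function(method, p, statistic = NA_real_, df = NULL,
                              note = NULL) {
  structure(list(method = method, p.value = p, statistic = statistic,
                 df = df, note = note),
            class = "emmpat_competitor")
}

#' @export
print.emmpat_competitor <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s\n", x$method, x$p.value,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

# minor allele frequency from the analyzed sample
sample_maf <- function(cohort) {
  q <- colMeans(cohort$G) / 2
  pmin(q, 1 - q)
}

# F-test of extra genetic regressors against the covariates-only model
anova_p <- function(cohort, Z, method, note = NULL) {
  Z <- as.matrix(Z)
  keep <- apply(Z, 2, function(z) stats::sd(z) > 0)
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) == 0) return(competitor_result(method, 1, note = "no usable regressor"))
  fit0 <- stats::lm(cohort$y ~ cohort$X - 1)
  fit1 <- stats::lm(cohort$y ~ cohort$X + Z - 1)
  an <- stats::anova(fit0, fit1)
  Fv <- an$F[2]
  p <- an$`Pr(>F)`[2]
  if (is.na(p)) return(competitor_result(method, 1, note = "collinear regressors"))
  competitor_result(method, p, statistic = Fv,
                    df = c(an$Df[2], an$Res.Df[2]), note = note)
}

#' Bonferroni-corrected minimum single-variant p-value
#'
#' The smallest one-variant-at-a-time OLS p-value among variants with minor
#' allele frequency above the threshold, multiplied by the number of
#' eligible variants and capped at 1.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param maf_threshold minor-allele-frequency cutoff for eligibility.
#' @return An \code{emmpat_competitor} with the corrected p-value.
#' @export
minp_test <- function(cohort, maf_threshold = 0.01) {
  maf <- sample_maf(cohort)
  ols <- ols_single_variant(cohort)
  elig <- maf > maf_threshold & ols$ok
  if (!any(elig)) {
    warning("no variant above the frequency threshold; p = 1", call. = FALSE)
    return(competitor_result("minp", 1, note = "no eligible variant"))
  }
  p <- min(1, min(ols$p.value[elig]) * sum(elig))
  competitor_result("minp", p, note = sprintf("%d eligible variants", sum(elig)))
}

#' Rare-allele-count (CAST-style) regression test
#'
#' Regression with the number of rare derived alleles carried by each
#' participant as a single covariate; the p-value is the F-test against the
#' nested covariates-only model.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param threshold variants with minor allele frequency at or below this
#'   value count as rare.
#' @return An \code{emmpat_competitor}.
#' @export
cast_test <- function(cohort, threshold = 0.01) {
  rare <- sample_maf(cohort) <= threshold
  if (!any(rare)) stop("no rare variant at threshold ", threshold, call. = FALSE)
  count <- rowSums(cohort$G[, rare, drop = FALSE])
  anova_p(cohort, count, "cast")
}

#' CMC-style regression test
#'
#' As \code{\link{cast_test}}, but variants above the frequency threshold
#' enter as free regression parameters alongside the rare-allele count.
#' With no common variant present it reduces to the CAST test exactly.
#'
#' @inheritParams cast_test
#' @return An \code{emmpat_competitor}.
#' @export
cmc_test <- function(cohort, threshold = 0.01) {
  maf <- sample_maf(cohort)
  rare <- maf <= threshold
  if (!any(rare)) stop("no rare variant at threshold ", threshold, call. = FALSE)
  Z <- cbind(count = rowSums(cohort$G[, rare, drop = FALSE]),
             cohort$G[, !rare, drop = FALSE])
  anova_p(cohort, Z, "cmc")
}

# Madsen-Browning weight from the estimated allele frequency (plain MLE
# frequency, no pseudo-count)
madsen_weights <- function(cohort) {
  n <- length(cohort$y)
  q <- colMeans(cohort$G) / 2
  1 / sqrt(n * q * (1 - q))
}

#' Weighted-sum burden test
#'
#' Each individual's burden is the weighted count of derived alleles, with
#' weights inversely proportional to the binomial standard deviation of the
#' allele frequency estimate (rarer variants weigh more).  Because the
#' phenotype is quantitative and modelled as normal, the score enters a
#' plain regression F-test (no rank transformation).  With a threshold,
#' only rare variants are collapsed and common variants enter free.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param threshold optional frequency cutoff; \code{NULL} collapses all
#'   variants.
#' @return An \code{emmpat_competitor}.
#' @export
weighted_sum_test <- function(cohort, threshold = NULL) {
  w <- madsen_weights(cohort)
  if (is.null(threshold)) {
    Z <- drop(cohort$G %*% w)
    return(anova_p(cohort, Z, "weighted_sum", note = "all variants"))
  }
  maf <- sample_maf(cohort)
  rare <- maf <= threshold
  if (!any(rare)) stop("no rare variant at threshold ", threshold, call. = FALSE)
  Z <- cbind(burden = drop(cohort$G[, rare, drop = FALSE] %*% w[rare]),
             cohort$G[, !rare, drop = FALSE])
  anova_p(cohort, Z, "weighted_sum")
}

#' Optimal-mean regression test
#'
#' A regression using the mean model of the evolutionary framework without
#' its variance components: the covariates plus two genetic regressors, the
#' per-individual derived-allele count and the fitness-prediction-weighted
#' count \code{sum_j g_ij shat_j}.  With a threshold, common variants enter
#' free.  When all predicted fitness effects are zero the weighted
#' regressor is dropped (with a warning) and the test reduces to the
#' allele-count test on all variants.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param prior a \code{\link{build_prior}} result.
#' @param threshold optional frequency cutoff for the free common variants.
#' @return An \code{emmpat_competitor}.
#' @export
optimal_mean_test <- function(cohort, prior, threshold = NULL) {
  if (all(prior$shat == 0))
    warning("all predicted fitness effects are zero; testing the allele count only",
            call. = FALSE)
  if (is.null(threshold)) {
    Z <- cbind(count = rowSums(cohort$G),
               sburden = drop(cohort$G %*% prior$shat))
    return(anova_p(cohort, Z, "optimal_mean", note = "all variants"))
  }
  maf <- sample_maf(cohort)
  rare <- maf <= threshold
  if (!any(rare)) stop("no rare variant at threshold ", threshold, call. = FALSE)
  Gr <- cohort$G[, rare, drop = FALSE]
  Z <- cbind(count = rowSums(Gr),
             sburden = drop(Gr %*% prior$shat[rare]),
             cohort$G[, !rare, drop = FALSE])
  anova_p(cohort, Z, "optimal_mean")
}
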