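#' Conditional fitness moments from a simulated pseudo-population
#'
#' Given a pseudo-population of variants with known selection coefficients
#' and population frequencies, computes the mean and variance of the
#' selection coefficient among simulated variants compatible with an
#' observed sample count.  The default uses the binomial-sampling shortcut:
#' each pseudo-variant is weighted by the probability that simple random
#' sampling of \code{n_chrom} chromosomes from its population frequency
#' yields exactly \code{k} copies.  Exact count matching (resampling each
#' pseudo-variant once and keeping those that hit \code{k}) is retained for
#' validation.
#'
#' @param pop a \code{\link{simulate_population}} result (or any
#'   \code{pseudo_population}).
#' @param n_chrom number of sampled chromosomes.
#' @param k observed derived-allele count, \code{1 <= k <= n_chrom}.
#' @param exact use exact-count matching instead of binomial weighting.
#' @param seed seed for the exact-matching resampling step.
#' @return Named vector \code{c(shat, vhat)} with \code{shat <= 0},
#'   \code{vhat >= 0}.
#' @export
conditional_moments <- function(pop, n_chrom, k, exact = FALSE, seed = NULL) {
  stopifnot(inherits(pop, "pseudo_population"))
  if (nrow(pop$variants) == 0)
    stop("pseudo-population is empty", call. = FALSE)
  if (k < 1 || k > n_chrom)
    stop("'k' must satisfy 1 <= k <= n_chrom", call. = FALSE)
  s <- pop$variants$s
  q <- pop$variants$q
  if (exact) {
    if (!is.null(seed)) set.seed(seed)
    counts <- rbinom(length(q), n_chrom, q)
    w <- as.numeric(counts == k)
  } else {
    w <- dbinom(k, n_chrom, q)
  }
  sw <- sum(w)
  if (sw == 0)
    stop("no pseudo-variant has support for count k = ", k,
         " out of ", n_chrom, call. = FALSE)
  shat <- sum(w * s) / sw
  vhat <- max(sum(w * s^2) / sw - shat^2, 0)
  c(shat = shat, vhat = vhat)
}

#' Assign an ethnicity of origin from group frequencies
#'
#' A variant observed in several groups is assigned to the group where its
#' observed frequency is highest -- the assignment most skeptical of the
#' variant being rare.  Ties are broken by the declared order of the
#' groups (the order of \code{group_frequencies}).
#'
#' @param group_frequencies named numeric vector of observed derived-allele
#'   frequencies per group.
#' @return The name of the assigned group.
#' @examples
#' assign_origin(c(white = 0.012, black = 0.003))  # -> "white"
#' @export
assign_origin <- function(group_frequencies) {
  if (length(group_frequencies) == 0 || is.null(names(group_frequencies)))
    stop("'group_frequencies' must be a named vector", call. = FALSE)
  if (all(group_frequencies <= 0))
    stop("all group frequencies are zero; monomorphic variants should have been filtered",
         call. = FALSE)
  names(group_frequencies)[which.max(group_frequencies)]
}

#' Build the per-variant fitness prior for a cohort
#'
#' For every variant, chooses an origin stratum by
#' \code{\link{assign_origin}} on the observed within-stratum frequencies,
#' then computes the predicted selection coefficient and its
#' prediction-error variance from that stratum's pseudo-population at the
#' stratum-specific observed count.  When no pseudo-variant supports the
#' observed count, the moments at the nearest supported count are used and
#' a warning is raised.
#'
#' @param cohort a \code{\link{cohort_data}}.
#' @param pops a named list of \code{pseudo_population}s, one per stratum
#'   level of the cohort.
#' @return An object of class \code{fitness_prior}: a data frame with one
#'   row per variant and columns \code{shat}, \code{vhat}, \code{count},
#'   \code{n_chrom}, \code{origin}.
#' @export
build_prior <- function(cohort, pops) {
  stopifnot(inherits(cohort, "cohort_data"))
  groups <- levels(cohort$strata)
  missing <- setdiff(groups, names(pops))
  if (length(missing))
    stop("missing pseudo-population for stratum: ",
         paste(missing, collapse = ", "), call. = FALSE)
  freqs <- stratum_frequencies(cohort)           # m x n_groups
  n_by_group <- 2 * tabulate(cohort$strata)
  names(n_by_group) <- groups
  m <- ncol(cohort$G)

  # moments per (group, count) pair are cached: many variants share counts
  cache <- new.env(parent = emptyenv())
  moments_at <- function(g, k, n_chrom) {
    key <- paste0(g, ":", k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch(conditional_moments(pops[[g]], n_chrom, k),
                    error = function(e) NULL)
    if (is.null(res)) {
      # fall back to the nearest count with support
      for (d in seq_len(n_chrom)) {
        for (k2 in c(k - d, k + d)) {
          if (k2 >= 1 && k2 <= n_chrom) {
            res <- tryCatch(conditional_moments(pops[[g]], n_chrom, k2),
                            error = function(e) NULL)
            if (!is.null(res)) break
          }
        }
        if (!is.null(res)) break
      }
      warning("no pseudo-variant support for count ", k, " in stratum '", g,
              "'; using nearest supported count", call. = FALSE)
    }
    cache[[key]] <- res
    res
  }

  out <- data.frame(variant = colnames(cohort$G), shat = numeric(m),
                    vhat = numeric(m), count = integer(m),
                    n_chrom = integer(m), origin = character(m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    fr <- freqs[j, ]
    names(fr) <- groups
    g <- assign_origin(fr)
    k <- as.integer(round(fr[g] * n_by_group[g]))
    mom <- moments_at(g, k, n_by_group[g])
    out$shat[j] <- mom["shat"]
    out$vhat[j] <- mom["vhat"]
    out$count[j] <- k
    out$n_chrom[j] <- n_by_group[g]
    out$origin[j] <- g
  }
  class(out) <- c("fitness_prior", "data.frame")
  out
}

#' @export
print.fitness_prior <- function(x, ...) {
  cat(sprintf("Fitness prior for %d variants (mean shat = %.4g, mean vhat = %.4g)\n",
              nrow(x), mean(x$shat), mean(x$vhat)))
  NextMethod()
}
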