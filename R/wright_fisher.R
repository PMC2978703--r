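#' Forward Wright-Fisher simulation of a candidate gene
#'
#' Simulates segregating variation in a candidate region under a DFE and a
#' demographic history, per site and without linkage: new mutations enter as
#' Poisson events (infinite-sites) at initial frequency \code{1/(2N)}, each
#' generation applies deterministic genic selection
#' \code{q' = q(1+s) / (1+qs)} (multiplicative fitness, heterozygote
#' \code{1+s}, no dominance) followed by binomial drift over \code{2N(t)}
#' chromosomes, and fixed or lost sites are dropped.  A burn-in of
#' \code{burn_mult * 2 * N_ancestral} generations at the first epoch's size
#' precedes the epoch schedule so the ancestral population is near
#' equilibrium.
#'
#' Selection is population-scaled internally: with \code{rescale_factor = R}
#' the simulation uses sizes \code{N/R}, coefficients \code{sR}, mutation
#' rate \code{mu*R}, durations \code{/R} and growth rates \code{*R}, which
#' preserves \code{4Ns} and \code{4N*mu} and makes desk-scale runs feasible.
#' Returned selection coefficients and frequencies are on the natural
#' (unrescaled) scale.  Rescaled coefficients are truncated at -0.95 so the
#' genic-selection update stays defined; effectively lethal variants never
#' segregate regardless.
#'
#' @param demography a \code{\link{demography_model}}.
#' @param dfe a \code{\link{dfe_config}}.
#' @param locus_length number of sites in the region (> 0).
#' @param mu per-site per-generation mutation rate (> 0).
#' @param seed integer seed; fixed seed gives an identical population.
#' @param rescale_factor 4Ns-preserving down-scaling factor (>= 1).
#' @param burn_mult burn-in length in units of \code{2 * N_ancestral}
#'   generations (default 10).
#' @return An object of class \code{pseudo_population}: a list with
#'   \code{variants} (data frame with columns \code{s}, \code{q}),
#'   \code{pop_size} (diploid size at sampling, unrescaled) and \code{meta}
#'   (seed, mutation rate, locus length, rescale factor).
#' @seealso \code{\link{conditional_moments}}, \code{\link{sample_cohort}}
#' @export
simulate_population <- function(demography, dfe, locus_length, mu,
                                seed = NULL, rescale_factor = 1,
                                burn_mult = 10) {
  stopifnot(inherits(demography, "demography_model"), inherits(dfe, "dfe_config"))
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (!is.numeric(locus_length) || locus_length <= 0)
    stop("'locus_length' must be positive", call. = FALSE)
  if (!is.numeric(rescale_factor) || rescale_factor < 1)
    stop("'rescale_factor' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  R <- rescale_factor
  muL <- mu * locus_length * R
  sizes <- demography_sizes(demography, rescale = R)
  n_anc <- sizes[1]
  sizes <- c(rep.int(n_anc, burn_mult * 2 * n_anc), sizes)
  ngen <- length(sizes)

  q <- numeric(0)
  s <- numeric(0)
  for (t in seq_len(ngen)) {
    N <- sizes[t]
    N_next <- if (t < ngen) sizes[t + 1] else N
    if (length(q)) {
      p <- q * (1 + s) / (1 + q * s)
      q <- rbinom(length(q), 2L * N_next, p) / (2 * N_next)
      keep <- q > 0 & q < 1
      if (!all(keep)) {
        q <- q[keep]
        s <- s[keep]
      }
    }
    # new mutations appear as single copies in the offspring generation
    n_mut <- rpois(1L, 2 * N_next * muL)
    if (n_mut > 0) {
      s_new <- pmax(sample_dfe(dfe, n_mut) * R, -0.95)
      q <- c(q, rep.int(1 / (2 * N_next), n_mut))
      s <- c(s, s_new)
    }
  }
  structure(list(
    variants = data.frame(s = s / R, q = q),
    pop_size = sizes[ngen] * R,
    meta = list(seed = seed, mutation_rate = mu, locus_length = locus_length,
                rescale_factor = R)
  ), class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  v <- x$variants
  cat(sprintf(paste0("Pseudo-population: %d segregating variants, diploid size %d\n",
                     "  %d variants above 1%% frequency; mean |s| among selected = %.4g\n"),
              nrow(v), x$pop_size, sum(pmin(v$q, 1 - v$q) > 0.01),
              if (any(v$s < 0)) mean(-v$s[v$s < 0]) else 0))
  invisible(x)
}

#' Pool several simulated populations into one pseudo-population
#'
#' The conditional-moment computation improves with the number of
#' pseudo-variants, so analysis-side priors are typically built from many
#' replicate simulations pooled together (the per-site model makes variants
#' exchangeable across replicates).
#'
#' @param pops list of \code{pseudo_population}s with a common population
#'   size.
#' @return A single \code{pseudo_population}.
#' @export
pool_populations <- function(pops) {
  stopifnot(length(pops) >= 1,
            all(vapply(pops, inherits, TRUE, "pseudo_population")))
  structure(list(
    variants = do.call(rbind, lapply(pops, `[[`, "variants")),
    pop_size = pops[[1]]$pop_size,
    meta = utils::modifyList(pops[[1]]$meta, list(pooled = length(pops)))
  ), class = "pseudo_population")
}

#' Write / read a pseudo-population as TSV
#'
#' The serialization is a plain two-column TSV (\code{s}, \code{q}) preceded
#' by \code{#key=value} metadata header lines.
#'
#' @param pop a \code{pseudo_population}.
#' @param path output file path.
#' @export
write_pseudo_population <- function(pop, path) {
  stopifnot(inherits(pop, "pseudo_population"))
  meta <- c(pop_size = pop$pop_size, pop$meta[!vapply(pop$meta, is.null, TRUE)])
  hdr <- sprintf("#%s=%s", names(meta), vapply(meta, format, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(pop$variants, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pseudo_population
#' @param path input file path.
#' @export
read_pseudo_population <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  structure(list(variants = data.frame(s = tab$s, q = tab$q),
                 pop_size = meta$pop_size,
                 meta = meta[setdiff(names(meta), "pop_size")]),
            class = "pseudo_population")
}
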