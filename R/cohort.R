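#' Assemble a cohort for association analysis
#'
#' Bundles the quantitative phenotype, covariate design, derived-allele
#' genotype matrix, stratum (ethnicity) labels and variant class labels, and
#' validates their consistency.  Genotypes are coded 0/1/2 as the number of
#' derived alleles carried.  Monomorphic columns carry no association
#' information and are dropped (with a message) by default; duplicated
#' columns are retained, since the mixed model splits their joint effect.
#'
#' @param y numeric phenotype vector, one value per individual.
#' @param X covariate design matrix including the intercept (and stratum
#'   main effects when several strata are analysed together); must have full
#'   column rank.
#' @param G n x m genotype matrix with entries in \{0, 1, 2\}.
#' @param strata factor (or vector) of stratum labels, one per individual;
#'   defaults to a single stratum.
#' @param classes variant class labels (e.g. \code{"non-synonymous"},
#'   \code{"non-coding"}), one per retained variant; defaults to one class.
#' @param drop_monomorphic drop columns of \code{G} with no variation.
#' @return An object of class \code{cohort_data}.
#' @export
cohort_data <- function(y, X, G, strata = NULL, classes = NULL,
                        drop_monomorphic = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  G <- as.matrix(G)
  n <- length(y)
  if (nrow(X) != n || nrow(G) != n)
    stop("'y', 'X' and 'G' must agree on the number of individuals", call. = FALSE)
  if (anyNA(y) || anyNA(X) || anyNA(G))
    stop("missing values are not supported; complete data required", call. = FALSE)
  if (!all(G %in% c(0, 1, 2)))
    stop("'G' entries must be derived-allele counts in {0, 1, 2}", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("'X' must have full column rank", call. = FALSE)
  if (is.null(strata)) strata <- rep("pooled", n)
  strata <- factor(strata)
  if (length(strata) != n)
    stop("'strata' must have one label per individual", call. = FALSE)
  if (is.null(classes)) classes <- rep("variant", ncol(G))
  if (length(classes) != ncol(G))
    stop("'classes' must have one label per variant", call. = FALSE)
  classes <- as.character(classes)
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))

  mono <- apply(G, 2, function(g) length(unique(g)) == 1L)
  if (drop_monomorphic && any(mono)) {
    message("dropping ", sum(mono), " monomorphic variant column(s)")
    G <- G[, !mono, drop = FALSE]
    classes <- classes[!mono]
  }
  structure(list(y = y, X = X, G = G, strata = strata, classes = classes),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals, %d variants, %d covariate column(s)\n",
              length(x$y), ncol(x$G), ncol(x$X)))
  cat("  strata: ", paste(sprintf("%s (%d)", levels(x$strata),
                                  tabulate(x$strata)), collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$classes)),
                                  table(x$classes)), collapse = ", "), "\n")
  invisible(x)
}

# derived-allele frequency of each variant within each stratum (m x groups)
stratum_frequencies <- function(cohort) {
  out <- vapply(levels(cohort$strata), function(g) {
    rows <- cohort$strata == g
    colSums(cohort$G[rows, , drop = FALSE]) / (2 * sum(rows))
  }, numeric(ncol(cohort$G)))
  matrix(out, nrow = ncol(cohort$G),
         dimnames = list(colnames(cohort$G), levels(cohort$strata)))
}
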