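# Readers and writers for the package's external formats: genotype matrices
# (VCF with ancestral-allele polarization, or plain TSV), phenotype/covariate
# tables with declared column roles, variant annotation tables, and the
# JSON/TSV result serializations.

#' Read a genotype matrix
#'
#' Genotypes are returned as derived-allele counts 0/1/2.  VCF input (read
#' via the vcfR package) uses the \code{AA} INFO tag to polarize alleles
#' when \code{polarity = "ancestral-tag"}: sites whose ancestral allele
#' equals the ALT allele are flipped, and sites with no usable tag are
#' dropped with a logged count.  \code{polarity = "assume-ref-ancestral"}
#' counts ALT alleles directly.  TSV input is a samples x variants matrix
#' of 0/1/2 values with sample IDs in the first column.  Missing genotypes
#' are an error: no imputation is performed.
#'
#' @param path VCF (\code{.vcf}) or TSV file.
#' @param polarity ancestral-allele handling for VCF input.
#' @return List with \code{G} (matrix, rownames = sample IDs) and
#'   \code{variants} (data frame of variant metadata).
#' @export
read_genotypes <- function(path,
                           polarity = c("ancestral-tag", "assume-ref-ancestral")) {
  polarity <- match.arg(polarity)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    read_genotypes_vcf(path, polarity)
  else
    read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path, polarity) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("VCF contains no GT genotypes", call. = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  aa <- vcfR::extract.info(v, element = "AA")
  alt_count <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  }
  counts <- apply(gt, c(1, 2), alt_count)
  if (anyNA(counts))
    stop("missing genotypes in VCF (no imputation is performed)", call. = FALSE)
  if (polarity == "ancestral-tag") {
    flip <- !is.na(aa) & toupper(aa) == toupper(fix$ALT)
    keep <- (!is.na(aa) & toupper(aa) == toupper(fix$REF)) | flip
    n_drop <- sum(!keep)
    if (n_drop > 0)
      message("dropping ", n_drop, " variant(s) without usable ancestral-allele polarity")
    counts[flip, ] <- 2L - counts[flip, ]
    counts <- counts[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
  }
  G <- t(counts)
  colnames(G) <- ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste(fix$CHROM, fix$POS, sep = ":"), fix$ID)
  list(G = G, variants = fix)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  G <- as.matrix(tab)
  if (anyNA(G) || !all(G %in% c(0, 1, 2)))
    stop("TSV genotypes must be complete 0/1/2 counts", call. = FALSE)
  list(G = G, variants = data.frame(ID = colnames(G)))
}

#' Write a genotype matrix as TSV
#'
#' @param G samples x variants 0/1/2 matrix with sample-ID rownames.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- data.frame(sample = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Piecewise-linear spline basis
#'
#' Truncated-line basis for a flexible covariate: the variable itself plus
#' \code{pmax(x - knot, 0)} for each interior knot; knots are placed at
#' multiples of \code{spacing} strictly inside the observed range.
#'
#' @param x numeric covariate.
#' @param spacing knot spacing in the variable's units.
#' @return Matrix with \code{1 + n_knots} columns.
#' @export
linear_spline_basis <- function(x, spacing) {
  lo <- min(x)
  hi <- max(x)
  knots <- seq(ceiling(lo / spacing) * spacing, hi, by = spacing)
  knots <- knots[knots > lo & knots < hi]
  out <- cbind(x, vapply(knots, function(k) pmax(x - k, 0), numeric(length(x))))
  colnames(out) <- c("lin", if (length(knots)) paste0("k", knots))
  out
}

#' Read a phenotype / covariate table and build the design matrix
#'
#' @param path TSV file with a header.
#' @param config a list declaring column roles: \code{id}, \code{trait},
#'   optional \code{covariates} (character vector), \code{splines} (named
#'   list mapping a covariate to its knot spacing; splined covariates get a
#'   piecewise-linear basis instead of a single column),
#'   \code{interactions} (character vector of \code{"a:b"} terms) and
#'   \code{stratum}.  The design always contains an intercept, and stratum
#'   dummies when a stratum column is declared.
#' @return List with \code{y}, \code{X}, \code{strata}, \code{ids}.
#' @export
read_phenotypes <- function(path, config) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (key in c("id", "trait"))
    if (is.null(config[[key]]))
      stop("phenotype config must declare '", key, "'", call. = FALSE)
  need <- unlist(c(config$id, config$trait, config$covariates, config$stratum))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("phenotype table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  splines <- config$splines
  terms <- character(0)
  for (v in config$covariates) {
    if (!is.null(splines[[v]])) {
      basis <- linear_spline_basis(df[[v]], splines[[v]])
      cn <- paste0(v, "_", colnames(basis))
      df[cn] <- basis
      terms <- c(terms, cn)
    } else {
      if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
      if (is.factor(df[[v]]) && nlevels(droplevels(df[[v]])) < 2) next
      terms <- c(terms, v)
    }
  }
  if (!is.null(config$stratum)) {
    df[[config$stratum]] <- factor(df[[config$stratum]])
    # a single stratum contributes no dummy columns
    if (nlevels(droplevels(df[[config$stratum]])) > 1)
      terms <- c(config$stratum, terms)
  }
  terms <- c(terms, config$interactions)
  fml <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  list(y = as.numeric(df[[config$trait]]), X = X,
       strata = if (is.null(config$stratum)) NULL else df[[config$stratum]],
       ids = as.character(df[[config$id]]))
}

#' Read a variant annotation table
#'
#' @param path TSV with columns \code{variant} and \code{class}.
#' @return Named character vector of classes.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("variant", "class") %in% names(tab)))
    stop("annotation table needs 'variant' and 'class' columns", call. = FALSE)
  stats::setNames(tab$class, tab$variant)
}

#' Assemble a cohort from genotype and phenotype inputs
#'
#' Joins genotype rows to phenotype rows by sample ID (any mismatch is a
#' hard error listing the offenders), attaches variant classes from an
#' annotation vector, and builds the \code{\link{cohort_data}}.
#'
#' @param geno a \code{\link{read_genotypes}} result.
#' @param pheno a \code{\link{read_phenotypes}} result.
#' @param annotations optional named class vector from
#'   \code{\link{read_annotations}}.
#' @return A \code{\link{cohort_data}}.
#' @export
make_cohort <- function(geno, pheno, annotations = NULL) {
  gids <- rownames(geno$G)
  missing <- setdiff(pheno$ids, gids)
  if (length(missing))
    stop("samples missing from genotypes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  G <- geno$G[pheno$ids, , drop = FALSE]
  classes <- if (!is.null(annotations)) {
    unknown <- setdiff(colnames(G), names(annotations))
    if (length(unknown))
      stop("variants without annotation: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    unname(annotations[colnames(G)])
  } else NULL
  cohort_data(pheno$y, pheno$X, G, strata = pheno$strata, classes = classes)
}

#' Serialize results
#'
#' \code{write_fit_json} writes the parameter estimates, log-likelihood and
#' convergence diagnostics; \code{write_test_json} additionally records the
#' permutation test; both embed the resolved seed so runs are reproducible.
#' \code{write_blup_tsv} writes the per-variant BLUP table.
#'
#' @param fit an \code{emmpat_fit}.
#' @param path output path.
#' @param seed seed to embed.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  p <- fit$params
  out <- list(parameters = list(b = p$b, alpha = as.list(p$alpha),
                                delta_mean = as.list(p$delta_mean),
                                delta_var = as.list(p$delta_var),
                                sigma_beta2 = as.list(p$sigma_beta2),
                                sigma_e2 = p$sigma_e2),
              loglik = fit$loglik, converged = fit$converged,
              gradient_norm = fit$gnorm,
              delta_mode = fit$spec$delta_mode, seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @param test an \code{emmpat_test}.
#' @export
write_test_json <- function(test, path, seed = NULL) {
  out <- list(lrt_stat = test$lrt_stat, p_perm = test$p_perm,
              n_perm = test$n_perm, loglik = test$fit$loglik,
              loglik_null = test$null$loglik,
              converged = test$fit$converged, seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_blup_tsv <- function(fit, path) {
  utils::write.table(fit$blup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
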