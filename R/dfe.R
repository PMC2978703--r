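#' Distribution of fitness effects (DFE) configuration
#'
#' The DFE of new mutations is modelled as a point mass at neutrality
#' (\code{s = 0}) mixed with a gamma distribution of deleterious magnitudes,
#' so that a draw is 0 with probability \code{neutral_mass} and
#' \code{-Gamma(gamma_shape, gamma_scale)} otherwise.  Selection coefficients
#' are per-generation, log-scale fitness decrements; all draws satisfy
#' \code{s <= 0}.
#'
#' @param neutral_mass probability in \[0,1\] that a new mutation is neutral.
#' @param gamma_shape shape of the gamma distribution of \code{|s|}; must be
#'   positive.
#' @param gamma_scale scale of the gamma distribution of \code{|s|} (selection
#'   coefficient units); the mean deleterious magnitude is
#'   \code{gamma_shape * gamma_scale}.
#' @return An object of class \code{dfe_config}.
#' @examples
#' dfe <- dfe_config(neutral_mass = 0.04, gamma_shape = 1, gamma_scale = 0.005)
#' mean(sample_dfe(dfe, 1000, seed = 1))
#' @export
dfe_config <- function(neutral_mass = 0.04, gamma_shape = 1, gamma_scale = 0.005) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1 ||
      is.na(neutral_mass) || neutral_mass < 0 || neutral_mass > 1)
    stop("'neutral_mass' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(gamma_shape) || length(gamma_shape) != 1 ||
      is.na(gamma_shape) || gamma_shape <= 0)
    stop("'gamma_shape' must be a single positive number", call. = FALSE)
  if (!is.numeric(gamma_scale) || length(gamma_scale) != 1 ||
      is.na(gamma_scale) || gamma_scale <= 0)
    stop("'gamma_scale' must be a single positive number", call. = FALSE)
  structure(list(neutral_mass = neutral_mass,
                 gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale),
            class = "dfe_config")
}

#' @export
print.dfe_config <- function(x, ...) {
  cat("DFE: point mass", x$neutral_mass, "at s = 0 +",
      sprintf("Gamma(shape = %g, scale = %g) deleterious (mean |s| = %g)\n",
              x$gamma_shape, x$gamma_scale, x$gamma_shape * x$gamma_scale))
  invisible(x)
}

#' Sample selection coefficients from a DFE
#'
#' @param config a \code{\link{dfe_config}}.
#' @param m number of draws (non-negative integer).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length \code{m}, each element \code{<= 0}.
#' @export
sample_dfe <- function(config, m, seed = NULL) {
  stopifnot(inherits(config, "dfe_config"))
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0 || m != round(m))
    stop("'m' must be a single non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (m == 0) return(numeric(0))
  s <- -rgamma(m, shape = config$gamma_shape, scale = config$gamma_scale)
  s[runif(m) < config$neutral_mass] <- 0
  s
}

#' Piecewise-exponential demographic model
#'
#' Population history is an ordered sequence of epochs, each with a duration
#' in generations, a diploid size at the start of the epoch, and a
#' per-generation exponential growth rate (0 for constant size).  The first
#' epoch's size is the ancestral size used for equilibrium burn-in by
#' \code{\link{simulate_population}}.
#'
#' @param epochs a data frame with columns \code{duration} (generations,
#'   positive), \code{size} (diploid individuals at epoch start, >= 2) and
#'   \code{growth} (per-generation exponential rate).
#' @return An object of class \code{demography_model} with the epoch table
#'   and the implied \code{final_size}.
#' @examples
#' demography_model(data.frame(duration = c(4000, 800, 1600),
#'                             size     = c(8000, 2000, 2000),
#'                             growth   = c(0, 0, log(10) / 1600)))
#' @export
demography_model <- function(epochs) {
  if (!is.data.frame(epochs) ||
      !all(c("duration", "size", "growth") %in% names(epochs)) ||
      nrow(epochs) < 1)
    stop("'epochs' must be a data frame with columns duration, size, growth",
         call. = FALSE)
  if (any(epochs$duration <= 0) || any(epochs$duration != round(epochs$duration)))
    stop("epoch durations must be positive integers", call. = FALSE)
  if (any(epochs$size < 2)) stop("epoch sizes must be >= 2", call. = FALSE)
  final <- epochs$size[nrow(epochs)] *
    exp(epochs$growth[nrow(epochs)] * (epochs$duration[nrow(epochs)] - 1))
  if (!is.finite(final)) stop("implied population sizes must be finite", call. = FALSE)
  structure(list(epochs = epochs, final_size = round(final)),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("Demographic model,", nrow(x$epochs), "epochs; final diploid size",
      x$final_size, "\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

# per-generation diploid sizes over the demographic epochs (excluding burn-in),
# optionally 4Ns-rescaled by 1/rescale
demography_sizes <- function(demography, rescale = 1) {
  unlist(lapply(seq_len(nrow(demography$epochs)), function(i) {
    e <- demography$epochs[i, ]
    dur <- ceiling(e$duration / rescale)
    t <- seq_len(dur) - 1
    pmax(2L, as.integer(round(e$size / rescale * exp(e$growth * rescale * t))))
  }))
}

#' Default DFE, demography, and mutation parameters
#'
#' Reads the configuration shipped with the package
#' (\code{inst/extdata/default_popgen.yaml}).  The values approximate the
#' published heavy-tailed gamma-DFE fits for new coding mutations and an
#' expansion-style size history (ancestral equilibrium followed by recent
#' exponential growth), jointly calibrated so that a simulated candidate
#' gene reproduces the polymorphism summaries of the power-study
#' population used throughout the package (see the methods vignette).  All
#' values are user-overridable via \code{\link{read_popgen_config}}.
#'
#' @return A list with elements \code{dfe} (\code{\link{dfe_config}}),
#'   \code{demography} (\code{\link{demography_model}}),
#'   \code{mutation_rate}, \code{locus_length}, \code{rescale_factor} and
#'   \code{seed}.
#' @export
default_popgen_config <- function() {
  read_popgen_config(system.file("extdata", "default_popgen.yaml",
                                 package = "emmpat", mustWork = TRUE))
}

#' Read a DFE/demography configuration file
#'
#' @param path a YAML or JSON file with keys \code{neutral_mass},
#'   \code{gamma_shape}, \code{gamma_scale}, \code{epochs} (list of
#'   \code{duration}/\code{size}/\code{growth}), \code{mutation_rate},
#'   \code{locus_length}, \code{rescale_factor}, and optionally \code{seed}.
#' @return A list as in \code{\link{default_popgen_config}}.
#' @export
read_popgen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("neutral_mass", "gamma_shape", "gamma_scale", "epochs",
              "mutation_rate", "locus_length", "rescale_factor")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  ep <- raw$epochs
  if (!is.data.frame(ep))
    ep <- do.call(rbind, lapply(ep, function(e)
      data.frame(duration = e$duration, size = e$size, growth = e$growth)))
  list(dfe = dfe_config(raw$neutral_mass, raw$gamma_shape, raw$gamma_scale),
       demography = demography_model(ep),
       mutation_rate = raw$mutation_rate,
       locus_length = raw$locus_length,
       rescale_factor = raw$rescale_factor,
       seed = if (is.null(raw$seed)) NULL else raw$seed)
}
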