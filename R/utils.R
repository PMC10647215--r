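# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Coding consequence classes; "other" is carried but never enters computations.
CODING_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift")
ALL_CLASSES <- c(CODING_CLASSES, "other")
DRIVER_CLASSES <- c("OG", "TSG", "PG")

# Fixed predictor order; every feature matrix in the package uses it.
FEATURE_NAMES <- c("E_gene", "E_summit", "log_omega", "log_phi",
                   "R_missense", "R_truncating", "R_peak", "R_summit",
                   "C_summit", "R_length")

#' Feature names in canonical order
#'
#' Returns the fixed order of the 10 gene-level predictors used throughout
#' the package: two long-term evolutionary rates (`E_gene`, `E_summit`,
#' in substitutions per billion years), two clamped log selection
#' coefficients (`log_omega`, `log_phi`), and six mutation-distribution
#' features (`R_missense`, `R_truncating`, `R_peak`, `R_summit`,
#' `C_summit`, `R_length`).
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() FEATURE_NAMES

# Run code under a temporary RNG seed; global stream untouched when seed
# is NULL.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Lightweight logging; silenced with options(selforest.verbose = FALSE).
sf_log <- function(fmt, ...) {
  if (isFALSE(getOption("selforest.verbose", TRUE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
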