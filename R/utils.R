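#' Derive a child seed from a master seed and a stage label
#'
#' The generator and the recovery harness derive one child seed per
#' (stage, group, replicate) so that adding a group or a stage never
#' perturbs the random draws of earlier ones. The scheme is a simple
#' multiplicative hash of the label folded into the master seed, reduced
#' modulo 2^31 - 1 so the result is always a valid 32-bit R seed.
#'
#' @param master integer master seed
#' @param label character stage label, e.g. "group:nematodes"
#' @return a single integer seed in [0, 2^31 - 2]
#' @export
seed_for <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in utf8ToInt(label)) {
    h <- (h * 69069 + k) %% m
  }
  as.integer(h)
}

#' Map a p-value to the conventional significance class
#'
#' @param p p-value in [0, 1] (vectorised)
#' @return character vector with levels "***", "**", "*", "n.s."
#' @export
significance_class <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "n.s.")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Z-score selected columns of a data frame
#'
#' Standardisation is computed once on the analysis subset and shared by
#' all candidate models, so coefficients from different models are on a
#' common scale. Columns with zero variance are left untouched (with a
#' warning) to avoid division by zero.
#'
#' @param data data frame
#' @param cols character vector of numeric column names to standardise
#' @return data frame with the named columns centred and scaled
#' @export
standardize_columns <- function(data, cols) {
  for (cl in cols) {
    x <- data[[cl]]
    if (!is.numeric(x)) next
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("column '", cl, "' has zero variance; not scaled")
      next
    }
    data[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}
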