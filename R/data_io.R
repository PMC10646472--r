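#' Read a community table from delimited text
#'
#' Expects a wide table: first column sample (plot) identifiers, remaining
#' columns taxa, cells non-negative abundances (counts or densities).
#' Orientation is taken as samples-in-rows unless \code{transpose = TRUE}.
#' The parse is locale-independent (C locale decimal points) and row and
#' column order is preserved.
#'
#' @param path file path; tab-delimited by default, comma-delimited for
#'   \code{.csv}
#' @param group_name label attached to the matrix (attribute "group")
#' @param sep field separator; defaults by file extension
#' @param transpose set TRUE if taxa are rows and samples are columns
#' @return numeric matrix samples x taxa with dimnames, attribute "group"
#' @export
read_community_table <- function(path, group_name = NULL, sep = NULL,
                                 transpose = FALSE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2)
    stop("community table needs a sample-id column plus at least 1 taxon")
  ids <- raw[[1]]
  taxa <- colnames(raw)[-1]
  dup_s <- unique(ids[duplicated(ids)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  dup_t <- unique(taxa[duplicated(taxa)])
  if (length(dup_t))
    stop("duplicate taxon identifiers: ", paste(dup_t, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, taxa))
  bad <- which(is.na(vals) & !(toupper(as.matrix(raw[-1])) %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric abundance at (", ids[bad[1, 1]], ", ",
         taxa[bad[1, 2]], ")")
  if (anyNA(vals))
    stop("missing abundance value(s) in ", path,
         ": community tables must be complete")
  neg <- which(vals < 0, arr.ind = TRUE)
  if (length(neg))
    stop("negative abundance at (", ids[neg[1, 1]], ", ",
         taxa[neg[1, 2]], "): abundances must be >= 0")
  if (any(!is.finite(vals) & !is.na(vals)))
    stop("non-finite abundance values in ", path)
  if (transpose) vals <- t(vals)
  if (nrow(vals) < 1 || ncol(vals) < 1)
    stop("community table must have at least 1 sample and 1 taxon")
  attr(vals, "group") <- group_name %||%
    sub("\\.[^.]+$", "", basename(path))
  vals
}

# shortest-ish round-trip float text: %.17g always round-trips doubles
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  back <- as.numeric(out)
  redo <- !is.na(x) & (is.na(back) | back != x)
  out[redo] <- sprintf("%.17g", x[redo])
  out[is.na(x)] <- "NA"
  out
}

#' Write a community table as delimited text
#'
#' Inverse of \code{\link{read_community_table}}: floats are written with
#' round-trip precision so write-then-read is the numeric identity.
#'
#' @param mat samples x taxa numeric matrix with dimnames
#' @param path output path; \code{.csv} switches to comma separation
#' @param sep field separator; defaults by extension
#' @export
write_community_table <- function(mat, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- fmt_num(mat[, j])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (plot, site, treatment, covariates)
#'
#' @param path TSV/CSV with columns plot_id, site_id, treatment and any
#'   covariate columns; empty cells or "NA" are missing values
#' @return data frame; treatment coerced to a grazed/ungrazed factor
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("plot_id", "site_id", "treatment")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
  dup <- unique(md$plot_id[duplicated(md$plot_id)])
  if (length(dup))
    stop("duplicate plot_id in metadata: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(md$treatment), c("grazed", "ungrazed", NA))
  if (length(bad))
    stop("treatment must be 'grazed' or 'ungrazed'; found: ",
         paste(bad, collapse = ", "))
  md$treatment <- factor(md$treatment, levels = c("grazed", "ungrazed"))
  md
}

#' Write sample metadata
#' @param metadata data frame as returned by \code{\link{read_metadata}}
#' @param path output path
#' @export
write_metadata <- function(metadata, path) {
  md <- metadata
  for (j in seq_along(md))
    if (is.numeric(md[[j]])) md[[j]] <- fmt_num(md[[j]])
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(md, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the constants of the analysis: what counts as presence, the
#' occupancy-quartile cohort bounds, model-selection settings, and the
#' sample-exclusion rules applied before driver modelling (the emulated
#' study dropped plots whose organic layer exceeded 100 cm, because no
#' carbon stock could be estimated there).
#'
#' @param presence_threshold abundance strictly above this counts as
#'   presence (default 0: any positive abundance)
#' @param cohort_bounds occupancy quartile bounds (lower, upper); taxa
#'   strictly below the lower bound are rare, strictly above the upper
#'   bound widespread, boundary values common
#' @param delta_threshold AICc delta below which models enter the
#'   averaged set (default 4)
#' @param averaging "conditional" (natural) or "full" (zero substitution)
#' @param max_terms cap on fixed-effect terms per candidate model
#' @param enumeration_cap hard cap on candidate-set size
#' @param estimation "ML" (required for cross-model AICc) or "REML"
#' @param exclusion_rules list of lists (covariate, op, value); matching
#'   samples are excluded from driver models only, never from the
#'   diversity statistics
#' @param seed integer seed for any stochastic stage
#' @return object of class \code{analysis_config}
#' @export
analysis_config <- function(presence_threshold = 0,
                            cohort_bounds = c(0.25, 0.75),
                            delta_threshold = 4,
                            averaging = c("conditional", "full"),
                            max_terms = Inf,
                            enumeration_cap = 20000,
                            estimation = c("ML", "REML"),
                            exclusion_rules = list(
                              list(covariate = "organic_layer_depth",
                                   op = ">", value = 100)),
                            seed = 1L) {
  if (!(cohort_bounds[1] >= 0 && cohort_bounds[1] < cohort_bounds[2] &&
        cohort_bounds[2] <= 1))
    stop("cohort_bounds must satisfy 0 <= lower < upper <= 1")
  if (delta_threshold <= 0) stop("delta_threshold must be > 0")
  structure(list(presence_threshold = presence_threshold,
                 cohort_bounds = as.numeric(cohort_bounds),
                 delta_threshold = delta_threshold,
                 averaging = match.arg(averaging),
                 max_terms = max_terms,
                 enumeration_cap = enumeration_cap,
                 estimation = match.arg(estimation),
                 exclusion_rules = exclusion_rules,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration as JSON
#' @param path JSON file
#' @return an \code{\link{analysis_config}}
#' @export
read_analysis_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- x$exclusion_rules
  if (!is.null(rules) && is.data.frame(rules))
    rules <- lapply(seq_len(nrow(rules)), function(i) as.list(rules[i, ]))
  do.call(analysis_config, c(
    x[setdiff(names(x), "exclusion_rules")],
    if (!is.null(rules)) list(exclusion_rules = rules) else NULL))
}

#' @rdname read_analysis_config
#' @param config an \code{\link{analysis_config}}
#' @export
write_analysis_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

apply_exclusion_rules <- function(metadata, rules) {
  hits <- list()
  for (r in rules) {
    x <- metadata[[r$covariate]]
    if (is.null(x)) next
    op <- match.fun(r$op)
    flag <- !is.na(x) & op(x, r$value)
    hits[[paste(r$covariate, r$op, r$value)]] <- metadata$plot_id[flag]
  }
  hits
}

#' Validate a dataset of community matrices against its metadata
#'
#' Checks sample/metadata correspondence, the paired design (every site
#' needs both treatment levels) and the config's exclusion rules. Samples
#' hit by an exclusion rule are flagged for removal from driver models
#' only; diversity statistics retain them.
#'
#' @param communities named list of community matrices
#' @param metadata sample metadata data frame
#' @param config an \code{\link{analysis_config}}
#' @param strict if TRUE (default), a sample present in a matrix but
#'   absent from metadata is a hard error (it cannot be assigned a site
#'   or treatment); if FALSE it is only reported
#' @return object of class \code{validation_report}: lists of problems
#'   and flagged samples; \code{is_clean(report)} tells if all are empty
#' @export
validate_dataset <- function(communities, metadata,
                             config = analysis_config(), strict = TRUE) {
  stopifnot(length(communities) >= 1)
  all_samples <- unique(unlist(lapply(communities, rownames)))
  missing_meta <- setdiff(all_samples, metadata$plot_id)
  if (strict && length(missing_meta))
    stop("samples present in community data but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta_only <- setdiff(metadata$plot_id, all_samples)
  tt <- table(metadata$site_id, metadata$treatment)
  unpaired <- rownames(tt)[rowSums(tt >= 1) < 2]
  excl <- apply_exclusion_rules(metadata, config$exclusion_rules)
  structure(list(samples_missing_metadata = missing_meta,
                 metadata_without_samples = meta_only,
                 sites_lacking_treatment = unpaired,
                 excluded_samples = excl),
            class = "validation_report")
}

#' @rdname validate_dataset
#' @param report a \code{validation_report}
#' @export
is_clean <- function(report) {
  length(report$samples_missing_metadata) == 0 &&
    length(report$metadata_without_samples) == 0 &&
    length(report$sites_lacking_treatment) == 0 &&
    sum(lengths(report$excluded_samples)) == 0
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation report\n")
  cat("  samples missing from metadata:",
      length(x$samples_missing_metadata), "\n")
  cat("  metadata rows without samples:",
      length(x$metadata_without_samples), "\n")
  cat("  sites lacking a treatment level:",
      length(x$sites_lacking_treatment), "\n")
  for (nm in names(x$excluded_samples))
    cat("  rule [", nm, "]: ", length(x$excluded_samples[[nm]]),
        " sample(s) flagged\n", sep = "")
  invisible(x)
}

#' Write a validation report as JSON
#' @param report a \code{validation_report}
#' @param path output path
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE,
                       null = "list")
  invisible(path)
}
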