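#' Run the full diversity and driver analysis end to end
#'
#' Orchestrates validation, the alpha/beta response-ratio table, the
#' cohort table and (optionally) the driver model-selection tables for
#' every organism group. Samples hit by the config's exclusion rules are
#' removed from the driver models only; the diversity statistics keep
#' them. Deterministic: the same inputs give identical outputs.
#'
#' @param communities named list of community matrices (one per group)
#' @param metadata sample metadata data frame
#' @param config an \code{\link{analysis_config}}
#' @param driver_covariates covariate columns for the driver analysis;
#'   NULL skips the driver stage (it is the slow stage)
#' @param driver_interactions include treatment x covariate interactions
#' @return object of class \code{grazediv_run}: \code{validation},
#'   \code{response_ratios} (the alpha/beta figure-shaped table),
#'   \code{cohorts} (group x cohort table), \code{drivers_alpha} /
#'   \code{drivers_beta} (per-group averaged-model lists plus formatted
#'   tables), \code{log} (character vector of stage events)
#' @export
run_full_analysis <- function(communities, metadata,
                              config = analysis_config(),
                              driver_covariates = NULL,
                              driver_interactions = TRUE) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  report <- validate_dataset(communities, metadata, config, strict = TRUE)
  excl <- unique(unlist(report$excluded_samples))
  note("validation: ", length(excl), " sample(s) flagged for exclusion ",
       "from driver models")

  rr <- response_ratio_table(communities, metadata, config)
  note("response ratios: ", length(communities), " group(s), ",
       sum(rr$pooled$n_excluded), " site-level ratio(s) excluded ",
       "(zero denominators)")

  cohorts <- list()
  for (g in names(communities)) {
    tab <- cohort_response_ratios(communities[[g]], metadata,
                                  config = config)
    cohorts[[g]] <- cbind(group = g, tab, stringsAsFactors = FALSE)
    absent <- tab$cohort[!tab$present]
    if (length(absent))
      note("cohorts[", g, "]: absent cohort(s): ",
           paste(absent, collapse = ", "))
  }
  cohorts <- do.call(rbind, c(cohorts, make.row.names = FALSE))

  drivers_alpha <- drivers_beta <- NULL
  if (!is.null(driver_covariates)) {
    md_use <- metadata[!(metadata$plot_id %in% excl), , drop = FALSE]
    note("driver models: ", nrow(metadata) - nrow(md_use),
         " plot(s) excluded by config rules")
    da <- db <- list()
    for (g in names(communities)) {
      mat <- communities[[g]]
      # alpha driver model: plot-level richness
      dat <- md_use[md_use$plot_id %in% rownames(mat), , drop = FALSE]
      dat$alpha <- as.numeric(
        richness(mat, config$presence_threshold)[dat$plot_id])
      da[[g]] <- driver_analysis(dat, "alpha", driver_covariates,
                                 interactions = driver_interactions,
                                 config = config)
      # beta driver model: site x treatment mean dissimilarity, with
      # covariates averaged over the contributing plots
      bt <- beta_table(mat, dat, config$presence_threshold)
      cov_means <- stats::aggregate(
        dat[driver_covariates],
        by = list(site_id = dat$site_id, treatment = dat$treatment),
        FUN = mean, na.rm = TRUE)
      bdat <- merge(bt, cov_means, by = c("site_id", "treatment"))
      bdat$treatment <- factor(bdat$treatment,
                               levels = c("grazed", "ungrazed"))
      bdat$beta <- bdat$mean_dissimilarity
      db[[g]] <- driver_analysis(bdat, "beta", driver_covariates,
                                 interactions = driver_interactions,
                                 config = config)
      note("drivers[", g, "]: ", da[[g]]$n_candidates, " candidates, ",
           da[[g]]$averaged$n_models, " (alpha) / ",
           db[[g]]$averaged$n_models, " (beta) models in the window")
    }
    drivers_alpha <- list(
      per_group = da,
      table = format_driver_table(lapply(da, `[[`, "averaged")))
    drivers_beta <- list(
      per_group = db,
      table = format_driver_table(lapply(db, `[[`, "averaged")))
  }

  structure(list(validation = report,
                 response_ratios = rr,
                 cohorts = cohorts,
                 drivers_alpha = drivers_alpha,
                 drivers_beta = drivers_beta,
                 config = config,
                 log = log),
            class = "grazediv_run")
}

#' @export
print.grazediv_run <- function(x, ...) {
  cat("grazediv run:", length(unique(x$response_ratios$pooled$group)),
      "group(s)\n")
  print(x$response_ratios$pooled, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Parameter-recovery experiment over replicate synthetic datasets
#'
#' Generates \code{n_replicates} datasets from the given configuration
#' (each with a child seed) and runs the diversity stage of the pipeline
#' on each, comparing estimates against the generator's declared truth.
#' Reports, per group: bias and RMSE of the pooled alpha response ratio,
#' the sign-recovery rate of the dissimilarity response ratio, and the
#' rejection rate of the treatment test (the type-I error rate when the
#' group's effects are null).
#'
#' @param config a \code{\link{synthetic_config}}
#' @param n_replicates number of replicate datasets (>= 2)
#' @param seed master seed for the experiment (overrides config$seed per
#'   replicate via the child-seed scheme)
#' @param analysis an \code{\link{analysis_config}}
#' @return list: \code{summary} data frame (one row per group) and
#'   \code{replicates} (long data frame of per-replicate estimates)
#' @export
recovery_experiment <- function(config, n_replicates, seed = 1L,
                                analysis = analysis_config()) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  reps <- list()
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed_for(seed, paste0("replicate:", i))
    ds <- generate_dataset(cfg)
    rr <- response_ratio_table(ds$communities, ds$metadata, analysis)
    p <- rr$pooled
    reps[[i]] <- data.frame(
      replicate = i, group = p$group[p$response == "delta_alpha"],
      delta_alpha = p$estimate[p$response == "delta_alpha"],
      delta_beta = p$estimate[p$response == "delta_dissimilarity"],
      p_alpha = p$p_value[p$response == "delta_alpha"],
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, c(reps, make.row.names = FALSE))
  truth <- config$group_specs
  rows <- lapply(names(truth), function(g) {
    tr_da <- -truth[[g]]$richness_loss / (1 - truth[[g]]$richness_loss)
    tr_sign <- sign(truth[[g]]$beta_effect)
    x <- long[long$group == g, ]
    data.frame(
      group = g,
      true_delta_alpha = tr_da,
      mean_delta_alpha = mean(x$delta_alpha, na.rm = TRUE),
      bias = mean(x$delta_alpha, na.rm = TRUE) - tr_da,
      rmse = sqrt(mean((x$delta_alpha - tr_da)^2, na.rm = TRUE)),
      mc_se = stats::sd(x$delta_alpha, na.rm = TRUE) /
        sqrt(sum(is.finite(x$delta_alpha))),
      beta_sign_rate = if (tr_sign == 0) NA_real_ else
        mean(sign(x$delta_beta) == tr_sign, na.rm = TRUE),
      rejection_rate = mean(x$p_alpha < 0.05, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       replicates = long)
}

#' Write the run's publication-shaped tables to a directory
#'
#' @param run a \code{grazediv_run}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_run_tables <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    response_ratios = file.path(dir, "response_ratios_pooled.tsv"),
    per_site = file.path(dir, "response_ratios_per_site.tsv"),
    cohorts = file.path(dir, "cohort_response_ratios.tsv"))
  utils::write.table(run$response_ratios$pooled, paths["response_ratios"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$response_ratios$per_site, paths["per_site"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$cohorts, paths["cohorts"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$drivers_alpha)) {
    paths["drivers_alpha"] <- file.path(dir, "drivers_alpha.tsv")
    paths["drivers_beta"] <- file.path(dir, "drivers_beta.tsv")
    utils::write.table(run$drivers_alpha$table, paths["drivers_alpha"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$drivers_beta$table, paths["drivers_beta"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(paths)
}
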