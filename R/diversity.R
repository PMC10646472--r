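#' Per-plot taxon richness
#'
#' Richness (the alpha-diversity measure used throughout) is the number
#' of taxa whose abundance is strictly greater than the presence
#' threshold, so with the default threshold of 0 any positive abundance
#' counts.
#'
#' @param mat samples x taxa abundance matrix
#' @param presence_threshold presence cut-off (strict inequality)
#' @return named integer vector, one richness per plot
#' @export
richness <- function(mat, presence_threshold = 0) {
  stopifnot(is.matrix(mat))
  as.integer(rowSums(mat > presence_threshold)) |>
    stats::setNames(rownames(mat))
}

#' Response ratio of alpha-diversity to cessation of grazing
#'
#' Delta alpha = (alpha_ungrazed - alpha_grazed) / alpha_ungrazed.
#' Positive values mean richness increased where grazing ceased. When
#' both means are zero the ratio is 0 by convention; when only the
#' ungrazed mean is zero the ratio is undefined and NA is returned (the
#' caller excludes such sites from pooling and logs the count).
#'
#' @param alpha_u mean ungrazed richness (vectorised)
#' @param alpha_g mean grazed richness
#' @return numeric response ratio(s)
#' @export
alpha_response_ratio <- function(alpha_u, alpha_g) {
  out <- (alpha_u - alpha_g) / alpha_u
  out[alpha_u == 0 & alpha_g == 0] <- 0
  out[alpha_u == 0 & alpha_g > 0] <- NA_real_
  out
}

#' Response ratio of within-site dissimilarity
#'
#' Delta dissimilarity = (d_ungrazed - d_grazed) / d_ungrazed. Positive
#' means plots diverged (beta-diversity up) after cessation of grazing,
#' negative means biotic homogenization. d_ungrazed = 0 leaves the ratio
#' undefined (NA; site excluded from pooling).
#'
#' @param d_u mean ungrazed within-site dissimilarity
#' @param d_g mean grazed within-site dissimilarity
#' @return numeric response ratio(s)
#' @export
beta_response_ratio <- function(d_u, d_g) {
  out <- (d_u - d_g) / d_u
  out[d_u == 0] <- NA_real_
  out
}

#' Pairwise Bray-Curtis dissimilarity between plots
#'
#' Computed on presence-absence by default (Bray-Curtis on 0/1 data,
#' identical to Sorensen dissimilarity (b + c) / (2a + b + c) with a the
#' shared presences and b, c the presences unique to either plot), via
#' vegan's vegdist. A pair of two all-absent plots is defined as 0 with a
#' warning. An abundance-weighted variant is available but is not the
#' default, since read-count abundances are primer-sensitive.
#'
#' @param mat samples x taxa abundance matrix
#' @param plots plot ids (rownames subset); default all
#' @param presence_threshold presence cut-off for the binary transform
#' @param method "presence" (default) or "abundance"
#' @return object of class \code{dist}
#' @export
pairwise_dissimilarity <- function(mat, plots = rownames(mat),
                                   presence_threshold = 0,
                                   method = c("presence", "abundance")) {
  method <- match.arg(method)
  if (length(plots) < 2)
    stop("dissimilarity needs >= 2 plots (got ", length(plots), ")")
  sub <- mat[plots, , drop = FALSE]
  x <- if (method == "presence") (sub > presence_threshold) * 1 else sub
  # vegdist warns on empty rows itself; we handle that case explicitly
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("pair(s) of all-absent plots: dissimilarity defined as 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Mean pairwise dissimilarity among same-treatment plots of one site
#'
#' The within-site beta-diversity estimate for one treatment: the
#' unweighted arithmetic mean of all C(n, 2) pairwise dissimilarities
#' among that site's plots of that treatment.
#'
#' @param mat samples x taxa abundance matrix
#' @param metadata sample metadata (plot_id, site_id, treatment)
#' @param site site id
#' @param treatment "grazed" or "ungrazed"
#' @param presence_threshold presence cut-off
#' @param method dissimilarity flavour, see
#'   \code{\link{pairwise_dissimilarity}}
#' @return list(mean_dissimilarity, n_pairs, n_plots)
#' @export
within_site_mean_dissimilarity <- function(mat, metadata, site, treatment,
                                           presence_threshold = 0,
                                           method = "presence") {
  plots <- metadata$plot_id[metadata$site_id == site &
                              metadata$treatment == treatment]
  plots <- intersect(plots, rownames(mat))
  if (length(plots) < 2)
    stop("site ", site, " has < 2 ", treatment,
         " plots with data; within-site beta-diversity undefined")
  d <- pairwise_dissimilarity(mat, plots, presence_threshold, method)
  list(mean_dissimilarity = mean(d), n_pairs = length(d),
       n_plots = length(plots))
}

# per (site x treatment) mean dissimilarity table for one group
beta_table <- function(mat, metadata, presence_threshold = 0,
                       method = "presence") {
  sites <- unique(metadata$site_id)
  rows <- list()
  skipped <- character(0)
  for (s in sites) for (tr in c("grazed", "ungrazed")) {
    res <- tryCatch(
      within_site_mean_dissimilarity(mat, metadata, s, tr,
                                     presence_threshold, method),
      error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, paste0(s, ":", tr))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      site_id = s, treatment = tr,
      mean_dissimilarity = res$mean_dissimilarity,
      n_pairs = res$n_pairs, n_plots = res$n_plots,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Classify taxa into occupancy cohorts (rare / common / widespread)
#'
#' Occupancy is the fraction of all plots (both treatments) in which a
#' taxon is present. Taxa occupying strictly less than the lower bound
#' (default 25 percent) are rare, strictly more than the upper bound
#' (default 75 percent) widespread, everything else — including exact
#' boundary values — common. Taxa absent from every plot are dropped.
#'
#' @param mat samples x taxa abundance matrix
#' @param presence_threshold presence cut-off
#' @param bounds lower/upper occupancy bounds
#' @return data frame (taxon_id, occupancy, cohort); attribute
#'   "n_dropped" counts never-present taxa
#' @export
classify_occupancy_cohorts <- function(mat, presence_threshold = 0,
                                       bounds = c(0.25, 0.75)) {
  stopifnot(bounds[1] < bounds[2])
  occ <- colMeans(mat > presence_threshold)
  keep <- occ > 0
  occ <- occ[keep]
  cohort <- ifelse(occ < bounds[1], "rare",
            ifelse(occ > bounds[2], "widespread", "common"))
  out <- data.frame(taxon_id = names(occ), occupancy = as.numeric(occ),
                    cohort = factor(cohort,
                                    levels = c("rare", "common",
                                               "widespread")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# per-site alpha response ratios for one group (optionally a taxon subset)
site_alpha_ratios <- function(mat, metadata, presence_threshold = 0,
                              taxa = colnames(mat)) {
  sub <- mat[, taxa, drop = FALSE]
  rich <- richness(sub, presence_threshold)
  md <- metadata[match(rownames(sub), metadata$plot_id), ]
  ag <- tapply(rich[md$treatment == "grazed"],
               md$site_id[md$treatment == "grazed"], mean)
  au <- tapply(rich[md$treatment == "ungrazed"],
               md$site_id[md$treatment == "ungrazed"], mean)
  sites <- intersect(names(ag), names(au))
  data.frame(site_id = sites,
             alpha_grazed = as.numeric(ag[sites]),
             alpha_ungrazed = as.numeric(au[sites]),
             delta_alpha = alpha_response_ratio(as.numeric(au[sites]),
                                                as.numeric(ag[sites])),
             stringsAsFactors = FALSE)
}

# pooled estimate across sites: mean of per-site ratios with cross-site sd
pool_ratios <- function(x) {
  ok <- is.finite(x)
  list(estimate = if (any(ok)) mean(x[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(x[ok]) else NA_real_,
       n_sites = sum(ok), n_excluded = sum(!ok))
}

#' Alpha- and beta-diversity response ratios for every organism group
#'
#' The per-site response ratios are the analysis unit: the pooled
#' estimate per group is their mean across sites, the error bar their
#' cross-site s.d. Significance of the treatment effect is assessed by
#' default with a Gaussian mixed model on the plot-level response
#' (richness, or the site x treatment mean dissimilarity for beta) with
#' treatment fixed and site as a random intercept; \code{method =
#' "ratio_t"} instead applies a one-sample t-test to the per-site ratios.
#'
#' @param communities named list of community matrices
#' @param metadata sample metadata
#' @param config an \code{\link{analysis_config}}
#' @param method significance engine, "lmm" (default) or "ratio_t"
#' @return list with \code{per_site} (long data frame of site-level
#'   ratios) and \code{pooled} (one row per group x response with
#'   estimate, sd, statistic, p, significance class)
#' @export
response_ratio_table <- function(communities, metadata,
                                 config = analysis_config(),
                                 method = c("lmm", "ratio_t")) {
  method <- match.arg(method)
  thr <- config$presence_threshold
  per_site <- list()
  pooled <- list()
  for (g in names(communities)) {
    mat <- communities[[g]]
    md <- metadata[metadata$plot_id %in% rownames(mat), ]

    a <- site_alpha_ratios(mat, md, thr)
    bt <- beta_table(mat, md, thr)
    bw <- stats::reshape(bt[c("site_id", "treatment",
                              "mean_dissimilarity")],
                         idvar = "site_id", timevar = "treatment",
                         direction = "wide")
    names(bw) <- sub("mean_dissimilarity\\.", "d_", names(bw))
    b <- merge(a["site_id"], bw, by = "site_id", all.x = TRUE)
    b$delta_beta <- beta_response_ratio(b$d_ungrazed, b$d_grazed)
    tab <- merge(a, b, by = "site_id")
    tab <- cbind(group = g, tab, stringsAsFactors = FALSE)
    per_site[[g]] <- tab

    pa <- pool_ratios(tab$delta_alpha)
    pb <- pool_ratios(tab$delta_beta)
    sig_a <- ratio_significance(richness(mat, thr), md, tab$delta_alpha,
                                method)
    dd <- bt
    dd$y <- dd$mean_dissimilarity
    sig_b <- ratio_significance_beta(dd, tab$delta_beta, method)
    pooled[[g]] <- data.frame(
      group = g,
      response = c("delta_alpha", "delta_dissimilarity"),
      estimate = c(pa$estimate, pb$estimate),
      sd = c(pa$sd, pb$sd),
      n_sites = c(pa$n_sites, pb$n_sites),
      n_excluded = c(pa$n_excluded, pb$n_excluded),
      statistic = c(sig_a$statistic, sig_b$statistic),
      df = c(sig_a$df, sig_b$df),
      p_value = c(sig_a$p, sig_b$p),
      significance = significance_class(c(sig_a$p, sig_b$p)),
      stringsAsFactors = FALSE)
  }
  list(per_site = do.call(rbind, c(per_site, make.row.names = FALSE)),
       pooled = do.call(rbind, c(pooled, make.row.names = FALSE)))
}

# treatment significance for richness: LMM on plot richness (default) or
# one-sample t on per-site ratios
ratio_significance <- function(rich, md, site_ratios,
                               method = c("lmm", "ratio_t")) {
  method <- match.arg(method)
  if (method == "ratio_t") return(one_sample_t(site_ratios))
  dat <- data.frame(y = as.numeric(rich),
                    treatment = md$treatment[match(names(rich),
                                                   md$plot_id)],
                    site_id = md$site_id[match(names(rich), md$plot_id)])
  fit <- fit_lmm(dat, "y", "treatment", group = "site_id", method = "REML")
  tt <- treatment_test(fit, "treatment")
  list(statistic = tt$statistic, df = tt$df, p = tt$p_value)
}

ratio_significance_beta <- function(site_treat_tab, site_ratios,
                                    method = c("lmm", "ratio_t")) {
  method <- match.arg(method)
  if (method == "ratio_t" ||
      length(unique(site_treat_tab$site_id)) < 2)
    return(one_sample_t(site_ratios))
  dat <- data.frame(y = site_treat_tab$mean_dissimilarity,
                    treatment = factor(site_treat_tab$treatment,
                                       levels = c("grazed", "ungrazed")),
                    site_id = site_treat_tab$site_id)
  fit <- fit_lmm(dat, "y", "treatment", group = "site_id", method = "REML")
  tt <- treatment_test(fit, "treatment")
  list(statistic = tt$statistic, df = tt$df, p = tt$p_value)
}

one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || stats::sd(x) == 0)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  tt <- stats::t.test(x)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Cohort-wise alpha response ratios (rare / common / widespread)
#'
#' Richness is recomputed per occupancy cohort (counting only that
#' cohort's taxa) and the per-site and pooled response ratios are formed
#' exactly as for total richness. Beta-diversity is deliberately not
#' computed per cohort. An empty cohort (e.g. no widespread taxa in a
#' group) is reported as absent, not as zero.
#'
#' @param mat community matrix of one group
#' @param metadata sample metadata
#' @param assignment cohort assignment from
#'   \code{\link{classify_occupancy_cohorts}}; computed if NULL
#' @param config an \code{\link{analysis_config}}
#' @param method significance engine, see
#'   \code{\link{response_ratio_table}}
#' @return data frame, one row per cohort: present flag, pooled estimate,
#'   sd, n_taxa, p-value and significance class
#' @export
cohort_response_ratios <- function(mat, metadata, assignment = NULL,
                                   config = analysis_config(),
                                   method = c("lmm", "ratio_t")) {
  method <- match.arg(method)
  thr <- config$presence_threshold
  if (is.null(assignment))
    assignment <- classify_occupancy_cohorts(mat, thr, config$cohort_bounds)
  md <- metadata[metadata$plot_id %in% rownames(mat), ]
  rows <- list()
  for (ch in levels(assignment$cohort)) {
    taxa <- assignment$taxon_id[assignment$cohort == ch]
    if (length(taxa) == 0) {
      rows[[ch]] <- data.frame(cohort = ch, present = FALSE,
                               n_taxa = 0L, estimate = NA_real_,
                               sd = NA_real_, n_sites = 0L,
                               p_value = NA_real_,
                               significance = NA_character_,
                               stringsAsFactors = FALSE)
      next
    }
    a <- site_alpha_ratios(mat, md, thr, taxa = taxa)
    p <- pool_ratios(a$delta_alpha)
    sig <- ratio_significance(richness(mat[, taxa, drop = FALSE], thr),
                              md, a$delta_alpha, method)
    rows[[ch]] <- data.frame(cohort = ch, present = TRUE,
                             n_taxa = length(taxa), estimate = p$estimate,
                             sd = p$sd, n_sites = p$n_sites,
                             p_value = sig$p,
                             significance = significance_class(sig$p),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$cohort <- factor(out$cohort, levels = c("rare", "common",
                                              "widespread"))
  out
}
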