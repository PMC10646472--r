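#' Enumerate candidate fixed-effect structures under marginality
#'
#' Generates every subset of the main effects together with every subset
#' of the declared interactions whose parent mains are both present
#' (marginality), including the intercept-only model, optionally capped
#' at \code{max_terms} terms per model. Ordering is deterministic: terms
#' keep the order given, models are sorted by size then by their
#' canonical term string.
#'
#' @param mains character vector of main-effect terms (e.g. "treatment",
#'   "pH")
#' @param interactions character vector like "treatment:pH"; both parents
#'   must appear in \code{mains}
#' @param max_terms cap on the number of terms per model
#' @param cap hard cap on the candidate-set size; exceeding it is an
#'   error advising to lower \code{max_terms} (guards the combinatorial
#'   blow-up of all-subsets enumeration)
#' @return object of class \code{candidate_set}: list of character term
#'   vectors (the intercept-only model is \code{character(0)})
#' @export
enumerate_submodels <- function(mains, interactions = character(),
                                max_terms = Inf, cap = 20000) {
  stopifnot(!anyDuplicated(mains))
  for (ia in interactions) {
    par <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(par %in% mains))
      stop("interaction '", ia, "' has parents outside mains")
  }
  m <- length(mains)
  if (m > 25) stop("too many main effects to enumerate (", m, " > 25)")
  models <- vector("list", 1024); nmod <- 0L
  add <- function(terms) {
    nmod <<- nmod + 1L
    if (nmod > cap)
      stop("candidate set exceeds the cap of ", cap,
           " models; lower max_terms or reduce the full model")
    if (nmod > length(models)) length(models) <<- 2L * nmod
    models[[nmod]] <<- terms
  }
  # iterate subsets of mains; for each, subsets of admissible interactions
  for (mask in 0:(2^m - 1)) {
    sel <- mains[bitwAnd(bitwShiftL(1, seq_len(m) - 1), mask) != 0]
    if (length(sel) > max_terms) next
    ok_ia <- interactions[vapply(interactions, function(ia) {
      all(strsplit(ia, ":", fixed = TRUE)[[1]] %in% sel)
    }, TRUE)]
    ni <- length(ok_ia)
    room <- max_terms - length(sel)
    for (imask in 0:(2^ni - 1)) {
      isel <- ok_ia[bitwAnd(bitwShiftL(1, seq_len(ni) - 1), imask) != 0]
      if (length(isel) > room) next
      add(c(sel, isel))
    }
  }
  models <- models[seq_len(nmod)]
  key <- vapply(models, function(tt) paste(tt, collapse = " + "), "")
  ord <- order(lengths(models), key)
  structure(list(models = models[ord],
                 ids = ifelse(key[ord] == "", "1", key[ord]),
                 mains = mains, interactions = interactions,
                 max_terms = max_terms),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$models), "models over",
      length(x$mains), "mains and", length(x$interactions),
      "interactions\n")
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1), with k the number of
#' estimated parameters (fixed coefficients plus the two variance
#' components). Returns NA when n - k - 1 <= 0 (such models are dropped
#' from ranking with a log entry). Cross-model comparison requires ML
#' fits.
#'
#' @param fit a \code{grazediv_lmm} (or a list with loglik, k_params,
#'   n_obs)
#' @return AICc value
#' @export
aicc <- function(fit) {
  k <- fit$k_params; n <- fit$n_obs; ll <- fit$loglik
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit every candidate model
#'
#' @param candidates a \code{candidate_set}
#' @param data analysis data frame (already standardised if desired)
#' @param response response column name
#' @param group grouping column
#' @param method estimation mode; ML by default (AICc across models
#'   differing in fixed effects is invalid under REML)
#' @return list of \code{grazediv_lmm} fits named by model id; failed or
#'   AICc-undefined fits are dropped, their ids in attribute "dropped"
#' @export
fit_candidates <- function(candidates, data, response, group = "site_id",
                           method = "ML") {
  stopifnot(inherits(candidates, "candidate_set"))
  fits <- list(); dropped <- character(0)
  for (i in seq_along(candidates$models)) {
    id <- candidates$ids[i]
    fit <- tryCatch(
      fit_lmm(data, response, candidates$models[[i]], group, method),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || is.na(aicc(fit))) {
      dropped <- c(dropped, id)
    } else {
      fits[[id]] <- fit
    }
  }
  if (length(fits) == 0) stop("all candidate models failed to fit")
  attr(fits, "dropped") <- dropped
  fits
}

#' Rank models by AICc and compute Akaike weights
#'
#' Delta_i = AICc_i - AICc_min and w_i = exp(-Delta_i / 2) /
#' sum_r exp(-Delta_r / 2), computed with max-subtraction so weights stay
#' finite for any Delta spread. Ties at Delta = 0 are broken stably by
#' the canonical term-set string.
#'
#' @param fits named list of ML fits (from \code{\link{fit_candidates}})
#' @return data frame (model, n_terms, k, aicc, delta, weight), sorted by
#'   delta then model id; weights sum to 1 over the full set
#' @export
rank_and_weight <- function(fits) {
  stopifnot(length(fits) >= 1)
  a <- vapply(fits, aicc, 0)
  delta <- a - min(a)
  ew <- exp(-(delta - min(delta)) / 2)
  w <- ew / sum(ew)
  out <- data.frame(model = names(fits),
                    n_terms = vapply(fits, function(f)
                      length(setdiff(f$fixed_terms, "1")), 0L),
                    k = vapply(fits, function(f) as.numeric(f$k_params), 0),
                    aicc = a, delta = delta, weight = w,
                    stringsAsFactors = FALSE)
  out <- out[order(out$delta, out$model), ]
  rownames(out) <- NULL
  out
}

#' Average the models within the AICc-delta window
#'
#' Retains models with Delta < \code{delta_threshold} (default 4),
#' renormalises their weights, and averages coefficients. The default is
#' the conditional ("natural") average: per coefficient, the weighted
#' mean over only the retained models containing it, with the
#' unconditional standard error sqrt(sum w (se^2 + (b - bbar)^2))
#' combining within-model uncertainty and between-model spread.
#' \code{mode = "full"} substitutes zero where a term is absent. The
#' cumulative Akaike weight of a term is the summed renormalised weight
#' of retained models containing it.
#'
#' @param ranked output of \code{\link{rank_and_weight}}
#' @param fits the fit list the ranking was computed from
#' @param delta_threshold retention window (default 4)
#' @param mode "conditional" (default) or "full"
#' @return list: \code{terms} data frame (term, estimate, se,
#'   cumulative_weight, n_models), \code{n_models} retained count,
#'   \code{r2m_range}, \code{r2c_range}, \code{site_effect_range},
#'   \code{retained} the renormalised ranking rows
#' @export
average_models <- function(ranked, fits, delta_threshold = 4,
                           mode = c("conditional", "full")) {
  mode <- match.arg(mode)
  keep <- ranked[ranked$delta < delta_threshold, , drop = FALSE]
  stopifnot(nrow(keep) >= 1)
  keep$weight <- keep$weight / sum(keep$weight)
  kf <- fits[keep$model]

  all_terms <- unique(unlist(lapply(kf, function(f) f$coefficients$term)))
  rows <- lapply(all_terms, function(tm) {
    est <- se <- w <- numeric(0)
    for (i in seq_along(kf)) {
      co <- kf[[i]]$coefficients
      j <- match(tm, co$term)
      if (!is.na(j)) {
        est <- c(est, co$estimate[j]); se <- c(se, co$se[j])
        w <- c(w, keep$weight[i])
      } else if (mode == "full") {
        est <- c(est, 0); se <- c(se, 0); w <- c(w, keep$weight[i])
      }
    }
    cw <- sum(keep$weight[vapply(kf, function(f)
      tm %in% f$coefficients$term, TRUE)])
    wn <- w / sum(w)
    bbar <- sum(wn * est)
    se_u <- sqrt(sum(wn * (se^2 + (est - bbar)^2)))
    data.frame(term = tm, estimate = bbar, se = se_u,
               cumulative_weight = cw,
               n_models = sum(vapply(kf, function(f)
                 tm %in% f$coefficients$term, TRUE)),
               stringsAsFactors = FALSE)
  })
  r2 <- t(vapply(kf, pseudo_r2, c(R2m = 0, R2c = 0)))
  list(terms = do.call(rbind, rows),
       n_models = nrow(keep),
       r2m_range = range(r2[, "R2m"]),
       r2c_range = range(r2[, "R2c"]),
       site_effect_range = range(r2[, "R2c"] - r2[, "R2m"]),
       retained = keep,
       mode = mode)
}

#' All-subsets driver analysis for one response
#'
#' The full workflow behind the driver tables: standardise the response
#' and continuous covariates on the analysis subset, enumerate all
#' submodels of treatment + covariates + treatment-by-covariate
#' interactions under marginality, fit each by ML, rank by AICc and
#' average the models within the delta window.
#'
#' @param data analysis rows (one response column, treatment, site and
#'   covariates); incomplete rows are dropped with a count
#' @param response response column name (scaled internally)
#' @param covariates covariate column names to consider
#' @param group grouping column
#' @param interactions include treatment x covariate interactions?
#' @param config an \code{\link{analysis_config}} supplying
#'   delta_threshold, averaging mode, max_terms and the enumeration cap
#' @return list: \code{ranked}, \code{averaged}, \code{n_candidates},
#'   \code{n_data}, \code{dropped_models}
#' @export
driver_analysis <- function(data, response, covariates,
                            group = "site_id", interactions = TRUE,
                            config = analysis_config()) {
  vars <- c(response, group, "treatment", covariates)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[keep, , drop = FALSE]
  dat <- standardize_columns(dat, c(response, covariates))
  mains <- c("treatment", covariates)
  ints <- if (interactions) paste0("treatment:", covariates)
          else character(0)
  cands <- enumerate_submodels(mains, ints,
                               max_terms = config$max_terms,
                               cap = config$enumeration_cap)
  fits <- fit_candidates(cands, dat, response, group,
                         method = config$estimation)
  ranked <- rank_and_weight(fits)
  avg <- average_models(ranked, fits, config$delta_threshold,
                        config$averaging)
  list(ranked = ranked, averaged = avg,
       n_candidates = length(cands$models),
       n_data = nrow(dat), n_rows_dropped = sum(!keep),
       dropped_models = attr(fits, "dropped"))
}

#' Format averaged driver results as a publication-shaped table
#'
#' One column per group, rows are terms, cells read
#' "estimate +/- se (cumulative weight; model count)", with footer rows
#' for the retained-model count and the R2m / R2c / site-effect ranges.
#'
#' @param avg_list named list of \code{\link{average_models}} outputs,
#'   one per organism group
#' @return data frame with a "factor" column and one column per group
#' @export
format_driver_table <- function(avg_list) {
  terms <- unique(unlist(lapply(avg_list, function(a) a$terms$term)))
  fmt <- function(a, tm) {
    j <- match(tm, a$terms$term)
    if (is.na(j)) return("")
    with(a$terms[j, ], sprintf("%.2f ± %.2f (%.2g;%d)",
                               estimate, se, cumulative_weight, n_models))
  }
  out <- data.frame(factor = terms, stringsAsFactors = FALSE)
  for (g in names(avg_list))
    out[[g]] <- vapply(terms, fmt, "", a = avg_list[[g]])
  footer <- data.frame(
    factor = c("n models (delta<thr)", "marginal R2 (range)",
               "conditional R2 (range)", "site effect (range)"),
    stringsAsFactors = FALSE)
  for (g in names(avg_list)) {
    a <- avg_list[[g]]
    footer[[g]] <- c(as.character(a$n_models),
                     sprintf("%.2f-%.2f", a$r2m_range[1], a$r2m_range[2]),
                     sprintf("%.2f-%.2f", a$r2c_range[1], a$r2c_range[2]),
                     sprintf("%.2f-%.2f", a$site_effect_range[1],
                             a$site_effect_range[2]))
  }
  rbind(out, footer)
}
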