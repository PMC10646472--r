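#' Fit a Gaussian linear mixed model with a random site intercept
#'
#' Fits y = X beta + u_site + eps with u_site ~ N(0, sigma2_site) i.i.d.
#' per site and eps ~ N(0, sigma2), by profiling beta and sigma2 out of
#' the (restricted) log-likelihood and maximising over the single
#' variance ratio lambda = sigma2_site / sigma2 >= 0 with a bracketed
#' scalar search on log(lambda) to relative tolerance 1e-8. The boundary
#' lambda = 0 (no site variance; the fit reduces to OLS) is admissible
#' and checked explicitly. The fit is fully deterministic.
#'
#' @param data data frame of complete analysis rows; rows with NA in the
#'   response, any fixed term or the grouping column are dropped and
#'   counted in \code{n_dropped}
#' @param response response column name
#' @param fixed_terms character vector of fixed-effect term labels, e.g.
#'   \code{c("treatment", "pH", "treatment:pH")}; "1" or an empty vector
#'   gives the intercept-only model. An intercept is always included.
#' @param group grouping (site) column name
#' @param method "ML" (needed for cross-model AICc comparison) or "REML"
#' @return object of class \code{grazediv_lmm}: coefficient table,
#'   variance components, log-likelihood, lambda, n_obs, k_params (fixed
#'   coefficients + 2 variance parameters), fitted fixed-part values
#' @export
fit_lmm <- function(data, response, fixed_terms = "1", group = "site_id",
                    method = c("ML", "REML")) {
  method <- match.arg(method)
  if (length(fixed_terms) == 0) fixed_terms <- "1"
  vars <- unique(c(response, group,
                   all.vars(stats::reformulate(fixed_terms))))
  vars <- intersect(vars, colnames(data))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]

  f <- stats::reformulate(fixed_terms, intercept = TRUE)
  X <- stats::model.matrix(f, data)
  y <- as.numeric(data[[response]])
  g <- factor(data[[group]])
  if (nlevels(g) < 2)
    stop("mixed model requires >= 2 groups (sites); got ", nlevels(g))
  n <- length(y); p <- ncol(X)

  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (n - p < 1) stop("more fixed-effect coefficients than observations")

  n_g <- as.numeric(table(g))
  Xg <- rowsum(X, g)                 # group sums of columns
  yg <- as.numeric(rowsum(y, g))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  profile <- function(lambda) {
    shrink <- lambda / (1 + lambda * n_g)
    XtViX <- XtX - crossprod(Xg * sqrt(shrink))
    XtViy <- Xty - crossprod(Xg, shrink * yg)
    yViy <- yty - sum(shrink * yg^2)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
    q <- max(yViy - sum(XtViy * beta), 1e-300)
    logdetV <- sum(log1p(lambda * n_g))
    if (method == "ML") {
      s2 <- q / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdetV + n)
    } else {
      s2 <- q / (n - p)
      logdetXVX <- 2 * sum(log(diag(ch)))
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) +
                      logdetV + logdetXVX + (n - p))
    }
    list(ll = ll, beta = as.numeric(beta), s2 = s2, XtViX = XtViX)
  }

  obj <- function(t) {
    pr <- profile(exp(t))
    if (is.null(pr)) return(1e300)
    -pr$ll
  }
  opt <- stats::optimize(obj, interval = c(log(1e-10), log(1e8)),
                         tol = 1e-9)
  cand <- c(0, exp(opt$minimum))
  lls <- vapply(cand, function(l) {
    pr <- profile(l)
    if (is.null(pr)) -Inf else pr$ll
  }, 0)
  lambda <- cand[which.max(lls)]
  pr <- profile(lambda)

  vc <- pr$s2 * solve(pr$XtViX)
  se <- sqrt(diag(vc))
  coefs <- data.frame(term = colnames(X), estimate = pr$beta,
                      se = se, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 vcov = vc,
                 sigma2_site = lambda * pr$s2,
                 sigma2_resid = pr$s2,
                 lambda = lambda,
                 loglik = pr$ll,
                 method = method,
                 n_obs = n,
                 n_groups = nlevels(g),
                 p_fixed = p,
                 k_params = p + 2L,
                 fixed_terms = fixed_terms,
                 response = response,
                 fitted_fixed = as.numeric(X %*% pr$beta),
                 n_dropped = n_dropped,
                 converged = TRUE),
            class = "grazediv_lmm")
}

#' @export
print.grazediv_lmm <- function(x, ...) {
  cat("Gaussian LMM (", x$method, "), random intercept by site\n", sep = "")
  cat("  n =", x$n_obs, " groups =", x$n_groups,
      " logLik =", format(x$loglik, digits = 6), "\n")
  cat("  sigma2_site =", format(x$sigma2_site, digits = 5),
      " sigma2_resid =", format(x$sigma2_resid, digits = 5), "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Marginal and conditional pseudo-R-squared of a mixed-model fit
#'
#' Variance-partition pseudo-R2 for Gaussian identity-link mixed models:
#' R2m = var_f / (var_f + sigma2_site + sigma2_resid) and
#' R2c = (var_f + sigma2_site) / (var_f + sigma2_site + sigma2_resid),
#' where var_f is the variance of the fixed-effect linear predictor over
#' the data. The difference R2c - R2m is the variance share of site.
#'
#' @param fit a \code{grazediv_lmm}
#' @return named numeric vector c(R2m, R2c)
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "grazediv_lmm"))
  vf <- stats::var(fit$fitted_fixed)
  tot <- vf + fit$sigma2_site + fit$sigma2_resid
  c(R2m = vf / tot, R2c = (vf + fit$sigma2_site) / tot)
}

#' Wald t-test on one fixed-effect coefficient
#'
#' Uses the containment approximation for the denominator degrees of
#' freedom: df = n_obs - n_fixed - n_sites. This is an approximation
#' (not Satterthwaite or Kenward-Roger); the significance classes, not
#' exact p-values, are the intended output.
#'
#' @param fit a \code{grazediv_lmm}
#' @param term coefficient name, or a fixed-term label that maps to
#'   exactly one coefficient (e.g. "treatment" matches
#'   "treatmentungrazed")
#' @return list(estimate, se, statistic, df, p_value, significance)
#' @export
treatment_test <- function(fit, term = "treatment") {
  stopifnot(inherits(fit, "grazediv_lmm"))
  co <- fit$coefficients
  i <- which(co$term == term)
  if (length(i) == 0)
    i <- which(startsWith(co$term, term) & co$term != "(Intercept)")
  if (length(i) != 1)
    stop("term '", term, "' does not identify exactly one coefficient; ",
         "available: ", paste(co$term, collapse = ", "))
  df <- max(fit$n_obs - fit$p_fixed - fit$n_groups, 1)
  tstat <- co$estimate[i] / co$se[i]
  p <- 2 * stats::pt(-abs(tstat), df)
  list(estimate = co$estimate[i], se = co$se[i], statistic = tstat,
       df = df, p_value = p, significance = significance_class(p))
}
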