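# design with genuinely zero site variance: each site holds an identical
# copy of the same (x, y) block, so residual site means are exactly equal
zero_site_block <- function() {
  x <- c(-2, -1, 0, 1, 2, 3)
  y <- 0.5 + 0.8 * x + c(0.3, -0.2, 0.1, -0.4, 0.25, -0.05)
  data.frame(site_id = rep(paste0("s", 1:4), each = 6),
             x = rep(x, 4), y = rep(y, 4))
}

test_that("zero site variance reduces the fit to ordinary least squares", {
  d <- zero_site_block()
  fit <- fit_lmm(d, "y", "x", method = "ML")
  ols <- stats::lm(y ~ x, d)
  expect_equal(fit$lambda, 0)
  expect_equal(fit$sigma2_site, 0)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("REML matches closed-form ANOVA estimators on balanced one-way designs", {
  for (seed in c(1, 7, 19)) {
    set.seed(seed)
    g <- rep(paste0("g", 1:6), each = 5)
    y <- rep(rnorm(6, 0, 1.5), each = 5) + rnorm(30)
    oracle <- anova_vc_oracle(y, g)
    if (oracle["sigma2_site"] <= 0) next  # only interior solutions
    fit <- fit_lmm(data.frame(site_id = g, y = y), "y", "1",
                   method = "REML")
    expect_equal(fit$sigma2_site, unname(oracle["sigma2_site"]),
                 tolerance = 1e-6)
    expect_equal(fit$sigma2_resid, unname(oracle["sigma2_resid"]),
                 tolerance = 1e-6)
    # and the intercept is the grand mean in the balanced case
    expect_equal(fit$coefficients$estimate[1], mean(y), tolerance = 1e-8)
  }
})

test_that("fits agree with lme4 on coefficients, variances and likelihood", {
  skip_if_not_installed("lme4")
  set.seed(77)
  d <- data.frame(site_id = rep(paste0("s", 1:8), each = 6),
                  x = rnorm(48),
                  treatment = factor(rep(c("grazed", "ungrazed"), 24),
                                     levels = c("grazed", "ungrazed")))
  d$y <- 0.6 * d$x - 0.5 * (d$treatment == "ungrazed") +
    rep(rnorm(8, 0, 0.7), each = 6) + rnorm(48)
  for (meth in c("ML", "REML")) {
    fit <- fit_lmm(d, "y", c("treatment", "x"), method = meth)
    ref <- lme4::lmer(y ~ treatment + x + (1 | site_id), d,
                      REML = (meth == "REML"))
    expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(as.matrix(vcov(ref))))),
                 tolerance = 1e-5)
    expect_equal(fit$sigma2_site,
                 unname(unlist(lme4::VarCorr(ref))), tolerance = 1e-5)
    expect_equal(fit$sigma2_resid, unname(stats::sigma(ref)^2),
                 tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
  }
})

test_that("profile optimum dominates the boundaries and the fit is invariant", {
  set.seed(3)
  d <- data.frame(site_id = rep(paste0("s", 1:6), each = 4), x = rnorm(24))
  d$y <- 0.4 * d$x + rep(rnorm(6, 0, 1), each = 4) + rnorm(24)
  fit <- fit_lmm(d, "y", "x", method = "ML")
  # optimality sanity against far-off lambda values
  ll_at <- function(lam) {
    n_g <- as.numeric(table(d$site_id))
    # reuse the package fit at pinned lambda via a one-point profile:
    # compare against a direct GLS evaluation
    V <- diag(24) + lam * tcrossprod(stats::model.matrix(~ 0 + site_id, d))
    X <- cbind(1, d$x)
    b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, d$y))
    r <- d$y - X %*% b
    q <- as.numeric(t(r) %*% solve(V, r))
    -0.5 * (24 * log(2 * pi) + 24 * log(q / 24) +
              determinant(V)$modulus[1] + 24)
  }
  expect_gte(fit$loglik + 1e-6, ll_at(0))
  expect_gte(fit$loglik + 1e-6, ll_at(1e6))
  expect_equal(fit$loglik, ll_at(fit$lambda), tolerance = 1e-6)

  # relabeling sites and permuting rows changes nothing
  d2 <- d[sample(24), ]
  d2$site_id <- paste0("zz_", d2$site_id)
  fit2 <- fit_lmm(d2, "y", "x", method = "ML")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit2$sigma2_site, fit$sigma2_site, tolerance = 1e-6)
})

test_that("standardisation makes coefficients scale-invariant", {
  set.seed(11)
  d <- data.frame(site_id = rep(paste0("s", 1:6), each = 4),
                  x = rnorm(24, 50, 10))
  d$y <- 0.03 * d$x + rep(rnorm(6, 0, 0.5), each = 4) + rnorm(24)
  d1 <- standardize_columns(d, c("x", "y"))
  d2 <- d; d2$x <- d2$x * 1000 - 7
  d2 <- standardize_columns(d2, c("x", "y"))
  f1 <- fit_lmm(d1, "y", "x", method = "ML")
  f2 <- fit_lmm(d2, "y", "x", method = "ML")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("degenerate designs fail informatively", {
  d <- zero_site_block()
  d$x2 <- d$x * 2
  expect_error(fit_lmm(d, "y", c("x", "x2")), "aliased.*x2")
  d1 <- d[d$site_id == "s1", ]
  expect_error(fit_lmm(d1, "y", "x"), ">= 2 groups")
})

test_that("pseudo-R2 partitions variance as designed", {
  d <- zero_site_block()
  fit0 <- fit_lmm(d, "y", "1", method = "REML")
  expect_equal(unname(pseudo_r2(fit0)["R2m"]), 0)   # no fixed signal
  fit <- fit_lmm(d, "y", "x", method = "ML")        # sigma2_site = 0 here
  r2 <- pseudo_r2(fit)
  expect_equal(unname(r2["R2m"]), unname(r2["R2c"]))
  expect_true(all(r2 >= 0 & r2 <= 1) && r2["R2m"] <= r2["R2c"])

  # constructed variances sigma2_f = 1, sigma2_site = 1, sigma2 = 2
  # -> (0.25, 0.50); checked as a plug-in on a large simulated design
  md <- grazediv:::metadata_skeleton(
    synthetic_config(60, 10, group_specs = list(g = group_spec("g", 10)),
                     covariate_specs = list()))
  md$x <- rep(c(-1, 1), nrow(md) / 2)  # fixed predictor with variance 1
  md$y <- simulate_response(md, c(x = 1), sigma_site = 1,
                            sigma_resid = sqrt(2), seed = 4)
  fit2 <- fit_lmm(md, "y", "x", method = "REML")
  r22 <- pseudo_r2(fit2)
  expect_equal(unname(r22["R2m"]), 0.25, tolerance = 0.08)
  expect_equal(unname(r22["R2c"]), 0.50, tolerance = 0.08)
})

test_that("treatment test maps p-values to the conventional classes", {
  expect_equal(significance_class(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "n.s."))
  ds <- generate_dataset(one_group_config(41, pool = 60,
                                          richness_loss = 0.35,
                                          n_sites = 8))
  dat <- ds$metadata
  dat$y <- as.numeric(richness(ds$communities$g)[dat$plot_id])
  fit <- fit_lmm(dat, "y", "treatment", method = "REML")
  tt <- treatment_test(fit, "treatment")
  expect_equal(tt$df, fit$n_obs - fit$p_fixed - fit$n_groups)
  expect_lt(tt$p_value, 0.001)
  expect_equal(tt$significance, "***")
  expect_error(treatment_test(fit, "nonexistent"), "does not identify")
})

test_that("REML and ML converge on large designs", {
  md <- grazediv:::metadata_skeleton(
    synthetic_config(200, 2, group_specs = list(g = group_spec("g", 10)),
                     covariate_specs = list()))
  md$y <- simulate_response(md, c(treatment = -0.5), 0.5, 1, seed = 10)
  f1 <- fit_lmm(md, "y", "treatment", method = "ML")
  f2 <- fit_lmm(md, "y", "treatment", method = "REML")
  expect_lt(max(abs(f1$coefficients$estimate - f2$coefficients$estimate)),
            0.01)
})
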