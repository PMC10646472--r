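# Independent oracles and tiny fixture builders shared across tests.

# Brute-force Sorensen / presence-absence Bray-Curtis via set arithmetic:
# a = shared presences, b/c = presences unique to either plot.
sorensen_oracle <- function(v1, v2) {
  s1 <- which(v1 > 0)
  s2 <- which(v2 > 0)
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  cc <- length(setdiff(s2, s1))
  if (2 * a + b + cc == 0) return(0)
  (b + cc) / (2 * a + b + cc)
}

# closed-form REML variance components for a balanced one-way design
anova_vc_oracle <- function(y, g) {
  m <- unname(table(g))[1]
  means <- tapply(y, g, mean)
  MSB <- m * stats::var(means)
  MSW <- sum((y - stats::ave(y, g))^2) / (length(y) - length(means))
  c(sigma2_site = (MSB - MSW) / m, sigma2_resid = MSW)
}

# single-group synthetic world at the default paired-exclosure design
one_group_config <- function(seed, pool = 100, richness_loss = 0,
                             rarity_bias = 0, beta_effect = 0,
                             n_sites = 12, ppt = 4,
                             covariates = list()) {
  synthetic_config(
    n_sites = n_sites, plots_per_treatment = ppt,
    group_specs = list(g = group_spec("g", pool,
                                      richness_loss = richness_loss,
                                      rarity_bias = rarity_bias,
                                      beta_effect = beta_effect)),
    covariate_specs = covariates, seed = seed)
}

# a small fixed community matrix used by several I/O and diversity tests
tiny_matrix <- function() {
  m <- matrix(c(0, 3, 0, 1, 7,
                2, 0, 1, 0, 0,
                5, 5, 5, 5, 5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"),
                              paste0("t", 1:5)))
  m
}

# minimal stand-in for a fitted model, for exercising ranking/averaging
# arithmetic without a data fit (aicc needs loglik/k/n; averaging needs
# the coefficient table and the pseudo-R2 ingredients)
fake_fit <- function(terms, est, se, loglik, k = 3, n = 100) {
  structure(list(coefficients = data.frame(term = terms, estimate = est,
                                           se = se,
                                           stringsAsFactors = FALSE),
                 loglik = loglik, k_params = k, n_obs = n,
                 fixed_terms = setdiff(terms, "(Intercept)"),
                 fitted_fixed = c(0, 1), sigma2_site = 0,
                 sigma2_resid = 1, converged = TRUE),
            class = "grazediv_lmm")
}
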