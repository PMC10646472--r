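test_that("submodel enumeration respects marginality and the term cap", {
  cs <- enumerate_submodels(c("T", "x"), "T:x")
  expect_equal(cs$ids, c("1", "T", "x", "T + x", "T + x + T:x"))
  # no model carries the interaction without both parents
  for (m in cs$models)
    if ("T:x" %in% m) expect_true(all(c("T", "x") %in% m))

  cs1 <- enumerate_submodels(c("T", "x"), max_terms = 1)
  expect_setequal(cs1$ids, c("1", "T", "x"))

  # counts: 2 mains + both interactions -> 3^2 states with T... spelled
  # out: every subset of {T,a,b} crossed with admissible interactions
  cs2 <- enumerate_submodels(c("T", "a", "b"), c("T:a", "T:b"))
  expect_equal(length(cs2$models), 8 + 2 + 2 + 1)  # 13 distinct models
  expect_false(anyDuplicated(cs2$ids) > 0)

  expect_error(enumerate_submodels(c("T", "x"), "T:z"), "parents")
  expect_error(enumerate_submodels(letters[1:12], cap = 100), "cap")
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(list(loglik = -10, k_params = 3, n_obs = 20)), 27.5)
  # n -> infinity recovers plain AIC
  expect_equal(aicc(list(loglik = -10, k_params = 3, n_obs = 1e9)),
               26, tolerance = 1e-6)
  # the penalty is monotone in k at fixed likelihood
  a3 <- aicc(list(loglik = -10, k_params = 3, n_obs = 100))
  a4 <- aicc(list(loglik = -10, k_params = 4, n_obs = 100))
  expect_gt(a4, a3)
  # undefined when the correction denominator vanishes
  expect_true(is.na(aicc(list(loglik = -1, k_params = 10, n_obs = 11))))
})

test_that("Akaike weights follow exp(-delta/2) with stable ties", {
  # delta = [0, 2]: weights [1/(1+e^-1), e^-1/(1+e^-1)]
  # build fits whose AICc differ by exactly 2 (same k, n; ll differs by 1)
  fits <- list(A = fake_fit("(Intercept)", 0, 1, loglik = -10),
               B = fake_fit("(Intercept)", 0, 1, loglik = -11))
  rk <- rank_and_weight(fits)
  expect_equal(rk$delta, c(0, 2))
  expect_equal(rk$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-6)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)

  # exact tie: equal weights, stable order by model id
  tie <- list(zz = fake_fit("(Intercept)", 0, 1, -10),
              aa = fake_fit("(Intercept)", 0, 1, -10))
  rkt <- rank_and_weight(tie)
  expect_equal(rkt$weight, c(0.5, 0.5))
  expect_equal(rkt$model, c("aa", "zz"))

  expect_equal(rank_and_weight(fits[1])$weight, 1)

  # invariant to a constant shift of all log-likelihoods
  sh <- lapply(fits, function(f) { f$loglik <- f$loglik + 123; f })
  expect_equal(rank_and_weight(sh)$weight, rk$weight)
})

test_that("model averaging follows the conditional (natural) definition", {
  f1 <- fake_fit(c("(Intercept)", "x"), c(0.1, 1.0), c(0.5, 0.2), -10)
  f2 <- fake_fit(c("(Intercept)", "x"), c(0.2, 2.0), c(0.5, 0.2), -10)
  f3 <- fake_fit("(Intercept)", 0.3, 0.5, -10)
  # two equal-weight models sharing a term: estimates 1 and 2 average 1.5
  rk <- rank_and_weight(list(m1 = f1, m2 = f2))
  avg <- average_models(rk, list(m1 = f1, m2 = f2))
  xrow <- avg$terms[avg$terms$term == "x", ]
  expect_equal(xrow$estimate, 1.5)
  expect_equal(xrow$cumulative_weight, 1)
  expect_equal(xrow$n_models, 2L)
  # unconditional se: sqrt(sum w (se^2 + (b - bbar)^2))
  expect_equal(xrow$se, sqrt(0.2^2 + 0.25))

  # term present in one of two equal-weight models: conditional average
  # keeps its own estimate, cumulative weight 0.5, count 1
  rk2 <- rank_and_weight(list(m1 = f2, m0 = f3))
  avg2 <- average_models(rk2, list(m1 = f2, m0 = f3))
  xr2 <- avg2$terms[avg2$terms$term == "x", ]
  expect_equal(xr2$estimate, 2.0)
  expect_equal(xr2$cumulative_weight, 0.5)
  expect_equal(xr2$n_models, 1L)
  # full-average mode substitutes zero instead
  avg2f <- average_models(rk2, list(m1 = f2, m0 = f3), mode = "full")
  expect_equal(avg2f$terms$estimate[avg2f$terms$term == "x"], 1.0)

  # a single retained model returns its own coefficients
  rk1 <- rank_and_weight(list(only = f1))
  avg1 <- average_models(rk1, list(only = f1))
  expect_equal(avg1$terms$estimate, f1$coefficients$estimate)
  expect_equal(avg1$n_models, 1L)

  # renormalised retained weights sum to 1
  expect_equal(sum(avg$retained$weight), 1, tolerance = 1e-12)
})

test_that("the delta window controls retention", {
  f_good <- fake_fit("(Intercept)", 0, 1, loglik = -10)
  f_bad <- fake_fit("(Intercept)", 0, 1, loglik = -13)  # delta = 6
  rk <- rank_and_weight(list(g = f_good, b = f_bad))
  avg <- average_models(rk, list(g = f_good, b = f_bad),
                        delta_threshold = 4)
  expect_equal(avg$n_models, 1L)
  avg8 <- average_models(rk, list(g = f_good, b = f_bad),
                         delta_threshold = 8)
  expect_equal(avg8$n_models, 2L)
})

test_that("driver analysis recovers a strong single driver end to end", {
  cfg <- synthetic_config(12, 4,
                          group_specs = list(g = group_spec("g", 10)),
                          seed = 55)
  md <- generate_dataset(cfg)$metadata
  md$y <- simulate_response(md, c(treatment = -0.3, pH = 0.8),
                            sigma_site = 0.4, sigma_resid = 1, seed = 8)
  res <- driver_analysis(md, "y", c("pH", "soil_carbon", "moisture"),
                         interactions = FALSE)
  expect_equal(res$n_candidates, 2^4)
  tt <- res$averaged$terms
  cw <- function(tm) {
    j <- match(tm, tt$term)
    if (is.na(j)) 0 else tt$cumulative_weight[j]
  }
  expect_gt(cw("pH"), cw("soil_carbon"))
  expect_gt(cw("pH"), cw("moisture"))
  expect_true(all(res$averaged$r2m_range <= res$averaged$r2c_range))
})

test_that("shuffling the response destroys driver recovery", {
  cfg <- synthetic_config(12, 4,
                          group_specs = list(g = group_spec("g", 10)),
                          seed = 59)
  md <- generate_dataset(cfg)$metadata
  covs <- c("pH", "soil_carbon", "moisture", "bulk_density")
  hits <- 0
  set.seed(60)
  for (i in 1:20) {
    md$y <- simulate_response(md, c(pH = 0.8), 0.4, 1, seed = 100 + i)
    md$y <- md$y[sample(nrow(md))]  # break the coupling
    res <- driver_analysis(md, "y", covs, interactions = FALSE)
    tt <- res$averaged$terms
    cwv <- tt$cumulative_weight[match(covs, tt$term)]
    cwv[is.na(cwv)] <- 0
    hits <- hits + sum(cwv > 0.9)
  }
  expect_lt(hits / 20, 0.5)  # high-confidence hits are rare under the null
})
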