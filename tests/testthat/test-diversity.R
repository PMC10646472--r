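test_that("richness counts taxa strictly above the presence threshold", {
  m <- matrix(c(0, 3, 0, 1, 7), nrow = 1,
              dimnames = list("p1", paste0("t", 1:5)))
  expect_equal(unname(richness(m, 0)), 3L)
  expect_equal(unname(richness(m, 2)), 2L)
  expect_equal(unname(richness(m * 0, 0)), 0L)
  # monotone non-increasing in the threshold
  ds <- generate_dataset(one_group_config(23, pool = 50, n_sites = 3,
                                          ppt = 2))
  r <- vapply(c(0, 0.5, 1, 2, 5),
              function(th) sum(richness(ds$communities$g, th)), 0)
  expect_true(all(diff(r) <= 0))
})

test_that("response-ratio formulas match direct evaluation", {
  expect_equal(alpha_response_ratio(5.8, 8.0), (5.8 - 8.0) / 5.8)
  expect_equal(alpha_response_ratio(4, 4), 0)
  expect_equal(alpha_response_ratio(4, 0), 1.0)
  expect_equal(alpha_response_ratio(0, 0), 0)        # convention
  expect_true(is.na(alpha_response_ratio(0, 3)))     # undefined ratio

  expect_equal(beta_response_ratio(0.5, 0.4), 0.2)
  expect_equal(beta_response_ratio(0.4, 0.5), -0.25)
  expect_equal(beta_response_ratio(0.3, 0.3), 0)
  expect_true(is.na(beta_response_ratio(0, 0.2)))
})

test_that("presence-absence Bray-Curtis equals the set-overlap oracle", {
  # {A,B,C} vs {B,C,D}: a = 2, b = c = 1 -> 1/3
  m <- rbind(p1 = c(1, 1, 1, 0), p2 = c(0, 1, 1, 1))
  colnames(m) <- LETTERS[1:4]
  expect_equal(as.numeric(pairwise_dissimilarity(m)), 1 / 3)
  # identity and disjoint extremes
  m2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 5))
  d2 <- as.matrix(pairwise_dissimilarity(m2))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # abundance does not matter on the presence scale
  m3 <- m; m3[m3 > 0] <- runif(sum(m3 > 0), 1, 9)
  expect_equal(as.numeric(pairwise_dissimilarity(m3)), 1 / 3)
  # all-absent pair defined as 0, with a warning
  m4 <- rbind(x = c(0, 0), y = c(0, 0))
  expect_warning(d4 <- pairwise_dissimilarity(m4), "all-absent")
  expect_equal(as.numeric(d4), 0)
  expect_error(pairwise_dissimilarity(m[1, , drop = FALSE]), ">= 2 plots")
})

test_that("dissimilarity axioms hold and random matrices agree with the oracle", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rbinom(8 * 12, 1, 0.4) * rexp(8 * 12), nrow = 8,
                dimnames = list(paste0("p", 1:8), paste0("t", 1:12)))
    d <- suppressWarnings(as.matrix(pairwise_dissimilarity(m)))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 8))
    for (i in 1:7) for (j in (i + 1):8)
      expect_equal(d[i, j], sorensen_oracle(m[i, ], m[j, ]))
  }
})

test_that("within-site mean dissimilarity averages all C(n,2) pairs", {
  ds <- generate_dataset(one_group_config(29, pool = 40, n_sites = 3,
                                          ppt = 4))
  res <- within_site_mean_dissimilarity(ds$communities$g, ds$metadata,
                                        "S02", "grazed")
  expect_equal(res$n_pairs, choose(4, 2))
  plots <- ds$metadata$plot_id[ds$metadata$site_id == "S02" &
                                 ds$metadata$treatment == "grazed"]
  expect_equal(res$mean_dissimilarity,
               mean(pairwise_dissimilarity(ds$communities$g, plots)))
  # two identical plots -> 0
  m <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  md <- data.frame(plot_id = c("a", "b"), site_id = "s",
                   treatment = factor(c("grazed", "grazed"),
                                      levels = c("grazed", "ungrazed")))
  expect_equal(within_site_mean_dissimilarity(m, md, "s", "grazed")$
                 mean_dissimilarity, 0)
  expect_error(within_site_mean_dissimilarity(m, md, "s", "ungrazed"),
               "< 2")
})

test_that("occupancy cohorts partition taxa with common-inclusive boundaries", {
  # 98 plots: 24/98 is strictly below a quarter -> rare
  n <- 98
  m <- cbind(rare = c(rep(1, 24), rep(0, n - 24)),
             edge = c(rep(1, 25), rep(0, n - 25)),
             mid = c(rep(1, 49), rep(0, n - 49)),
             wide = rep(1, n),
             gone = rep(0, n))
  rownames(m) <- paste0("p", 1:n)
  asg <- classify_occupancy_cohorts(m)
  expect_equal(as.character(asg$cohort[match(
    c("rare", "mid", "wide"), asg$taxon_id)]),
    c("rare", "common", "widespread"))
  # 25/98 > 0.25 so "edge" is common only because it is not < 0.25... at
  # exactly the bound: construct occupancy exactly 0.25 and 0.75 on 4 plots
  m2 <- cbind(q1 = c(1, 0, 0, 0), q3 = c(1, 1, 1, 0))
  rownames(m2) <- paste0("p", 1:4)
  asg2 <- classify_occupancy_cohorts(m2)
  expect_equal(as.character(asg2$cohort), c("common", "common"))
  # absent taxa are dropped, the rest partition
  expect_false("gone" %in% asg$taxon_id)
  expect_equal(attr(asg, "n_dropped"), 1L)
  expect_equal(nrow(asg), 4)
})

test_that("statistics are invariant to taxon relabeling and plot order", {
  ds <- generate_dataset(one_group_config(31, pool = 60, n_sites = 4,
                                          ppt = 3, richness_loss = 0.2))
  mat <- ds$communities$g
  md <- ds$metadata
  rr1 <- response_ratio_table(list(g = mat), md, method = "ratio_t")
  perm_r <- sample(nrow(mat)); perm_c <- sample(ncol(mat))
  mat2 <- mat[perm_r, perm_c]
  rr2 <- response_ratio_table(list(g = mat2), md[rev(seq_len(nrow(md))), ],
                              method = "ratio_t")
  expect_equal(rr1$pooled$estimate, rr2$pooled$estimate, tolerance = 1e-12)
  expect_equal(rr1$per_site$delta_alpha, rr2$per_site$delta_alpha)
})

test_that("cohort response ratios mark empty cohorts absent, not zero", {
  # no taxon above 75 percent occupancy -> widespread cohort absent
  set.seed(8)
  m <- matrix(rbinom(12 * 20, 1, 0.3), nrow = 12,
              dimnames = list(sprintf("S%02d_%s%d", rep(1:3, each = 4),
                                      rep(c("G", "G", "U", "U"), 3),
                                      rep(1:2, 6)),
                              paste0("t", 1:20)))
  md <- data.frame(plot_id = rownames(m),
                   site_id = substr(rownames(m), 1, 3),
                   treatment = factor(ifelse(grepl("_U", rownames(m)),
                                             "ungrazed", "grazed"),
                                      levels = c("grazed", "ungrazed")))
  stopifnot(max(colMeans(m > 0)) <= 0.75)
  tab <- cohort_response_ratios(m, md, method = "ratio_t")
  expect_false(tab$present[tab$cohort == "widespread"])
  expect_true(is.na(tab$estimate[tab$cohort == "widespread"]))
  expect_true(all(tab$present[tab$cohort %in% c("rare", "common")]))
})

test_that("rarity-biased loss hits the rare cohort hardest (scaled check)", {
  # full 100-replicate version runs in the acceptance suite
  res <- vapply(1:20, function(i) {
    ds <- generate_dataset(one_group_config(700 + i, pool = 150,
                                            richness_loss = 0.3,
                                            rarity_bias = 3, n_sites = 8))
    tab <- cohort_response_ratios(ds$communities$g, ds$metadata,
                                  method = "ratio_t")
    c(rare = tab$estimate[tab$cohort == "rare"],
      common = tab$estimate[tab$cohort == "common"])
  }, c(0, 0))
  expect_lt(mean(res[1, ]), mean(res[2, ]))
})
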