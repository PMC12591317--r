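test_that("normality gate calibrates under Gaussian data and detects skew", {
  set.seed(101)
  n_trials <- 200
  null_pass <- 0
  exp_fail <- 0
  for (i in seq_len(n_trials)) {
    vals <- lapply(setNames(nm = phosdiff_groups()),
                   function(g) rnorm(30))
    if (gate_tests(vals)$normal_all) null_pass <- null_pass + 1
    vals$EGFR <- rexp(30)
    if (!gate_tests(vals)$normal_all) exp_fail <- exp_fail + 1
  }
  # per-group false rejection 5% -> all four pass ~0.95^4 = 81%; demand >= 70%
  expect_gte(null_pass / n_trials, 0.70)
  expect_gte(exp_fail / n_trials, 0.95)
})

test_that("variance gate detects strong heteroscedasticity", {
  set.seed(102)
  hits <- 0
  for (i in seq_len(200)) {
    vals <- list(a = rnorm(30, sd = 1), b = rnorm(30, sd = 5))
    if (!gate_tests(vals)$equal_var) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("small or constant groups are routed away from parametric tests", {
  vals <- list(EML4_ALK = c(1, 2), EGFR = rnorm(10), KRAS = rnorm(10),
               WT = rnorm(10))
  g <- gate_tests(vals)
  expect_false(g$normal_all)          # n = 2 cannot establish normality
  expect_equal(omnibus_test(vals, g)$test, "Kruskal_Wallis")

  vals$EML4_ALK <- c(5, 5, 5, 5)      # constant group
  g2 <- gate_tests(vals)
  expect_false(g2$normal_all)
})

test_that("the omnibus cascade picks the gated test and separates big effects", {
  set.seed(103)
  # null: p-values uniform under ANOVA branch
  ps <- replicate(500, {
    vals <- lapply(setNames(nm = phosdiff_groups()), function(g) rnorm(10))
    omnibus_test(vals, list(normal_all = TRUE, equal_var = TRUE))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # one group shifted by 5 SD
  vals <- lapply(setNames(nm = phosdiff_groups()), function(g) rnorm(6))
  vals$KRAS <- vals$KRAS + 5
  g <- gate_tests(vals)
  expect_lt(omnibus_test(vals, g)$p, 0.001)

  # non-normal gate forces Kruskal-Wallis whatever the variance gate says
  expect_equal(
    omnibus_test(vals, list(normal_all = FALSE, equal_var = TRUE))$test,
    "Kruskal_Wallis"
  )
  expect_equal(
    omnibus_test(vals, list(normal_all = TRUE, equal_var = FALSE))$test,
    "Welch_ANOVA"
  )
})

test_that("pairwise tests follow the sign convention and exactness rules", {
  vals <- list(
    EML4_ALK = c(1, 2, 3), EGFR = c(1, 2, 3),
    KRAS = c(9, 10, 11), WT = c(7.9, 8, 8.1)
  )
  g <- gate_tests(vals)
  pw <- pairwise_tests(vals, g)
  row_ae <- pw[pw$comparison == "EML4_ALK_vs_EGFR", ]
  expect_equal(row_ae$log2fc, 0)
  expect_equal(row_ae$raw_p, 1)

  # mean log2 10 vs 8 -> log2fc +2, i.e. 4-fold
  row_kw <- pw[pw$comparison == "KRAS_vs_WT", ]
  expect_equal(row_kw$log2fc, 2)

  # Wilcoxon exact two-sided p for {1,2,3} vs {4,5,6}: enumerate all
  # C(6,3) = 20 assignments of ranks to the first group
  combos <- combn(6, 3)
  w_obs <- sum(1:3)
  w_all <- apply(combos, 2, sum)
  p_enum <- 2 * mean(w_all <= w_obs)
  expect_equal(p_enum, 0.1)
  expect_equal(phosdiff:::wilcoxon_p(c(1, 2, 3), c(4, 5, 6)), p_enum)
})

test_that("reversing a comparison negates the fold-change, p unchanged", {
  set.seed(104)
  vals <- lapply(setNames(nm = phosdiff_groups()), function(g) rnorm(8, 20))
  g <- gate_tests(vals)
  spec <- comparison_spec()
  rev_spec <- spec
  rev_spec$group_a <- spec$group_b
  rev_spec$group_b <- spec$group_a
  pw <- pairwise_tests(vals, g, spec)
  pw_rev <- pairwise_tests(vals, g, rev_spec)
  expect_equal(pw_rev$log2fc, -pw$log2fc, tolerance = 1e-12)
  expect_equal(pw_rev$raw_p, pw$raw_p, tolerance = 1e-12)
})

test_that("BH agrees with a brute-force step-up to 1e-12", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)),
               rep(0.06, 6), tolerance = 1e-12)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(105)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(1:6, 1))
    worst <- max(worst, max(abs(bh_adjust(p) - bh_brute(p))))
    expect_true(all(bh_adjust(p) >= p - 1e-15 & bh_adjust(p) <= 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("full analysis flags spiked features and handles degenerate rows", {
  cfg <- synth_config(n_features = 150, dropout_slope = 0,
                      spike_design = make_spike_design(8, effect_log2 = 2),
                      seed = 7)
  sim <- simulate_cohort(cfg)
  m <- log2_transform(sim$matrix)
  # inject a constant feature
  v <- unclass(m)
  v["PROT0150", ] <- 21
  m <- intensity_matrix(v, scale = "log2")
  st <- analyze_features(m, sim$meta)

  expect_s3_class(st, "phosdiff_stats")
  expect_equal(nrow(st), 150 * 6)
  # fdr >= raw p wherever both are defined
  ok <- !is.na(st$raw_p)
  expect_true(all(st$fdr[ok] >= st$raw_p[ok] - 1e-15))
  # gated-out features carry no pairwise results and no significance
  gated <- st$omnibus_p >= 0.05
  expect_true(all(st$pairwise_test[gated] == "none"))
  expect_true(all(!st$significant[gated]))
  # constant feature: clean non-significant rows
  cst <- st[st$feature_id == "PROT0150", ]
  expect_true(all(!cst$significant))

  # each spiked feature significant in all three comparisons of its group
  spec <- comparison_spec()
  spiked <- sim$truth[sim$truth$spiked, ]
  hits <- vapply(seq_len(nrow(spiked)), function(i) {
    gcmp <- spec$comparison[spec$group_a == spiked$target[i] |
                              spec$group_b == spiked$target[i]]
    rows <- st[st$feature_id == spiked$feature_id[i] &
                 st$comparison %in% gcmp, ]
    all(rows$significant)
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)

  # determinism: no RNG in this module
  st2 <- analyze_features(m, sim$meta)
  expect_identical(as.data.frame(st), as.data.frame(st2))
})

test_that("null data keep the significant-call rate near nominal", {
  rates <- vapply(1:5, function(seed) {
    cfg <- synth_config(n_features = 200, dropout_slope = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    st <- analyze_features(log2_transform(sim$matrix), sim$meta)
    any_sig <- tapply(st$significant, st$feature_id, any)
    mean(any_sig)
  }, numeric(1))
  expect_lte(mean(rates), 2 * 0.05)
})
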