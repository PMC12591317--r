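test_that("significance matrix applies both thresholds strictly", {
  fdr <- list(
    edge = c(0.049, 0.05, 0.3, 0.3, 0.3, 0.3),
    zero = rep(0.5, 6)
  )
  fc <- list(
    edge = c(1.01, 2, 0.5, -0.5, 0.2, -0.2),
    zero = rep(0, 6)
  )
  sig <- significance_matrix(stats_from_vectors(fdr, fc))
  expect_equal(unname(sig["edge", ]), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(sig["zero", ]), rep(0L, 6))

  # |log2fc| exactly 1 (fold-change exactly 2) is not "over 2"
  fdr2 <- list(x = c(0.01, 0.01, 0.3, 0.3, 0.3, 0.3))
  fc2 <- list(x = c(1, -1.5, 0, 0, 0, 0))
  sig2 <- significance_matrix(stats_from_vectors(fdr2, fc2))
  expect_equal(unname(sig2["x", ]), c(0L, -1L, 0L, 0L, 0L, 0L))
})

test_that("classifier agrees with brute force on all 729 sign patterns", {
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 6)))
  colnames(grid) <- comparison_spec()$comparison
  rownames(grid) <- paste0("pat", seq_len(nrow(grid)))
  calls <- classify_specific(grid)

  fmt <- function(rows) {
    if (all(rows$type %in% c("group", "partition"))) {
      sort(paste0(rows$label, ":", rows$direction))
    } else rows$type[1]
  }
  got <- lapply(split(calls, calls$feature_id)[rownames(grid)], fmt)
  want <- lapply(seq_len(nrow(grid)), function(i) classify_brute(grid[i, ]))
  agree <- vapply(seq_len(nrow(grid)), function(i) {
    identical(unname(got[[i]]), unname(want[[i]]))
  }, logical(1))
  expect_true(all(agree))

  # no pattern can make one feature specific-UP for two different groups
  both_up <- vapply(got, function(g) {
    is.character(g) && sum(grepl("^(EML4_ALK|EGFR|KRAS|WT):UP$", g)) > 1
  }, logical(1))
  expect_false(any(both_up))
})

test_that("canonical multi-group patterns are recognised", {
  spec <- comparison_spec()
  # higher in EML4_ALK and KRAS than in EGFR and WT, within-pair null
  s_part <- integer(6)
  for (j in 1:6) {
    a_in <- spec$group_a[j] %in% c("EML4_ALK", "KRAS")
    b_in <- spec$group_b[j] %in% c("EML4_ALK", "KRAS")
    if (a_in && !b_in) s_part[j] <- 1L
    if (!a_in && b_in) s_part[j] <- -1L
  }
  # one group above the middle pair which is above a fourth group:
  # EML4_ALK > {EGFR, KRAS} > WT with the EGFR-KRAS comparison null
  s_double <- c(1L, 1L, 1L, 0L, 1L, 1L)

  m <- rbind(scamp2_like = s_part, lmnb2_like = s_double,
             silent = integer(6))
  colnames(m) <- spec$comparison
  calls <- classify_specific(m)

  part <- calls[calls$feature_id == "scamp2_like", ]
  expect_equal(part$type, "partition")
  expect_equal(part$label, "EML4_ALK+KRAS|EGFR+WT")
  expect_equal(part$direction, "UP")

  dbl <- calls[calls$feature_id == "lmnb2_like", ]
  expect_setequal(paste0(dbl$label, ":", dbl$direction),
                  c("EML4_ALK:UP", "WT:DOWN"))

  expect_equal(calls$type[calls$feature_id == "silent"], "none")
})

test_that("classification is invariant to comparison storage order", {
  set.seed(106)
  spec <- comparison_spec()
  grid <- matrix(sample(c(-1L, 0L, 1L), 50 * 6, replace = TRUE), 50, 6,
                 dimnames = list(paste0("f", 1:50), spec$comparison))
  base <- classify_specific(grid, spec)
  perm <- sample(6)
  calls_perm <- classify_specific(grid[, perm], spec[perm, ])
  key <- function(x) x[order(x$feature_id, x$label), ]
  expect_equal(key(as.data.frame(base)), key(as.data.frame(calls_perm)),
               ignore_attr = TRUE)
})

test_that("summary counting handles double labels and the union", {
  calls <- tibble::tibble(
    feature_id = c("f1", "f2", "f2", "f3"),
    label = c("EML4_ALK", "EML4_ALK", "WT", NA),
    type = c("group", "group", "group", "none"),
    direction = c("UP", "UP", "DOWN", NA)
  )
  s <- summarize_specificity(calls)
  expect_equal(s$n[s$label == "EML4_ALK"], 2)
  expect_equal(s$n[s$label == "WT"], 1)
  expect_equal(s$n[s$type == "union"], 2)

  empty <- summarize_specificity(calls[0, ])
  expect_true(all(empty$n == 0))
})

test_that("end-to-end spike recovery attributes features to their groups", {
  cfg <- synth_config(n_features = 400, dropout_slope = 0,
                      spike_design = tibble::tibble(
                        feature = 1:10, target = "EML4_ALK",
                        effect_log2 = rep(c(2, -2), 5)
                      ),
                      seed = 21)
  sim <- simulate_cohort(cfg)
  st <- analyze_features(log2_transform(sim$matrix), sim$meta)
  calls <- classify_specific(significance_matrix(st))
  s <- summarize_specificity(calls)
  expect_gte(s$n[s$label == "EML4_ALK"], 9)
})

test_that("site fold-changes are compared to parent-protein fold-changes", {
  spec <- comparison_spec()
  site_stats <- tibble::tibble(
    feature_id = c("KRR1;S3", "ORPH;S9", "FLAT;S1"),
    comparison = spec$comparison[4],
    log2fc = c(1.0, 1.2, 1.1),
    fdr = 0.01, significant = TRUE
  )
  protein_stats <- tibble::tibble(
    feature_id = c("KRR1", "FLAT"),
    comparison = spec$comparison[4],
    log2fc = c(log2(1.7), 0)
  )
  map <- tibble::tibble(site_id = c("KRR1;S3", "ORPH;S9", "FLAT;S1"),
                        protein_id = c("KRR1", "ORPH", "FLAT"))
  out <- phospho_vs_protein(site_stats, protein_stats, map)
  # 2.0-fold site with 1.7-fold protein: protein-driven candidate
  expect_true(out$protein_driven[out$site_id == "KRR1;S3"])
  # no parent protein quantified: undefined, never flagged
  expect_true(is.na(out$protein_log2fc[out$site_id == "ORPH;S9"]))
  expect_false(out$protein_driven[out$site_id == "ORPH;S9"])
  # flat protein: not flagged
  expect_false(out$protein_driven[out$site_id == "FLAT;S1"])
})
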