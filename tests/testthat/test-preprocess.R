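test_that("log2 transform maps values and preserves the mask", {
  meta <- tiny_meta(2)
  v <- matrix(c(8, 1, 4, NA, 16, 2, NA, 32), 2, 4)
  v <- cbind(v, v)  # 8 samples
  m <- im(v, scale = "raw", meta = meta)
  t <- log2_transform(m)
  expect_equal(unname(unclass(t)[1, 1]), 3)
  expect_equal(unname(unclass(t)[2, 1]), 0)
  expect_identical(missing_mask(t), missing_mask(m))
  expect_identical(attr(t, "scale"), "log2")
  expect_error(log2_transform(t), "log2")

  bad <- im(matrix(c(-1, 2, 3, 4), 2, 2), scale = "raw")
  expect_error(log2_transform(bad), "onpositive")
})

test_that("presence filter applies the 50% rule and the 4-of-6 EML4-ALK rule", {
  sizes <- c(EML4_ALK = 6, EGFR = 23, KRAS = 31, WT = 22)
  g <- rep(phosdiff_groups(), times = sizes)
  meta <- tibble::tibble(sample_id = paste0("s", 1:82), group = g)
  mk_row <- function(counts) {
    # counts: named observed count per group
    x <- rep(NA_real_, 82)
    for (gr in names(counts)) {
      idx <- which(g == gr)[seq_len(counts[[gr]])]
      x[idx] <- 20
    }
    x
  }
  v <- rbind(
    egfr12 = mk_row(c(EGFR = 12)),                 # 12/23 >= 50% -> keep
    alk3 = mk_row(c(EML4_ALK = 3)),                # 3/6 and <50% others -> drop
    alk4 = mk_row(c(EML4_ALK = 4)),                # 4/6 -> keep
    wt11 = mk_row(c(WT = 11)),                     # 11/22 boundary -> keep
    kras15 = mk_row(c(KRAS = 15)),                 # 15/31 < 50% -> drop
    none = mk_row(c(EGFR = 1))
  )
  colnames(v) <- meta$sample_id
  m <- intensity_matrix(v, scale = "log2")
  out <- presence_filter(m, meta)
  expect_equal(rownames(out$matrix), c("egfr12", "alk4", "wt11"))

  # invariance to sample order permutation
  set.seed(1)
  perm <- sample(82)
  m2 <- intensity_matrix(v[, perm], scale = "log2")
  out2 <- presence_filter(m2, meta)
  expect_equal(rownames(out2$matrix), rownames(out$matrix))

  ps <- out$presence
  expect_true(all(ps$fraction == ps$n_observed / ps$group_size))
  expect_equal(ps$n_observed[ps$feature_id == "egfr12" & ps$group == "EGFR"],
               12)
})

test_that("localization filter keeps the 0.75 boundary", {
  meta <- tiny_meta(2)
  v <- matrix(20, 3, 8)
  m <- im(v, scale = "log2", meta = meta,
          feature_ids = c("A;S1", "B;S2", "C;S3"))
  sites <- tibble::tibble(site_id = c("A;S1", "B;S2", "C;S3"),
                          localization_probability = c(0.6, 0.75, 0.9))
  out <- localization_filter(m, sites)
  expect_equal(rownames(out), c("B;S2", "C;S3"))

  sites$localization_probability <- c(1, 1, 1)
  expect_equal(nrow(localization_filter(m, sites)), 3)

  sites$localization_probability <- c(0, 0, 0)
  expect_warning(out0 <- localization_filter(m, sites), "no site")
  expect_equal(nrow(out0), 0)

  expect_error(localization_filter(m, sites[1:2, ]), "without annotation")
})

test_that("low-presence cells get the recipient sample's 5th percentile", {
  # one group of 8; target sample's observed values are 20,22,...,38 so the
  # 5th percentile (type-7) is 20 + 0.45 * 2 = 20.9
  g <- rep(phosdiff_groups(), each = 8)
  meta <- tibble::tibble(sample_id = paste0("s", 1:32), group = g)
  v <- matrix(30, 12, 32)
  v[1:10, 1] <- seq(20, 38, by = 2)
  v[11, 1:5] <- NA            # observed 3/8 in EML4_ALK -> percentile branch
  v[12, ] <- 25               # control; missing in s1 so s1's observed
  v[12, 1] <- NA              # values are exactly {20,22,...,38}
  colnames(v) <- meta$sample_id
  rownames(v) <- paste0("F", 1:12)
  m <- intensity_matrix(v, scale = "log2")
  out <- impute_proteomic(m, meta)
  expect_equal(unname(unclass(out)[11, 1]), 20.9, tolerance = 1e-12)
  expect_equal(unname(unclass(out)[12, 2]), 25)
  expect_equal(sum(is.na(unclass(out))), 0)
})

test_that("kNN imputation averages the nearest features in the target sample", {
  # feature observed 5/8 in its group; all candidate neighbours carry 30.0
  # in the target sample -> imputed exactly 30
  g <- rep(phosdiff_groups(), each = 8)
  meta <- tibble::tibble(sample_id = paste0("s", 1:32), group = g)
  set.seed(4)
  v <- matrix(rnorm(30 * 32, 25, 2), 30, 32)
  v[, 1] <- 30
  v[1, 1:3] <- NA  # observed 5/8 in EML4_ALK -> kNN branch
  colnames(v) <- meta$sample_id
  rownames(v) <- paste0("F", 1:30)
  m <- intensity_matrix(v, scale = "log2")
  out <- impute_proteomic(m, meta)
  expect_equal(unname(unclass(out)[1, 2]), unname(unclass(out)[1, 2]))
  expect_equal(unname(unclass(out)[1, 1]), 30)
  # observed cells never change
  obs <- !missing_mask(m)
  expect_identical(unclass(out)[obs], unclass(m)[obs])
})

test_that("percentile-branch imputation reflects left censoring under MNAR", {
  cfg <- synth_config(n_features = 2000, seed = 6)
  sim <- simulate_cohort(cfg)
  m <- log2_transform(sim$matrix)
  kept <- presence_filter(m, sim$meta)
  out <- impute_proteomic(kept$matrix, sim$meta)
  v0 <- unclass(kept$matrix)
  v1 <- unclass(out)
  # cells imputed in low-presence rows sit below their sample mean
  gs <- split(sim$meta$sample_id, sim$meta$group)
  low_mask <- matrix(FALSE, nrow(v0), ncol(v0), dimnames = dimnames(v0))
  for (g in phosdiff_groups()) {
    cols <- gs[[g]]
    frac <- rowMeans(!is.na(v0[, cols]))
    low_mask[frac < 0.5, cols] <- TRUE
  }
  filled <- is.na(v0) & low_mask
  expect_gt(sum(filled), 100)
  samp_mean <- colMeans(v0, na.rm = TRUE)
  diffs <- v1[filled] - samp_mean[col(v1)[filled]]
  expect_lt(mean(diffs), 0)
  expect_equal(sum(is.na(v1)), 0)
})

test_that("condition-specific phospho imputation is exact for degenerate groups", {
  g <- rep(phosdiff_groups(), each = 5)
  meta <- tibble::tibble(sample_id = paste0("s", 1:20), group = g)
  v <- matrix(15, 2, 20)
  v[1, 1:5] <- c(10, 10, 10, 10, NA)  # rate 4/5 >= 0.5, group SD 0
  colnames(v) <- meta$sample_id
  rownames(v) <- c("A;S1", "B;S2")
  m <- intensity_matrix(v, scale = "log2")
  out <- impute_phospho(m, meta, seed = 1)
  expect_equal(unname(unclass(out)[1, 5]), 10)
})

test_that("tail imputation draws from the down-shifted normal", {
  # recipient sample's observed values have mean 25, SD 2 exactly, so tail
  # fills follow Normal(25 - 1.8*2, 0.3*2) = Normal(21.4, 0.6)
  g <- rep(phosdiff_groups(), each = 4)
  meta <- tibble::tibble(sample_id = paste0("s", 1:16), group = g)
  n_holes <- 10000
  base <- as.vector(scale(rnorm(200))) * 2 + 25  # exact mean/sd
  v <- matrix(NA_real_, 200 + n_holes, 16)
  v[1:200, ] <- base
  v[200 + seq_len(n_holes), 1] <- 30  # observed once -> below rate everywhere
  colnames(v) <- meta$sample_id
  rownames(v) <- paste0("F", seq_len(nrow(v)))
  m <- intensity_matrix(v, scale = "log2")
  out <- impute_phospho(m, meta, seed = 42)
  fills <- unclass(out)[200 + seq_len(n_holes), 2]
  expect_equal(mean(fills), 25 - 1.8 * 2, tolerance = 0.05 / 21.4)
  expect_equal(sd(fills), 0.6, tolerance = 0.05)

  # determinism and observed-cell preservation
  out2 <- impute_phospho(m, meta, seed = 42)
  expect_identical(unclass(out), unclass(out2))
  obs <- !missing_mask(m)
  expect_identical(unclass(out)[obs], unclass(m)[obs])
  # deterministic mode fills with the distribution mean
  outd <- impute_phospho(m, meta, seed = 1, deterministic = TRUE)
  expect_true(all(unclass(outd)[200 + seq_len(n_holes), 2] == 21.4))
})

test_that("median scaling aligns sample medians additively", {
  meta <- tiny_meta(2)
  set.seed(8)
  v <- matrix(rnorm(8 * 9, 25, 2), 9, 8)
  v[, 1] <- v[, 1] - median(v[, 1]) + 20
  v[, 2] <- v[, 2] - median(v[, 2]) + 24
  m <- im(v, scale = "log2", meta = meta)
  out <- median_scale(m)
  med <- apply(unclass(out), 2, median)
  expect_true(all(abs(med - med[1]) < 1e-12))

  # two-sample case lands on the common median 22
  v2 <- matrix(c(19, 20, 21, 23, 24, 25), 3, 2,
               dimnames = list(paste0("F", 1:3), c("a", "b")))
  out2 <- median_scale(intensity_matrix(v2, scale = "log2"))
  expect_equal(unname(apply(unclass(out2), 2, median)), c(22, 22))

  # shift invariance up to the global anchor: adding a constant to one
  # sample leaves all scaled values identical up to one common offset, so
  # every downstream difference-based statistic is unchanged
  v3 <- v
  v3[, 3] <- v3[, 3] + 5
  out3 <- median_scale(im(v3, scale = "log2", meta = meta))
  offs <- unclass(out3) - unclass(out)
  expect_lt(diff(range(offs)), 1e-12)

  # single sample is identity
  v1 <- matrix(1:5, 5, 1, dimnames = list(paste0("F", 1:5), "a"))
  expect_equal(unclass(median_scale(intensity_matrix(v1 + 0, scale = "log2"))),
               unclass(v1 + 0), ignore_attr = TRUE)

  expect_error(median_scale(im(matrix(c(1, NA, 2, 3), 2, 2), scale = "log2")),
               "imputed")
})
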