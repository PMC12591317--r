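#' Log2-transform raw intensities
#'
#' Applied exactly once, directly after reading: observed raw intensities
#' are replaced by their log2; the missingness mask is untouched.
#'
#' @param m a raw-scale [intensity_matrix()] with all observed values > 0.
#' @return A log2-scale [intensity_matrix()].
#' @export
log2_transform <- function(m) {
  if (im_scale(m) != "raw") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  v <- unclass(m)
  if (any(v[!is.na(v)] <= 0)) {
    stop("nonpositive observed intensity; raw intensities must be > 0",
         call. = FALSE)
  }
  im_replace(m, log2(v), scale = "log2")
}

#' Per-feature, per-group presence summary
#'
#' @param m an [intensity_matrix()].
#' @param meta sample metadata.
#' @return Tibble with `feature_id`, `group`, `n_observed`, `group_size`,
#'   `fraction`.
#' @export
presence_summary <- function(m, meta) {
  gs <- group_samples(meta, m)
  purrr::map_dfr(names(gs), function(g) {
    sub <- unclass(m)[, gs[[g]], drop = FALSE]
    n_obs <- unname(rowSums(!is.na(sub)))
    tibble::tibble(
      feature_id = feature_ids(m),
      group = g,
      n_observed = n_obs,
      group_size = length(gs[[g]]),
      fraction = n_obs / length(gs[[g]])
    )
  })
}

#' Group-wise presence filter
#'
#' Keeps a feature if it is observed in at least `presence_fraction`
#' (default half) of the samples of the KRAS, EGFR or WT group, or in at
#' least `eml4alk_min_present` (default 4 of 6) EML4-ALK samples. The
#' EML4-ALK group gets a count rule rather than the fraction rule because
#' with six samples "at least half" would admit features seen only three
#' times.
#'
#' @param m a log2-scale [intensity_matrix()].
#' @param meta sample metadata.
#' @param params [analysis_params()].
#' @return A list with `matrix` (filtered, input order preserved) and
#'   `presence` (the [presence_summary()] of the input).
#' @export
presence_filter <- function(m, meta, params = analysis_params()) {
  stopifnot(im_scale(m) == "log2")
  ps <- presence_summary(m, meta)
  wide <- tidyr::pivot_wider(ps[, c("feature_id", "group", "n_observed",
                                    "fraction")],
                             names_from = "group",
                             values_from = c("n_observed", "fraction"))
  # restore matrix row order
  wide <- wide[match(feature_ids(m), wide$feature_id), ]
  keep <- wide$fraction_KRAS >= params$presence_fraction |
    wide$fraction_EGFR >= params$presence_fraction |
    wide$fraction_WT >= params$presence_fraction |
    wide$n_observed_EML4_ALK >= params$eml4alk_min_present
  list(matrix = im_subset(m, which(keep)), presence = ps)
}

#' Localization-probability filter for phosphosites
#'
#' Restricts the site matrix to class I sites, those whose phosphate
#' placement is confident: localization probability >= `localization_min`
#' (boundary kept).
#'
#' @param m site-level [intensity_matrix()].
#' @param sites annotation tibble with `site_id` and
#'   `localization_probability`.
#' @param params [analysis_params()].
#' @return The filtered [intensity_matrix()].
#' @export
localization_filter <- function(m, sites, params = analysis_params()) {
  idx <- match(feature_ids(m), sites$site_id)
  if (any(is.na(idx))) {
    stop("site(s) without annotation: ",
         paste(utils::head(feature_ids(m)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  keep <- sites$localization_probability[idx] >= params$localization_min
  if (!any(keep)) {
    warning("no site passes the localization filter", call. = FALSE)
  }
  im_subset(m, which(keep))
}

# 5th-percentile (type-7 linear interpolation) of each sample's observed
# values
sample_floor <- function(m, percentile) {
  apply(unclass(m), 2, function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) == 0) return(NA_real_)
    unname(stats::quantile(obs, percentile / 100, type = 7))
  })
}

#' Hybrid proteomic imputation (sample 5-percentile / feature kNN)
#'
#' Works group by group. For a feature missing in some samples of a group:
#' if it was observed in fewer than half of that group's samples, missing
#' cells get the recipient sample's low-abundance floor — the 5th
#' percentile of that sample's observed log2 intensities — reflecting that
#' sparse observation under left-censored dropout means low abundance. If
#' it was observed in at least half, missing cells are filled by kNN over
#' features: the `knn_k` nearest features by Euclidean distance across that
#' group's samples (pairwise-complete, distances scaled by
#' `sqrt(n_total/n_shared)`) that are observed in the recipient sample
#' supply the mean of their values there. Observed cells are never
#' modified.
#'
#' @param m a log2-scale, presence-filtered [intensity_matrix()].
#' @param meta sample metadata.
#' @param params [analysis_params()].
#' @return A fully imputed [intensity_matrix()].
#' @export
impute_proteomic <- function(m, meta, params = analysis_params()) {
  stopifnot(im_scale(m) == "log2")
  v <- unclass(m)
  floors <- sample_floor(m, params$low_presence_percentile)
  if (any(is.na(floors))) {
    stop("sample(s) with zero observed values: ",
         paste(names(floors)[is.na(floors)], collapse = ", "), call. = FALSE)
  }
  gs <- group_samples(meta, m)
  out <- v
  for (g in names(gs)) {
    cols <- gs[[g]]
    sub <- v[, cols, drop = FALSE]
    frac <- rowMeans(!is.na(sub))
    holes <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(holes) == 0) next
    knn_rows <- frac >= 0.5
    # stats::dist on rows: pairwise-complete euclidean scaled by
    # sqrt(ncol/n_shared), exactly the target metric
    D <- NULL
    if (any(knn_rows & frac < 1)) D <- as.matrix(stats::dist(sub))
    for (h in seq_len(nrow(holes))) {
      f <- holes[h, 1]
      s <- holes[h, 2]
      if (!knn_rows[f]) {
        out[f, cols[s]] <- floors[cols[s]]
      } else {
        cand <- which(!is.na(sub[, s]) & is.finite(D[f, ]))
        cand <- cand[cand != f]
        if (length(cand) == 0) {
          stop("no kNN candidate for feature ", feature_ids(m)[f],
               " in sample ", cols[s], call. = FALSE)
        }
        if (length(cand) < params$knn_k) {
          warning("only ", length(cand), " neighbour candidates (k = ",
                  params$knn_k, ") for ", feature_ids(m)[f], call. = FALSE)
        }
        nn <- cand[order(D[f, cand])][seq_len(min(params$knn_k, length(cand)))]
        out[f, cols[s]] <- mean(sub[nn, s])
      }
    }
  }
  im_replace(m, out)
}

#' Phosphosite imputation (condition-specific, then tail-based)
#'
#' Two passes per the left-censoring model. First, condition-specific: for
#' each feature x group with observed fraction >= `condition_rate_min`,
#' missing cells are drawn from `Normal(group mean, group SD)` of the
#' observed values (SD of a single observation treated as 0). Cells still
#' missing are then tail-imputed per sample from a down-shifted normal,
#' `Normal(sample mean - tail_shift * sample SD, tail_scale * sample SD)`
#' over that sample's observed values — unobserved sites are presumed to
#' sit in the low-abundance tail. Observed cells never change.
#'
#' @param m a log2-scale, filtered [intensity_matrix()].
#' @param meta sample metadata.
#' @param params [analysis_params()].
#' @param seed integer seed for the stochastic draws.
#' @param deterministic if `TRUE`, fill with the distribution means instead
#'   of random draws (exact-value testing mode).
#' @return A fully imputed [intensity_matrix()].
#' @export
impute_phospho <- function(m, meta, params = analysis_params(),
                           seed = params$rng_seed, deterministic = FALSE) {
  stopifnot(im_scale(m) == "log2")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("invalid seed", call. = FALSE)
  }
  set.seed(as.integer(seed))
  v <- unclass(m)
  out <- v
  gs <- group_samples(meta, m)
  for (g in names(gs)) {
    cols <- gs[[g]]
    if (length(cols) == 0) stop("empty group ", g, call. = FALSE)
    sub <- v[, cols, drop = FALSE]
    frac <- rowMeans(!is.na(sub))
    rows <- which(frac >= params$condition_rate_min & frac < 1)
    for (f in rows) {
      obs <- sub[f, !is.na(sub[f, ])]
      mu <- mean(obs)
      sdv <- if (length(obs) > 1) stats::sd(obs) else 0
      miss <- which(is.na(sub[f, ]))
      fill <- if (deterministic) rep(mu, length(miss)) else
        stats::rnorm(length(miss), mu, sdv)
      out[f, cols[miss]] <- fill
    }
  }
  # tail pass over whatever is still missing, per sample
  still <- is.na(out)
  if (any(still)) {
    for (s in seq_len(ncol(out))) {
      miss <- which(still[, s])
      if (length(miss) == 0) next
      obs <- v[!is.na(v[, s]), s]
      if (length(obs) < 2) {
        stop("sample ", sample_ids(m)[s],
             " has too few observed values for tail imputation",
             call. = FALSE)
      }
      mu <- mean(obs) - params$tail_shift * stats::sd(obs)
      sdv <- params$tail_scale * stats::sd(obs)
      out[miss, s] <- if (deterministic) rep(mu, length(miss)) else
        stats::rnorm(length(miss), mu, sdv)
    }
  }
  im_replace(m, out)
}

#' Median scaling (additive, no variance scaling)
#'
#' Shifts each sample additively so that all per-sample medians equal the
#' grand median of the per-sample medians. No multiplicative scaling is
#' applied, so within-sample spread is untouched.
#'
#' @param m a fully imputed log2-scale [intensity_matrix()].
#' @return The scaled [intensity_matrix()].
#' @export
median_scale <- function(m) {
  v <- unclass(m)
  if (anyNA(v)) stop("median_scale requires a fully imputed matrix",
                     call. = FALSE)
  med <- apply(v, 2, stats::median)
  target <- stats::median(med)
  im_replace(m, sweep(v, 2, med - target))
}
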