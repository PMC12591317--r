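#' Normality and variance-homogeneity gates
#'
#' Decides which branch of the test cascade a feature takes. Normality is
#' assessed per group with Shapiro-Wilk (a group with fewer than 3 values
#' or constant values cannot be tested and is treated as non-normal);
#' variance homogeneity across the supplied groups with the robust Levene
#' test (Brown-Forsythe variant, centred at the median). Both gates pass
#' when their p-value is at least `gate_alpha`.
#'
#' @param values_by_group named list of numeric vectors.
#' @param params [analysis_params()].
#' @return A list with `normal_all`, `equal_var` and the per-group
#'   Shapiro-Wilk p-values (`shapiro_p`).
#' @export
gate_tests <- function(values_by_group, params = analysis_params()) {
  shapiro_p <- vapply(values_by_group, function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) return(0)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }, numeric(1))
  normal_all <- all(shapiro_p >= params$gate_alpha)

  vals <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), lengths(values_by_group)))
  equal_var <- if (length(unique(vals)) == 1) {
    TRUE
  } else {
    lev <- tryCatch(
      car::leveneTest(vals ~ grp, center = stats::median)[1, "Pr(>F)"],
      error = function(e) NA_real_
    )
    isTRUE(lev >= params$gate_alpha) || is.na(lev)
  }
  list(normal_all = normal_all, equal_var = equal_var, shapiro_p = shapiro_p)
}

#' Adaptive omnibus test across the four groups
#'
#' Normal + equal variances: one-way ANOVA. Normal + unequal variances:
#' Welch-ANOVA. Any non-normal group: Kruskal-Wallis.
#'
#' @param values_by_group named list of numeric vectors (>= 2 each).
#' @param gates result of [gate_tests()] on the same values.
#' @return A list with `test` and `p`.
#' @export
omnibus_test <- function(values_by_group, gates) {
  if (any(lengths(values_by_group) < 2)) {
    stop("omnibus test needs >= 2 values per group", call. = FALSE)
  }
  vals <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), lengths(values_by_group)))
  if (length(unique(vals)) == 1) {
    # constant feature: no evidence of any difference
    return(list(test = "Kruskal_Wallis", p = 1))
  }
  if (gates$normal_all && gates$equal_var) {
    p <- stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
    list(test = "ANOVA", p = p)
  } else if (gates$normal_all) {
    p <- stats::oneway.test(vals ~ grp, var.equal = FALSE)$p.value
    list(test = "Welch_ANOVA", p = p)
  } else {
    p <- stats::kruskal.test(vals, grp)$p.value
    list(test = "Kruskal_Wallis", p = p)
  }
}

# Wilcoxon rank-sum with the cascade's exactness convention
wilcoxon_p <- function(a, b) {
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 25 && length(b) <= 25 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Adaptive pairwise two-group tests
#'
#' For each of the six canonical comparisons: both groups Shapiro-normal
#' and pairwise Levene homogeneous gives Student's t; normal but
#' heteroscedastic gives Welch's t; otherwise the Wilcoxon rank-sum test
#' (exact when both n <= 25 and there are no ties, else normal
#' approximation with continuity correction). The log2 fold-change is
#' `mean(group_a) - mean(group_b)` regardless of the test.
#'
#' @param values_by_group named list covering the four groups.
#' @param gates result of [gate_tests()] (per-group Shapiro p-values are
#'   reused; the variance gate is re-evaluated per pair).
#' @param spec [comparison_spec()].
#' @param params [analysis_params()].
#' @return Tibble with `comparison`, `pairwise_test`, `raw_p`, `log2fc`.
#' @export
pairwise_tests <- function(values_by_group, gates,
                           spec = comparison_spec(),
                           params = analysis_params()) {
  purrr::pmap_dfr(spec, function(comparison, group_a, group_b) {
    a <- values_by_group[[group_a]]
    b <- values_by_group[[group_b]]
    log2fc <- mean(a) - mean(b)
    normal_pair <- gates$shapiro_p[[group_a]] >= params$gate_alpha &&
      gates$shapiro_p[[group_b]] >= params$gate_alpha
    if (length(unique(c(a, b))) == 1) {
      return(tibble::tibble(comparison = comparison,
                            pairwise_test = "Wilcoxon",
                            raw_p = 1, log2fc = log2fc))
    }
    if (normal_pair) {
      pair_gate <- gate_tests(list(a = a, b = b), params)
      if (pair_gate$equal_var) {
        p <- stats::t.test(a, b, var.equal = TRUE)$p.value
        test <- "Student_t"
      } else {
        p <- stats::t.test(a, b, var.equal = FALSE)$p.value
        test <- "Welch_t"
      }
    } else {
      p <- wilcoxon_p(a, b)
      test <- "Wilcoxon"
    }
    tibble::tibble(comparison = comparison, pairwise_test = test,
                   raw_p = p, log2fc = log2fc)
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over `p.adjust(method = "BH")`; in this pipeline
#' it is applied within each feature across its six pairwise p-values
#' ("FDR controlled separately for every feature").
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Full adaptive differential analysis
#'
#' Runs the gated cascade per feature: omnibus across the four groups,
#' then — only for features with omnibus p below `omnibus_alpha` — the six
#' pairwise tests, BH-adjusted within the feature. Features failing the
#' omnibus gate keep their fold-changes (descriptive, and consumed by
#' KSEA) but carry no pairwise test results and are non-significant
#' everywhere. A comparison is called significant when
#' `fdr < fdr_q` and `|log2fc| > log2(fc_threshold)` (both strict).
#'
#' @param m a fully imputed log2-scale [intensity_matrix()].
#' @param meta sample metadata.
#' @param params [analysis_params()].
#' @param spec [comparison_spec()].
#' @param bh_scope `"within_feature"` (default; the per-feature reading of
#'   FDR control) or `"global"` (one BH pass across all features and
#'   comparisons, for sensitivity analysis).
#' @return A long tibble of class `phosdiff_stats`: one row per feature x
#'   comparison with `omnibus_test`, `omnibus_p`, `pairwise_test`,
#'   `raw_p`, `fdr`, `log2fc`, `significant`.
#' @export
analyze_features <- function(m, meta, params = analysis_params(),
                             spec = comparison_spec(),
                             bh_scope = c("within_feature", "global")) {
  bh_scope <- match.arg(bh_scope)
  stopifnot(im_scale(m) == "log2")
  if (anyNA(unclass(m))) {
    stop("analyze_features requires a fully imputed matrix", call. = FALSE)
  }
  gs <- group_samples(meta, m)
  v <- unclass(m)
  res <- purrr::map(feature_ids(m), function(fid) {
    vals <- lapply(gs, function(cols) v[fid, cols])
    gates <- gate_tests(vals, params)
    omni <- omnibus_test(vals, gates)
    fc <- vapply(seq_len(nrow(spec)), function(j) {
      mean(vals[[spec$group_a[j]]]) - mean(vals[[spec$group_b[j]]])
    }, numeric(1))
    if (omni$p < params$omnibus_alpha && is.finite(omni$p)) {
      pw <- pairwise_tests(vals, gates, spec, params)
      tibble::tibble(
        feature_id = fid, comparison = spec$comparison,
        omnibus_test = omni$test, omnibus_p = omni$p,
        pairwise_test = pw$pairwise_test, raw_p = pw$raw_p,
        fdr = NA_real_, log2fc = pw$log2fc
      )
    } else {
      tibble::tibble(
        feature_id = fid, comparison = spec$comparison,
        omnibus_test = omni$test, omnibus_p = omni$p,
        pairwise_test = "none", raw_p = NA_real_,
        fdr = NA_real_, log2fc = fc
      )
    }
  })
  out <- dplyr::bind_rows(res)
  if (bh_scope == "within_feature") {
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$feature_id),
      fdr = ifelse(is.na(.data$raw_p), NA_real_,
                   bh_adjust_allow_na(.data$raw_p))
    )
    out <- dplyr::ungroup(out)
  } else {
    ok <- !is.na(out$raw_p)
    out$fdr[ok] <- bh_adjust(out$raw_p[ok])
  }
  out$significant <- !is.na(out$fdr) & out$fdr < params$fdr_q &
    abs(out$log2fc) > log2(params$fc_threshold)
  class(out) <- c("phosdiff_stats", class(out))
  out
}

# BH over the non-NA entries, NA elsewhere
bh_adjust_allow_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bh_adjust(p[ok])
  out
}

#' @method glance phosdiff_stats
#' @export
glance.phosdiff_stats <- function(x, ...) {
  per_feature <- dplyr::summarise(
    dplyr::group_by(x, .data$feature_id),
    any_sig = any(.data$significant),
    .groups = "drop"
  )
  tibble::tibble(
    n_features = nrow(per_feature),
    n_comparisons = length(unique(x$comparison)),
    n_significant_features = sum(per_feature$any_sig),
    n_significant_calls = sum(x$significant)
  )
}
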