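#' Kinase-substrate enrichment z-scores for one comparison
#'
#' Infers relative kinase activity from its substrates' fold-changes. With
#' `s_bar` the mean log2 fold-change of a kinase's quantified substrates,
#' `p_bar` the mean over all quantified sites, `delta` the (n-1) SD over
#' all quantified sites and `m` the substrate count,
#' `z = (s_bar - p_bar) * sqrt(m) / delta`, with a two-sided normal
#' p-value. A kinase is called significant when `m >= ksea_min_substrates`
#' and `p < ksea_alpha`. All quantified sites contribute to `p_bar` and
#' `delta`, not only significant ones. Kinases with no quantified
#' substrate are reported with `m = 0` and no score.
#'
#' @param site_log2fc named numeric vector: site id -> log2 fold-change of
#'   all quantified sites for one comparison.
#' @param ks_map named list: kinase id -> substrate site ids.
#' @param params [analysis_params()].
#' @return Tibble sorted by `z` (descending): `kinase_id`, `m`, `s_bar`,
#'   `p_bar`, `delta`, `z`, `p_value`, `significant`.
#' @export
ksea_scores <- function(site_log2fc, ks_map, params = analysis_params()) {
  stopifnot(!is.null(names(site_log2fc)))
  fc <- site_log2fc[!is.na(site_log2fc)]
  if (length(fc) < 2) stop("need >= 2 sites with fold-changes", call. = FALSE)
  p_bar <- mean(fc)
  delta <- stats::sd(fc)
  if (!is.finite(delta) || delta == 0) {
    stop("degenerate fold-change distribution", call. = FALSE)
  }
  out <- purrr::map_dfr(names(ks_map), function(k) {
    subs <- intersect(ks_map[[k]], names(fc))
    m <- length(subs)
    if (m == 0) {
      return(tibble::tibble(kinase_id = k, m = 0L, s_bar = NA_real_,
                            p_bar = p_bar, delta = delta, z = NA_real_,
                            p_value = NA_real_, significant = FALSE))
    }
    s_bar <- mean(fc[subs])
    z <- (s_bar - p_bar) * sqrt(m) / delta
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(
      kinase_id = k, m = as.integer(m), s_bar = s_bar, p_bar = p_bar,
      delta = delta, z = z, p_value = p,
      significant = m >= params$ksea_min_substrates & p < params$ksea_alpha
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$z))
}

#' KSEA across all six comparisons
#'
#' Runs [ksea_scores()] on each comparison's site fold-changes (all
#' filtered, imputed sites — the fold-change is defined whether or not a
#' site passed the significance gates) and summarises kinases significant
#' in at least one comparison.
#'
#' @param stats site-level [analyze_features()] table.
#' @param ks_map kinase -> substrate site ids.
#' @param params [analysis_params()].
#' @param spec [comparison_spec()].
#' @return Object of class `phosdiff_ksea`: list with `scores` (long
#'   tibble with a `comparison` column) and `significant_kinases`
#'   (tibble `kinase_id`, `n_significant_comparisons`).
#' @export
ksea_all_comparisons <- function(stats, ks_map, params = analysis_params(),
                                 spec = comparison_spec()) {
  scores <- purrr::map_dfr(spec$comparison, function(cmp) {
    sub <- stats[stats$comparison == cmp, ]
    fc <- stats::setNames(sub$log2fc, sub$feature_id)
    dplyr::mutate(ksea_scores(fc, ks_map, params), comparison = cmp,
                  .before = 1)
  })
  sig <- dplyr::summarise(
    dplyr::group_by(scores[scores$significant, ], .data$kinase_id),
    n_significant_comparisons = dplyr::n(), .groups = "drop"
  )
  structure(list(scores = scores, significant_kinases = sig,
                 params = params),
            class = "phosdiff_ksea")
}

#' @export
print.phosdiff_ksea <- function(x, ...) {
  cat(sprintf(
    "<phosdiff KSEA> %d kinases x %d comparisons; %d kinase(s) significant (m >= %d, p < %g)\n",
    length(unique(x$scores$kinase_id)),
    length(unique(x$scores$comparison)),
    nrow(x$significant_kinases),
    x$params$ksea_min_substrates, x$params$ksea_alpha
  ))
  invisible(x)
}

#' @method tidy phosdiff_ksea
#' @export
tidy.phosdiff_ksea <- function(x, ...) x$scores

#' @method glance phosdiff_ksea
#' @export
glance.phosdiff_ksea <- function(x, ...) {
  tibble::tibble(
    n_kinases = length(unique(x$scores$kinase_id)),
    n_scored = length(unique(x$scores$kinase_id[x$scores$m > 0])),
    n_significant = nrow(x$significant_kinases),
    max_m = max(x$scores$m)
  )
}
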