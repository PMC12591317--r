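#' Cohen's d standardized effect size
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled SD
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))` — the ranking
#' statistic for preranked enrichment analysis.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return The effect size, or `NA` with a warning when the pooled SD is
#'   zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    warning("pooled SD is zero; effect size undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Effect-size ranking for one comparison
#'
#' Computes Cohen's d per feature between the two groups of a comparison,
#' drops undefined effects, and returns a ranking sorted by d descending
#' (ties broken by feature id, ascending, for determinism).
#'
#' @param m fully imputed log2-scale [intensity_matrix()].
#' @param meta sample metadata.
#' @param group_a,group_b canonical group names.
#' @return Named numeric vector (feature -> d), sorted descending.
#' @export
rank_by_effect_size <- function(m, meta, group_a, group_b) {
  gs <- group_samples(meta, m)
  v <- unclass(m)
  d <- vapply(feature_ids(m), function(f) {
    suppressWarnings(cohens_d(v[f, gs[[group_a]]], v[f, gs[[group_b]]]))
  }, numeric(1))
  d <- d[!is.na(d)]
  d[order(-d, names(d))]
}

# weighted KS running-sum enrichment score, weight exponent 1
gsea_es <- function(ranked_stats, member_idx) {
  n <- length(ranked_stats)
  n_hit <- length(member_idx)
  if (n_hit == 0 || n_hit == n) return(NA_real_)
  w <- abs(ranked_stats[member_idx])
  if (sum(w) == 0) w <- rep(1, n_hit)  # all-zero stats: unweighted steps
  inc <- numeric(n)
  inc[member_idx] <- w / sum(w)
  dec <- rep(1 / (n - n_hit), n)
  dec[member_idx] <- 0
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment analysis
#'
#' Classic permutation-based preranked GSEA: a weighted Kolmogorov-Smirnov
#' running sum (weight exponent 1 — member increments proportional to
#' |d|, uniform decrements for non-members; the enrichment score ES is the
#' extreme deviation). The null is built from `gsea_nperm` random
#' same-size gene draws; the p-value is the one-sided tail frequency with
#' a +1 pseudocount, NES is ES divided by the mean |null ES| of matching
#' sign, and FDR is BH across the reported sets. Sets are restricted to
#' the ranked universe and to `[gsea_min_set, gsea_max_set]` members.
#'
#' @param ranking named numeric vector (gene -> effect size), any order
#'   (it is re-sorted descending with deterministic tie-breaking).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param params [analysis_params()].
#' @param seed integer seed for the permutation null.
#' @return Object of class `phosdiff_gsea` wrapping a tibble with
#'   `set_name`, `size`, `es`, `nes`, `p_value`, `fdr`, `leading_edge`.
#' @export
preranked_gsea <- function(ranking, sets, params = analysis_params(),
                           seed = params$rng_seed) {
  stopifnot(!is.null(names(ranking)))
  ranking <- ranking[order(-ranking, names(ranking))]
  genes <- names(ranking)
  n <- length(genes)
  restricted <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(restricted)
  keep <- sizes >= params$gsea_min_set & sizes <= params$gsea_max_set &
    sizes < n
  if (!any(keep)) {
    warning("no gene set survives the size restriction", call. = FALSE)
    out <- tibble::tibble(set_name = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0),
                          p_value = numeric(0), fdr = numeric(0),
                          leading_edge = list())
    return(structure(list(results = out, params = params),
                     class = "phosdiff_gsea"))
  }
  restricted <- restricted[keep]

  set.seed(as.integer(seed))
  # one shared null per distinct set size
  null_by_size <- lapply(
    stats::setNames(nm = sort(unique(lengths(restricted)))),
    function(k) {
      k <- as.integer(k)
      vapply(seq_len(params$gsea_nperm), function(i) {
        gsea_es(ranking, sort(sample.int(n, k)))
      }, numeric(1))
    }
  )

  res <- purrr::map_dfr(names(restricted), function(nm) {
    members <- restricted[[nm]]
    idx <- sort(match(members, genes))
    es <- gsea_es(ranking, idx)
    null <- null_by_size[[as.character(length(members))]]
    same <- null[sign(null) == sign(es)]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
    # leading edge: members at or before (after, for negative ES) the peak
    w <- abs(ranking[idx])
    if (sum(w) == 0) w <- rep(1, length(idx))
    inc <- numeric(n)
    inc[idx] <- w / sum(w)
    dec <- rep(1 / (n - length(idx)), n)
    dec[idx] <- 0
    run <- cumsum(inc - dec)
    peak <- which.max(abs(run))
    le <- if (es >= 0) genes[idx[idx <= peak]] else genes[idx[idx >= peak]]
    tibble::tibble(set_name = nm, size = length(members), es = es,
                   nes = nes, p_value = p, leading_edge = list(le))
  })
  res$fdr <- bh_adjust(res$p_value)
  res <- res[, c("set_name", "size", "es", "nes", "p_value", "fdr",
                 "leading_edge")]
  structure(list(results = res, params = params), class = "phosdiff_gsea")
}

#' @export
print.phosdiff_gsea <- function(x, ...) {
  cat(sprintf("<phosdiff GSEA> %d set(s); %d with FDR < 0.05\n",
              nrow(x$results), sum(x$results$fdr < 0.05)))
  invisible(x)
}

#' @method tidy phosdiff_gsea
#' @export
tidy.phosdiff_gsea <- function(x, ...) x$results

#' @method glance phosdiff_gsea
#' @export
glance.phosdiff_gsea <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$results),
    n_fdr05 = sum(x$results$fdr < 0.05),
    nperm = x$params$gsea_nperm
  )
}
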