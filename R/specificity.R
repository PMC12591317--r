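#' Signed significance matrix
#'
#' Collapses a [analyze_features()] table to one signed entry per feature
#' and comparison: `sign(log2fc)` when the comparison is a discovery
#' (`fdr < fdr_q` and `|log2fc| > log2(fc_threshold)`, both strict), else
#' 0.
#'
#' @param stats long statistics tibble (`feature_id`, `comparison`, `fdr`,
#'   `log2fc`).
#' @param params [analysis_params()].
#' @param spec [comparison_spec()].
#' @return Integer matrix, features x six comparisons, entries in
#'   `{-1, 0, 1}`.
#' @export
significance_matrix <- function(stats, params = analysis_params(),
                                spec = comparison_spec()) {
  sig <- !is.na(stats$fdr) & stats$fdr < params$fdr_q &
    abs(stats$log2fc) > log2(params$fc_threshold)
  entry <- ifelse(sig, sign(stats$log2fc), 0L)
  wide <- tidyr::pivot_wider(
    tibble::tibble(feature_id = stats$feature_id,
                   comparison = stats$comparison, entry = entry),
    names_from = "comparison", values_from = "entry", values_fill = 0L
  )
  out <- as.matrix(wide[, spec$comparison, drop = FALSE])
  rownames(out) <- wide$feature_id
  storage.mode(out) <- "integer"
  out
}

# partitions of the 4 groups into 2+2, as list(side1, side2)
group_partitions <- function() {
  g <- phosdiff_groups()
  list(
    list(c(g[1], g[2]), c(g[3], g[4])),
    list(c(g[1], g[3]), c(g[2], g[4])),
    list(c(g[1], g[4]), c(g[2], g[3]))
  )
}

# classify one sign vector (length 6, canonical comparison order)
classify_pattern <- function(s, spec = comparison_spec()) {
  groups <- phosdiff_groups()
  labels <- list()
  for (g in groups) {
    idx <- which(spec$group_a == g | spec$group_b == g)
    oriented <- ifelse(spec$group_a[idx] == g, s[idx], -s[idx])
    if (all(oriented == 1L)) {
      labels[[length(labels) + 1]] <- list(label = g, type = "group",
                                           direction = "UP")
    } else if (all(oriented == -1L)) {
      labels[[length(labels) + 1]] <- list(label = g, type = "group",
                                           direction = "DOWN")
    }
  }
  if (length(labels) == 0) {
    for (part in group_partitions()) {
      side1 <- part[[1]]
      cross <- which((spec$group_a %in% side1) != (spec$group_b %in% side1))
      within <- setdiff(seq_along(s), cross)
      oriented <- ifelse(spec$group_a[cross] %in% side1, s[cross], -s[cross])
      if (all(s[within] == 0L) && all(oriented == 1L)) {
        labels[[length(labels) + 1]] <- list(
          label = paste(paste(side1, collapse = "+"),
                        paste(part[[2]], collapse = "+"), sep = "|"),
          type = "partition", direction = "UP"
        )
      } else if (all(s[within] == 0L) && all(oriented == -1L)) {
        labels[[length(labels) + 1]] <- list(
          label = paste(paste(side1, collapse = "+"),
                        paste(part[[2]], collapse = "+"), sep = "|"),
          type = "partition", direction = "DOWN"
        )
      }
    }
  }
  if (length(labels) > 0) return(labels)
  if (all(s == 0L)) {
    list(list(label = NA_character_, type = "none",
              direction = NA_character_))
  } else {
    list(list(label = NA_character_, type = "mixed",
              direction = NA_character_))
  }
}

#' Alteration-specificity classification
#'
#' Labels each feature by the structure of its significant comparisons. A
#' feature is *group-specific* for group `g` when all three comparisons
#' involving `g` are discoveries with a consistent direction once
#' re-oriented as (g minus other); it is then UP or DOWN relative to `g`.
#' A feature can legitimately carry two group labels (e.g. higher in one
#' group than the middle pair, which in turn is higher than a fourth
#' group: that is specific UP for the first and specific DOWN for the
#' last). Features matching no group are tested against the three 2-vs-2
#' partitions: all four cross-partition comparisons discoveries with
#' consistent orientation, both within-side comparisons null. Remaining
#' features with any discovery are `mixed`; featureless rows are `none`.
#'
#' @param sig sign matrix from [significance_matrix()].
#' @param spec [comparison_spec()].
#' @return Tibble with one row per (feature, label): `feature_id`,
#'   `label`, `type` (`group`/`partition`/`mixed`/`none`), `direction`.
#' @export
classify_specific <- function(sig, spec = comparison_spec()) {
  purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    labs <- classify_pattern(sig[i, ], spec)
    tibble::tibble(
      feature_id = rownames(sig)[i],
      label = vapply(labs, function(l) l$label, ""),
      type = vapply(labs, function(l) l$type, ""),
      direction = vapply(labs, function(l) l$direction, "")
    )
  })
}

#' Specificity count summary
#'
#' Per-group counts include every feature carrying that group's label
#' (doubly labelled features count in both groups); the unique union
#' deduplicates. Partition-pattern features are counted separately — the
#' two classes are disjoint by construction.
#'
#' @param calls tibble from [classify_specific()].
#' @return Tibble with `label`, `type` (`group`, `partition`, `union`) and
#'   `n`.
#' @export
summarize_specificity <- function(calls) {
  groups <- phosdiff_groups()
  grp <- dplyr::filter(calls, .data$type == "group")
  per_group <- tibble::tibble(
    label = groups, type = "group",
    n = unname(vapply(groups, function(g) sum(grp$label == g), integer(1)))
  )
  part <- dplyr::filter(calls, .data$type == "partition")
  per_part <- dplyr::count(part, .data$label, name = "n")
  per_part <- tibble::tibble(label = per_part$label, type = "partition",
                             n = per_part$n)
  union_row <- tibble::tibble(
    label = "any_group", type = "union",
    n = length(unique(grp$feature_id))
  )
  dplyr::bind_rows(per_group, per_part, union_row)
}

#' Compare phosphosite and parent-protein fold-changes
#'
#' For each significant phosphosite, joins the fold-change of its parent
#' protein in the same comparison. A site is flagged as a protein-driven
#' candidate when the protein moves in the same direction by at least
#' `protein_driven_ratio` of the site's log2 fold-change — such sites may
#' reflect abundance change rather than altered phosphorylation. Sites
#' whose parent protein is absent from the protein table keep an `NA`
#' protein fold-change and are never flagged.
#'
#' @param site_stats site-level [analyze_features()] table (significant
#'   rows are compared).
#' @param protein_stats protein-level [analyze_features()] table.
#' @param site_map tibble mapping `site_id` to `protein_id`.
#' @param params [analysis_params()].
#' @return Tibble with `site_id`, `protein_id`, `comparison`,
#'   `site_log2fc`, `protein_log2fc`, `protein_driven`.
#' @export
phospho_vs_protein <- function(site_stats, protein_stats, site_map,
                               params = analysis_params()) {
  sig_sites <- dplyr::filter(site_stats, .data$significant)
  joined <- dplyr::left_join(
    tibble::tibble(site_id = sig_sites$feature_id,
                   comparison = sig_sites$comparison,
                   site_log2fc = sig_sites$log2fc),
    site_map[, c("site_id", "protein_id")],
    by = "site_id"
  )
  prot <- tibble::tibble(protein_id = protein_stats$feature_id,
                         comparison = protein_stats$comparison,
                         protein_log2fc = protein_stats$log2fc)
  joined <- dplyr::left_join(joined, prot,
                             by = c("protein_id", "comparison"))
  joined$protein_driven <- !is.na(joined$protein_log2fc) &
    joined$protein_log2fc != 0 &
    sign(joined$protein_log2fc) == sign(joined$site_log2fc) &
    abs(joined$protein_log2fc) >=
      params$protein_driven_ratio * abs(joined$site_log2fc)
  joined[, c("site_id", "protein_id", "comparison", "site_log2fc",
             "protein_log2fc", "protein_driven")]
}
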