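#' Canonical genotype groups and pairwise comparisons
#'
#' The cohort design distinguishes four genotype groups of lung
#' adenocarcinoma samples: `EML4_ALK` (ALK-rearranged), `EGFR`-mutated,
#' `KRAS`-mutated and triple wild-type (`WT`). All pairwise statistics are
#' reported for the six two-group comparisons in a fixed canonical order,
#' with the sign convention `log2fc = mean(group_a) - mean(group_b)`.
#'
#' @return `phosdiff_groups()` returns the four canonical group names.
#'   `comparison_spec()` returns a tibble with columns `comparison`,
#'   `group_a`, `group_b` (six rows, canonical order).
#' @examples
#' comparison_spec()
#' @export
phosdiff_groups <- function() {
  c("EML4_ALK", "EGFR", "KRAS", "WT")
}

#' @rdname phosdiff_groups
#' @export
comparison_spec <- function() {
  g <- phosdiff_groups()
  pairs <- utils::combn(g, 2)
  tibble::tibble(
    group_a = pairs[1, ],
    group_b = pairs[2, ],
    comparison = paste(pairs[1, ], pairs[2, ], sep = "_vs_")
  )[, c("comparison", "group_a", "group_b")]
}

#' Analysis parameters
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults encode the analysis conventions of the genotype-group cohort
#' design: features must be observed in at least half the samples of one of
#' the larger groups (or 4 of 6 EML4-ALK samples), phosphosites require
#' localization probability >= 0.75 (class I sites), missing values are
#' imputed with the sample 5-percentile or feature-kNN (k = 10), tests are
#' gated at alpha 0.05, discoveries require BH FDR < 0.05 and fold-change
#' > 2 (|log2 fc| > 1), and kinases need at least 3 quantified substrates.
#'
#' @param presence_fraction minimum observed fraction within KRAS/EGFR/WT
#'   for the presence filter (default 0.5).
#' @param eml4alk_min_present minimum observed count in the EML4-ALK group
#'   (default 4, i.e. 4 of 6).
#' @param knn_k number of feature neighbours for kNN imputation.
#' @param low_presence_percentile percentile (0-100 scale) of a sample's
#'   observed intensities used for low-presence imputation (default 5).
#' @param localization_min minimum site localization probability kept.
#' @param condition_rate_min minimum within-group observed fraction for
#'   condition-specific phospho imputation.
#' @param gate_alpha alpha for the Shapiro-Wilk and Levene gates.
#' @param omnibus_alpha omnibus p-value below which pairwise tests run.
#' @param fdr_q BH FDR cutoff for significance calls.
#' @param fc_threshold linear fold-change cutoff (applied as
#'   `|log2fc| > log2(fc_threshold)`).
#' @param ksea_min_substrates minimum substrate count m for a kinase to be
#'   eligible for the significance summary.
#' @param ksea_alpha p-value cutoff for KSEA significance.
#' @param tail_shift down-shift of the tail imputation distribution, in
#'   units of the sample SD.
#' @param tail_scale width of the tail imputation distribution, in units of
#'   the sample SD.
#' @param protein_driven_ratio a significant phosphosite is flagged as a
#'   protein-driven candidate when its parent protein changes in the same
#'   direction by at least this fraction of the site fold-change.
#' @param gsea_nperm number of gene-set permutations for the enrichment
#'   null.
#' @param gsea_min_set,gsea_max_set gene-set size bounds after restriction
#'   to the ranked universe.
#' @param rng_seed integer seed used by stochastic stages.
#'
#' @return A named list of class `phosdiff_params`.
#' @examples
#' p <- analysis_params()
#' p$fdr_q
#' @export
analysis_params <- function(presence_fraction = 0.5,
                            eml4alk_min_present = 4L,
                            knn_k = 10L,
                            low_presence_percentile = 5,
                            localization_min = 0.75,
                            condition_rate_min = 0.5,
                            gate_alpha = 0.05,
                            omnibus_alpha = 0.05,
                            fdr_q = 0.05,
                            fc_threshold = 2,
                            ksea_min_substrates = 3L,
                            ksea_alpha = 0.05,
                            tail_shift = 1.8,
                            tail_scale = 0.3,
                            protein_driven_ratio = 0.75,
                            gsea_nperm = 1000L,
                            gsea_min_set = 10L,
                            gsea_max_set = 500L,
                            rng_seed = 1L) {
  p <- list(
    presence_fraction = presence_fraction,
    eml4alk_min_present = as.integer(eml4alk_min_present),
    knn_k = as.integer(knn_k),
    low_presence_percentile = low_presence_percentile,
    localization_min = localization_min,
    condition_rate_min = condition_rate_min,
    gate_alpha = gate_alpha,
    omnibus_alpha = omnibus_alpha,
    fdr_q = fdr_q,
    fc_threshold = fc_threshold,
    ksea_min_substrates = as.integer(ksea_min_substrates),
    ksea_alpha = ksea_alpha,
    tail_shift = tail_shift,
    tail_scale = tail_scale,
    protein_driven_ratio = protein_driven_ratio,
    gsea_nperm = as.integer(gsea_nperm),
    gsea_min_set = as.integer(gsea_min_set),
    gsea_max_set = as.integer(gsea_max_set),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    p$presence_fraction > 0, p$presence_fraction <= 1,
    p$eml4alk_min_present >= 1,
    p$knn_k >= 1,
    p$low_presence_percentile > 0, p$low_presence_percentile < 100,
    p$localization_min >= 0, p$localization_min <= 1,
    p$condition_rate_min > 0, p$condition_rate_min <= 1,
    p$gate_alpha > 0, p$gate_alpha < 1,
    p$omnibus_alpha > 0, p$omnibus_alpha < 1,
    p$fdr_q > 0, p$fdr_q < 1,
    p$fc_threshold > 1,
    p$ksea_min_substrates >= 1,
    p$ksea_alpha > 0, p$ksea_alpha < 1,
    p$tail_shift >= 0, p$tail_scale > 0,
    p$protein_driven_ratio > 0, p$protein_driven_ratio <= 1,
    p$gsea_nperm >= 10,
    p$gsea_min_set >= 2, p$gsea_max_set > p$gsea_min_set
  )
  structure(p, class = "phosdiff_params")
}

#' @export
print.phosdiff_params <- function(x, ...) {
  cat("<phosdiff analysis parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

canonical_group <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]+", "_", trimws(x)))
  map <- c(
    EML4_ALK = "EML4_ALK", ALK = "EML4_ALK", EML4ALK = "EML4_ALK",
    EGFR = "EGFR", KRAS = "KRAS", WT = "WT", WILD_TYPE = "WT",
    WILDTYPE = "WT", TRIPLE_WT = "WT"
  )
  key <- sub("^EML4_ALK$", "EML4_ALK", key)
  out <- unname(map[key])
  bad <- unique(x[is.na(out)])
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected one of EML4_ALK, EGFR, KRAS, WT", call. = FALSE)
  }
  out
}
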