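#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: either a
#' synthetic-cohort configuration or paths to input tables, the analysis
#' parameters, the output directory, the master seed, and stage toggles.
#' The master seed is fanned out to fixed per-stage child seeds so a
#' stage's stream does not depend on which other stages are enabled.
#'
#' @param out_dir output directory.
#' @param synth a [synth_config()] used when `input` is `NULL`.
#' @param input optional named list of file paths
#'   (`intensity`, `metadata`, `sites`, `kinase_substrate`) read through
#'   the package readers instead of simulating.
#' @param gmt optional GMT path; when `NULL` on a synthetic run, small
#'   random gene sets over the simulated universe are generated so the
#'   enrichment stage can exercise end-to-end.
#' @param params [analysis_params()].
#' @param seed master integer seed.
#' @param stages stages to run, in fixed order.
#' @param gsea_comparison comparison whose effect-size ranking feeds the
#'   enrichment stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       synth = synth_config(
                         n_features = 1000,
                         spike_design = make_spike_design(20),
                         kinase_design = tibble::tibble(
                           kinase_id = c("KIN_SPIKED", "KIN_DECOY"),
                           n_substrates = c(8L, 8L),
                           target_group = c("EML4_ALK", "EML4_ALK"),
                           shift_log2 = c(2, 0)
                         )
                       ),
                       input = NULL,
                       gmt = NULL,
                       params = analysis_params(),
                       seed = 1L,
                       stages = c("simulate", "preprocess", "diffstats",
                                  "specificity", "ksea", "gsea"),
                       gsea_comparison = "EGFR_vs_WT") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(out_dir = out_dir, synth = synth, input = input,
                 gmt = gmt, params = params, seed = as.integer(seed),
                 stages = stages, gsea_comparison = gsea_comparison),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate (or read) -> preprocess -> differential statistics ->
#' specificity -> KSEA -> GSEA in fixed order, writing each stage's table
#' and a run manifest to `config$out_dir`. Identical config and seed give
#' byte-identical outputs. A failure aborts with the stage name in the
#' error message.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  stages <- config$stages
  res <- list()
  tables <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate / read -------------------------------------------------
  if (!is.null(config$input)) {
    dat <- stage("read", {
      inp <- config$input
      rd <- read_intensity_table(inp$intensity, dialect = "phosphosite")
      list(matrix = rd$matrix, sites = rd$sites,
           meta = read_metadata(inp$metadata),
           ks_map = if (!is.null(inp$kinase_substrate))
             read_kinase_substrate_table(inp$kinase_substrate) else NULL,
           truth = NULL)
    })
  } else {
    if (!"simulate" %in% stages) stop("no input and simulate disabled",
                                      call. = FALSE)
    dat <- stage("simulate", {
      sc <- config$synth
      sc$seed <- config$seed + 101L
      simulate_phospho(sc)
    })
    if (!is.null(dat$truth)) tables$synth_truth <- dat$truth
  }
  res$data <- dat

  # --- preprocess ------------------------------------------------------
  if ("preprocess" %in% stages) {
    pre <- stage("preprocess", {
      m <- log2_transform(dat$matrix)
      m <- localization_filter(m, dat$sites, p)
      pf <- presence_filter(m, dat$meta, p)
      m <- impute_phospho(pf$matrix, dat$meta, p, seed = config$seed + 202L)
      list(matrix = median_scale(m), presence = pf$presence)
    })
    res$preprocess <- pre
    tables$presence_summary <- pre$presence
    tm <- tidy(pre$matrix)
    tables$imputed_matrix <- tm[, c("feature_id", "sample_id", "intensity")]
  }

  # --- diffstats -------------------------------------------------------
  if ("diffstats" %in% stages) {
    stats_tab <- stage("diffstats",
                       analyze_features(res$preprocess$matrix, dat$meta, p))
    res$stats <- stats_tab
    tables$feature_stats <- as.data.frame(stats_tab)
  }

  # --- specificity -----------------------------------------------------
  if ("specificity" %in% stages) {
    spc <- stage("specificity", {
      sig <- significance_matrix(res$stats, p)
      calls <- classify_specific(sig)
      list(calls = calls, summary = summarize_specificity(calls))
    })
    res$specificity <- spc
    tables$specificity_calls <- spc$calls
    tables$specificity_summary <- spc$summary
  }

  # --- ksea ------------------------------------------------------------
  if ("ksea" %in% stages && !is.null(dat$ks_map)) {
    ks <- stage("ksea", ksea_all_comparisons(res$stats, dat$ks_map, p))
    res$ksea <- ks
    tables$ksea_scores <- ks$scores
  }

  # --- gsea ------------------------------------------------------------
  if ("gsea" %in% stages) {
    gs <- stage("gsea", {
      cmp <- comparison_spec()
      cmp <- cmp[cmp$comparison == config$gsea_comparison, ]
      # gene-level ranking: site ids collapse to their gene token
      m <- res$preprocess$matrix
      gene_m <- collapse_to_genes(m)
      ranking <- rank_by_effect_size(gene_m, dat$meta,
                                     cmp$group_a, cmp$group_b)
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else
        synthetic_gene_sets(names(ranking), seed = config$seed + 303L)
      preranked_gsea(ranking, sets, p, seed = config$seed + 304L)
    })
    res$gsea <- gs
    tables$gsea_results <- dplyr::mutate(
      gs$results,
      leading_edge = vapply(.data$leading_edge, paste, "", collapse = ";")
    )
  }

  paths <- write_results(tables, config$out_dir, params = p,
                         seed = config$seed)
  res$paths <- paths
  invisible(res)
}

# mean log2 intensity per gene (site ids "GENE;residue+pos" -> gene)
collapse_to_genes <- function(m) {
  gene <- sub(";.*$", "", feature_ids(m))
  v <- unclass(m)
  agg <- rowsum(v, gene) / as.vector(table(gene)[sort(unique(gene))])
  intensity_matrix(agg[sort(unique(gene)), , drop = FALSE],
                   scale = im_scale(m))
}

# random same-universe gene sets for synthetic end-to-end runs
synthetic_gene_sets <- function(universe, n_sets = 20, seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- sample(15:50, n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, min(k, length(universe))))
  names(sets) <- sprintf("SYNTH_SET_%02d", seq_len(n_sets))
  sets
}
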