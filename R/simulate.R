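#' Synthetic cohort configuration
#'
#' Describes a simulated label-free cohort with the statistical structure
#' the pipeline assumes: four genotype groups (default sizes 6/23/31/22,
#' the design of the lung adenocarcinoma cohort this package models),
#' log-normal intensities (normal on the log2 scale), group-specific spiked
#' effects, and intensity-dependent (MNAR) dropout following a logistic
#' curve in log2 intensity — low-abundance measurements drop out more
#' often, the left-censoring that motivates percentile and tail-based
#' imputation.
#'
#' @param group_sizes named integer vector of samples per genotype group.
#' @param n_features number of simulated features.
#' @param baseline_mean mean of the per-feature baseline log2 intensity.
#' @param feature_sd between-feature SD of the baseline (log2 units).
#' @param noise_sd within-feature residual SD (log2 units).
#' @param spike_design tibble with columns `feature` (row index), `target`
#'   (a group name, or a partition written `"A+B|C+D"`) and `effect_log2`
#'   (signed log2 offset added to the target group / first partition side);
#'   `NULL` for no spikes. See [make_spike_design()].
#' @param dropout_midpoint log2 intensity at which dropout probability is
#'   50%.
#' @param dropout_slope steepness of the logistic dropout curve; `0`
#'   disables dropout.
#' @param loc_prob_alpha,loc_prob_beta Beta parameters for simulated site
#'   localization probabilities (defaults give mean 0.9).
#' @param kinase_design tibble with columns `kinase_id`, `n_substrates`,
#'   `target_group`, `shift_log2` (0 for decoy kinases); `NULL` for none.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(group_sizes = c(EML4_ALK = 6, EGFR = 23,
                                         KRAS = 31, WT = 22),
                         n_features = 2000,
                         baseline_mean = 25,
                         feature_sd = 2,
                         noise_sd = 0.5,
                         spike_design = NULL,
                         dropout_midpoint = 22.5,
                         dropout_slope = 0.8,
                         loc_prob_alpha = 9,
                         loc_prob_beta = 1,
                         kinase_design = NULL,
                         seed = 1L) {
  stopifnot(all(group_sizes >= 2), n_features >= 1, feature_sd >= 0,
            noise_sd >= 0, dropout_slope >= 0,
            loc_prob_alpha > 0, loc_prob_beta > 0)
  if (is.null(names(group_sizes)) ||
      !setequal(names(group_sizes), phosdiff_groups())) {
    stop("`group_sizes` must be named with the four canonical groups",
         call. = FALSE)
  }
  if (!is.null(spike_design)) {
    stopifnot(all(c("feature", "target", "effect_log2") %in%
                    names(spike_design)))
    if (any(spike_design$feature < 1 | spike_design$feature > n_features)) {
      stop("spike feature index out of range", call. = FALSE)
    }
    if (anyDuplicated(spike_design$feature)) {
      stop("each feature may be spiked at most once", call. = FALSE)
    }
    stopifnot(all(is.finite(spike_design$effect_log2)))
  }
  structure(list(
    group_sizes = group_sizes[phosdiff_groups()],
    n_features = as.integer(n_features),
    baseline_mean = baseline_mean, feature_sd = feature_sd,
    noise_sd = noise_sd, spike_design = spike_design,
    dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
    loc_prob_alpha = loc_prob_alpha, loc_prob_beta = loc_prob_beta,
    kinase_design = kinase_design, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Build a simple spike design
#'
#' Assigns `n_spikes` features (rows `1..n_spikes`) round-robin to the four
#' groups — a deterministic design whose features are exchangeable with any
#' others because baselines are drawn independently per feature. Spikes are
#' up-shifts by default, the conventional spike-in: a down-shift pushes a
#' low-abundance feature into the censored (MNAR) regime where every group
#' saturates against the imputation floor and the recoverable fold-change
#' collapses, so signed designs probe that limitation rather than the
#' pipeline (pass `signs = c(1, -1)` to do exactly that).
#'
#' @param n_spikes number of spiked features.
#' @param effect_log2 absolute spiked effect in log2 units.
#' @param groups groups to cycle over.
#' @param signs recycled vector of effect signs.
#' @return A spike-design tibble for [synth_config()].
#' @export
make_spike_design <- function(n_spikes = 40, effect_log2 = 2,
                              groups = phosdiff_groups(), signs = 1) {
  tibble::tibble(
    feature = seq_len(n_spikes),
    target = rep_len(groups, n_spikes),
    effect_log2 = effect_log2 * rep_len(signs, n_spikes)
  )
}

# delta matrix (feature x group) of true log2 offsets implied by a design
spike_offsets <- function(config) {
  groups <- phosdiff_groups()
  delta <- matrix(0, config$n_features, 4, dimnames = list(NULL, groups))
  sd <- config$spike_design
  if (!is.null(sd)) {
    for (i in seq_len(nrow(sd))) {
      tgt <- sd$target[i]
      if (grepl("|", tgt, fixed = TRUE)) {
        side1 <- strsplit(strsplit(tgt, "|", fixed = TRUE)[[1]][1], "+",
                          fixed = TRUE)[[1]]
        delta[sd$feature[i], side1] <- delta[sd$feature[i], side1] +
          sd$effect_log2[i]
      } else {
        stopifnot(tgt %in% groups)
        delta[sd$feature[i], tgt] <- delta[sd$feature[i], tgt] +
          sd$effect_log2[i]
      }
    }
  }
  delta
}

#' Simulate a label-free proteomic cohort
#'
#' Draws per-feature baselines `mu_f ~ N(baseline_mean, feature_sd)`, adds
#' the designed group offsets and residual noise `N(0, noise_sd)` on the
#' log2 scale, exponentiates to raw intensities, and censors cells at
#' random with probability `plogis((dropout_midpoint - log2(value)) *
#' dropout_slope)` so that dropout is missing-not-at-random in intensity.
#'
#' @param config a [synth_config()].
#' @param feature_ids optional feature id vector (default `PROT0001`...).
#' @return A list with `matrix` (raw-scale [intensity_matrix()]), `meta`
#'   (sample metadata tibble) and `truth` (per-feature tibble with the
#'   spiked flag, target, effect and true group means of the log2 signal).
#' @export
simulate_cohort <- function(config, feature_ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  groups <- phosdiff_groups()
  gs <- config$group_sizes
  sample_group <- rep(groups, times = gs)
  sample_id <- unlist(lapply(groups, function(g) {
    paste0(g, "_", seq_len(gs[[g]]))
  }))
  n <- config$n_features
  if (is.null(feature_ids)) feature_ids <- sprintf("PROT%04d", seq_len(n))

  mu <- stats::rnorm(n, config$baseline_mean, config$feature_sd)
  delta <- spike_offsets(config)
  signal <- mu + delta[, sample_group, drop = FALSE]
  log2val <- signal + stats::rnorm(n * length(sample_id), 0, config$noise_sd)
  dimnames(log2val) <- list(feature_ids, sample_id)

  raw <- 2^log2val
  if (config$dropout_slope > 0) {
    p_miss <- stats::plogis((config$dropout_midpoint - log2val) *
                              config$dropout_slope)
    raw[stats::runif(length(raw)) < p_miss] <- NA_real_
  }

  sd_ <- config$spike_design
  truth <- tibble::tibble(
    feature_id = feature_ids,
    spiked = FALSE, target = NA_character_, effect_log2 = NA_real_
  )
  if (!is.null(sd_)) {
    truth$spiked[sd_$feature] <- TRUE
    truth$target[sd_$feature] <- sd_$target
    truth$effect_log2[sd_$feature] <- sd_$effect_log2
  }
  means <- mu + delta
  colnames(means) <- paste0("mean_", groups)
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(means))

  list(
    matrix = intensity_matrix(raw, scale = "raw"),
    meta = tibble::tibble(sample_id = sample_id, group = sample_group),
    truth = truth
  )
}

#' Simulate a phosphoproteomic cohort with kinase-driven shifts
#'
#' As [simulate_cohort()], with phosphosite trimmings: features are named
#' `"GENEnnnn;S<pos>"`, each carries a localization probability drawn from
#' `Beta(loc_prob_alpha, loc_prob_beta)`, and the substrates of each
#' designed kinase receive that kinase's `shift_log2` in its target group —
#' a coordinated shift that KSEA should detect. Decoy kinases
#' (`shift_log2 = 0`) get substrates whose sites carry no shift, so their
#' expected activity score is zero. Kinase substrates are assigned from
#' features left untouched by `spike_design`.
#'
#' @param config a [synth_config()] with an optional `kinase_design`.
#' @return A list with `matrix`, `meta`, `truth` (as [simulate_cohort()],
#'   plus a `substrate_of` column), `sites` (annotation tibble with
#'   localization probabilities) and `ks_map` (kinase -> site ids list).
#' @export
simulate_phospho <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_features
  kd <- config$kinase_design
  # fold kinase shifts into the spike design as extra single-group offsets
  substrate_rows <- integer(0)
  substrate_of <- rep(NA_character_, n)
  if (!is.null(kd)) {
    stopifnot(all(c("kinase_id", "n_substrates", "target_group",
                    "shift_log2") %in% names(kd)))
    taken <- if (is.null(config$spike_design)) integer(0) else
      config$spike_design$feature
    free <- setdiff(seq_len(n), taken)
    need <- sum(kd$n_substrates)
    if (need > length(free)) stop("not enough free features for kinase substrates",
                                  call. = FALSE)
    idx <- utils::head(free, need)
    off <- 0L
    extra <- list()
    for (i in seq_len(nrow(kd))) {
      rows <- idx[(off + 1):(off + kd$n_substrates[i])]
      off <- off + kd$n_substrates[i]
      substrate_of[rows] <- kd$kinase_id[i]
      if (kd$shift_log2[i] != 0) {
        extra[[length(extra) + 1]] <- tibble::tibble(
          feature = rows, target = kd$target_group[i],
          effect_log2 = kd$shift_log2[i]
        )
      }
      substrate_rows <- c(substrate_rows, rows)
    }
    if (length(extra) > 0) {
      config$spike_design <- dplyr::bind_rows(
        config$spike_design, dplyr::bind_rows(extra)
      )
    }
  }

  # site ids: one site per synthetic gene, S/T residues dominate
  set.seed(config$seed + 7L)
  residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                    prob = c(0.75, 0.2, 0.05))
  position <- sample.int(900, n, replace = TRUE)
  site_ids <- sprintf("GENE%04d;%s%d", seq_len(n), residue, position)
  loc_prob <- stats::rbeta(n, config$loc_prob_alpha, config$loc_prob_beta)

  sim <- simulate_cohort(config, feature_ids = site_ids)
  sim$truth$substrate_of <- substrate_of
  # spiked flag should reflect designed single/partition spikes, not kinase
  sim$truth$spiked[substrate_rows] <- FALSE

  sites <- tibble::tibble(
    site_id = site_ids,
    protein_id = sprintf("GENE%04d", seq_len(n)),
    residue = residue, position = position,
    localization_probability = loc_prob
  )
  ks_map <- NULL
  if (!is.null(kd)) {
    ks_map <- lapply(stats::setNames(kd$kinase_id, kd$kinase_id),
                     function(k) site_ids[which(substrate_of == k)])
  }
  kinase_truth <- if (is.null(kd)) NULL else kd
  list(matrix = sim$matrix, meta = sim$meta, truth = sim$truth,
       sites = sites, ks_map = ks_map, kinase_truth = kinase_truth)
}

#' Synthetic differential-result table with a designed significance
#' architecture
#'
#' Builds a long-format statistics table (feature x six comparisons, with
#' per-feature BH-adjusted p-values and signed log2 fold-changes) whose
#' composition — how many features are significant with fold-change > 2,
#' how many are alteration-specific per group (including doubly-labelled
#' features), partition-patterned, or significant without passing the
#' fold-change rule — is specified by a design. This is a synthetic
#' stand-in for a published-style per-comparison result table; the built-in
#' designs (`result_table_design("protein")`, `"phospho"`) mirror the
#' significance architecture reported for the modelled lung adenocarcinoma
#' cohort, so applying the significance and specificity rules to the
#' generated numbers must recover the designed counts.
#'
#' Raw p-values for significant cells are drawn well below the threshold
#' and for null cells well above it, then BH-adjusted within feature, so
#' the designed pattern survives adjustment by construction.
#'
#' @param design a list as returned by [result_table_design()].
#' @param seed integer seed.
#' @return A list with `stats` (long tibble compatible with
#'   [significance_matrix()]) and `truth` (designed per-feature category
#'   labels).
#' @export
simulate_result_table <- function(design = result_table_design("protein"),
                                  seed = 1L) {
  set.seed(seed)
  spec <- comparison_spec()
  groups <- phosdiff_groups()
  partitions <- list(
    c("EML4_ALK+EGFR", "KRAS+WT"),
    c("EML4_ALK+KRAS", "EGFR+WT"),
    c("EML4_ALK+WT", "EGFR+KRAS")
  )

  rows <- list()   # each: list(category, sign6) ; sign6 in {-1,0,1}
  oriented_sign <- function(g, dir) {
    # sign vector for a feature specific to group g with direction dir
    s <- integer(6)
    for (j in seq_len(6)) {
      if (spec$group_a[j] == g) s[j] <- dir
      if (spec$group_b[j] == g) s[j] <- -dir
    }
    s
  }
  dir_cycle <- c(1, -1)

  for (g in names(design$single)) {
    k <- design$single[[g]]
    for (i in seq_len(k)) {
      rows[[length(rows) + 1]] <- list(
        category = "group", label = g,
        sign = oriented_sign(g, dir_cycle[1 + i %% 2])
      )
    }
  }
  for (pair in design$double) {
    s <- oriented_sign(pair[1], 1L)
    s2 <- oriented_sign(pair[2], -1L)
    comb <- s
    comb[s2 != 0] <- s2[s2 != 0]
    # the shared comparison gets the (consistent) group-1 orientation
    shared <- which(s != 0 & s2 != 0)
    comb[shared] <- s[shared]
    rows[[length(rows) + 1]] <- list(
      category = "double", label = paste(pair, collapse = "+"), sign = comb
    )
  }
  for (i in seq_len(design$partition)) {
    part <- partitions[[1 + (i - 1) %% 3]]
    side1 <- strsplit(part[1], "+", fixed = TRUE)[[1]]
    dir <- dir_cycle[1 + i %% 2]
    s <- integer(6)
    for (j in seq_len(6)) {
      a_in <- spec$group_a[j] %in% side1
      b_in <- spec$group_b[j] %in% side1
      if (a_in && !b_in) s[j] <- dir
      if (!a_in && b_in) s[j] <- -dir
    }
    rows[[length(rows) + 1]] <- list(
      category = "partition", label = paste(part, collapse = "|"), sign = s
    )
  }
  for (i in seq_len(design$nonspecific_fc)) {
    s <- integer(6)
    s[1 + (i - 1) %% 6] <- dir_cycle[1 + i %% 2]
    rows[[length(rows) + 1]] <- list(category = "nonspecific_fc",
                                     label = NA_character_, sign = s)
  }
  for (i in seq_len(design$sig_only)) {
    s <- integer(6)
    s[1 + (i - 1) %% 6] <- 9L  # marker: significant p, sub-threshold fc
    rows[[length(rows) + 1]] <- list(category = "sig_only",
                                     label = NA_character_, sign = s)
  }

  n <- length(rows)
  ids <- design$id_maker(seq_len(n))
  stats <- vector("list", n)
  tests <- c("Student_t", "Welch_t", "Wilcoxon")
  omni <- c("ANOVA", "Welch_ANOVA", "Kruskal_Wallis")
  for (i in seq_len(n)) {
    s <- rows[[i]]$sign
    sig <- s != 0
    raw_p <- ifelse(sig, stats::runif(6, 1e-6, 1e-3), stats::runif(6, 0.3, 1))
    fdr <- stats::p.adjust(raw_p, method = "BH")
    log2fc <- ifelse(
      s == 9L, stats::runif(6, 0.2, 0.9),
      ifelse(sig, sign(s) * stats::runif(6, 1.2, 3.5),
             stats::runif(6, -0.8, 0.8))
    )
    stats[[i]] <- tibble::tibble(
      feature_id = ids[i],
      comparison = spec$comparison,
      omnibus_test = sample(omni, 1),
      omnibus_p = stats::runif(1, 1e-6, 1e-3),
      pairwise_test = sample(tests, 6, replace = TRUE),
      raw_p = raw_p, fdr = fdr, log2fc = log2fc
    )
  }
  truth <- tibble::tibble(
    feature_id = ids,
    category = vapply(rows, `[[`, "", "category"),
    label = vapply(rows, function(r) as.character(r$label), "")
  )
  list(stats = dplyr::bind_rows(stats), truth = truth)
}

#' @rdname simulate_result_table
#' @param dataset `"protein"` or `"phospho"`.
#' @export
result_table_design <- function(dataset = c("protein", "phospho")) {
  dataset <- match.arg(dataset)
  if (dataset == "protein") {
    list(
      single = c(EML4_ALK = 13, EGFR = 16, KRAS = 2, WT = 5),
      double = list(),
      partition = 7,
      nonspecific_fc = 123,
      sig_only = 338,
      id_maker = function(i) sprintf("PROT%04d", i)
    )
  } else {
    list(
      single = c(EML4_ALK = 17, EGFR = 11, KRAS = 9, WT = 13),
      double = list(c("EML4_ALK", "WT"), c("EGFR", "KRAS")),
      partition = 17,
      nonspecific_fc = 114,
      sig_only = 28,
      id_maker = function(i) sprintf("GENE%04d;S%d", i, i)
    )
  }
}
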