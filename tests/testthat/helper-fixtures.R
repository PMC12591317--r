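# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# tiny balanced metadata: `n` samples per canonical group
tiny_meta <- function(n = 2) {
  g <- rep(phosdiff_groups(), each = n)
  tibble::tibble(sample_id = paste0(g, "_", sequence(rep(n, 4))), group = g)
}

# intensity matrix from a plain matrix, auto-naming rows/cols
im <- function(values, scale = "log2", meta = NULL,
               feature_ids = sprintf("F%02d", seq_len(nrow(values)))) {
  cn <- if (!is.null(meta)) meta$sample_id else
    sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(feature_ids, cn)
  intensity_matrix(values, scale = scale)
}

# write a MaxQuant-style protein TSV and return its path
write_protein_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# long stats tibble from named per-feature lists of fdr / log2fc 6-vectors
stats_from_vectors <- function(fdr_list, fc_list) {
  spec <- comparison_spec()
  purrr::map_dfr(names(fdr_list), function(id) {
    tibble::tibble(
      feature_id = id, comparison = spec$comparison,
      raw_p = fdr_list[[id]], fdr = fdr_list[[id]],
      log2fc = fc_list[[id]]
    )
  })
}

# independent brute-force BH step-up (sort, p*n/rank, cumulative min from
# the largest rank down, cap at 1, unsort)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in seq(n - 1, 1, length.out = max(0, n - 1))) {
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# independent brute-force specificity rule evaluator over one sign vector
classify_brute <- function(s) {
  spec <- comparison_spec()
  groups <- phosdiff_groups()
  out <- list()
  for (g in groups) {
    oriented <- c()
    for (j in 1:6) {
      if (spec$group_a[j] == g) oriented <- c(oriented, s[j])
      else if (spec$group_b[j] == g) oriented <- c(oriented, -s[j])
    }
    if (length(oriented) == 3 && all(oriented == 1)) {
      out[[length(out) + 1]] <- paste0(g, ":UP")
    }
    if (length(oriented) == 3 && all(oriented == -1)) {
      out[[length(out) + 1]] <- paste0(g, ":DOWN")
    }
  }
  if (length(out) == 0) {
    sides <- list(c(1, 2), c(1, 3), c(1, 4))
    for (sd1 in sides) {
      side1 <- groups[sd1]
      ok_up <- TRUE
      ok_dn <- TRUE
      for (j in 1:6) {
        a_in <- spec$group_a[j] %in% side1
        b_in <- spec$group_b[j] %in% side1
        if (a_in == b_in) {
          if (s[j] != 0) { ok_up <- FALSE; ok_dn <- FALSE }
        } else {
          or <- if (a_in) s[j] else -s[j]
          if (or != 1) ok_up <- FALSE
          if (or != -1) ok_dn <- FALSE
        }
      }
      lab <- paste(paste(side1, collapse = "+"),
                   paste(setdiff(groups, side1), collapse = "+"), sep = "|")
      if (ok_up) out[[length(out) + 1]] <- paste0(lab, ":UP")
      if (ok_dn) out[[length(out) + 1]] <- paste0(lab, ":DOWN")
    }
  }
  if (length(out) > 0) return(sort(unlist(out)))
  if (all(s == 0)) "none" else "mixed"
}

# tweak a synth_config field without re-validating through the constructor
modifyList_synth <- function(cfg, ...) {
  out <- unclass(cfg)
  args <- list(...)
  for (n in names(args)) out[[n]] <- args[[n]]
  structure(out, class = "synth_config")
}
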