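#' Write result tables with a run manifest
#'
#' Writes each table as TSV with a deterministic column order (the order the
#' pipeline produced) and a `manifest.json` recording the package version,
#' analysis parameters, seed and an md5 checksum per written file, so a run
#' can be reproduced and verified byte-for-byte.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param params [analysis_params()] echoed into the manifest.
#' @param seed seed echoed into the manifest.
#' @return Invisibly, a character vector of written file paths (manifest
#'   last).
#' @export
write_results <- function(tables, out_dir, params = analysis_params(),
                          seed = params$rng_seed) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as.data.frame(tables[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "phosdiff",
    version = as.character(utils::packageVersion("phosdiff")),
    seed = seed,
    parameters = unclass(params),
    percentile_method = "linear interpolation (type 7)",
    ksea_delta = "sample (n-1) standard deviation",
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) list(md5 = unname(tools::md5sum(p))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

#' Write / read an intensity matrix as TSV
#'
#' Round-trip-exact serialisation: missing cells are written as `NA`, the
#' scale is recorded in a header comment line, and feature/sample order is
#' preserved.
#'
#' @param m an [intensity_matrix()].
#' @param path file path.
#' @return `write_intensity_matrix()` returns `path` invisibly;
#'   `read_intensity_matrix()` returns the reconstructed
#'   [intensity_matrix()].
#' @export
write_intensity_matrix <- function(m, path) {
  writeLines(paste0("# scale=", im_scale(m)), path)
  df <- data.frame(feature_id = feature_ids(m), unclass(m),
                   check.names = FALSE)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(path) {
  header <- readLines(path, n = 1)
  scale <- sub("^# scale=", "", header)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  intensity_matrix(vals, scale = scale)
}
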