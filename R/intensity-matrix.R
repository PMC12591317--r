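#' Feature-by-sample intensity matrix
#'
#' The container every pipeline stage transforms: a numeric matrix of
#' label-free intensities with features as rows and samples as columns.
#' Missing measurements are stored as `NA` (the missingness mask) so no
#' statistic can silently consume an unobserved cell. The `scale` attribute
#' records whether values are raw intensities or log2-transformed; the
#' transformation is applied exactly once by [log2_transform()].
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); `NA` marks missing cells.
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An `intensity_matrix` object.
#' @examples
#' m <- intensity_matrix(matrix(2^rnorm(6, 20), 3, 2,
#'   dimnames = list(paste0("P", 1:3), c("s1", "s2"))))
#' dim(m)
#' @export
intensity_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  structure(values, scale = scale, class = c("intensity_matrix", "matrix"))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "<intensity_matrix> %d features x %d samples [%s scale], %.1f%% missing\n",
    nrow(x), ncol(x), im_scale(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

im_scale <- function(m) attr(m, "scale")

feature_ids <- function(m) rownames(m)

sample_ids <- function(m) colnames(m)

#' Missingness mask of an intensity matrix
#'
#' @param m an [intensity_matrix()].
#' @return Logical matrix, `TRUE` where the measurement is missing.
#' @export
missing_mask <- function(m) is.na(unclass(m))

im_replace <- function(m, values, scale = im_scale(m)) {
  dimnames(values) <- dimnames(m)
  structure(values, scale = scale, class = c("intensity_matrix", "matrix"))
}

# subset while keeping class/scale
im_subset <- function(m, i = NULL, j = NULL) {
  v <- unclass(m)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  structure(v, scale = im_scale(m), class = c("intensity_matrix", "matrix"))
}

#' Tidy an intensity matrix into long format
#'
#' @param x an [intensity_matrix()].
#' @param ... unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `intensity`
#'   (`NA` when missing) and `missing`.
#' @method tidy intensity_matrix
#' @export
tidy.intensity_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(feature_ids(x), times = ncol(x)),
    sample_id = rep(sample_ids(x), each = nrow(x)),
    intensity = as.vector(unclass(x)),
    missing = as.vector(is.na(unclass(x)))
  )
}

#' @method glance intensity_matrix
#' @export
glance.intensity_matrix <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_samples = ncol(x),
    scale = im_scale(x),
    missing_fraction = mean(is.na(x))
  )
}

#' Validate sample metadata against an intensity matrix
#'
#' Sample metadata is a tibble with `sample_id` and `group` columns (group
#' one of the four canonical genotype labels), optionally clinical
#' covariates. Every sample column of the matrix must appear exactly once.
#'
#' @param meta metadata tibble.
#' @param m optional [intensity_matrix()] to cross-check sample ids against.
#' @return `meta`, invisibly, after validation.
#' @export
validate_metadata <- function(meta, m = NULL) {
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata needs `sample_id` and `group` columns", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id(s) in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(meta$group %in% phosdiff_groups())) {
    stop("non-canonical group labels; run read_metadata() or canonicalise",
         call. = FALSE)
  }
  tab <- table(meta$group)
  if (any(tab < 2)) {
    stop("every group needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (!is.null(m)) {
    missing <- setdiff(sample_ids(m), meta$sample_id)
    if (length(missing) > 0) {
      stop("samples absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(meta)
}

# named list group -> character vector of sample ids present in m
group_samples <- function(meta, m) {
  validate_metadata(meta, m)
  keep <- meta$sample_id %in% sample_ids(m)
  split(meta$sample_id[keep], factor(meta$group[keep], phosdiff_groups()))
}
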