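#' Read a MaxQuant-style intensity table
#'
#' Reads a tab-separated protein-groups or phosphosite table in the
#' simplified one-intensity-column-per-sample dialect. Sample columns are
#' recognised by a prefix (`"LFQ intensity "` for proteins, `"Intensity "`
#' for phosphosites by default); zero and blank cells are treated as
#' missing, following the label-free quantification convention that a zero
#' means "not quantified", not "absent at zero abundance". Contaminant and
#' decoy rows (feature ids prefixed `CON__` / `REV__`) are dropped and
#' counted.
#'
#' @param path file path.
#' @param dialect `"protein"` or `"phosphosite"`. The phosphosite dialect
#'   additionally requires a `Localization prob` column and uses the
#'   `Site ID` column (`"GENE;residue+position"`) as feature id.
#' @param intensity_prefix overrides the default sample-column prefix.
#' @param id_col overrides the default feature-id column (`"Protein IDs"`
#'   for proteins, `"Site ID"` for phosphosites; falls back to the first
#'   column if the default is absent for the protein dialect).
#'
#' @return A list with elements `matrix` (an [intensity_matrix()], raw
#'   scale), `sites` (tibble of site annotations with
#'   `localization_probability`, phosphosite dialect only, else `NULL`) and
#'   `n_dropped` (contaminant/decoy rows removed).
#' @export
read_intensity_table <- function(path,
                                 dialect = c("protein", "phosphosite"),
                                 intensity_prefix = NULL,
                                 id_col = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(intensity_prefix)) {
    intensity_prefix <- if (dialect == "protein") "LFQ intensity " else "Intensity "
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  sample_cols <- names(tab)[startsWith(names(tab), intensity_prefix)]
  if (length(sample_cols) == 0) {
    stop("no sample intensity columns found with prefix \"",
         intensity_prefix, "\"", call. = FALSE)
  }
  if (is.null(id_col)) {
    id_col <- if (dialect == "protein") "Protein IDs" else "Site ID"
    if (dialect == "protein" && !id_col %in% names(tab)) id_col <- names(tab)[1]
  }
  if (!id_col %in% names(tab)) {
    stop("feature id column \"", id_col, "\" not found", call. = FALSE)
  }
  if (dialect == "phosphosite" && !"Localization prob" %in% names(tab)) {
    stop("phosphosite dialect requires a \"Localization prob\" column",
         call. = FALSE)
  }

  ids <- tab[[id_col]]
  drop <- startsWith(ids, "CON__") | startsWith(ids, "REV__")
  n_dropped <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  ids <- ids[!drop]
  if (anyDuplicated(ids)) {
    stop("duplicated feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  vals <- vapply(sample_cols, function(cl) {
    x <- suppressWarnings(as.numeric(tab[[cl]]))
    x[!is.na(x) & x == 0] <- NA_real_
    x
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, substring(sample_cols,
                                                nchar(intensity_prefix) + 1L)))

  sites <- NULL
  if (dialect == "phosphosite") {
    parsed <- parse_site_id(ids)
    sites <- tibble::tibble(
      site_id = ids,
      protein_id = parsed$gene,
      residue = parsed$residue,
      position = parsed$position,
      localization_probability = as.numeric(tab[["Localization prob"]])
    )
    if (any(is.na(sites$localization_probability)) ||
        any(sites$localization_probability < 0 |
            sites$localization_probability > 1)) {
      stop("localization probabilities must lie in [0, 1]", call. = FALSE)
    }
  }

  list(matrix = intensity_matrix(vals, scale = "raw"),
       sites = sites, n_dropped = n_dropped)
}

# "GENE;residue+position" -> list(gene, residue, position); NA where invalid
parse_site_id <- function(x) {
  ok <- grepl("^[^;]+;[STY][0-9]+$", x)
  gene <- ifelse(ok, sub(";.*$", "", x), NA_character_)
  res <- ifelse(ok, sub("^[^;]+;([STY])[0-9]+$", "\\1", x), NA_character_)
  pos <- rep(NA_integer_, length(x))
  pos[ok] <- as.integer(sub("^[^;]+;[STY]([0-9]+)$", "\\1", x[ok]))
  list(gene = gene, residue = res, position = pos, valid = ok)
}

#' Read sample metadata
#'
#' Expects a CSV or TSV with `sample_id` and `group` columns; group labels
#' are matched case-insensitively against the four canonical genotype
#' groups (`EML4_ALK`, `EGFR`, `KRAS`, `WT`), accepting common spelling
#' variants ("EML4-ALK", "wild-type"). Any other label is an error.
#'
#' @param path file path (delimiter inferred from content).
#' @return A tibble with canonical `group` values plus any covariate
#'   columns present.
#' @export
read_metadata <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must contain `sample_id` and `group` columns",
         call. = FALSE)
  }
  meta$group <- canonical_group(meta$group)
  validate_metadata(meta)
  meta
}

#' Read gene sets in GMT format
#'
#' Standard GMT semantics: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`; duplicate members within a set are
#' deduplicated.
#'
#' @param path file path.
#' @return A named list of character vectors (set members), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nms <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  sets
}

#' Read a kinase-substrate annotation table
#'
#' Accepts a PhosphoSitePlus-style TSV with either a combined substrate
#' site column (`"GENE;residue+position"`) or separate gene / residue /
#' position columns (auto-detected). Rows whose site fails the syntactic
#' check (residue must be S, T or Y; position >= 1) are skipped with a
#' warning; duplicates collapse under set semantics.
#'
#' @param path file path.
#' @param kinase_col,site_col optional explicit column names.
#' @return A named list mapping kinase id to a character vector of site
#'   ids.
#' @export
read_kinase_substrate_table <- function(path, kinase_col = NULL,
                                        site_col = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  nml <- tolower(names(tab))
  if (is.null(kinase_col)) {
    kinase_col <- names(tab)[match(TRUE, nml %in% c("kinase", "kinase_id", "gene"))]
  }
  if (is.na(kinase_col) || is.null(kinase_col)) {
    stop("could not detect a kinase column", call. = FALSE)
  }
  if (is.null(site_col)) {
    site_col <- names(tab)[match(TRUE, nml %in% c("site", "site_id",
                                                  "substrate", "sub_site"))]
  }
  if (!is.na(site_col) && !is.null(site_col) && site_col %in% names(tab)) {
    sites <- tab[[site_col]]
  } else {
    gene_col <- names(tab)[match(TRUE, nml %in% c("sub_gene", "substrate_gene"))]
    rsd_col <- names(tab)[match(TRUE, nml %in% c("sub_mod_rsd", "residue_position", "rsd"))]
    if (is.na(gene_col) || is.na(rsd_col)) {
      stop("could not detect substrate site columns", call. = FALSE)
    }
    sites <- paste0(tab[[gene_col]], ";", tab[[rsd_col]])
  }
  valid <- parse_site_id(sites)$valid
  if (any(!valid)) {
    warning(sum(!valid), " malformed substrate site(s) skipped, e.g. ",
            sites[!valid][1], call. = FALSE)
  }
  kin <- tab[[kinase_col]][valid]
  sites <- sites[valid]
  if (length(sites) == 0) stop("no valid kinase-substrate rows", call. = FALSE)
  lapply(split(sites, kin), unique)
}
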