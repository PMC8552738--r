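#' @importFrom rlang .data abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# ---- internal representation helpers ----------------------------------------

#' Convert a feature-table tibble to a counts matrix
#'
#' Feature tables are wide tibbles: a `feature_id` character column followed by
#' one numeric column per sample. This returns the features x samples matrix
#' with dimnames.
#'
#' @param tbl A feature-table tibble.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
feature_matrix <- function(tbl) {
  tbl <- validate_feature_table(tbl, integer_counts = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$feature_id
  m
}

#' Build a feature-table tibble from a counts matrix
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param integer_counts Passed to [validate_feature_table()]; set `FALSE` for
#'   proportion matrices.
#' @return A feature-table tibble (`feature_id` + one column per sample).
#' @export
as_feature_table <- function(m, integer_counts = TRUE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(feature_id = rownames(m)) |> dplyr::bind_cols(out)
  validate_feature_table(out, integer_counts = integer_counts)
}

#' Validate a feature table
#'
#' Checks the invariants of a counts table: a `feature_id` first column,
#' unique feature and sample ids, non-negative finite integer-valued counts,
#' at least one feature and two samples.
#'
#' @param tbl A candidate feature-table tibble or data frame.
#' @param integer_counts Require counts to be whole numbers (default `TRUE`;
#'   set `FALSE` for relative-abundance tables).
#' @return The validated tibble, invisibly classed as-is.
#' @export
validate_feature_table <- function(tbl, integer_counts = TRUE) {
  if (!is.data.frame(tbl)) abort("feature table must be a data frame")
  tbl <- as_tibble(tbl)
  if (ncol(tbl) < 3L) abort("feature table needs a feature_id column and at least 2 samples")
  if (names(tbl)[1] != "feature_id") names(tbl)[1] <- "feature_id"
  ids <- as.character(tbl$feature_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate feature ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samp <- names(tbl)[-1]
  if (anyDuplicated(samp)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(samp[duplicated(samp)]), collapse = ", ")))
  }
  if (nrow(tbl) < 1L) abort("feature table has no features")
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("counts must be numeric")
  if (anyNA(vals) || any(!is.finite(vals))) abort("counts must be finite and non-missing")
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at feature '%s', sample '%s'",
                  ids[bad[1]], samp[bad[2]]))
  }
  if (integer_counts && any(vals != round(vals))) {
    bad <- which(vals != round(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count at feature '%s', sample '%s'",
                  ids[bad[1]], samp[bad[2]]))
  }
  tbl$feature_id <- ids
  tbl
}

# ---- readers / writers -------------------------------------------------------

#' Read a feature count table from TSV
#'
#' Expects the QIIME-style "classic" layout: first column feature ids, header
#' row sample ids, integer counts in the cells.
#'
#' @param path Path to a tab-separated file.
#' @return A validated feature-table tibble.
#' @export
read_feature_table <- function(path) {
  header <- readr::read_lines(path, n_max = 1L)
  if (length(header) == 0L || !nzchar(header)) abort("no samples: feature table is empty")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 2L) abort("no samples: feature table has no sample columns")
  types <- readr::cols(.default = readr::col_double())
  types$cols[[cols[1]]] <- readr::col_character()
  tbl <- suppressWarnings(
    readr::read_tsv(path, col_types = types, progress = FALSE)
  )
  if (nrow(tbl) < 1L) abort("no samples: feature table has no feature rows")
  names(tbl)[1] <- "feature_id"
  prob <- which(is.na(as.matrix(tbl[, -1, drop = FALSE])), arr.ind = TRUE)
  if (nrow(prob)) {
    abort(sprintf("cannot parse count at feature '%s', sample '%s'",
                  tbl$feature_id[prob[1, 1]], names(tbl)[-1][prob[1, 2]]))
  }
  validate_feature_table(tbl)
}

#' Write a feature table as TSV
#'
#' @param tbl Feature-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_tsv(validate_feature_table(tbl, integer_counts = FALSE), path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two-or-more-column TSV: feature id, then a lineage string with levels
#' separated by ";" (e.g. `"Bacteria;Proteobacteria;...;USCgamma"`). The
#' terminal non-empty level is exposed as the display label; empty or missing
#' levels become `"unclassified"`.
#'
#' @param path Path to a TSV with columns `feature_id`, `lineage`.
#' @return Tibble with `feature_id`, `lineage`, `label`.
#' @export
read_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) < 2L) abort("taxonomy table needs feature_id and lineage columns")
  names(tbl)[1:2] <- c("feature_id", "lineage")
  make_taxonomy(tbl$feature_id, tbl$lineage)
}

#' Build a taxonomy tibble from ids and lineage strings
#'
#' @param feature_id Character vector of feature ids.
#' @param lineage Character vector of ";"-separated lineages.
#' @return Tibble with `feature_id`, `lineage`, `label` (terminal level;
#'   `"unclassified"` where no informative level exists).
#' @export
make_taxonomy <- function(feature_id, lineage) {
  if (anyDuplicated(feature_id)) abort("duplicate feature ids in taxonomy")
  lineage <- ifelse(is.na(lineage) | lineage == "", "unclassified", lineage)
  label <- vapply(strsplit(lineage, ";", fixed = TRUE), function(lv) {
    lv <- trimws(lv)
    lv <- lv[lv != "" & !is.na(lv)]
    if (length(lv) == 0) "unclassified" else lv[length(lv)]
  }, character(1))
  tibble(feature_id = as.character(feature_id), lineage = lineage, label = label)
}

#' Write a taxonomy table as TSV
#' @param tax Taxonomy tibble from [read_taxonomy()] or [make_taxonomy()].
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  readr::write_tsv(tax[, c("feature_id", "lineage")], path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV keyed by sample id in the first column; remaining columns are numeric
#' environmental variables (pH, ion concentrations in mg/kg, CH4 and CO2 in
#' ppm, element ratios) or categorical design factors (cave, site, niche).
#'
#' @param path Path to a TSV.
#' @return Tibble with `sample_id` first.
#' @export
read_sample_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) abort("duplicate sample ids in metadata")
  tbl
}

#' Write sample metadata as TSV
#' @param metadata Metadata tibble.
#' @param path Output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' Check that every sample of a feature table has a metadata row
#'
#' @param tbl Feature-table tibble.
#' @param metadata Metadata tibble with `sample_id`.
#' @return Invisibly `TRUE`; errors naming missing samples otherwise.
#' @export
check_metadata_complete <- function(tbl, metadata) {
  samples <- names(tbl)[-1]
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing)) {
    abort(paste0("samples missing from metadata: ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# ---- transforms --------------------------------------------------------------

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total so columns sum to 1.
#'
#' @param tbl Feature-table tibble of counts.
#' @return Feature-table tibble of proportions.
#' @export
to_relative_abundance <- function(tbl) {
  m <- feature_matrix(tbl)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  as_feature_table(sweep(m, 2, tot, "/"), integer_counts = FALSE)
}

#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (multivariate hypergeometric) of each
#' sample's reads to a common depth, so diversity comparisons are not driven by
#' sequencing effort.
#'
#' @param tbl Feature-table tibble of counts.
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; rarefaction is random and the seed is mandatory so
#'   runs are reproducible.
#' @param drop_small Drop samples whose total is below `depth` instead of
#'   erroring (default `FALSE`).
#' @return Feature-table tibble in which every sample sums to `depth`.
#' @export
rarefy_counts <- function(tbl, depth, seed, drop_small = FALSE) {
  stopifnot(length(depth) == 1L, depth >= 1, depth == round(depth))
  m <- feature_matrix(tbl)
  tot <- colSums(m)
  shallow <- colnames(m)[tot < depth]
  if (length(shallow)) {
    if (!drop_small) {
      abort(paste0("rarefaction depth ", depth, " exceeds total counts of sample(s): ",
                   paste(shallow, collapse = ", ")))
    }
    m <- m[, tot >= depth, drop = FALSE]
    if (ncol(m) < 2L) abort("fewer than 2 samples remain after depth filtering")
  }
  set.seed(as.integer(seed))
  # vegan::rrarefy works on samples-as-rows community matrices
  r <- t(suppressWarnings(vegan::rrarefy(t(m), depth)))
  storage.mode(r) <- "double"
  as_feature_table(r)
}

#' Prevalence/abundance filter for network candidates
#'
#' Keeps features whose mean relative abundance across samples is strictly
#' above `min_mean_relabund` and which are detected (nonzero) in strictly more
#' than a fraction `min_occurrence` of samples. The defaults are the common
#' complexity-reduction rule for amplicon cooccurrence networks: mean relative
#' abundance above 0.1% and occurrence above 20%.
#'
#' @param tbl Feature-table tibble of counts.
#' @param min_mean_relabund Mean relative-abundance threshold in \[0,1\]
#'   (default 0.001). Strict.
#' @param min_occurrence Occurrence-fraction threshold in \[0,1\]
#'   (default 0.2). Strict.
#' @return Filtered feature-table tibble; samples unchanged.
#' @export
prevalence_filter <- function(tbl, min_mean_relabund = 0.001, min_occurrence = 0.2) {
  stopifnot(min_mean_relabund >= 0, min_mean_relabund <= 1,
            min_occurrence >= 0, min_occurrence <= 1)
  m <- feature_matrix(tbl)
  rel <- sweep(m, 2, colSums(m), "/")
  keep <- rowMeans(rel) > min_mean_relabund &
    rowMeans(m > 0) > min_occurrence
  if (!any(keep)) abort("no feature passes the prevalence filter; network impossible")
  tbl[keep, , drop = FALSE]
}
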