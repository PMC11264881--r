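#' Feature table container
#'
#' A `feature_table` holds an untargeted LC-MS feature-intensity matrix with
#' samples as rows and metabolite features as columns, together with the
#' run-structure annotations needed for quality control: plate (batch) label,
#' injection order within plate, and the QC role of each row. Missing cells
#' (`NA`) encode "not detected"; a measured zero is a valid intensity distinct
#' from missing, and negative intensities are rejected.
#'
#' @param intensities Numeric matrix, samples x features, `NA` for missing.
#'   Row names are sample ids, column names feature ids.
#' @param plate Character or factor, one plate label per sample.
#' @param injection_order Positive integers, unique within each plate.
#' @param qc_flag One of `"analytical"`, `"external_control"`, `"plate_pool"`
#'   per sample. Analytical rows are study samples; the other two are repeated
#'   QC injections (adult-blood external control, plate-specific pool).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, plate, injection_order,
                          qc_flag = rep("analytical", nrow(intensities))) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  sample_ids <- rownames(intensities)
  feature_ids <- colnames(intensities)
  if (is.null(sample_ids) || is.null(feature_ids))
    format_error("intensity matrix must carry sample (row) and feature (column) ids")
  if (anyDuplicated(sample_ids))
    format_error("duplicate sample ids: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    format_error("duplicate feature ids: %s",
                 paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (length(plate) != n || length(injection_order) != n || length(qc_flag) != n)
    format_error("plate, injection_order and qc_flag must have one entry per sample")
  if (any(intensities < 0, na.rm = TRUE))
    format_error("negative intensities are not allowed")
  injection_order <- as.integer(injection_order)
  if (any(is.na(injection_order)) || any(injection_order < 1L))
    format_error("injection_order must be positive integers")
  plate <- as.character(plate)
  for (pl in unique(plate)) {
    ord <- injection_order[plate == pl]
    if (anyDuplicated(ord))
      format_error("injection_order not unique within plate '%s'", pl)
  }
  qc_flag <- as.character(qc_flag)
  bad <- setdiff(unique(qc_flag), c("analytical", "external_control", "plate_pool"))
  if (length(bad))
    format_error("unknown qc_flag value(s): %s", paste(bad, collapse = ", "))
  structure(
    list(intensities = intensities, plate = plate,
         injection_order = injection_order, qc_flag = qc_flag),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples x %d features (%d analytical, %d QC), %d plates, %.1f%% missing\n",
    nrow(x$intensities), ncol(x$intensities),
    sum(x$qc_flag == "analytical"), sum(x$qc_flag != "analytical"),
    length(unique(x$plate)),
    100 * mean(is.na(x$intensities))
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Sample and feature identifiers of a feature table
#' @param x A `feature_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$intensities)

#' Subset a feature table by samples and/or features
#' @param x A `feature_table`.
#' @param i,j Sample and feature indices (any standard matrix index).
#' @param ... Unused.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, rownames(x$intensities))
  if (is.logical(i)) i <- which(i)
  feature_table(x$intensities[i, j, drop = FALSE],
                plate = x$plate[i],
                injection_order = x$injection_order[i],
                qc_flag = x$qc_flag[i])
}

#' Restrict a feature table to analytical (non-QC) rows
#' @param x A `feature_table`.
#' @return A `feature_table` containing only analytical samples.
#' @export
analytical_samples <- function(x) x[x$qc_flag == "analytical", ]

#' Restrict a feature table to QC rows
#' @param x A `feature_table`.
#' @param type QC roles to keep.
#' @return A `feature_table` of QC injections.
#' @export
qc_samples <- function(x, type = c("plate_pool", "external_control")) {
  type <- match.arg(type, c("plate_pool", "external_control"), several.ok = TRUE)
  x[x$qc_flag %in% type, ]
}

#' Read a wide feature-intensity table with its run metadata
#'
#' The intensity file is tab-delimited: first column the sample id, remaining
#' columns one metabolite feature each; missing cells are empty or `NA`. The
#' metadata file is tab-delimited with columns `sample_id`, `plate`,
#' `injection_order` and `qc_flag`, one row per sample.
#'
#' @param path Path to the wide intensity `.tsv`.
#' @param metadata_path Path to the run-metadata `.tsv`.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) format_error("feature table needs a sample-id column and >= 1 feature")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) format_error("duplicate sample ids in '%s'", path)
  if (anyDuplicated(names(raw)[-1]))
    format_error("duplicate feature column ids in '%s'", path)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ids
  meta <- utils::read.delim(metadata_path, check.names = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "plate", "injection_order", "qc_flag")
  if (!all(need %in% names(meta)))
    format_error("metadata must have columns: %s", paste(need, collapse = ", "))
  idx <- match(ids, meta$sample_id)
  if (any(is.na(idx)))
    format_error("samples missing from metadata: %s",
                 paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  feature_table(mat, plate = meta$plate[idx],
                injection_order = meta$injection_order[idx],
                qc_flag = meta$qc_flag[idx])
}

#' Write a feature table and its run metadata
#'
#' Inverse of [read_feature_table()]: round-trips the intensity matrix and the
#' missingness mask exactly (missing written as empty cells, never zero).
#'
#' @param x A [feature_table].
#' @inheritParams read_feature_table
#' @return Invisibly, `x`.
#' @export
write_feature_table <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "feature_table"))
  mat <- x$intensities
  chr <- matrix(vapply(mat, function(v)
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE),
    character(1)), nrow = nrow(mat), dimnames = dimnames(mat))
  df <- data.frame(sample_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = rownames(mat), plate = x$plate,
                     injection_order = x$injection_order, qc_flag = x$qc_flag,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read and write subject metadata (sample records)
#'
#' Subject records hold the case-control design: outcome group, matching pair,
#' matching covariates (gestational age in weeks, age at sampling in days,
#' season and year of birth), confounders (family history of psychiatric
#' disorders, standardized polygenic score, six genetic principal components)
#' and, for cases, age at diagnosis in years.
#'
#' @param path Tab-delimited file path.
#' @return A data frame with one row per subject.
#' @export
read_sample_records <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (anyDuplicated(df$sample_id)) format_error("duplicate sample ids in '%s'", path)
  if ("group" %in% names(df)) {
    bad <- setdiff(unique(df$group), c("case", "control"))
    if (length(bad)) format_error("unknown group value(s): %s", paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_sample_records
#' @param records Data frame of subject records.
#' @export
write_sample_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}
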