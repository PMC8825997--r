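#' Construct a samples-by-features intensity matrix
#'
#' The central container of the chemometrics stage: a numeric matrix of
#' non-negative intensities with sample identifiers as row names and feature
#' identifiers as column names, optional per-feature metadata (representative
#' m/z or neutral mass and retention time), and optional per-sample group
#' labels.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param feature_info Optional tibble with one row per feature; must contain
#'   a `feature_id` column matching `colnames(values)`.
#' @param group_labels Optional character vector of per-sample class labels,
#'   recycled against the rows of `values`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_info = NULL, group_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("feature ids must be unique")
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (any(values < 0, na.rm = TRUE)) {
    stop("feature matrix contains negative intensities")
  }
  if (!is.null(feature_info)) {
    feature_info <- tibble::as_tibble(feature_info)
    if (!"feature_id" %in% names(feature_info) ||
        !identical(feature_info$feature_id, colnames(values))) {
      stop("feature_info$feature_id must match colnames(values)")
    }
  }
  if (!is.null(group_labels)) {
    if (length(group_labels) == 1L) {
      group_labels <- rep(group_labels, nrow(values))
    }
    if (length(group_labels) != nrow(values)) {
      stop("group_labels length must equal the number of samples")
    }
    group_labels <- as.character(group_labels)
  }
  structure(
    list(values = values, feature_info = feature_info,
         group_labels = group_labels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  if (!is.null(x$group_labels)) {
    cat("groups: ", paste(unique(x$group_labels), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Write / read a feature matrix as a long-format TSV
#'
#' The long format (one row per sample-feature pair, with feature metadata
#' and group labels repeated) round-trips the full object through a single
#' plain-text file.
#'
#' @param fm A [feature_matrix()].
#' @param path Output TSV path.
#' @return `write_feature_matrix` invisibly returns `path`;
#'   `read_feature_matrix` returns the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(fm$values, rownames = "sample_id"),
    -"sample_id", names_to = "feature_id", values_to = "intensity"
  )
  if (!is.null(fm$group_labels)) {
    long$group <- fm$group_labels[match(long$sample_id, rownames(fm$values))]
  }
  if (!is.null(fm$feature_info)) {
    long <- dplyr::left_join(long, fm$feature_info, by = "feature_id")
  }
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  wide <- tidyr::pivot_wider(long[, c("sample_id", "feature_id", "intensity")],
                             names_from = "feature_id",
                             values_from = "intensity")
  values <- as.matrix(wide[, -1, drop = FALSE])
  rownames(values) <- wide$sample_id
  meta_cols <- setdiff(names(long),
                       c("sample_id", "feature_id", "intensity", "group"))
  feature_info <- NULL
  if (length(meta_cols)) {
    feature_info <- dplyr::distinct(
      long[, c("feature_id", meta_cols), drop = FALSE]
    )
    feature_info <- feature_info[match(colnames(values),
                                       feature_info$feature_id), ]
  }
  group_labels <- NULL
  if ("group" %in% names(long)) {
    first <- !duplicated(long$sample_id)
    group_labels <- long$group[first][match(wide$sample_id,
                                            long$sample_id[first])]
  }
  feature_matrix(values, feature_info = feature_info,
                 group_labels = group_labels)
}
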