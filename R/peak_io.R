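#' Read an LC-MS peak list into ion features
#'
#' Ingests a per-sample peak list (one detected ion per row) from a CSV/TSV
#' file. Two dialects are supported: `csv_simple` expects columns `mz`, `rt`
#' and `intensity` (plus optional `polarity` and `sample_id`);
#' `mzmine_export` expects the aligned-table export convention with columns
#' `row m/z`, `row retention time` and one `<sample> Peak area` (or
#' `Peak height`) column per sample.
#'
#' Chromatographic peak picking itself is out of scope: finished peak lists
#' are the ingestion boundary of this package.
#'
#' @param path Path to the peak-list file; delimiter is inferred from the
#'   extension (`.csv` vs `.tsv`).
#' @param dialect `"csv_simple"` (default) or `"mzmine_export"`.
#' @param polarity Ionization mode of the whole file (`"positive"` or
#'   `"negative"`); required unless a `polarity` column is present.
#' @param sample_id Sample label applied to all rows when the file has no
#'   `sample_id` column (defaults to the file name without extension).
#' @return A tibble of ion features with columns `mz`, `rt`, `intensity`,
#'   `polarity`, `sample_id`, in file row order.
#' @export
read_peak_list <- function(path, dialect = c("csv_simple", "mzmine_export"),
                           polarity = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak list file not found: ", path)
  df <- read_delim_auto(path)
  if (dialect == "csv_simple") {
    features <- parse_simple_peaks(df, polarity, sample_id, path)
  } else {
    features <- parse_mzmine_peaks(df, polarity)
  }
  if (nrow(features) == 0L) {
    warning("peak list '", path, "' contains no peaks")
  }
  validate_ion_features(features)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

parse_simple_peaks <- function(df, polarity, sample_id, path) {
  for (col in c("mz", "rt", "intensity")) {
    if (!col %in% names(df)) {
      stop("peak list is missing required column '", col, "'")
    }
  }
  pol <- if ("polarity" %in% names(df)) {
    df$polarity
  } else if (!is.null(polarity)) {
    rep(polarity, nrow(df))
  } else {
    stop("no 'polarity' column; supply the file-level polarity argument")
  }
  sid <- if ("sample_id" %in% names(df)) {
    as.character(df$sample_id)
  } else {
    rep(sample_id %||% tools::file_path_sans_ext(basename(path)), nrow(df))
  }
  tibble::tibble(
    mz = as.numeric(df$mz), rt = as.numeric(df$rt),
    intensity = as.numeric(df$intensity),
    polarity = as.character(pol), sample_id = sid
  )
}

parse_mzmine_peaks <- function(df, polarity) {
  mz_col <- grep("m/z", names(df), fixed = TRUE, value = TRUE)[1]
  rt_col <- grep("retention time", names(df), fixed = TRUE, value = TRUE)[1]
  int_cols <- grep("Peak (area|height)$", names(df), value = TRUE)
  if (is.na(mz_col)) stop("peak list is missing required column 'row m/z'")
  if (is.na(rt_col)) stop("peak list is missing required column 'row retention time'")
  if (!length(int_cols)) stop("no '<sample> Peak area' intensity columns found")
  if (is.null(polarity)) stop("mzmine_export dialect requires the polarity argument")
  long <- lapply(int_cols, function(col) {
    sid <- sub(" Peak (area|height)$", "", col)
    sid <- sub("\\.mzX?ML$", "", sid)
    tibble::tibble(
      mz = as.numeric(df[[mz_col]]), rt = as.numeric(df[[rt_col]]),
      intensity = as.numeric(df[[col]]),
      polarity = polarity, sample_id = sid
    )
  })
  out <- dplyr::bind_rows(long)
  out[!is.na(out$intensity) & out$intensity > 0, , drop = FALSE]
}

validate_ion_features <- function(features) {
  bad_pol <- !features$polarity %in% c("positive", "negative")
  if (any(bad_pol)) {
    stop("invalid polarity in row(s) ", paste(which(bad_pol), collapse = ", "),
         " (must be 'positive' or 'negative')")
  }
  bad <- !is.finite(features$mz) | features$mz <= 0
  if (any(bad)) {
    stop("non-positive or missing m/z in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  bad <- !is.finite(features$rt) | features$rt < 0
  if (any(bad)) {
    stop("negative or missing retention time in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  bad <- !is.finite(features$intensity) | features$intensity < 0
  if (any(bad)) {
    stop("negative or missing intensity in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  features
}

#' Read centroided spectra from an mzML file as ion features
#'
#' Thin wrapper over the `mzR` reader: every centroid peak of every MS1
#' spectrum becomes one ion feature, with retention time converted to
#' minutes. Profile-mode data are not supported.
#'
#' @param path Path to an mzML file containing centroided spectra.
#' @param polarity Ionization mode of the acquisition.
#' @param sample_id Sample label (defaults to the file name).
#' @param min_intensity Drop centroids below this intensity (default 0).
#' @return A tibble of ion features as in [read_peak_list()].
#' @export
read_mzml_peaks <- function(path, polarity, sample_id = NULL,
                            min_intensity = 0) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML ingestion requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  sid <- sample_id %||% tools::file_path_sans_ext(basename(path))
  peaks <- lapply(ms1, function(i) {
    p <- mzR::peaks(handle, i)
    tibble::tibble(
      mz = p[, 1], rt = hdr$retentionTime[i] / 60,
      intensity = p[, 2], polarity = polarity, sample_id = sid
    )
  })
  out <- dplyr::bind_rows(peaks)
  validate_ion_features(out[out$intensity >= min_intensity, , drop = FALSE])
}

#' Read a compound library table
#'
#' Reads a natural-product library (TSV or CSV) with at least `name` and
#' `formula` columns; optional columns (`source`, `reference`, `note`, and
#' any instrument-derived metadata) are carried through. The neutral
#' monoisotopic mass is computed from each formula.
#'
#' @param path Path to the library table.
#' @return A tibble of compound records with a computed `monoisotopic_mass`
#'   column.
#' @seealso [streptomyces_library()] for the bundled mini-library.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("compound library file not found: ", path)
  df <- read_delim_auto(path)
  for (col in c("name", "formula")) {
    if (!col %in% names(df)) {
      stop("compound library is missing required column '", col, "'")
    }
  }
  if (any(!nzchar(df$name) | is.na(df$name))) {
    stop("compound library contains empty names")
  }
  mass <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(monoisotopic_mass(df$formula[i]), error = function(e) {
      stop("record '", df$name[i], "': ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(1))
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup)) {
    warning("duplicate compound name(s): ", paste(dup, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  df$monoisotopic_mass <- mass
  if (!"source" %in% names(df)) df$source <- NA_character_
  if (!"reference" %in% names(df)) df$reference <- NA_character_
  if (!"note" %in% names(df)) df$note <- NA_character_
  df
}

#' Bundled Streptomyces secondary-metabolite mini-library
#'
#' A 40-record library of secondary metabolites putatively identified in
#' crude extracts of soil Streptomyces isolates, with the literature source
#' organism for each compound and the ionization mode, retention time and
#' reported molecular weight under which each was observed. Intended as a
#' small built-in dereplication target and as the seed compound set for the
#' synthetic-data generator; user-supplied libraries in the same format can
#' be used anywhere this one can.
#'
#' @return A compound-library tibble, see [read_compound_library()].
#' @examples
#' lib <- streptomyces_library()
#' nrow(lib)
#' @export
streptomyces_library <- function() {
  path <- system.file("extdata", "streptomyces_np_library.tsv",
                      package = "derepms", mustWork = TRUE)
  read_compound_library(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
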