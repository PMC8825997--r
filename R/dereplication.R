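#' Signed ppm mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical Masses in Da (vectorised).
#' @return Signed error in parts per million.
#' @examples
#' ppm_error(460.1476, 460.1482)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Match one neutral feature against a compound library
#'
#' Returns every library compound whose neutral monoisotopic mass lies
#' within `tol_ppm` of the feature's neutral mass, sorted by absolute ppm
#' error with ties broken alphabetically by compound name. Several isobaric
#' compounds may legitimately match one feature; no forced unique
#' assignment is made. An empty result means "no hit". Matching is on
#' neutral mass only; retention times are not comparable across instruments
#' and are carried in reports for human inspection only.
#'
#' @param feature One-row neutral-feature tibble, or a bare neutral mass.
#' @param library Compound-library tibble (see [read_compound_library()]);
#'   may be empty.
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return A tibble of hits: `compound`, `formula`, `library_mass`,
#'   `ppm_error`, `source`, `reference`.
#' @export
match_feature <- function(feature, library, tol_ppm = 5) {
  mass <- if (is.data.frame(feature)) feature$neutral_mass[1] else feature
  if (is.null(library) || nrow(library) == 0L) return(empty_hits())
  err <- ppm_error(mass, library$monoisotopic_mass)
  sel <- which(abs(err) <= tol_ppm)
  if (!length(sel)) return(empty_hits())
  ord <- sel[order(abs(err[sel]), library$name[sel])]
  tibble::tibble(
    compound = library$name[ord],
    formula = library$formula[ord],
    library_mass = library$monoisotopic_mass[ord],
    ppm_error = err[ord],
    source = library$source[ord],
    reference = library$reference[ord]
  )
}

empty_hits <- function() {
  tibble::tibble(
    compound = character(), formula = character(), library_mass = numeric(),
    ppm_error = numeric(), source = character(), reference = character()
  )
}

#' Dereplicate a table of neutral features against a library
#'
#' Applies [match_feature()] to every feature and classifies each as `hit`
#' or `no_hit`. Every input feature appears exactly once in the report and
#' the summary counts are conserved (`n_hit + n_no_hit = n_features`).
#'
#' @param features Neutral-feature tibble (see [merge_polarities()]), or any
#'   tibble with `feature_id` and `neutral_mass` columns.
#' @param library Compound-library tibble.
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return An object of class `derep_report`: a list with `table` (one row
#'   per feature-hit pair, or a single `no_hit` row per unmatched feature),
#'   `summary` (`n_features`, `n_hit`, `n_no_hit`) and `tol_ppm`.
#' @export
dereplicate_table <- function(features, library, tol_ppm = 5) {
  stopifnot(all(c("feature_id", "neutral_mass") %in% names(features)))
  template <- dplyr::bind_cols(
    tibble::tibble(feature_id = character(), neutral_mass = numeric(),
                   rt = numeric(), provenance = character(),
                   status = character()),
    empty_hits()
  )
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    hits <- match_feature(f$neutral_mass, library, tol_ppm)
    base <- tibble::tibble(
      feature_id = f$feature_id,
      neutral_mass = f$neutral_mass,
      rt = if ("rt" %in% names(f)) f$rt else NA_real_,
      provenance = if ("provenance" %in% names(f)) f$provenance
                   else NA_character_
    )
    if (nrow(hits) == 0L) {
      base$status <- "no_hit"
      return(dplyr::bind_cols(base, empty_hits()[NA_integer_, ]))
    }
    out <- base[rep(1L, nrow(hits)), ]
    out$status <- "hit"
    dplyr::bind_cols(out, hits)
  })
  table <- dplyr::bind_rows(template, rows)
  n_hit <- length(unique(table$feature_id[table$status == "hit"]))
  report <- list(
    table = table,
    summary = list(
      n_features = nrow(features),
      n_hit = n_hit,
      n_no_hit = nrow(features) - n_hit
    ),
    tol_ppm = tol_ppm
  )
  class(report) <- "derep_report"
  report
}

#' @export
print.derep_report <- function(x, ...) {
  s <- x$summary
  cat("<derep_report> ", s$n_features, " features: ", s$n_hit, " with hits, ",
      s$n_no_hit, " without (tolerance ", x$tol_ppm, " ppm)\n", sep = "")
  invisible(x)
}

#' Filter dereplication hits by source organism
#'
#' Secondary screen mirroring the practice of checking whether database hits
#' are of actinobacterial origin: keeps only hit rows whose `source` field
#' matches `pattern` (case-insensitive regular expression). Features whose
#' hits are all removed are re-classified as `no_hit`.
#'
#' @param report A `derep_report`.
#' @param pattern Regular expression matched against the hit source text
#'   (default matches Streptomyces/Streptoverticillium records).
#' @return A filtered `derep_report`.
#' @export
filter_hits_by_source <- function(report, pattern = "Strepto") {
  stopifnot(inherits(report, "derep_report"))
  tab <- report$table
  drop <- tab$status == "hit" & !grepl(pattern, tab$source, ignore.case = TRUE)
  kept <- tab[!drop, , drop = FALSE]
  lost <- setdiff(unique(tab$feature_id), unique(kept$feature_id))
  if (length(lost)) {
    stub <- tab[tab$feature_id %in% lost & !duplicated(tab$feature_id), ]
    stub$status <- "no_hit"
    stub[, names(empty_hits())] <- NA
    kept <- dplyr::bind_rows(kept, stub)
    kept <- kept[order(match(kept$feature_id, tab$feature_id)), ]
  }
  n_hit <- length(unique(kept$feature_id[kept$status == "hit"]))
  report$table <- kept
  report$summary$n_hit <- n_hit
  report$summary$n_no_hit <- report$summary$n_features - n_hit
  report
}
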