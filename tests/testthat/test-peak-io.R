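write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("simple peak lists ingest row-by-row with fields preserved", {
  path <- write_tmp(c(
    "mz,rt,intensity,polarity",
    "127.0755,2.19,1500,positive",
    "265.1546,2.85,800,positive",
    "162.1125,2.82,50,positive"
  ))
  feats <- read_peak_list(path)
  expect_equal(nrow(feats), 3L)
  expect_equal(feats$mz, c(127.0755, 265.1546, 162.1125))
  expect_equal(feats$rt[2], 2.85)
  expect_true(all(feats$polarity == "positive"))
  expect_equal(unique(feats$sample_id), tools::file_path_sans_ext(basename(path)))
})

test_that("empty peak lists warn and malformed rows are rejected by number", {
  empty <- write_tmp("mz,rt,intensity,polarity")
  expect_warning(feats <- read_peak_list(empty), "no peaks")
  expect_equal(nrow(feats), 0L)

  bad <- write_tmp(c("mz,rt,intensity,polarity", "-5.0,1.0,100,positive"))
  expect_error(read_peak_list(bad), "row\\(s\\) 1")

  missing <- write_tmp(c("mz,rt,polarity", "100,1,positive"))
  expect_error(read_peak_list(missing), "intensity")

  nopol <- write_tmp(c("mz,rt,intensity", "100,1,50"))
  expect_error(read_peak_list(nopol), "polarity")
  expect_equal(nrow(read_peak_list(nopol, polarity = "negative")), 1L)
})

test_that("aligned-table exports unpivot into per-sample ion features", {
  path <- write_tmp(c(
    "row m/z,row retention time,SH4.mzML Peak area,SH8.mzML Peak area",
    "127.0755,2.19,1500,0",
    "265.1546,2.85,800,900"
  ))
  feats <- read_peak_list(path, dialect = "mzmine_export",
                          polarity = "positive")
  expect_equal(nrow(feats), 3L) # zero-intensity cells are dropped
  expect_setequal(unique(feats$sample_id), c("SH4", "SH8"))
  expect_equal(sum(feats$sample_id == "SH8"), 1L)
})

test_that("compound libraries compute masses and flag bad records", {
  lib <- streptomyces_library()
  expect_equal(nrow(lib), 40L)
  expect_true(all(c("name", "formula", "monoisotopic_mass", "mz", "adduct",
                    "mw") %in% names(lib)))
  # invariant: stored mass equals the mass recomputed from the formula
  recomputed <- vapply(lib$formula, monoisotopic_mass, numeric(1))
  expect_equal(unname(lib$monoisotopic_mass), unname(recomputed),
               tolerance = 1e-9)
  expect_equal(lib$name[25], "Oxytetracycline")
  expect_equal(round(lib$monoisotopic_mass[25], 4), 460.1482)

  bad <- write_tmp(c("name\tformula", "Badrec\tC22Hx"), ext = ".tsv")
  expect_error(read_compound_library(bad), "Badrec")

  dup <- write_tmp(c("name\tformula", "A\tC6H6", "A\tC7H8"), ext = ".tsv")
  expect_warning(read_compound_library(dup), "duplicate")
})

test_that("reports round-trip through TSV and JSON", {
  lib <- streptomyces_library()
  features <- tibble::tibble(
    feature_id = c("M0001", "M0002"),
    neutral_mass = c(460.1482, 999.9999),
    rt = c(5.4, 1.1),
    provenance = c("both_modes", "positive_only")
  )
  report <- dereplicate_table(features, lib, 5)

  tsv <- tempfile(fileext = ".tsv")
  write_report(report, tsv)
  back <- read_report(tsv)
  expect_equal(nrow(back), nrow(report$table))
  expect_equal(back$compound, report$table$compound)
  expect_equal(back$ppm_error, report$table$ppm_error, tolerance = 1e-12)

  js <- tempfile(fileext = ".json")
  write_report(report, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$schema_version, "1.0")
  rep2 <- read_report(js)
  expect_s3_class(rep2, "derep_report")
  expect_equal(rep2$summary$n_hit, report$summary$n_hit)
  expect_equal(rep2$table$neutral_mass, report$table$neutral_mass,
               tolerance = 1e-12)

  # empty report -> header-only TSV
  empty <- dereplicate_table(features[0, ], lib, 5)
  tsv2 <- tempfile(fileext = ".tsv")
  write_report(empty, tsv2)
  expect_length(readLines(tsv2), 1L)
})

test_that("feature matrices round-trip through long-format TSV", {
  values <- matrix(c(0, 5, 2.5, 7, 1, 0), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("F1", "F2", "F3")))
  fm <- feature_matrix(
    values,
    feature_info = tibble::tibble(feature_id = c("F1", "F2", "F3"),
                                  mz = c(100.1, 200.2, 300.3),
                                  rt = c(1, 2, 3)),
    group_labels = c("a", "b")
  )
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values)
  expect_equal(back$feature_info$mz, fm$feature_info$mz)
  expect_equal(back$group_labels, fm$group_labels)
})

test_that("feature matrix invariants are enforced", {
  expect_error(feature_matrix(matrix(-1, 1, 1)), "negative")
  v <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("F1", "F1")))
  expect_error(feature_matrix(v), "unique")
  expect_error(
    feature_matrix(matrix(1, 2, 2), group_labels = c("a", "b", "c")),
    "group_labels"
  )
})
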