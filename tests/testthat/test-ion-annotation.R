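test_that("adduct arithmetic reproduces reported molecular weights", {
  # deprotonated oxytetracycline ion and protonated novamethymycin ion
  expect_equal(round(neutral_mass_from_ion(459.14032, "[M-H]-"), 4), 460.1476)
  expect_equal(round(neutral_mass_from_ion(486.3055, "[M+H]+"), 4), 485.2982)
  # massless limit: a bare proton has no neutral counterpart
  expect_error(neutral_mass_from_ion(1.00728, "[M+H]+"), "non-positive")
  expect_error(neutral_mass_from_ion(100, "[M+Na]+"), "unknown adduct")
})

test_that("ion m/z is the exact inverse of the neutral-mass conversion", {
  expect_equal(ion_mz_from_neutral(460.14760, "[M-H]-"), 459.14032,
               tolerance = 1e-9)
  expect_equal(ion_mz_from_neutral(126.0681, "[M+H]+"), 127.07538,
               tolerance = 1e-9)
  set.seed(5)
  for (x in runif(20, 50, 1200)) {
    for (a in c("[M+H]+", "[M-H]-")) {
      expect_equal(ion_mz_from_neutral(neutral_mass_from_ion(x, a), a), x,
                   tolerance = 1e-9)
    }
  }
})

test_that("the bundled library's ion/MW pairs obey the proton shift", {
  lib <- streptomyces_library()
  neutral <- mapply(neutral_mass_from_ion, lib$mz, lib$adduct)
  dev <- abs(neutral - lib$mw)
  # row 39 is internally inconsistent in the source table (its m/z repeats a
  # negative-mode record under a positive-mode label); all others agree
  expect_identical(which(dev > 3e-4), 39L)
  expect_true(all(dev[-39] <= 3e-4))
})

test_that("feature alignment clusters within tolerance and not beyond", {
  one <- tibble::tibble(
    mz = c(200.1, 300.2), rt = c(2, 3), intensity = c(10, 20),
    polarity = "positive", sample_id = "s1"
  )
  fm <- align_features(one)
  expect_equal(dim(fm$values), c(1L, 2L))
  expect_equal(unname(fm$values[1, ]), c(10, 20))
  expect_equal(fm$feature_info$mz, c(200.1, 300.2))

  # +3 ppm / +0.02 min jitter collapses at (5 ppm, 0.1 min)
  jit <- dplyr::bind_rows(
    one[1, ],
    tibble::tibble(mz = 200.1 * (1 + 3e-6), rt = 2.02, intensity = 12,
                   polarity = "positive", sample_id = "s2")
  )
  fm2 <- align_features(jit, ppm_tol = 5, rt_tol = 0.1)
  expect_equal(ncol(fm2$values), 1L)
  # intensity-weighted mean m/z
  expect_equal(fm2$feature_info$mz,
               (200.1 * 10 + 200.1 * (1 + 3e-6) * 12) / 22, tolerance = 1e-10)

  far <- jit
  far$mz[2] <- 200.1 * (1 + 20e-6)
  expect_equal(ncol(align_features(far, 5, 0.1)$values), 2L)

  mixed <- one
  mixed$polarity <- c("positive", "negative")
  expect_error(align_features(mixed), "single polarity")
})

test_that("alignment is idempotent on already-aligned data", {
  sim <- simulate_extract_profiles(simulation_design(seed = 31))
  fm <- align_features(sim$pos)
  # re-emit each matrix cell as an ion at its column's consensus m/z and rt
  idx <- which(fm$values > 0, arr.ind = TRUE)
  again <- tibble::tibble(
    mz = fm$feature_info$mz[idx[, 2]],
    rt = fm$feature_info$rt[idx[, 2]],
    intensity = fm$values[idx],
    polarity = "positive",
    sample_id = rownames(fm$values)[idx[, 1]]
  )
  fm2 <- align_features(again)
  expect_equal(ncol(fm2$values), ncol(fm$values))
  expect_equal(fm2$feature_info$mz, fm$feature_info$mz, tolerance = 1e-9)
  expect_equal(unname(fm2$values[rownames(fm$values), ]),
               unname(fm$values), tolerance = 1e-9)
})

test_that("polarity merging pairs agreeing features and conserves signal", {
  mk <- function(id, mass, rt, sample, intensity, prov) {
    tibble::tibble(
      feature_id = id, neutral_mass = mass, rt = rt, provenance = prov,
      intensities = list(stats::setNames(intensity, sample)),
      ions = list(tibble::tibble(mz = mass, polarity = "x", adduct = "x"))
    )
  }
  pos <- mk("P1", 460.1476, 5.45, "s1", 100, "positive_only")
  # 2 ppm discrepancy merges at 5 ppm
  neg <- mk("N1", 460.1476 * (1 + 2e-6), 5.46, "s1", 50, "negative_only")
  merged <- merge_polarities(pos, neg, 5, 0.1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$provenance, "both_modes")
  expect_equal(sum(merged$intensities[[1]]), 150)
  # intensity-weighted mass, weights 100:50
  expect_equal(merged$neutral_mass,
               (460.1476 * 100 + 460.1476 * (1 + 2e-6) * 50) / 150,
               tolerance = 1e-10)

  # same masses 1.0 min apart stay separate at rt_tol 0.1
  neg_far <- mk("N1", 460.1476, 6.45, "s1", 50, "negative_only")
  expect_equal(nrow(merge_polarities(pos, neg_far, 5, 0.1)), 2L)

  # empty negative list passes positives through
  out <- merge_polarities(pos, pos[0, ], 5, 0.1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$provenance, "positive_only")
})

test_that("merging never changes total intensity on simulated data", {
  sim <- simulate_extract_profiles(simulation_design(seed = 17))
  pos <- neutral_features(align_features(sim$pos))
  neg <- neutral_features(align_features(sim$neg))
  merged <- merge_polarities(pos, neg)
  expect_equal(sum(unlist(merged$intensities)),
               sum(sim$pos$intensity) + sum(sim$neg$intensity),
               tolerance = 1e-6)
  # each feature merges at most once: ids partition the inputs
  expect_equal(
    sum(lengths(strsplit(merged$source_ids, "\\+"))),
    nrow(pos) + nrow(neg)
  )
})
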