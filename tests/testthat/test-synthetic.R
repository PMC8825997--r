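test_that("profile simulation is a pure function of its seed", {
  d <- simulation_design(seed = 7)
  a <- simulate_extract_profiles(d)
  b <- simulate_extract_profiles(d)
  expect_identical(a, b)
  c <- simulate_extract_profiles(simulation_design(seed = 8))
  expect_false(identical(a$pos$mz, c$pos$mz))

  # written CSVs are byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  simulate_extract_profiles(d, out_dir = d1)
  simulate_extract_profiles(d, out_dir = d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "positive.csv"))),
    unname(tools::md5sum(file.path(d2, "positive.csv")))
  )
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a single noiseless compound lands at its exact ion m/z", {
  lib <- streptomyces_library()
  d <- simulation_design(
    extract_ids = "E1", outlier = "E1", pairs = list("E1"),
    library = lib[25, ], n_decoys = 0,
    mass_error_ppm_sd = 0, rt_jitter_sd = 0, dropout_rate = 0, seed = 1
  )
  sim <- simulate_extract_profiles(d)
  expect_equal(nrow(sim$neg), 1L)
  # deprotonated oxytetracycline from its formula mass
  expect_equal(sim$neg$mz, lib$monoisotopic_mass[25] - 1.00728,
               tolerance = 1e-9)
  expect_equal(sim$pos$mz, lib$monoisotopic_mass[25] + 1.00728,
               tolerance = 1e-9)
})

test_that("full dropout leaves only decoys and empty ground truth", {
  d <- simulation_design(dropout_rate = 1, seed = 4)
  sim <- simulate_extract_profiles(d)
  expect_false(any(sim$truth$compounds$emitted))
  all_mz <- c(sim$pos$mz, sim$neg$mz)
  lib_masses <- streptomyces_library()$monoisotopic_mass
  # every emitted ion is a decoy: its implied neutral mass is far from the
  # library (20 ppm placement minus 3 sigma of 2 ppm jitter)
  for (pol in c("positive", "negative")) {
    tab <- if (pol == "positive") sim$pos else sim$neg
    neutral <- neutral_mass_from_ion(tab$mz, pol)
    mindev <- vapply(neutral, function(m) {
      min(abs(1e6 * (m - lib_masses) / lib_masses))
    }, numeric(1))
    expect_true(all(mindev > 10))
  }
})

test_that("decoy masses respect the 20 ppm exclusion zone", {
  d <- simulation_design(seed = 23)
  sim <- simulate_extract_profiles(d)
  lib_masses <- streptomyces_library()$monoisotopic_mass
  dev <- vapply(sim$truth$decoys$neutral_mass, function(m) {
    min(abs(1e6 * (m - lib_masses) / lib_masses))
  }, numeric(1))
  expect_true(all(dev >= 20))
})

test_that("intensity matrices have the designed shape and planted effects", {
  sim <- simulate_intensity_matrix(n_groups = 3, n_per_group = 4,
                                   n_features = 50, n_discriminant = 5,
                                   effect_size = 3, seed = 5)
  expect_equal(dim(sim$matrix), c(12L, 50L))
  expect_equal(length(sim$labels), 12L)
  expect_equal(nrow(sim$truth), 5L)
  # planted features really are shifted in their target group (log scale)
  lx <- log(as.matrix(sim$matrix))
  for (k in seq_len(5)) {
    j <- sim$truth$feature_id[k]
    tgt <- sim$labels == sim$truth$group[k]
    expect_gt(mean(lx[tgt, j]) - mean(lx[!tgt, j]), 1)
  }
  expect_error(simulate_intensity_matrix(effect_size = -1, seed = 1),
               "non-negative")
  expect_error(simulate_intensity_matrix(seed = NULL), "seed")
})

test_that("a null matrix produces no spuriously dominant ANOVA feature", {
  sim <- simulate_intensity_matrix(n_discriminant = 0, seed = 2)
  ta <- top_features_anova(log(as.matrix(sim$matrix)), sim$labels, 200)
  # under the null the p-value distribution is roughly uniform
  expect_gt(min(ta$p_value), 1e-4)
  expect_lt(mean(ta$p_value < 0.05), 0.12)
})

test_that("dose-response plates carry the dose series and reproducible noise", {
  sim <- simulate_dose_response(7, noise_sd = 0.02, seed = 9)
  treated <- sim$plate[sim$plate$role == "treated", ]
  expect_setequal(unique(treated$dose), c(100, 25, 6.3, 1.6, 0.4))
  expect_equal(sim$truth$ic50, 7)
  again <- simulate_dose_response(7, noise_sd = 0.02, seed = 9)
  expect_identical(sim$plate, again$plate)
  other <- simulate_dose_response(7, noise_sd = 0.02, seed = 10)
  expect_false(identical(sim$plate$a570, other$plate$a570))
  expect_identical(sim$truth, other$truth)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_intensity_matrix(seed = 99))
  expect_identical(.Random.seed, before)
})
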