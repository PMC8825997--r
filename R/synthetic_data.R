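# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (design, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation design for synthetic multi-extract LC-HRMS profiles
#'
#' Describes the study layout the generator emulates: five crude extracts
#' acquired in both ionization modes, sharing a core of library metabolites,
#' with two chemically similar pairs, one deliberately distinct outlier
#' extract, decoy features, ppm-scale mass error, retention-time jitter and
#' log-normal intensities.
#'
#' Defaults: 40 planted library compounds split as a 16-compound core
#' present in all extracts, 8 compounds per similar pair, and 8 unique to
#' the outlier; 160 decoy features whose masses are kept at least 20 ppm
#' from every library mass, half of them unique to the outlier extract;
#' Gaussian mass error of sd 2 ppm; retention jitter of sd 0.02 min;
#' log-normal intensities with a per-feature base level (meanlog 12,
#' sdlog 1) and a smaller per-extract deviation (sdlog 0.5), reflecting
#' that a metabolite's abundance is largely compound-specific; dropout
#' rate 0.1.
#'
#' @param extract_ids Extract labels (default the five-isolate layout).
#' @param outlier Which extract carries the distinct profile.
#' @param pairs List of two character vectors naming the similar pairs.
#' @param library Compound library whose records are planted (default the
#'   bundled mini-library).
#' @param n_decoys Number of decoy features (split across polarities).
#' @param mass_error_ppm_sd,rt_jitter_sd Noise scales (ppm / minutes).
#' @param intensity_meanlog,intensity_sdlog Log-normal distribution of the
#'   per-feature base intensity.
#' @param intensity_extract_sdlog Log-sd of the per-extract deviation
#'   around a feature's base intensity.
#' @param dropout_rate Probability that a planted compound is absent from a
#'   given extract.
#' @param seed Mandatory RNG seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(extract_ids = c("SH4", "SH8", "SH10", "SH12",
                                              "SH13"),
                              outlier = "SH4",
                              pairs = list(c("SH8", "SH13"),
                                           c("SH10", "SH12")),
                              library = streptomyces_library(),
                              n_decoys = 160,
                              mass_error_ppm_sd = 2,
                              rt_jitter_sd = 0.02,
                              intensity_meanlog = 12,
                              intensity_sdlog = 1,
                              intensity_extract_sdlog = 0.5,
                              dropout_rate = 0.1,
                              seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  stopifnot(mass_error_ppm_sd >= 0, rt_jitter_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            outlier %in% extract_ids)
  design <- list(
    extract_ids = extract_ids, outlier = outlier, pairs = pairs,
    library = library, n_decoys = as.integer(n_decoys),
    mass_error_ppm_sd = mass_error_ppm_sd, rt_jitter_sd = rt_jitter_sd,
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    intensity_extract_sdlog = intensity_extract_sdlog,
    dropout_rate = dropout_rate, seed = as.integer(seed)
  )
  class(design) <- "simulation_design"
  design
}

# Assign library compounds to extracts: core to everyone, one block per
# similar pair, one block to the outlier.
plant_compounds <- function(design) {
  lib <- design$library
  n <- nrow(lib)
  others <- setdiff(design$extract_ids, design$outlier)
  n_core <- min(16L, n)
  n_block <- max(0L, (n - n_core) %/% (length(design$pairs) + 1L))
  idx <- seq_len(n)
  blocks <- list()
  taken <- seq_len(n_core)
  for (pr in design$pairs) {
    block <- setdiff(idx, taken)[seq_len(min(n_block, n - length(taken)))]
    taken <- c(taken, block)
    blocks[[length(blocks) + 1L]] <- list(extracts = pr, rows = block)
  }
  outlier_rows <- setdiff(idx, taken)
  assignment <- stats::setNames(
    lapply(design$extract_ids, function(e) integer(0)), design$extract_ids)
  for (e in design$extract_ids) assignment[[e]] <- seq_len(n_core)
  for (b in blocks) {
    for (e in b$extracts) assignment[[e]] <- c(assignment[[e]], b$rows)
  }
  assignment[[design$outlier]] <- c(assignment[[design$outlier]],
                                    outlier_rows)
  assignment
}

#' Simulate dual-polarity peak lists for a multi-extract study
#'
#' Every planted library compound emits a protonated ion in the positive
#' file and a deprotonated ion in the negative file of each extract it is
#' assigned to, at the m/z implied by its formula's monoisotopic mass plus
#' Gaussian ppm error; its retention time is drawn once and jittered per
#' sample. Decoy features are placed at random masses at least 20 ppm from
#' every library mass. Planted presence is thinned by the design's dropout
#' rate; the emitted ground truth reflects what was actually written.
#'
#' @param design A [simulation_design()].
#' @param out_dir Optional directory; when given, `positive.csv`,
#'   `negative.csv` and `ground_truth.json` are written there.
#' @return A list with `pos` and `neg` ion-feature tibbles and `truth`, a
#'   list holding the planted-compound table (`compounds`) and the decoy
#'   mass table (`decoys`).
#' @export
simulate_extract_profiles <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  lib <- design$library
  if (!nrow(lib)) stop("design library is empty")
  with_seed(design$seed, {
    assignment <- plant_compounds(design)
    neutral <- lib$monoisotopic_mass
    rt_true <- stats::runif(nrow(lib), 0.5, 10)
    # compound-specific base abundance, drawn once per compound and mode
    base_log <- matrix(stats::rnorm(2L * nrow(lib), design$intensity_meanlog,
                                    design$intensity_sdlog),
                       nrow = nrow(lib), ncol = 2,
                       dimnames = list(NULL, c("positive", "negative")))

    planted <- list()
    for (e in design$extract_ids) {
      rows <- assignment[[e]]
      kept <- rows[stats::runif(length(rows)) >= design$dropout_rate]
      if (length(kept)) {
        planted[[e]] <- tibble::tibble(extract = e, row = kept)
      }
    }
    planted <- dplyr::bind_rows(planted)
    if (nrow(planted)) {
      ions <- lapply(c("positive", "negative"), function(pol) {
        adduct <- resolve_adduct(pol)
        mz0 <- ion_mz_from_neutral(neutral[planted$row], adduct)
        tibble::tibble(
          mz = mz0 * (1 + stats::rnorm(nrow(planted), 0,
                                       design$mass_error_ppm_sd) * 1e-6),
          rt = pmax(0, rt_true[planted$row] +
                      stats::rnorm(nrow(planted), 0, design$rt_jitter_sd)),
          intensity = exp(base_log[planted$row, pol] +
                            stats::rnorm(nrow(planted), 0,
                                         design$intensity_extract_sdlog)),
          polarity = pol,
          sample_id = planted$extract,
          compound = lib$name[planted$row]
        )
      })
      planted_ions <- dplyr::bind_rows(ions)
    } else {
      planted_ions <- NULL
    }

    decoys <- make_decoys(design, neutral)
    decoy_ions <- emit_decoys(design, decoys)

    all_ions <- dplyr::bind_rows(planted_ions, decoy_ions)
    all_ions <- all_ions[order(all_ions$polarity, all_ions$sample_id,
                               all_ions$mz), ]
    pos <- all_ions[all_ions$polarity == "positive",
                    c("mz", "rt", "intensity", "polarity", "sample_id")]
    neg <- all_ions[all_ions$polarity == "negative",
                    c("mz", "rt", "intensity", "polarity", "sample_id")]

    emitted <- unique(planted_ions$compound)
    truth <- list(
      compounds = tibble::tibble(
        compound = lib$name, formula = lib$formula,
        neutral_mass = neutral, rt = rt_true,
        emitted = lib$name %in% emitted
      ),
      decoys = decoys
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(pos, file.path(out_dir, "positive.csv"),
                       progress = FALSE)
      readr::write_csv(neg, file.path(out_dir, "negative.csv"),
                       progress = FALSE)
      jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(pos = pos, neg = neg, truth = truth)
  })
}

# Decoy neutral masses kept >= 20 ppm away from every library mass and
# from each other, so every decoy resolves into its own aligned feature.
make_decoys <- function(design, library_masses) {
  n <- design$n_decoys
  if (n == 0L) {
    return(tibble::tibble(decoy_id = character(), neutral_mass = numeric(),
                          rt = numeric(), polarity = character(),
                          block = character(), base_log = numeric()))
  }
  masses <- numeric(0)
  while (length(masses) < n) {
    cand <- stats::runif(1, 150, 850)
    excl <- c(library_masses, masses)
    if (all(abs(1e6 * (cand - excl) / excl) >= 20)) {
      masses <- c(masses, cand)
    }
  }
  n_out <- round(0.50 * n)
  n_all <- round(0.30 * n)
  n_p1 <- (n - n_out - n_all) %/% 2L
  n_p2 <- n - n_out - n_all - n_p1
  block <- c(rep("outlier", n_out), rep("all", n_all),
             rep("pair1", n_p1), rep("pair2", n_p2))
  tibble::tibble(
    decoy_id = sprintf("decoy_%03d", seq_len(n)),
    neutral_mass = masses,
    rt = stats::runif(n, 0.5, 10),
    polarity = rep(c("positive", "negative"), length.out = n),
    block = block,
    base_log = stats::rnorm(n)
  )
}

emit_decoys <- function(design, decoys) {
  if (!nrow(decoys)) return(NULL)
  members <- list(
    outlier = design$outlier,
    all = design$extract_ids,
    pair1 = design$pairs[[1]],
    pair2 = if (length(design$pairs) > 1) design$pairs[[2]]
            else design$pairs[[1]]
  )
  rows <- lapply(seq_len(nrow(decoys)), function(i) {
    d <- decoys[i, ]
    extracts <- members[[d$block]]
    adduct <- resolve_adduct(d$polarity)
    mz0 <- ion_mz_from_neutral(d$neutral_mass, adduct)
    tibble::tibble(
      mz = mz0 * (1 + stats::rnorm(length(extracts), 0,
                                   design$mass_error_ppm_sd) * 1e-6),
      rt = pmax(0, d$rt + stats::rnorm(length(extracts), 0,
                                       design$rt_jitter_sd)),
      intensity = exp(design$intensity_meanlog +
                        design$intensity_sdlog * d$base_log +
                        stats::rnorm(length(extracts), 0,
                                     design$intensity_extract_sdlog)),
      polarity = d$polarity,
      sample_id = extracts,
      compound = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a grouped intensity matrix with planted discriminants
#'
#' Baseline log-normal intensities with a common log-mean; each
#' discriminatory feature is shifted upward by `effect_size` log-standard
#' deviations in the samples of its designated group (groups are assigned
#' cyclically over the discriminant features).
#'
#' @param n_groups Number of sample groups (default 5).
#' @param n_per_group Replicates per group (default 3).
#' @param n_features Total number of features (default 200).
#' @param n_discriminant Number of planted discriminatory features
#'   (default 10).
#' @param effect_size Shift in units of the log-sd (must be >= 0;
#'   default 3).
#' @param meanlog,sdlog Log-normal intensity parameters (defaults 12, 1).
#' @param seed Mandatory RNG seed.
#' @return A list with `matrix` (a [feature_matrix()] carrying group
#'   labels), `labels`, and `truth` (tibble of planted feature ids and
#'   their target groups).
#' @export
simulate_intensity_matrix <- function(n_groups = 5, n_per_group = 3,
                                      n_features = 200, n_discriminant = 10,
                                      effect_size = 3, meanlog = 12,
                                      sdlog = 1, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  if (effect_size < 0) stop("effect size must be non-negative")
  stopifnot(n_groups >= 2, n_per_group >= 1,
            n_discriminant <= n_features)
  with_seed(seed, {
    n <- n_groups * n_per_group
    labels <- rep(paste0("G", seq_len(n_groups)), each = n_per_group)
    logx <- matrix(stats::rnorm(n * n_features, meanlog, sdlog),
                   nrow = n, ncol = n_features)
    disc <- if (n_discriminant > 0) {
      sort(sample.int(n_features, n_discriminant))
    } else integer(0)
    target <- rep(paste0("G", seq_len(n_groups)),
                  length.out = n_discriminant)
    for (k in seq_along(disc)) {
      sel <- labels == target[k]
      logx[sel, disc[k]] <- logx[sel, disc[k]] + effect_size * sdlog
    }
    values <- exp(logx)
    rownames(values) <- paste0(labels, "_r",
                               rep(seq_len(n_per_group), n_groups))
    colnames(values) <- sprintf("F%03d", seq_len(n_features))
    fm <- feature_matrix(values, group_labels = labels)
    list(
      matrix = fm, labels = labels,
      truth = tibble::tibble(feature_id = colnames(values)[disc],
                             group = target)
    )
  })
}

#' Simulate an MTT dose-response plate with known IC50
#'
#' Viabilities follow a four-parameter logistic curve at the given doses;
#' they are converted to 570/690 nm absorbance pairs around typical assay
#' levels, with additive Gaussian noise on the 570 nm reading, plus
#' untreated control and medium blank wells.
#'
#' @param true_ic50 Ground-truth IC50 (same units as `doses`).
#' @param hill,top,bottom Remaining 4PL parameters (defaults 1.2, 100, 0).
#' @param noise_sd Additive absorbance noise sd (0.03 corresponds to about
#'   3% of the control signal; default 0).
#' @param replicates Number of replicate experiments (default 3).
#' @param wells_per_dose Technical replicate wells per concentration within
#'   each experiment (default 3, the usual 96-well layout).
#' @param doses Dose series; defaults to the five-point series 100, 25,
#'   6.3, 1.6, 0.4 ug/ml.
#' @param seed Mandatory RNG seed.
#' @return A list with `plate` (well-level tibble: `well`, `role`, `dose`,
#'   `a570`, `a690`, `replicate`) and `truth`.
#' @export
simulate_dose_response <- function(true_ic50, hill = 1.2, top = 100,
                                   bottom = 0, noise_sd = 0,
                                   replicates = 3, wells_per_dose = 3,
                                   doses = c(100, 25, 6.3, 1.6, 0.4),
                                   seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  stopifnot(true_ic50 > 0, noise_sd >= 0, all(doses > 0))
  with_seed(seed, {
    blank_corr <- 0.10
    control_corr <- 1.05
    a690 <- 0.05
    rows <- list()
    for (r in seq_len(replicates)) {
      dose_w <- rep(doses, each = wells_per_dose)
      v <- four_pl(dose_w, top, bottom, log10(true_ic50), hill)
      well_corr <- blank_corr + v / 100 * (control_corr - blank_corr)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        well = sprintf("r%d_d%d_w%d", r, rep(seq_along(doses),
                                             each = wells_per_dose),
                       rep(seq_len(wells_per_dose), length(doses))),
        role = "treated", dose = dose_w,
        a570 = well_corr + a690 + stats::rnorm(length(dose_w), 0, noise_sd),
        a690 = a690, replicate = r
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        well = sprintf("r%d_ctrl%d", r, 1:3), role = "control",
        dose = NA_real_,
        a570 = control_corr + a690 + stats::rnorm(3, 0, noise_sd),
        a690 = a690, replicate = r
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        well = sprintf("r%d_blank%d", r, 1:2), role = "blank",
        dose = NA_real_,
        a570 = blank_corr + stats::rnorm(2, 0, noise_sd),
        a690 = 0, replicate = r
      )
    }
    list(
      plate = dplyr::bind_rows(rows),
      truth = list(ic50 = true_ic50, hill = hill, top = top,
                   bottom = bottom)
    )
  })
}

#' Score a dereplication report against simulator ground truth
#'
#' Precision is the fraction of hit-classified features whose neutral mass
#' lies within `tol_ppm` of an emitted planted compound; recall is the
#' fraction of emitted planted compounds recovered as a named hit.
#'
#' @param report A `derep_report` from [dereplicate_table()].
#' @param truth Ground truth from [simulate_extract_profiles()].
#' @param tol_ppm Tolerance used for crediting a feature to a planted mass.
#' @return A list with `precision`, `recall`, `n_hit_features`,
#'   `n_planted`.
#' @export
evaluate_dereplication <- function(report, truth, tol_ppm = 5) {
  stopifnot(inherits(report, "derep_report"))
  tab <- report$table
  planted <- truth$compounds[truth$compounds$emitted, , drop = FALSE]
  hits <- tab[tab$status == "hit", , drop = FALSE]
  hit_features <- unique(hits[, c("feature_id", "neutral_mass")])
  tp <- vapply(hit_features$neutral_mass, function(m) {
    any(abs(1e6 * (m - planted$neutral_mass) / planted$neutral_mass)
        <= tol_ppm)
  }, logical(1))
  precision <- if (nrow(hit_features)) mean(tp) else NA_real_
  recovered <- planted$compound %in% hits$compound
  recall <- if (nrow(planted)) mean(recovered) else NA_real_
  list(
    precision = precision, recall = recall,
    n_hit_features = nrow(hit_features), n_planted = nrow(planted)
  )
}
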