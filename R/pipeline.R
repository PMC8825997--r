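#' Validate a pipeline run configuration
#'
#' A run configuration holds exactly one input source (`simulation` design
#' parameters or `inputs` with positive/negative peak-list paths), the
#' tolerances, chemometrics settings and the output directory. Invalid
#' configurations fail here, before any stage runs.
#'
#' @param config A list, or the path of a YAML file holding one.
#' @return The normalised configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: configuration must be a list")
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop("config error: exactly one of 'simulation' or 'inputs' must be set")
  }
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  if (has_sim && is.null(config$simulation$seed)) {
    stop("config error: simulation requires a seed")
  }
  if (has_inputs &&
      (is.null(config$inputs$positive) || is.null(config$inputs$negative))) {
    stop("config error: inputs require 'positive' and 'negative' paths")
  }
  config$ppm_tol <- config$ppm_tol %||% 5
  config$rt_tol <- config$rt_tol %||% 0.1
  config$derep_tol_ppm <- config$derep_tol_ppm %||% 5
  for (tol in c("ppm_tol", "rt_tol", "derep_tol_ppm")) {
    if (config[[tol]] <= 0) stop("config error: ", tol, " must be positive")
  }
  chem <- config$chemometrics %||% list()
  chem$ncomp <- chem$ncomp %||% 3
  chem$top_n <- chem$top_n %||% 50
  chem$linkage <- chem$linkage %||% "ward"
  config$chemometrics <- chem
  config
}

#' Run the full profiling pipeline
#'
#' Executes the stages in order - simulate or ingest peak lists, align each
#' polarity, convert to neutral masses and merge the modes, dereplicate
#' against the compound library, run the chemometric analyses, and
#' optionally summarise dose-response plates - writing every interchange
#' file into the run directory. Any stage failure aborts with the stage
#' name; the run manifest (configuration echo, per-stage record counts and
#' md5 checksums of all outputs) is written last, so its presence marks a
#' complete run.
#'
#' @param config Run configuration (list or YAML path), see
#'   [validate_run_config()].
#' @return The manifest, invisibly; it is also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  library_tab <- stage("library", {
    if (is.null(config$library)) streptomyces_library()
    else read_compound_library(config$library)
  })

  peaks <- stage("ingest", {
    if (!is.null(config$simulation)) {
      design <- do.call(simulation_design, config$simulation)
      simulate_extract_profiles(design, out_dir = out_dir)
    } else {
      list(
        pos = read_peak_list(config$inputs$positive, polarity = "positive"),
        neg = read_peak_list(config$inputs$negative, polarity = "negative")
      )
    }
  })
  counts$ions_positive <- nrow(peaks$pos)
  counts$ions_negative <- nrow(peaks$neg)

  merged <- stage("annotate", {
    pos_nf <- neutral_features(
      align_features(peaks$pos, config$ppm_tol, config$rt_tol))
    neg_nf <- neutral_features(
      align_features(peaks$neg, config$ppm_tol, config$rt_tol))
    merge_polarities(pos_nf, neg_nf, config$ppm_tol, config$rt_tol)
  })
  counts$neutral_features <- nrow(merged)
  stage("annotate", {
    flat <- merged[, c("feature_id", "neutral_mass", "rt", "provenance",
                       "source_ids")]
    readr::write_tsv(flat, file.path(out_dir, "neutral_features.tsv"),
                     progress = FALSE)
  })

  report <- stage("dereplicate", {
    rep <- dereplicate_table(merged, library_tab, config$derep_tol_ppm)
    write_report(rep, file.path(out_dir, "dereplication.tsv"))
    write_report(rep, file.path(out_dir, "dereplication.json"))
    rep
  })
  counts$features_hit <- report$summary$n_hit
  counts$features_no_hit <- report$summary$n_no_hit

  stage("chemometrics", {
    fm <- neutral_feature_matrix(merged)
    scaled <- pareto_scale(impute_halfmin(fm))
    ncomp <- min(config$chemometrics$ncomp, nrow(scaled) - 1L, ncol(scaled))
    pca <- fit_pca(scaled, ncomp)
    readr::write_tsv(
      tibble::as_tibble(pca$scores, rownames = "sample_id"),
      file.path(out_dir, "pca_scores.tsv"), progress = FALSE)
    readr::write_tsv(
      tibble::as_tibble(pca$loadings, rownames = "feature_id"),
      file.path(out_dir, "pca_loadings.tsv"), progress = FALSE)
    variance <- tibble::tibble(
      component = paste0("PC", seq_along(pca$explained_variance_pct)),
      explained_variance_pct = pca$explained_variance_pct,
      r2_cum = pca$r2_cum
    )
    if (nrow(scaled) >= 3L) {
      q2 <- q2_crossval(scaled, min(ncomp, nrow(scaled) - 2L))
      variance$q2_cum <- c(q2, rep(NA_real_, nrow(variance) - length(q2)))
    }
    readr::write_tsv(variance, file.path(out_dir, "pca_variance.tsv"),
                     progress = FALSE)
    tree <- hca(scaled, linkage = config$chemometrics$linkage)
    writeLines(hca_to_newick(tree), file.path(out_dir, "hca.nwk"))

    groups <- config$groups
    if (!is.null(groups)) {
      labels <- unname(unlist(groups)[rownames(scaled)])
      if (length(unique(labels)) >= 2L) {
        pls <- fit_plsda(scaled, labels,
                         min(ncomp, nrow(scaled) - 1L),
                         config$chemometrics$keep_per_component)
        vip <- vip_scores(pls)
        readr::write_tsv(
          tibble::tibble(feature_id = names(vip), vip = unname(vip)),
          file.path(out_dir, "vip.tsv"), progress = FALSE)
        hm <- heatmap_data(scaled, labels, config$chemometrics$top_n,
                           config$chemometrics$linkage)
        readr::write_tsv(
          tibble::as_tibble(hm$values, rownames = "feature_id"),
          file.path(out_dir, "heatmap.tsv"), progress = FALSE)
      }
    }
  })

  if (!is.null(config$plates)) {
    stage("bioassay", {
      rows <- lapply(names(config$plates), function(nm) {
        plate <- readr::read_csv(config$plates[[nm]], show_col_types = FALSE,
                                 progress = FALSE)
        est <- ic50_from_plate(plate)
        tibble::tibble(assay = nm, ic50_mean = est$mean, ic50_sd = est$sd,
                       n_replicates = length(est$values))
      })
      readr::write_tsv(dplyr::bind_rows(rows),
                       file.path(out_dir, "ic50.tsv"), progress = FALSE)
    })
  }

  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("derepms")),
    config = config,
    counts = counts,
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(outputs))))
  )
  names(manifest$checksums) <- sort(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
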