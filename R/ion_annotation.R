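#' Convert between ion m/z and neutral monoisotopic mass
#'
#' `neutral_mass_from_ion()` maps a measured m/z to the neutral mass implied
#' by an adduct: `neutral = mz * |charge| - mass_shift`. For the default
#' registry this subtracts a proton (1.00728 Da) for `[M+H]+` and adds one
#' for `[M-H]-`. `ion_mz_from_neutral()` is the exact inverse and is what
#' the synthetic-data generator uses to plant ions.
#'
#' The unrounded value is returned; reports conventionally round neutral
#' masses to 4 decimals.
#'
#' @param mz Measured mass-to-charge ratio (Da), vectorised.
#' @param neutral Neutral monoisotopic mass (Da), vectorised.
#' @param adduct Adduct label, polarity, or one-row adduct data frame
#'   (see [resolve_adduct()]).
#' @param registry Adduct registry (see [default_adducts()]).
#' @return Neutral mass, respectively ion m/z, in Da.
#' @examples
#' neutral_mass_from_ion(459.14032, "[M-H]-") # 460.1476
#' ion_mz_from_neutral(460.1476, "[M-H]-")
#' @export
neutral_mass_from_ion <- function(mz, adduct, registry = default_adducts()) {
  a <- resolve_adduct(adduct, registry)
  neutral <- mz * abs(a$charge) - a$mass_shift
  if (any(neutral <= 0)) {
    stop("adduct ", a$label, " implies a non-positive neutral mass")
  }
  neutral
}

#' @rdname neutral_mass_from_ion
#' @export
ion_mz_from_neutral <- function(neutral, adduct, registry = default_adducts()) {
  a <- resolve_adduct(adduct, registry)
  if (any(neutral <= 0)) stop("neutral mass must be positive")
  (neutral + a$mass_shift) / abs(a$charge)
}

#' Align ion features across samples into a feature matrix
#'
#' Greedy clustering of same-polarity ion features: the highest-intensity
#' unassigned feature seeds a cluster that absorbs every feature within
#' `ppm_tol` of its m/z and `rt_tol` of its retention time; cluster
#' centroids that themselves fall within the tolerances are then merged
#' until no such pair remains, so the output clusters are pairwise
#' separated and re-aligning an aligned matrix changes nothing. Each
#' cluster becomes one matrix column with an intensity-weighted mean m/z
#' and retention time; a sample absent from a cluster gets intensity 0, and
#' a sample contributing several ions to one cluster has them summed. Ties
#' in seed intensity are broken by smaller m/z, so the procedure is
#' deterministic.
#'
#' @param features Tibble of ion features (see [read_peak_list()]); all rows
#'   must share one polarity. A list of per-sample tibbles is also accepted.
#' @param ppm_tol m/z tolerance in ppm (default 5, typical Orbitrap
#'   practice).
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return A [feature_matrix()] whose `feature_info` carries the
#'   representative `mz`, `rt` and `polarity` per column.
#' @export
align_features <- function(features, ppm_tol = 5, rt_tol = 0.1) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  if (is.list(features) && !is.data.frame(features)) {
    features <- dplyr::bind_rows(features)
  }
  features <- validate_ion_features(features)
  pol <- unique(features$polarity)
  if (length(pol) > 1L) {
    stop("align_features requires a single polarity; got: ",
         paste(pol, collapse = ", "))
  }
  n <- nrow(features)
  if (n == 0L) stop("no features to align")

  ord <- order(-features$intensity, features$mz, features$rt)
  assigned <- integer(n) # 0 = unassigned
  seeds <- list()
  k <- 0L
  for (i in ord) {
    if (assigned[i] > 0L) next
    k <- k + 1L
    sel <- assigned == 0L &
      abs(features$mz - features$mz[i]) <= features$mz[i] * ppm_tol * 1e-6 &
      abs(features$rt - features$rt[i]) <= rt_tol
    assigned[sel] <- k
  }

  samples <- sort(unique(features$sample_id))
  w <- features$intensity
  # guard against all-zero clusters when averaging
  wplus <- ifelse(w > 0, w, 1e-12)
  cl_w <- as.numeric(tapply(wplus, assigned, sum))
  cl_mz <- as.numeric(tapply(features$mz * wplus, assigned, sum)) / cl_w
  cl_rt <- as.numeric(tapply(features$rt * wplus, assigned, sum)) / cl_w

  values <- matrix(0, nrow = length(samples), ncol = length(cl_mz),
                   dimnames = list(samples, NULL))
  si <- match(features$sample_id, samples)
  ci <- match(assigned, sort(unique(assigned))) # tapply key order
  for (r in seq_len(n)) {
    values[si[r], ci[r]] <- values[si[r], ci[r]] + features$intensity[r]
  }

  # merge any clusters whose centroids still fall within the tolerances
  # (a compound's per-sample jitter can exceed the tolerance between the
  # extreme ions even though every ion is within it of the centroid)
  repeat {
    k <- length(cl_mz)
    if (k < 2L) break
    pair <- NULL; best <- Inf; best_rt <- Inf
    ord <- order(cl_mz)
    for (a in seq_len(k - 1L)) {
      i <- ord[a]
      for (b in (a + 1L):k) {
        j <- ord[b]
        dppm <- 1e6 * (cl_mz[j] - cl_mz[i]) / cl_mz[i]
        if (dppm > ppm_tol) break
        if (abs(cl_rt[i] - cl_rt[j]) > rt_tol) next
        rt_min <- min(cl_rt[i], cl_rt[j])
        if (dppm < best - 1e-12 ||
            (abs(dppm - best) <= 1e-12 && rt_min < best_rt)) {
          best <- dppm; best_rt <- rt_min; pair <- c(i, j)
        }
      }
    }
    if (is.null(pair)) break
    i <- pair[1]; j <- pair[2]
    wt <- cl_w[i] + cl_w[j]
    cl_mz[i] <- (cl_mz[i] * cl_w[i] + cl_mz[j] * cl_w[j]) / wt
    cl_rt[i] <- (cl_rt[i] * cl_w[i] + cl_rt[j] * cl_w[j]) / wt
    cl_w[i] <- wt
    values[, i] <- values[, i] + values[, j]
    keep <- setdiff(seq_len(length(cl_mz)), j)
    cl_mz <- cl_mz[keep]; cl_rt <- cl_rt[keep]; cl_w <- cl_w[keep]
    values <- values[, keep, drop = FALSE]
  }

  cl_order <- order(cl_mz, cl_rt)
  values <- values[, cl_order, drop = FALSE]
  prefix <- if (pol == "positive") "P" else "N"
  ids <- sprintf("%s%04d", prefix, seq_along(cl_order))
  colnames(values) <- ids
  feature_matrix(
    values,
    feature_info = tibble::tibble(
      feature_id = ids,
      mz = cl_mz[cl_order],
      rt = cl_rt[cl_order],
      polarity = pol
    )
  )
}

#' Convert an aligned single-polarity matrix to neutral features
#'
#' Applies the adduct implied by the matrix polarity (protonated for
#' positive mode, deprotonated for negative mode by default) to every
#' feature, yielding the table of neutral monoisotopic masses that
#' dereplication matches on.
#'
#' @param fm A single-polarity [feature_matrix()] from [align_features()].
#' @param adduct Optional explicit adduct; defaults to the registry entry
#'   for the matrix polarity.
#' @param registry Adduct registry.
#' @return A tibble of neutral features: `feature_id`, `neutral_mass`, `rt`,
#'   `provenance`, a list-column `intensities` (named per-sample vectors)
#'   and a list-column `ions` of supporting ion records.
#' @export
neutral_features <- function(fm, adduct = NULL, registry = default_adducts()) {
  stopifnot(inherits(fm, "feature_matrix"))
  info <- fm$feature_info
  pol <- unique(info$polarity)
  stopifnot(length(pol) == 1L)
  a <- resolve_adduct(adduct %||% pol, registry)
  provenance <- if (pol == "positive") "positive_only" else "negative_only"
  intensities <- lapply(seq_len(ncol(fm$values)), function(j) {
    stats::setNames(fm$values[, j], rownames(fm$values))
  })
  ions <- lapply(seq_len(nrow(info)), function(j) {
    tibble::tibble(mz = info$mz[j], polarity = pol, adduct = a$label)
  })
  tibble::tibble(
    feature_id = info$feature_id,
    neutral_mass = neutral_mass_from_ion(info$mz, a),
    rt = info$rt,
    provenance = provenance,
    intensities = intensities,
    ions = ions
  )
}

#' Merge positive- and negative-mode neutral features
#'
#' Pairs features from the two ionization modes whose neutral masses agree
#' within `ppm_tol` and retention times within `rt_tol`, merging each pair
#' into one `both_modes` feature (per-sample intensities summed, neutral
#' mass and retention time intensity-weighted means). Pairing is greedy
#' best-first on absolute ppm discrepancy with ties broken by earlier
#' retention time, and each feature merges at most once. Unpaired features
#' pass through with their single-mode provenance.
#'
#' Total intensity is conserved: merging never creates or destroys signal.
#'
#' @param pos,neg Neutral-feature tibbles from [neutral_features()]; either
#'   may be empty or NULL.
#' @param ppm_tol Neutral-mass tolerance in ppm (default 5).
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return A combined neutral-feature tibble sorted by neutral mass, with
#'   fresh `feature_id`s (`M0001`, ...) and the contributing ids in
#'   `source_ids`.
#' @export
merge_polarities <- function(pos, neg, ppm_tol = 5, rt_tol = 0.1) {
  empty <- function(x) is.null(x) || nrow(x) == 0L
  if (empty(pos) && empty(neg)) {
    return(relabel_neutral(dplyr::bind_rows(pos, neg)))
  }
  if (empty(pos) || empty(neg)) {
    return(relabel_neutral(if (empty(pos)) neg else pos))
  }

  pairs <- tidyr::expand_grid(i = seq_len(nrow(pos)), j = seq_len(nrow(neg)))
  mean_mass <- (pos$neutral_mass[pairs$i] + neg$neutral_mass[pairs$j]) / 2
  dppm <- 1e6 * abs(pos$neutral_mass[pairs$i] - neg$neutral_mass[pairs$j]) /
    mean_mass
  drt <- abs(pos$rt[pairs$i] - neg$rt[pairs$j])
  pairs <- pairs[dppm <= ppm_tol & drt <= rt_tol, , drop = FALSE]
  dppm <- dppm[dppm <= ppm_tol & drt <= rt_tol]
  min_rt <- pmin(pos$rt[pairs$i], neg$rt[pairs$j])
  ord <- order(dppm, min_rt)
  pairs <- pairs[ord, , drop = FALSE]

  used_pos <- logical(nrow(pos))
  used_neg <- logical(nrow(neg))
  merged <- vector("list", nrow(pairs))
  m <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_pos[i] || used_neg[j]) next
    used_pos[i] <- TRUE; used_neg[j] <- TRUE
    m <- m + 1L
    merged[[m]] <- merge_pair(pos[i, ], neg[j, ])
  }
  out <- dplyr::bind_rows(
    if (m > 0L) dplyr::bind_rows(merged[seq_len(m)]),
    pos[!used_pos, , drop = FALSE],
    neg[!used_neg, , drop = FALSE]
  )
  relabel_neutral(out)
}

merge_pair <- function(a, b) {
  wa <- sum(a$intensities[[1]])
  wb <- sum(b$intensities[[1]])
  w <- if (wa + wb > 0) c(wa, wb) else c(1, 1)
  samples <- union(names(a$intensities[[1]]), names(b$intensities[[1]]))
  ints <- stats::setNames(numeric(length(samples)), samples)
  ints[names(a$intensities[[1]])] <- a$intensities[[1]]
  ints[names(b$intensities[[1]])] <- ints[names(b$intensities[[1]])] +
    b$intensities[[1]]
  tibble::tibble(
    feature_id = paste(a$feature_id, b$feature_id, sep = "+"),
    neutral_mass = sum(c(a$neutral_mass, b$neutral_mass) * w) / sum(w),
    rt = sum(c(a$rt, b$rt) * w) / sum(w),
    provenance = "both_modes",
    intensities = list(ints),
    ions = list(dplyr::bind_rows(a$ions[[1]], b$ions[[1]]))
  )
}

relabel_neutral <- function(nf) {
  if (is.null(nf) || nrow(nf) == 0L) {
    return(tibble::tibble(
      feature_id = character(), neutral_mass = numeric(), rt = numeric(),
      provenance = character(), intensities = list(), ions = list(),
      source_ids = character()
    ))
  }
  nf <- nf[order(nf$neutral_mass, nf$rt), , drop = FALSE]
  nf$source_ids <- nf$feature_id
  nf$feature_id <- sprintf("M%04d", seq_len(nrow(nf)))
  nf
}

#' Build a samples-by-features matrix from neutral features
#'
#' @param nf Neutral-feature tibble from [merge_polarities()] or
#'   [neutral_features()].
#' @param group_labels Optional per-sample class labels (named by sample or
#'   in sample order).
#' @return A [feature_matrix()] whose `feature_info` carries `neutral_mass`,
#'   `rt` and `provenance`.
#' @export
neutral_feature_matrix <- function(nf, group_labels = NULL) {
  samples <- sort(unique(unlist(lapply(nf$intensities, names))))
  values <- matrix(0, nrow = length(samples), ncol = nrow(nf),
                   dimnames = list(samples, nf$feature_id))
  for (j in seq_len(nrow(nf))) {
    v <- nf$intensities[[j]]
    values[names(v), j] <- v
  }
  if (!is.null(group_labels) && !is.null(names(group_labels))) {
    group_labels <- unname(group_labels[samples])
  }
  feature_matrix(
    values,
    feature_info = tibble::tibble(
      feature_id = nf$feature_id, neutral_mass = nf$neutral_mass,
      rt = nf$rt, provenance = nf$provenance
    ),
    group_labels = group_labels
  )
}
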