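#' Pareto-scale an intensity matrix
#'
#' Per feature: subtract the mean and divide by the square root of the
#' (sample) standard deviation. Pareto scaling damps, but does not erase,
#' the dominance of high-intensity metabolites, which is why it is the
#' customary normalisation for MS intensity matrices. Zero-variance
#' features are mapped to all-zero columns and flagged in the
#' `zero_variance` attribute.
#'
#' @param x A [feature_matrix()] or a numeric samples-by-features matrix
#'   with at least 2 samples.
#' @return The scaled numeric matrix, with attributes `center`, `scale` and
#'   `zero_variance`.
#' @export
pareto_scale <- function(x) {
  x <- to_values(x)
  if (nrow(x) < 2L) stop("Pareto scaling needs at least 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero_var <- sds == 0
  scl <- sqrt(ifelse(zero_var, 1, sds))
  out <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  out[, zero_var] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "zero_variance") <- zero_var
  out
}

#' Impute missing intensities as half the minimum positive value
#'
#' Zeros (a feature not detected in a sample) and NAs are replaced by half
#' the smallest positive intensity in the whole matrix, the common
#' metabolomics stand-in for values below the detection limit.
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @return Numeric matrix with no zeros or NAs.
#' @export
impute_halfmin <- function(x) {
  x <- to_values(x)
  pos <- x[is.finite(x) & x > 0]
  if (!length(pos)) stop("matrix has no positive intensities to impute from")
  x[!is.finite(x) | x == 0] <- min(pos) / 2
  x
}

to_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Principal component analysis with deterministic sign convention
#'
#' Columns are mean-centred and decomposed by singular values; component
#' `a` is the best rank-`a` least-squares direction. The explained-variance
#' percentages are computed from the singular values over the full rank, so
#' they sum to 100. For reproducibility each loading vector is flipped so
#' its largest-magnitude element is positive. `r2_cum` is the cumulative
#' explained-variance fraction (the usual goodness-of-fit R2 of a PCA
#' model).
#'
#' @param x Scaled numeric matrix (samples x features) or
#'   [feature_matrix()].
#' @param n_components Number of components to retain (default: full rank).
#' @return An object of class `pca_model` with `scores`, `loadings`,
#'   `explained_variance_pct`, `eigenvalues`, `r2_cum` and `center`.
#' @export
fit_pca <- function(x, n_components = NULL) {
  x <- to_values(x)
  n <- nrow(x); p <- ncol(x)
  rank_max <- min(n - 1L, p)
  n_components <- n_components %||% rank_max
  if (n_components < 1L || n_components > rank_max) {
    stop("n_components must be between 1 and min(samples - 1, features) = ",
         rank_max)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr, "-")
  if (all(abs(xc) < 1e-12)) stop("matrix is constant: PCA undefined")
  sv <- svd(xc)
  d <- sv$d[seq_len(rank_max)]
  var_pct <- 100 * d^2 / sum(d^2)
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(d[k], nrow = length(k))
  loadings <- sv$v[, k, drop = FALSE]
  for (a in k) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", k))
  dimnames(loadings) <- list(colnames(x), paste0("PC", k))
  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_variance_pct = var_pct[k],
      full_variance_pct = var_pct,
      eigenvalues = d^2 / (n - 1),
      r2_cum = cumsum(var_pct[k]) / 100,
      center = ctr
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", ncol(x$scores), " components; explained variance: ",
      paste0(sprintf("%.1f", x$explained_variance_pct), "%",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cross-validated predictability (Q2) of a PCA model
#'
#' Leave-one-out scheme: each sample is held out in turn, a PCA is refitted
#' on the rest, and the held-out sample is predicted by projection onto the
#' training loadings. `Q2 = 1 - PRESS/TSS`, reported cumulatively over
#' components. Values above 0.5 are conventionally read as a significant
#' model; white noise scores near or below zero.
#'
#' @param x Scaled numeric matrix (>= 3 samples) or [feature_matrix()].
#' @param n_components Number of components; must not exceed the rank of
#'   the leave-one-out refits, `min(samples - 2, features)`.
#' @return Numeric vector of cumulative Q2 per component.
#' @export
q2_crossval <- function(x, n_components = NULL) {
  x <- to_values(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("Q2 cross-validation needs at least 3 samples")
  rank_max <- min(n - 2L, p)
  n_components <- n_components %||% rank_max
  if (n_components < 1L || n_components > rank_max) {
    stop("n_components exceeds leave-one-out refit rank ", rank_max)
  }
  press <- numeric(n_components)
  tss <- 0
  for (i in seq_len(n)) {
    train <- x[-i, , drop = FALSE]
    ctr <- colMeans(train)
    sv <- svd(sweep(train, 2, ctr, "-"), nu = 0, nv = n_components)
    held <- x[i, ] - ctr
    tss <- tss + sum(held^2)
    proj <- numeric(length(held))
    for (a in seq_len(n_components)) {
      v <- sv$v[, a]
      proj <- proj + sum(held * v) * v
      press[a] <- press[a] + sum((held - proj)^2)
    }
  }
  1 - press / tss
}

#' Partial least-squares discriminant analysis (PLS-DA / sPLS-DA)
#'
#' Fits a PLS2 model of the scaled intensity matrix against the one-hot
#' (dummy) class matrix by the NIPALS algorithm with deflation of both
#' blocks. When `keep_per_component` is given, each component's weight
#' vector is truncated to its largest-magnitude entries before
#' normalisation (the sparse variant, sPLS-DA); by default all features are
#' kept, i.e. plain PLS-DA. Weight vectors are sign-fixed so their
#' largest-magnitude element is positive.
#'
#' @param x Scaled numeric matrix (samples x features) or
#'   [feature_matrix()].
#' @param labels Per-sample class labels (>= 2 distinct classes).
#' @param n_components Number of latent components (default
#'   `min(3, samples - 1)`; must be `<= samples - 1`).
#' @param keep_per_component Optional number of features retained per
#'   component (sparsity).
#' @return An object of class `plsda_model` with `scores`, `weights`,
#'   `x_loadings`, `y_loadings`, `explained_variance_pct` (feature block),
#'   `ssy` (class variance explained per component, used by VIP),
#'   `selected_features`, `classes` and `labels`.
#' @export
fit_plsda <- function(x, labels, n_components = NULL,
                      keep_per_component = NULL) {
  x <- to_values(x)
  n <- nrow(x); p <- ncol(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("PLS-DA needs at least 2 distinct classes")
  }
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    warning("class(es) with a single sample: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "),
            "; downstream cross-validation will be unstable")
  }
  n_components <- n_components %||% min(3L, n - 1L)
  if (n_components > n - 1L) stop("n_components must be <= samples - 1")

  Y <- outer(labels, classes, "==") * 1
  Y <- sweep(Y, 2, colMeans(Y), "-")
  ctr <- colMeans(x)
  X <- sweep(x, 2, ctr, "-")
  tss_x <- sum(X^2)

  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, length(classes), n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- xvar <- numeric(n_components)
  selected <- vector("list", n_components)

  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (iter in seq_len(500L)) {
      w <- crossprod(X, u)[, 1] / sum(u^2)
      if (!is.null(keep_per_component) && keep_per_component < p) {
        cut <- sort(abs(w), decreasing = TRUE)[keep_per_component]
        w[abs(w) < cut] <- 0
      }
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) stop("degenerate weight vector (component ", a, ")")
      w <- w / nw
      tt <- X %*% w
      q <- crossprod(Y, tt)[, 1] / sum(tt^2)
      u <- (Y %*% q)[, 1] / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-12 * sum(tt^2)) break
      t_old <- tt
    }
    j <- which.max(abs(w))
    if (w[j] < 0) {
      w <- -w; tt <- -tt; q <- -q
    }
    pp <- crossprod(X, tt)[, 1] / sum(tt^2)
    X <- X - tt %*% t(pp)
    Y <- Y - tt %*% t(q)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)
    xvar[a] <- 100 * sum(tt^2) * sum(pp^2) / tss_x
    selected[[a]] <- which(w != 0)
  }

  fid <- colnames(x) %||% paste0("F", seq_len(p))
  dimnames(W) <- dimnames(P) <- list(fid, paste0("comp", seq_len(n_components)))
  dimnames(Tm) <- list(rownames(x), colnames(W))
  dimnames(Q) <- list(classes, colnames(W))
  selected <- lapply(selected, function(i) fid[i])
  structure(
    list(
      scores = Tm, weights = W, x_loadings = P, y_loadings = Q,
      explained_variance_pct = xvar, ssy = ssy,
      selected_features = selected, classes = classes, labels = labels,
      center = ctr, keep_per_component = keep_per_component
    ),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", ncol(x$scores), " components over ",
      length(x$classes), " classes; X variance: ",
      paste0(sprintf("%.1f", x$explained_variance_pct), "%",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with `p` features
#' and `SSY_a` the class variance explained by component `a`. Because the
#' weight vectors are unit-norm, the mean of `VIP^2` over features is
#' exactly 1; features with VIP above ~1 contribute disproportionately to
#' class separation.
#'
#' @param model A fitted [fit_plsda()] model.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$weights
  p <- nrow(W)
  num <- (W^2) %*% model$ssy
  sqrt(p * num[, 1] / sum(model$ssy))
}

#' Hierarchical cluster analysis of sample profiles
#'
#' Agglomerative clustering of the rows of a (scaled) matrix under the
#' chosen metric and linkage. Ward linkage on Euclidean distances is the
#' default pairing, matching common metabolomics practice. The result is a
#' standard `hclust` structure (so `plot()` draws a dendrogram) annotated
#' with the metric and linkage used.
#'
#' @param x Numeric matrix (rows are clustered) or [feature_matrix()].
#' @param metric Distance metric; `"euclidean"`.
#' @param linkage One of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @return An object of classes `hca_tree` and `hclust`.
#' @export
hca <- function(x, metric = "euclidean",
                linkage = c("ward", "average", "complete", "single")) {
  x <- to_values(x)
  linkage <- match.arg(linkage)
  if (nrow(x) < 2L) stop("clustering needs at least 2 rows")
  if (any(!is.finite(x))) stop("matrix contains non-finite values")
  metric <- match.arg(metric, "euclidean")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(stats::dist(x, method = metric), method = method)
  tree$metric <- metric
  tree$linkage <- linkage
  class(tree) <- c("hca_tree", "hclust")
  tree
}

#' Export an HCA tree in Newick format
#'
#' @param tree An `hca_tree` / `hclust` object.
#' @return A single Newick string with branch lengths from merge heights.
#' @export
hca_to_newick <- function(tree) {
  phylo <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phylo)
}

#' Rank features by one-way ANOVA across groups
#'
#' Computes a per-feature one-way analysis of variance over the sample
#' groups and returns the `n` features with the smallest p-values (ties
#' broken by larger F). With two groups the F statistic is the square of
#' the pooled-variance t statistic. When any group has fewer than 2 samples
#' a valid F cannot be formed and the ranking falls back to overall feature
#' variance, with a warning. Fisher's LSD pairwise p-values are attached
#' for the selected features as post hoc context; they do not affect the
#' ranking.
#'
#' @param x Numeric matrix (samples x features) or [feature_matrix()].
#' @param labels Per-sample group labels.
#' @param n Number of features to return (must be positive).
#' @param posthoc Attach Fisher's LSD pairwise p-values per selected
#'   feature (default TRUE when a valid ANOVA is possible).
#' @return A tibble `feature_id`, `f_statistic`, `p_value` (and list-column
#'   `lsd` of pairwise p-value matrices when `posthoc`), ordered by
#'   ascending p.
#' @export
top_features_anova <- function(x, labels, n, posthoc = TRUE) {
  x <- to_values(x)
  if (n <= 0) stop("n must be positive")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  fid <- colnames(x) %||% paste0("F", seq_len(ncol(x)))
  g <- factor(labels)
  sizes <- table(g)
  valid <- nlevels(g) >= 2L && all(sizes >= 2L)
  if (!valid) {
    warning("groups unsuitable for ANOVA (need >= 2 groups with >= 2 ",
            "samples each); falling back to variance ranking")
    v <- apply(x, 2, stats::var)
    ord <- order(-v)
    keep <- ord[seq_len(min(n, ncol(x)))]
    return(tibble::tibble(
      feature_id = fid[keep], f_statistic = NA_real_, p_value = NA_real_,
      variance = v[keep]
    ))
  }
  stats_tab <- vapply(seq_len(ncol(x)), function(j) {
    ft <- tryCatch(stats::oneway.test(x[, j] ~ g, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$statistic)) c(0, 1) else
      c(unname(ft$statistic), unname(ft$p.value))
  }, numeric(2))
  fstat <- stats_tab[1, ]; pval <- stats_tab[2, ]
  ord <- order(pval, -fstat)
  keep <- ord[seq_len(min(n, ncol(x)))]
  out <- tibble::tibble(
    feature_id = fid[keep], f_statistic = fstat[keep], p_value = pval[keep]
  )
  if (posthoc) {
    out$lsd <- lapply(keep, function(j) {
      pt <- stats::pairwise.t.test(x[, j], g, p.adjust.method = "none",
                                   pool.sd = TRUE)
      pt$p.value
    })
  }
  out
}

#' Assemble heatmap data from ANOVA-selected features
#'
#' Restricts the matrix to the `n_top` most group-discriminating features
#' (one-way ANOVA ranking), autoscales each feature to z-scores for
#' display, and orders both features and samples by hierarchical
#' clustering. Rows of the result are features, columns are samples, the
#' layout conventional for metabolite-intensity heatmaps (red high, blue
#' low once plotted).
#'
#' @param x Numeric matrix (samples x features) or [feature_matrix()].
#' @param labels Per-sample group labels.
#' @param n_top Number of top features to keep.
#' @param linkage Linkage passed to [hca()] for both axes.
#' @return An object of class `heatmap_data`: list with `values`
#'   (features x samples, z-scored and ordered), `feature_order`,
#'   `sample_order`, `feature_tree`, `sample_tree`, `top_features`.
#' @export
heatmap_data <- function(x, labels, n_top, linkage = "ward") {
  x <- to_values(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  top <- top_features_anova(x, labels, n_top, posthoc = FALSE)
  sub <- x[, top$feature_id, drop = FALSE]
  z <- scale(sub) # per-feature z-score
  z[, attr(z, "scaled:scale") == 0] <- 0
  zt <- t(z) # features x samples
  feature_tree <- if (nrow(zt) >= 2L) hca(zt, linkage = linkage) else NULL
  sample_tree <- if (ncol(zt) >= 2L) hca(t(zt), linkage = linkage) else NULL
  f_ord <- if (is.null(feature_tree)) seq_len(nrow(zt)) else feature_tree$order
  s_ord <- if (is.null(sample_tree)) seq_len(ncol(zt)) else sample_tree$order
  structure(
    list(
      values = zt[f_ord, s_ord, drop = FALSE],
      feature_order = rownames(zt)[f_ord],
      sample_order = colnames(zt)[s_ord],
      feature_tree = feature_tree,
      sample_tree = sample_tree,
      top_features = top,
      group_labels = stats::setNames(as.character(labels), rownames(x))
    ),
    class = "heatmap_data"
  )
}

#' @export
print.heatmap_data <- function(x, ...) {
  cat("<heatmap_data> ", nrow(x$values), " features x ", ncol(x$values),
      " samples (z-scored)\n", sep = "")
  invisible(x)
}
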