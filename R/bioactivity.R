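#' Percent viability from MTT absorbances
#'
#' Each well's corrected absorbance is its signal reading (570 nm) minus its
#' background reading (690 nm). Viability is the corrected well absorbance
#' relative to untreated control wells, after subtracting the medium blank:
#' `100 * (well - blank) / (control - blank)`. Negative values (wells below
#' the blank) are clipped to 0 and flagged in the `clipped` attribute. The
#' computation is invariant to adding a constant to both readings of every
#' well type.
#'
#' @param well_signal,well_background Per-well absorbances (vectorised).
#' @param control_signal,control_background Averaged untreated-control
#'   absorbances.
#' @param blank_signal,blank_background Averaged medium-blank absorbances.
#' @return Percent viability, with attribute `clipped`.
#' @examples
#' viability_percent(0.60, 0.05, 1.15, 0.05, 0.10, 0.00) # 45.00
#' @export
viability_percent <- function(well_signal, well_background,
                              control_signal, control_background,
                              blank_signal = 0, blank_background = 0) {
  well <- well_signal - well_background
  control <- control_signal - control_background
  blank <- blank_signal - blank_background
  if (control <= blank) {
    stop("control absorbance does not exceed blank: assay failure")
  }
  v <- 100 * (well - blank) / (control - blank)
  clipped <- v < 0
  v[clipped] <- 0
  attr(v, "clipped") <- clipped
  v
}

#' Summarise a plate table into per-dose viabilities
#'
#' Expects the plate layout used throughout this package: columns `role`
#' (`treated` / `control` / `blank`), `dose`, `a570`, `a690` and
#' optionally `replicate`. Control and blank wells are averaged
#' (per replicate when a `replicate` column is present) and every treated
#' well is converted to percent viability.
#'
#' @param plate A data frame of plate readings.
#' @return A tibble `dose`, `replicate`, `viability`.
#' @export
plate_viability <- function(plate) {
  for (col in c("role", "dose", "a570", "a690")) {
    if (!col %in% names(plate)) stop("plate table is missing column '", col, "'")
  }
  if (!"replicate" %in% names(plate)) plate$replicate <- 1L
  reps <- sort(unique(plate$replicate))
  out <- lapply(reps, function(r) {
    p <- plate[plate$replicate == r, ]
    ctrl <- p[p$role == "control", ]
    blk <- p[p$role == "blank", ]
    trt <- p[p$role == "treated", ]
    if (!nrow(ctrl)) stop("no control wells in replicate ", r)
    v <- viability_percent(
      trt$a570, trt$a690,
      mean(ctrl$a570), mean(ctrl$a690),
      if (nrow(blk)) mean(blk$a570) else 0,
      if (nrow(blk)) mean(blk$a690) else 0
    )
    tibble::tibble(dose = trt$dose, replicate = r,
                   viability = as.numeric(v))
  })
  dplyr::bind_rows(out)
}

# 4-parameter logistic on log10 concentration: decreasing for hill > 0
four_pl <- function(conc, top, bottom, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log_ic50)))
}

#' Fit an IC50 from a dose-response curve
#'
#' Fits a four-parameter logistic (4PL) survival curve on log10
#' concentration by least squares (Levenberg-Marquardt), with the top
#' asymptote constrained to at most 120% and the bottom to at least -5% to
#' stabilise fits on short 5-dose series. The IC50 is the concentration at
#' 50% viability. If the optimiser fails, the estimate falls back to
#' log-linear interpolation between the doses bracketing 50% and records
#' `method = "interpolation"`. When the observed viabilities never cross
#' 50% the estimate is flagged `extrapolated`.
#'
#' @param concentrations Dose series (same units as the reported IC50,
#'   conventionally ug/ml).
#' @param viabilities Mean percent viability per dose.
#' @return An object of class `ic50_fit`: list with `ic50`, `top`,
#'   `bottom`, `hill`, `method`, `extrapolated`, `residual_sd`.
#' @export
fit_ic50 <- function(concentrations, viabilities) {
  stopifnot(length(concentrations) == length(viabilities),
            all(concentrations > 0))
  if (length(concentrations) < 4L) {
    stop("at least 4 concentrations are needed for a 4-parameter fit")
  }
  ord <- order(concentrations)
  conc <- concentrations[ord]
  v <- viabilities[ord]
  spans50 <- min(v) <= 50 && max(v) >= 50

  start <- list(
    top = min(max(v), 120), bottom = max(min(v), -5),
    log_ic50 = log10(interp_ic50(conc, v) %||% stats::median(conc)),
    hill = 1
  )
  df <- data.frame(conc = conc, v = v)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      v ~ four_pl(conc, top, bottom, log_ic50, hill),
      data = df, start = start,
      lower = c(top = 10, bottom = -5, log_ic50 = log10(min(conc)) - 3,
                hill = 0.05),
      upper = c(top = 120, bottom = 45, log_ic50 = log10(max(conc)) + 3,
                hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )),
    error = function(e) NULL
  )

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    est <- list(
      ic50 = unname(10^cf[["log_ic50"]]), top = unname(cf[["top"]]),
      bottom = unname(cf[["bottom"]]), hill = unname(cf[["hill"]]),
      method = "4PL",
      residual_sd = stats::sigma(fit)
    )
  } else {
    ic <- interp_ic50(conc, v)
    if (is.null(ic)) {
      stop("dose-response curve does not allow IC50 estimation: ",
           "no convergent fit and no doses bracketing 50%")
    }
    est <- list(ic50 = ic, top = max(v), bottom = min(v), hill = NA_real_,
                method = "interpolation", residual_sd = NA_real_)
  }
  est$extrapolated <- !spans50 ||
    est$ic50 < min(conc) || est$ic50 > max(conc)
  if (!spans50 && min(v) > 50) {
    # viability never drops below 50%: the IC50 lies beyond the top dose
    est$ic50 <- max(est$ic50, max(conc) * (1 + 1e-9))
  }
  class(est) <- "ic50_fit"
  est
}

# log-linear interpolation between the pair of adjacent doses bracketing 50%
interp_ic50 <- function(conc, v) {
  for (i in seq_len(length(conc) - 1L)) {
    lo <- v[i]; hi <- v[i + 1L]
    if ((lo - 50) * (hi - 50) <= 0 && lo != hi) {
      f <- (50 - lo) / (hi - lo)
      return(10^(log10(conc[i]) + f * (log10(conc[i + 1L]) - log10(conc[i]))))
    }
  }
  NULL
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit> IC50 = ", signif(x$ic50, 4), " (", x$method,
      if (x$extrapolated) ", extrapolated" else "", ")\n", sep = "")
  invisible(x)
}

#' Fit IC50 per replicate and summarise as mean +/- sd
#'
#' @param plate Plate table (see [plate_viability()]).
#' @return A list with `mean`, `sd`, `fits` (per-replicate `ic50_fit`s) and
#'   `values` (per-replicate IC50s).
#' @export
ic50_from_plate <- function(plate) {
  via <- plate_viability(plate)
  reps <- split(via, via$replicate)
  fits <- lapply(reps, function(d) {
    agg <- stats::aggregate(viability ~ dose, data = d, FUN = mean)
    fit_ic50(agg$dose, agg$viability)
  })
  values <- vapply(fits, function(f) f$ic50, numeric(1))
  list(mean = mean(values), sd = stats::sd(values), fits = fits,
       values = values)
}

#' Compare two groups of IC50 replicates by unpaired t-test
#'
#' Two-sample pooled-variance (Student's) t-test with a two-sided p-value,
#' mapped to the conventional significance tiers: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, otherwise `ns`. When both groups
#' are constant and equal the statistic is undefined; the comparison is
#' reported as `ns` with `undefined = TRUE`.
#'
#' @param a,b Numeric vectors of replicate values (>= 2 each).
#' @return An object of class `group_comparison`: list with `t_statistic`,
#'   `df`, `p_value`, `tier`, `undefined`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    out <- list(t_statistic = 0, df = length(a) + length(b) - 2L,
                p_value = 1, tier = "ns", undefined = TRUE)
  } else {
    out <- list(
      t_statistic = unname(res$statistic), df = unname(res$parameter),
      p_value = res$p.value, tier = significance_tier(res$p.value),
      undefined = FALSE
    )
  }
  class(out) <- "group_comparison"
  out
}

#' Map a p-value to a significance tier
#'
#' @param p p-value in `[0, 1]`.
#' @return `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significance_tier <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> t = ", signif(x$t_statistic, 4), ", df = ", x$df,
      ", p = ", signif(x$p_value, 3), " (", x$tier, ")\n", sep = "")
  invisible(x)
}
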