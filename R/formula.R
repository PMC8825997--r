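#' Parse a molecular formula string
#'
#' Parses Hill-notation formula strings such as `"C22H24N2O9"` into a named
#' integer vector of element counts. A count of 1 may be omitted
#' (`"C16H21NO"`). Underscore-decorated subscripts (`"C_7_H_10_O_2_"`) are
#' tolerated since library tables are often exported that way.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts, in Hill order.
#' @examples
#' parse_formula("C22H24N2O9")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[_[:space:]]", "", formula)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1L]]
  tokens <- regmatches(s, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("unparseable molecular formula: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(counts == "", "1", counts)
  counts <- as.integer(counts)
  unknown <- setdiff(elems, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s) in '", formula, "': ",
         paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, elems, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  hill_order(counts)
}

# Order a count vector in Hill convention: C, then H, then others
# alphabetically. Zero counts are dropped.
hill_order <- function(counts) {
  counts <- counts[counts > 0]
  elems <- names(counts)
  rest <- sort(setdiff(elems, c("C", "H")))
  ord <- c(intersect(c("C", "H"), elems), rest)
  counts[ord]
}

#' Format element counts as a Hill-notation string
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string, e.g. `"C22H24N2O9"`.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts)
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums monoisotopic atomic masses over the element counts
#' (C 12 exactly, H 1.0078250319, N 14.0030740052, O 15.9949146221,
#' P 30.97376151, S 31.97207069).
#'
#' @param formula Formula string or named count vector.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C22H24N2O9") # 460.1482
#' @export
monoisotopic_mass <- function(formula) {
  counts <- as_counts(formula)
  if (!length(counts) || all(counts == 0L)) {
    stop("formula has no atoms")
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

as_counts <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  if (any(formula < 0)) stop("negative element count")
  unknown <- setdiff(names(formula)[formula > 0], names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- as.integer(round(formula))
  names(counts) <- names(formula)
  hill_order(counts)
}

#' Rings-plus-double-bond equivalents (RDBE)
#'
#' `RDBE = C - H/2 + (N + P)/2 + 1`; oxygen and sulfur are neutral. Used to
#' reject chemically impossible formula candidates.
#'
#' @inheritParams monoisotopic_mass
#' @return A half-integer RDBE value.
#' @examples
#' rdbe("C6H6") # 4
#' @export
rdbe <- function(formula) {
  counts <- as_counts(formula)
  cnt <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  cnt("C") - cnt("H") / 2 + (cnt("N") + cnt("P")) / 2 + 1
}

#' Nitrogen-rule check for an even-electron neutral molecule
#'
#' A formula passes when its RDBE is integer-valued, i.e. the N + P parity is
#' consistent with an even-electron neutral species.
#'
#' @inheritParams monoisotopic_mass
#' @return Logical.
#' @export
nitrogen_rule_ok <- function(formula) {
  r <- rdbe(formula)
  abs(r - round(r)) < 1e-9
}

#' Default element ranges for formula enumeration
#'
#' Wide CHNOPS box covering typical microbial secondary metabolites up to
#' well beyond 1 kDa (C 0-60, H 0-100, N 0-10, O 0-25, P 0-3, S 0-3).
#'
#' @return Named list of `c(min, max)` integer pairs.
#' @export
default_element_ranges <- function() {
  list(
    C = c(0L, 60L), H = c(0L, 100L), N = c(0L, 10L),
    O = c(0L, 25L), P = c(0L, 3L), S = c(0L, 3L)
  )
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Exhaustively enumerates elemental compositions inside the given integer
#' box whose monoisotopic mass matches `neutral_mass` within `tol_ppm`, then
#' filters on RDBE bounds and (optionally) the nitrogen rule. Candidates are
#' returned sorted by absolute ppm error, ties broken by fewer total atoms
#' and then lexicographic Hill string, with consecutive ranks from 1.
#'
#' The search sweeps the non-hydrogen elements over their ranges with
#' mass-bound pruning and solves the hydrogen count arithmetically from the
#' mass remainder, so the enumeration is exhaustive over the box.
#'
#' @param neutral_mass Query neutral monoisotopic mass (Da).
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param element_ranges Named list of `c(min, max)` pairs per element, see
#'   [default_element_ranges()].
#' @param rdbe_min,rdbe_max RDBE bounds (defaults 0 and 40).
#' @param nitrogen_rule If `TRUE`, candidates failing the nitrogen rule are
#'   dropped; by default the rule is only annotated.
#' @return A tibble with columns `formula`, `mass`, `ppm_error`,
#'   `rdbe`, `passes_nitrogen_rule`, `rank`.
#' @examples
#' enumerate_formulas(460.1476, tol_ppm = 5)
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm = 5,
                               element_ranges = default_element_ranges(),
                               rdbe_min = 0, rdbe_max = 40,
                               nitrogen_rule = FALSE) {
  stopifnot(neutral_mass > 0, tol_ppm > 0)
  ranges <- lapply(element_ranges, function(r) {
    r <- as.integer(r)
    stopifnot(length(r) == 2L, r[1] >= 0L, r[2] >= r[1])
    r
  })
  unknown <- setdiff(names(ranges), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  n_comb <- prod(vapply(ranges, function(r) r[2] - r[1] + 1, numeric(1)))
  if (n_comb > 1e8) {
    stop("element ranges imply ~", format(n_comb, big.mark = ","),
         " combinations; refusing (limit 1e8)")
  }

  tol_da <- neutral_mass * tol_ppm * 1e-6
  has_h <- "H" %in% names(ranges)
  heavy <- setdiff(names(ranges), "H")
  # heaviest first so pruning bites early
  heavy <- heavy[order(MONOISOTOPIC_MASS[heavy], decreasing = TRUE)]

  # grid over non-H elements, grown element-by-element with pruning on the
  # accumulated mass
  grid <- matrix(0L, nrow = 1, ncol = 0)
  gmass <- 0
  for (el in heavy) {
    r <- ranges[[el]]
    cnts <- r[1]:r[2]
    n_old <- length(gmass)
    grid <- grid[rep(seq_len(n_old), times = length(cnts)), , drop = FALSE]
    newcol <- rep(cnts, each = n_old)
    gmass <- rep(gmass, times = length(cnts)) + newcol * MONOISOTOPIC_MASS[[el]]
    grid <- cbind(grid, newcol)
    colnames(grid)[ncol(grid)] <- el
    max_h_mass <- if (has_h) ranges$H[2] * MONOISOTOPIC_MASS[["H"]] else 0
    remaining_min <- neutral_mass - tol_da - gmass
    # prune combos already too heavy, and combos whose mass deficit cannot be
    # covered even by maxing out every element still to be placed (plus H)
    keep <- gmass <= neutral_mass + tol_da &
      remaining_min <= sum_remaining_max(ranges, heavy, el) + max_h_mass + 1e-9
    grid <- grid[keep, , drop = FALSE]
    gmass <- gmass[keep]
  }

  if (has_h) {
    h_mass <- MONOISOTOPIC_MASS[["H"]]
    h_lo <- pmax(ranges$H[1], ceiling((neutral_mass - tol_da - gmass) / h_mass - 1e-9))
    h_hi <- pmin(ranges$H[2], floor((neutral_mass + tol_da - gmass) / h_mass + 1e-9))
    n_h <- pmax(0L, h_hi - h_lo + 1L)
    idx <- rep(seq_along(gmass), times = n_h)
    h_cnt <- unlist(lapply(seq_along(gmass), function(i) {
      if (n_h[i] > 0) seq.int(h_lo[i], h_hi[i]) else integer(0)
    }), use.names = FALSE)
    grid <- grid[idx, , drop = FALSE]
    mass <- gmass[idx] + h_cnt * h_mass
    grid <- cbind(grid, H = as.integer(h_cnt))
  } else {
    mass <- gmass
  }

  keep <- abs(mass - neutral_mass) <= tol_da & mass > 0
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]
  if (!nrow(grid)) return(empty_candidates())

  cnt <- function(e) if (e %in% colnames(grid)) grid[, e] else 0L
  rdbe_v <- cnt("C") - cnt("H") / 2 + (cnt("N") + cnt("P")) / 2 + 1
  nrule <- abs(rdbe_v - round(rdbe_v)) < 1e-9
  keep <- rdbe_v >= rdbe_min & rdbe_v <= rdbe_max
  if (nitrogen_rule) keep <- keep & nrule
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]
  rdbe_v <- rdbe_v[keep]
  nrule <- nrule[keep]
  if (!nrow(grid)) return(empty_candidates())

  formula <- apply(grid, 1, function(row) format_formula(row))
  ppm <- 1e6 * (mass - neutral_mass) / neutral_mass
  n_atoms <- rowSums(grid)
  ord <- order(abs(ppm), n_atoms, formula)
  tibble::tibble(
    formula = formula[ord],
    mass = unname(mass[ord]),
    ppm_error = unname(ppm[ord]),
    rdbe = unname(rdbe_v[ord]),
    passes_nitrogen_rule = unname(nrule[ord]),
    rank = seq_along(ord)
  )
}

# Maximum mass still to be added by elements after `el` in the sweep order.
sum_remaining_max <- function(ranges, heavy, el) {
  pos <- match(el, heavy)
  later <- heavy[seq_along(heavy) > pos]
  if (!length(later)) return(0)
  sum(vapply(later, function(e) ranges[[e]][2] * MONOISOTOPIC_MASS[[e]],
             numeric(1)))
}

empty_candidates <- function() {
  tibble::tibble(
    formula = character(), mass = numeric(), ppm_error = numeric(),
    rdbe = numeric(), passes_nitrogen_rule = logical(), rank = integer()
  )
}
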