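# Independent oracles used by the tests. These deliberately re-derive
# results through different code paths (naive loops, closed forms) than the
# package implementation.

# IUPAC monoisotopic masses, typed independently of the package constants.
ORACLE_MASS <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, P = 30.97376151, S = 31.97207069
)

oracle_hill <- function(counts) {
  counts <- counts[counts > 0]
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

# Naive nested-loop enumeration of CHNOPS formulas matching a neutral mass,
# with plain early breaks when the partial mass overshoots. Returns the
# unordered set of Hill strings.
naive_formula_oracle <- function(mass, tol_ppm, ranges,
                                 rdbe_min = 0, rdbe_max = 40) {
  tol <- mass * tol_ppm * 1e-6
  rng <- function(e) if (e %in% names(ranges)) ranges[[e]] else c(0L, 0L)
  cr <- rng("C"); nr <- rng("N"); or <- rng("O"); pr <- rng("P")
  sr <- rng("S"); hr <- rng("H")
  out <- character(0)
  for (C in cr[1]:cr[2]) {
    mC <- C * ORACLE_MASS[["C"]]
    if (mC > mass + tol) break
    for (N in nr[1]:nr[2]) {
      mN <- mC + N * ORACLE_MASS[["N"]]
      if (mN > mass + tol) break
      for (O in or[1]:or[2]) {
        mO <- mN + O * ORACLE_MASS[["O"]]
        if (mO > mass + tol) break
        for (P in pr[1]:pr[2]) {
          mP <- mO + P * ORACLE_MASS[["P"]]
          if (mP > mass + tol) break
          for (S in sr[1]:sr[2]) {
            mS <- mP + S * ORACLE_MASS[["S"]]
            if (mS > mass + tol) break
            rem <- mass - mS
            h_lo <- max(hr[1], floor((rem - tol) / ORACLE_MASS[["H"]]))
            h_hi <- min(hr[2], ceiling((rem + tol) / ORACLE_MASS[["H"]]))
            if (h_hi < h_lo) next
            for (H in h_lo:h_hi) {
              total <- mS + H * ORACLE_MASS[["H"]]
              if (abs(total - mass) > tol || total <= 0) next
              r <- C - H / 2 + (N + P) / 2 + 1
              if (r < rdbe_min || r > rdbe_max) next
              out <- c(out, oracle_hill(c(C = C, H = H, N = N, O = O,
                                          P = P, S = S)))
            }
          }
        }
      }
    }
  }
  sort(unique(out))
}

# Minimal independent NIPALS extraction of the first PLS2 component weights
# against a centred one-hot class matrix.
nipals_first_weights <- function(x, labels) {
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, "==") * 1
  Y <- sweep(Y, 2, colMeans(Y), "-")
  X <- sweep(x, 2, colMeans(x), "-")
  u <- Y[, which.max(apply(Y, 2, var))]
  for (i in 1:500) {
    w <- drop(crossprod(X, u)); w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    q <- drop(crossprod(Y, tt)) / sum(tt^2)
    u_new <- drop(Y %*% q) / sum(q^2)
    if (sum((u_new - u)^2) < 1e-14) break
    u <- u_new
  }
  j <- which.max(abs(w))
  if (w[j] < 0) w <- -w
  w
}

# Small in-memory compound library for constructed matching cases.
toy_library <- function(names, formulas) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = names, formula = formulas), path,
                   progress = FALSE)
  read_compound_library(path)
}
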