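# Monoisotopic atomic masses (Da) of the elements handled by the formula
# machinery. Values are the most-abundant-isotope masses used throughout
# small-molecule mass spectrometry.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

# Mass of a proton (Da), electron-corrected: the shift applied when a neutral
# molecule is observed as [M+H]+ or [M-H]-.
PROTON_MASS <- 1.00728

#' Default adduct registry
#'
#' Returns the registry of ion species used to convert between measured m/z
#' and neutral monoisotopic mass. By default only the singly charged
#' protonated `[M+H]+` and deprotonated `[M-H]-` species are registered,
#' which are the dominant electrospray adducts for small natural products.
#' Additional singly or multiply charged adducts can be appended by the
#' caller.
#'
#' @return A tibble with columns `label`, `mass_shift` (Da, signed),
#'   `charge` (signed integer) and `polarity`.
#' @examples
#' default_adducts()
#' @export
default_adducts <- function() {
  tibble::tibble(
    label      = c("[M+H]+", "[M-H]-"),
    mass_shift = c(PROTON_MASS, -PROTON_MASS),
    charge     = c(1L, -1L),
    polarity   = c("positive", "negative")
  )
}

#' Look up an adduct by label or polarity
#'
#' @param x An adduct label (e.g. `"[M+H]+"`), a polarity (`"positive"` /
#'   `"negative"`), or a one-row data frame already describing an adduct.
#' @param registry Adduct registry, see [default_adducts()].
#' @return A one-row tibble describing the adduct.
#' @export
resolve_adduct <- function(x, registry = default_adducts()) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("mass_shift", "charge") %in% names(x)))
    if (x$charge == 0) stop("adduct charge must be non-zero")
    return(tibble::as_tibble(x))
  }
  hit <- registry[registry$label == x | registry$polarity == x, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("unknown adduct: ", x)
  }
  hit[1L, ]
}
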