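# Monoisotopic atomic masses (CODATA/AME2020). Deltas are recomputed from these
# at full precision; the 4-decimal values usually quoted in methods sections are
# display roundings and are too coarse for sub-ppm matching at low m/z.
.atomic_mass <- c(
  H    = 1.00782503207,
  C    = 12.0,
  C13  = 13.00335483507,
  N    = 14.0030740052,
  O    = 15.9949146221,
  Na   = 22.9897692820,
  K    = 38.9637064864,
  Cl35 = 34.9688526820,
  Cl37 = 36.9659026020,
  S32  = 31.9720711744,
  S34  = 33.9678670040
)

#' Mass of a proton in Da
#'
#' Constant used to convert between anchor ion m/z and neutral mass for singly
#' charged ions.
#' @export
PROTON_MASS <- 1.00727646688

#' m/z difference of one 13C substitution
#' @export
C13_DELTA <- .atomic_mass[["C13"]] - .atomic_mass[["C"]]

#' Mass tolerance for delta matching
#'
#' The matching tolerance is the minimum of a relative (ppm) tolerance and an
#' absolute cap: `min(ppm * mz, abs_cap)`. With the defaults this gives 5 ppm
#' below m/z 100 and a flat 0.0005 Da above.
#'
#' @param mz m/z value(s), Da. Must be positive.
#' @param ppm relative tolerance as a ratio (default `5e-6`, i.e. 5 ppm).
#' @param abs_cap absolute cap in Da (default 0.0005).
#' @return tolerance in Da, vectorized over `mz`.
#' @export
#' @examples
#' mass_tolerance(c(50, 100, 500))
mass_tolerance <- function(mz, ppm = 5e-6, abs_cap = 5e-4) {
  stopifnot(is.numeric(mz), all(mz > 0))
  pmin(ppm * mz, abs_cap)
}

#' Conservative isotope and adduct patterns per ionization mode
#'
#' Returns the conservative list of mass-difference patterns used to relate
#' coeluting ions of one compound: natural-abundance isotope substitutions and
#' a small set of common ESI adducts. Deltas are computed from atomic masses at
#' full precision.
#'
#' @param mode ionization polarity, `"positive"` or `"negative"`.
#' @return A tibble with columns `label`, `delta` (Da), `kind`
#'   (`"isotope"` or `"adduct"`), and `isotope_step` (0 for adducts).
#' @export
#' @examples
#' default_patterns("positive")
default_patterns <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  am <- .atomic_mass
  iso <- tibble::tibble(
    label = c("13C/12C", "13C/12C*2", "37Cl/35Cl"),
    delta = c(C13_DELTA, 2 * C13_DELTA, am[["Cl37"]] - am[["Cl35"]]),
    kind = "isotope",
    isotope_step = c(1L, 2L, 2L)
  )
  if (mode == "negative") {
    iso <- dplyr::bind_rows(iso, tibble::tibble(
      label = "34S/32S", delta = am[["S34"]] - am[["S32"]],
      kind = "isotope", isotope_step = 2L
    ))
  }
  add_pos <- tibble::tibble(
    label = c("Na/H", "ACN", "NaCOOH", "K/H", "CH3OH"),
    delta = c(
      am[["Na"]] - am[["H"]],
      2 * am[["C"]] + 3 * am[["H"]] + am[["N"]],
      am[["C"]] + am[["H"]] + am[["Na"]] + 2 * am[["O"]],
      am[["K"]] - am[["H"]],
      am[["C"]] + 4 * am[["H"]] + am[["O"]]
    ),
    kind = "adduct", isotope_step = 0L
  )
  add_neg <- tibble::tibble(
    label = c("Na/H", "NaCOOH", "NaCH2COOH"),
    delta = c(
      am[["Na"]] - am[["H"]],
      am[["C"]] + am[["H"]] + am[["Na"]] + 2 * am[["O"]],
      2 * am[["C"]] + 3 * am[["H"]] + am[["Na"]] + 2 * am[["O"]]
    ),
    kind = "adduct", isotope_step = 0L
  )
  out <- dplyr::bind_rows(iso, if (mode == "positive") add_pos else add_neg)
  out$mode <- mode
  out
}

#' Curated list of common ESI neutral losses
#'
#' Small in-source neutral losses seen across LC-MS platforms (water, ammonia,
#' CO, CO2, formic acid). Used to seed in-source-fragment searching when the
#' data-driven mass-difference histogram is too sparse to nominate candidates
#' on its own.
#'
#' @return A tibble with columns `label` and `delta` (Da).
#' @export
curated_neutral_losses <- function() {
  am <- .atomic_mass
  h2o <- 2 * am[["H"]] + am[["O"]]
  tibble::tibble(
    label = c("H2O", "2xH2O", "NH3", "CO", "CO2", "HCOOH"),
    delta = c(
      h2o, 2 * h2o,
      am[["N"]] + 3 * am[["H"]],
      am[["C"]] + am[["O"]],
      am[["C"]] + 2 * am[["O"]],
      am[["C"]] + 2 * am[["H"]] + 2 * am[["O"]]
    )
  )
}

#' Neutral mass from the anchor ion m/z
#'
#' Assumes a singly charged protonated (positive) or deprotonated (negative)
#' molecular ion.
#'
#' @param mz anchor ion m/z, Da.
#' @param mode ionization polarity.
#' @return neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_anchor <- function(mz, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  if (mode == "positive") mz - PROTON_MASS else mz + PROTON_MASS
}
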