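# Regional intestinal absorption: Caco-2 permeability -> effective
# permeability -> first-order absorption rate constants, plus the
# gut-lumen transit derivatives.

#' Effective intestinal permeability from Caco-2 apparent permeability
#'
#' Log-linear correlation `logPeff = 0.4926 * logPapp - 0.1454` with the
#' unit convention Papp in 1e-6 cm/s in, Peff in 1e-4 cm/s out.  This is
#' the only unit pairing under which `2 * Peff / r` reproduces the
#' reference regional absorption rate constants (0.21, 0.26, 0.29 per
#' hour) from Papp = 0.675e-6 cm/s.
#'
#' @param papp apparent permeability in units of 1e-6 cm/s.
#' @return effective permeability in units of 1e-4 cm/s.
#' @export
#' @examples
#' papp_to_peff(0.675)    # 0.5893
papp_to_peff <- function(papp) {
  if (any(papp <= 0)) stop("permeability must be positive")
  10^(0.4926 * log10(papp) - 0.1454)
}

#' Absorption rate constant from effective permeability and gut radius
#'
#' `Ka = 2 * Peff / r`, converted from per-second (Peff at the 1e-4 cm/s
#' scale) to per-hour.
#'
#' @param peff effective permeability, 1e-4 cm/s.
#' @param radius_cm radius of the intestinal segment, cm.
#' @return absorption rate constant, 1/h.
#' @export
#' @examples
#' ka_from_peff(papp_to_peff(0.675), 1.63)   # 0.26 /h (jejunum)
ka_from_peff <- function(peff, radius_cm) {
  if (any(radius_cm <= 0)) stop("radius must be positive")
  2 * peff * 1e-4 / radius_cm * 3600
}

#' Regional P-gp efflux rate constants
#'
#' The efflux constants for the absorptive segments are fixed reference
#' values (0.07, 0.12, 0.16 per hour in duodenum, jejunum, ileum); the
#' non-absorptive caecum and colon have zero efflux.  They are stored
#' constants rather than recomputed, because the printed directional
#' permeability identities cannot be reconciled algebraically with both
#' reported Papp values and this list (see the methods vignette).
#'
#' @return named numeric vector over the five gut regions, 1/h.
#' @export
kb_values <- function() {
  c(duodenum = 0.07, jejunum = 0.12, ileum = 0.16, caecum = 0, colon = 0)
}

#' Regional absorption table for the gut chain
#'
#' Builds the per-region absorption data frame used inside the model
#' parameter state: transit rates, radii and P-gp scaling factors for
#' the absorptive segments, absorption constants derived from the
#' Caco-2 permeability of the parent drug measured under P-gp
#' inhibition (0.675e-6 cm/s), and the packaged efflux constants.
#'
#' @param papp Caco-2 apparent permeability used for Ka, 1e-6 cm/s.
#' @return data frame with one row per region (duodenum, jejunum,
#'   ileum, caecum, colon): `radius` (cm, NA for non-absorptive
#'   segments), `tsf`, `kt`, `ka`, `kb` (1/h).
#' @export
derive_absorption_rates <- function(papp = 0.675) {
  radius <- c(2.0, 1.63, 1.45, NA, NA)
  ka <- c(ka_from_peff(papp_to_peff(papp), radius[1:3]), 0, 0)
  data.frame(
    region = .gut_regions,
    radius = radius,
    tsf = c(0.64, 0.84, 1, NA, NA),
    kt = c(4.2, 1.8, 2.4, 0.18, 0.06),
    ka = ka,
    kb = unname(kb_values()),
    row.names = .gut_regions, stringsAsFactors = FALSE)
}

#' Gut-lumen derivatives: gastric emptying, transit, absorption, efflux
#'
#' Time derivatives of the drug amounts in the stomach lumen and the
#' five sequential gut-lumen segments.  The stomach empties into the
#' duodenum; each segment passes drug downstream at its transit rate,
#' loses drug to its gut-wall compartment at the absorption rate and
#' regains drug from the wall at the efflux rate (scaled by the
#' gut-wall free fraction); colonic transit is irreversible faecal
#' loss, returned as the last element.
#'
#' @param a0 amount in the stomach lumen, nmol.
#' @param a amounts in the five gut-lumen segments (duodenum..colon),
#'   nmol.
#' @param gut gut table as in [derive_absorption_rates()].
#' @param kt0 gastric emptying rate constant, 1/h.
#' @param gw_conc gut-wall concentrations per region, nmol/L.
#' @param gw_volume gut-wall volumes per region, L.
#' @param fugut free fraction in the gut wall.
#' @return list with `da0`, `da` (nmol/h) and `colon_outflow` (nmol/h,
#'   rate of faecal loss).
#' @export
lumen_derivatives <- function(a0, a, gut, kt0, gw_conc, gw_volume, fugut) {
  if (a0 < 0 || any(a < 0)) stop("lumen amounts must be non-negative")
  stopifnot(length(a) == 5, length(gw_conc) == 5, length(gw_volume) == 5)
  absorbed <- gut$ka * a
  efflux <- gut$kb * gw_conc * gw_volume * fugut
  trans_in <- c(kt0 * a0, gut$kt[1:4] * a[1:4])
  list(da0 = -kt0 * a0,
       da = trans_in - gut$kt * a - absorbed + efflux,
       colon_outflow = gut$kt[5] * a[5])
}
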