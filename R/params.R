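#' Published kinetic and thermodynamic parameters for the Ru-MtrC proteins
#'
#' Returns the experimentally determined parameter set for the two
#' photosensitized decaheme cytochrome variants studied in this package's
#' reference system: Ru-MtrC Met8 (His/Met-ligated Heme 8) and Ru-MtrC His8
#' (all-His/His). These numbers are the published measurement results and are
#' used as generating truth for synthetic experiments and as inputs to the
#' ET-theory post-analysis.
#'
#' @details
#' The list contains:
#' \describe{
#'   \item{pl_conformers}{Biexponential photoluminescence decay parameters per
#'     protein: conformer contributions (fractions) and charge-separation rate
#'     constants (s^-1).}
#'   \item{ta_conformers}{Three-conformer parameters from transient absorbance:
#'     shared contributions and charge-separation rates, and per-protein
#'     charge-recombination rates (s^-1).}
#'   \item{chain}{Per-protein heme-chain ET rate constants (s^-1), see
#'     [chain_rates()] for the naming convention.}
#'   \item{lambda_eV}{Reorganization energies used for the free-energy
#'     optimized rates: 0.70 eV for the Heme 10 <-> 9 pair and 0.73 eV for the
#'     Heme 9 <-> 8 pair.}
#'   \item{injection}{Dye-to-heme edge distances (Angstrom) for Hemes 10, 9, 8
#'     and the exponential distance-decay constant beta = 1.39 per Angstrom.}
#'   \item{edge_distances_A}{Closest macrocycle edge-to-edge distances of the
#'     Heme 10 <-> 9 and 9 <-> 8 pairs (3.7 and 4.3 Angstrom).}
#'   \item{em_heme8_met_mV}{Midpoint potential of the His/Met Heme 8
#'     (+199 mV vs SHE).}
#'   \item{k_ru_free}{Intrinsic triplet decay rate of the free Ru dye
#'     (2e6 s^-1).}
#' }
#' @return A nested list, see Details.
#' @export
ru_mtrc_params <- function() {
  list(
    pl_conformers = list(
      met8 = list(weights = c(a = 0.09, b = 0.91),
                  k_cs = c(a = 5e6, b = 55e6)),
      his8 = list(weights = c(a = 0.11, b = 0.89),
                  k_cs = c(a = 8e6, b = 56e6))
    ),
    ta_conformers = list(
      weights = c(a = 0.14, b = 0.66, c = 0.20),
      k_cs = c(a = 5.2e6, b = 112e6, c = 3840e6),
      k_cr = list(
        his8 = c(a = 71e6, b = 301e6, c = 11100e6),
        met8 = c(a = 333e6, b = 63e6, c = 108000e6)
      )
    ),
    chain = list(
      met8 = chain_rates(k_10to9 = 76e6, k_9to10 = 66e6,
                         k_9to8 = 11100e6, k_8to9 = 3.3e6),
      his8 = chain_rates(k_10to9 = 219e6, k_9to10 = 14e6,
                         k_9to8 = 105e6, k_8to9 = 1560e6)
    ),
    lambda_eV = c(pair_10_9 = 0.70, pair_9_8 = 0.73),
    injection = list(d_edge_A = c(heme10 = 5, heme9 = 14, heme8 = 18),
                     beta_per_A = 1.39),
    edge_distances_A = c(pair_10_9 = 3.7, pair_9_8 = 4.3),
    em_heme8_met_mV = 199,
    k_ru_free = 2e6
  )
}

#' Reference photocycle models for the two Ru-MtrC proteins
#'
#' Convenience constructors assembling [photocycle_model()] objects from the
#' published transient-absorbance parameter set of [ru_mtrc_params()].
#'
#' @param protein `"met8"` or `"his8"`.
#' @param k_intrinsic Intrinsic triplet decay rate (s^-1); 0 by default as in
#'   the published fits.
#' @return A `photocycle_model` object.
#' @export
ru_mtrc_model <- function(protein = c("met8", "his8"), k_intrinsic = 0) {
  protein <- match.arg(protein)
  p <- ru_mtrc_params()
  w <- p$ta_conformers$weights
  kcs <- p$ta_conformers$k_cs
  kcr <- p$ta_conformers$k_cr[[protein]]
  conf <- lapply(names(w), function(x)
    conformer_params(label = x, weight = w[[x]], k_cs = kcs[[x]],
                     k_cr = kcr[[x]]))
  photocycle_model(
    conformers = conf,
    chain = p$chain[[protein]],
    k_intrinsic = k_intrinsic,
    heme8_ligation = if (protein == "met8") "His/Met" else "His/His"
  )
}
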