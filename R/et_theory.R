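#' @title Marcus / Hopfield ET theory and distance rulers
#'
#' @description
#' Post-analysis of measured heme-to-heme ET rate constants: driving forces
#' from detailed balance, conversion of measured rates to free-energy
#' optimized ("activationless") rates via the Hopfield one-mode term
#' `10^(3.1 (dG + lambda)^2 / lambda)`, the nonadiabatic Marcus rate
#' expression, exponential distance scaling of injection rates, and the
#' empirical Moser-Dutton (edge-to-edge) and Winkler-Gray (metal-to-metal)
#' log-linear distance rulers.
#'
#' @name et_theory
NULL

#' Parameters describing one donor/acceptor heme pair
#'
#' @param delta_g Driving force (eV, negative = exergonic).
#' @param lambda Reorganization energy (eV), > 0.
#' @param h_ab Electronic coupling (eV), optional.
#' @param temperature Temperature (K), default 298.15.
#' @param d_edge Closest macrocycle edge-to-edge distance (Angstrom).
#' @param d_metal Fe-Fe distance (Angstrom).
#' @param motif Packing motif: `"stacked"`, `"T-shaped"` or `"other"`.
#' @return An `et_pair_params` object.
#' @export
et_pair_params <- function(delta_g, lambda, h_ab = NA_real_,
                           temperature = 298.15, d_edge = NA_real_,
                           d_metal = NA_real_,
                           motif = c("stacked", "T-shaped", "other")) {
  motif <- match.arg(motif)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (!is.na(d_edge) && d_edge < 0) stop("distances must be >= 0")
  structure(list(delta_g = delta_g, lambda = lambda, h_ab = h_ab,
                 temperature = temperature, d_edge = d_edge,
                 d_metal = d_metal, motif = motif),
            class = "et_pair_params")
}

#' Driving force from forward/backward rate constants (detailed balance)
#'
#' `dG = -kB T ln(k_forward / k_backward)`; negative when the forward
#' direction is the faster (exergonic) one.
#'
#' @param k_forward,k_backward Rate constants (s^-1), > 0.
#' @param temperature Temperature (K).
#' @return Driving force in eV.
#' @export
delta_g_from_rates <- function(k_forward, k_backward, temperature = 298.15) {
  if (any(!is.finite(c(k_forward, k_backward))) ||
      any(c(k_forward, k_backward) <= 0))
    stop("rate constants must be positive and finite")
  -et_constants(temperature)$kBT * log(k_forward / k_backward)
}

#' Hopfield free-energy optimization factor
#'
#' The multiplier `10^(3.1 (dG + lambda)^2 / lambda)` (energies in eV) that
#' converts a measured ET rate to its activationless (dG = -lambda) value.
#' Equals 1 exactly at dG = -lambda and is >= 1 for `dG` in `[-2 lambda, 0]`.
#'
#' @param delta_g Driving force (eV).
#' @param lambda Reorganization energy (eV), > 0.
#' @return Dimensionless factor.
#' @export
optimization_factor <- function(delta_g, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  10^(3.1 * (delta_g + lambda)^2 / lambda)
}

#' Free-energy optimized ET rate
#'
#' `k_max = k_obs * optimization_factor(delta_g, lambda)`. The measured rate
#' must be supplied in the exergonic direction (`delta_g <= 0`).
#'
#' @param k_obs Measured rate constant (s^-1) in the exergonic direction.
#' @param delta_g Driving force (eV), <= 0.
#' @param lambda Reorganization energy (eV).
#' @return Optimized rate (s^-1).
#' @export
free_energy_optimized_rate <- function(k_obs, delta_g, lambda) {
  if (any(k_obs <= 0)) stop("k_obs must be > 0")
  if (any(delta_g > 0))
    stop("delta_g > 0: supply the exergonic direction (swap forward/backward)")
  k_obs * optimization_factor(delta_g, lambda)
}

#' Free-energy optimized rates for a table of reversible pairs
#'
#' For each pair the exergonic direction is selected automatically, the
#' driving force is computed from the rate ratio by detailed balance and
#' rounded to `round_dg` eV (0.01 by default, matching how the published
#' endpoints were obtained), and the exergonic rate is multiplied by the
#' Hopfield optimization factor.
#'
#' @param pairs Data frame with columns `k_f`, `k_b` (s^-1) and `lambda`
#'   (eV); optional `pair` labels and `d_edge`, `d_metal`, `motif` columns
#'   are carried through.
#' @param temperature Temperature (K).
#' @param round_dg Rounding quantum for the driving force (eV); `NA` to
#'   disable rounding.
#' @return The input data frame with added columns `delta_g_eV` (rounded),
#'   `k_exergonic`, `opt_factor` and `k_max`.
#' @export
kmax_table <- function(pairs, temperature = 298.15, round_dg = 0.01) {
  stopifnot(all(c("k_f", "k_b", "lambda") %in% names(pairs)))
  kf <- pmax(pairs$k_f, pairs$k_b)
  kb <- pmin(pairs$k_f, pairs$k_b)
  dg <- delta_g_from_rates(kf, kb, temperature)
  if (!is.na(round_dg)) dg <- round(dg / round_dg) * round_dg
  pairs$delta_g_eV <- dg
  pairs$k_exergonic <- kf
  pairs$opt_factor <- optimization_factor(dg, pairs$lambda)
  pairs$k_max <- kf * pairs$opt_factor
  pairs
}

#' Nonadiabatic (Marcus) ET rate
#'
#' `k = (2 pi / hbar) H_ab^2 (4 pi lambda kB T)^(-1/2)
#'      exp(-(dG + lambda)^2 / (4 lambda kB T))`
#' with energies in eV; satisfies detailed balance
#' `k(dG) / k(-dG) = exp(-dG / kB T)` exactly.
#'
#' @param h_ab Electronic coupling (eV), > 0.
#' @param delta_g Driving force (eV).
#' @param lambda Reorganization energy (eV), > 0.
#' @param temperature Temperature (K).
#' @return Rate constant (s^-1).
#' @export
marcus_rate <- function(h_ab, delta_g, lambda, temperature = 298.15) {
  if (any(h_ab <= 0) || any(lambda <= 0))
    stop("h_ab and lambda must be > 0")
  cst <- et_constants(temperature)
  (2 * pi / cst$hbar) * h_ab^2 / sqrt(4 * pi * lambda * cst$kBT) *
    exp(-(delta_g + lambda)^2 / (4 * lambda * cst$kBT))
}

#' Exponential distance scaling of ET rates
#'
#' `k = k_ref exp(-beta (d - d_ref))`: the standard square-barrier tunneling
#' attenuation used to compare electron-injection distances.
#'
#' @param k_ref Reference rate (s^-1) at distance `d_ref`.
#' @param d_ref,d Distances (Angstrom).
#' @param beta Decay constant (1/Angstrom), > 0 (default 1.39).
#' @return Scaled rate (s^-1).
#' @export
distance_scaled_rate <- function(k_ref, d_ref, d, beta = 1.39) {
  if (any(beta <= 0)) stop("beta must be > 0")
  k_ref * exp(-beta * (d - d_ref))
}

#' Injection attenuation factor between two distances
#'
#' `factor = exp(beta (d - d_ref))`: how many times slower injection is at
#' distance `d` than at `d_ref`. Also reports the order of magnitude
#' `floor(log10(factor))`.
#'
#' @param d,d_ref Distances (Angstrom).
#' @param beta Decay constant (1/Angstrom), default 1.39.
#' @return List with `factor` and `order_of_magnitude`.
#' @export
injection_ratio <- function(d, d_ref, beta = 1.39) {
  if (any(beta <= 0)) stop("beta must be > 0")
  f <- exp(beta * (d - d_ref))
  list(factor = f, order_of_magnitude = floor(log10(f)))
}

#' Empirical distance-ruler prediction of the optimized ET rate
#'
#' Log-linear rulers `log10 k_max = A - B (d - d0)`:
#' \describe{
#'   \item{moser_dutton}{versus closest edge-to-edge distance; defaults
#'     `A = 15`, `B = 0.6` per Angstrom, `d0 = 0`, i.e. the canonical
#'     log10 k = 15 - 0.6 d with about 10 decades of rate per 1.7 nm.}
#'   \item{winkler_gray}{versus metal-to-metal distance; defaults `A = 13`,
#'     `B = 0.72`, `d0 = 3`.}
#' }
#' All constants are configuration, not hard-coded science; override them to
#' reproduce a specific published ruler.
#'
#' @param distance Distance (Angstrom): edge-to-edge for `moser_dutton`,
#'   metal-to-metal for `winkler_gray`.
#' @param ruler `"moser_dutton"` or `"winkler_gray"`.
#' @param k_max Optional measured optimized rate(s) (s^-1); if supplied, the
#'   deviation from the ruler in orders of magnitude is returned too.
#' @param A,B,d0 Ruler constants (override the per-ruler defaults).
#' @return List with `log10_k` (predicted) and, when `k_max` is given,
#'   `deviation_orders` (`log10 k_max - log10_k`; negative = below the
#'   ruler).
#' @export
ruler_log_rate <- function(distance, ruler = c("moser_dutton", "winkler_gray"),
                           k_max = NULL, A = NULL, B = NULL, d0 = NULL) {
  ruler <- match.arg(ruler)
  def <- switch(ruler,
                moser_dutton = c(A = 15, B = 0.6, d0 = 0),
                winkler_gray = c(A = 13, B = 0.72, d0 = 3))
  if (is.null(A)) A <- def[["A"]]
  if (is.null(B)) B <- def[["B"]]
  if (is.null(d0)) d0 <- def[["d0"]]
  log10_k <- A - B * (distance - d0)
  out <- list(log10_k = log10_k)
  if (!is.null(k_max)) out$deviation_orders <- log10(k_max) - log10_k
  out
}

#' Free-energy-optimized rates for the four stacked MtrC heme pairs
#'
#' Applies [kmax_table()] to the published experimental chain rates of the
#' two Ru-MtrC proteins (Heme 10 <-> 9 and 9 <-> 8 pairs, both stacked), with
#' the reorganization energies and edge-to-edge distances of
#' [ru_mtrc_params()].
#'
#' @param temperature Temperature (K).
#' @param round_dg Driving-force rounding (eV), see [kmax_table()].
#' @return Data frame, one row per (protein, pair), with `k_max` in s^-1.
#' @export
mtrc_stacked_kmax <- function(temperature = 298.15, round_dg = 0.01) {
  p <- ru_mtrc_params()
  rows <- list()
  for (prot in c("met8", "his8")) {
    ch <- p$chain[[prot]]
    rows[[length(rows) + 1]] <- data.frame(
      protein = prot, pair = "10<->9",
      k_f = ch$k_10to9, k_b = ch$k_9to10,
      lambda = p$lambda_eV[["pair_10_9"]],
      d_edge = p$edge_distances_A[["pair_10_9"]], motif = "stacked")
    rows[[length(rows) + 1]] <- data.frame(
      protein = prot, pair = "9<->8",
      k_f = ch$k_9to8, k_b = ch$k_8to9,
      lambda = p$lambda_eV[["pair_9_8"]],
      d_edge = p$edge_distances_A[["pair_9_8"]], motif = "stacked")
  }
  kmax_table(do.call(rbind, rows), temperature = temperature,
             round_dg = round_dg)
}
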