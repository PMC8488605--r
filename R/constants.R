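#' Physical constants used by the ET-theory calculations
#'
#' All energies are in electron volts. The thermal energy defaults to
#' `0.025693` eV, i.e. kB * 298.15 K, which also fixes the Nernst slope at
#' `59.16` mV per decade for an n = 1 couple.
#'
#' @param temperature Temperature in kelvin.
#' @return A list with elements `kB` (eV/K), `kBT` (eV), `hbar` (eV s),
#'   `temperature` (K) and `nernst_slope_mV` (mV/decade for n = 1).
#' @export
et_constants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB <- 8.617333262e-5            # eV / K
  kBT <- kB * temperature
  list(
    kB = kB,
    kBT = kBT,
    hbar = 6.582119569e-16,       # eV s
    temperature = temperature,
    nernst_slope_mV = 1000 * kBT * log(10)
  )
}
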