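#' @title Synthetic pump-probe, photoluminescence and titration data
#'
#' @description
#' Seeded generators producing data with the statistical structure the
#' analysis assumes: transient difference-absorbance cubes rendered from a
#' photocycle model and per-species Gaussian band spectra, multi-exponential
#' photoluminescence decays, and multi-center Nernstian titration curves.
#' Band-shape defaults are free, configurable constants chosen to satisfy the
#' qualitative spectroscopy of the system (His/Met ferroheme Soret lobe
#' broader and red-shifted relative to His/His; Q-bands at 552/522 nm); they
#' do not claim quantitative fidelity to any instrument.
#'
#' @name synthetic_data
NULL

#' Gaussian spectral band
#'
#' @param center Band center (nm).
#' @param fwhm Full width at half maximum (nm), > 0.
#' @param amplitude Amplitude at the center in mOD per unit population
#'   (signed; negative for bleaches).
#' @return A `gaussian_band` object.
#' @export
gaussian_band <- function(center, fwhm, amplitude) {
  stopifnot(is.finite(center), is.finite(fwhm), is.finite(amplitude))
  if (fwhm <= 0) stop("fwhm must be > 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "gaussian_band")
}

.eval_band <- function(band, wavelengths) {
  band$amplitude * exp(-4 * log(2) * ((wavelengths - band$center) / band$fwhm)^2)
}

#' Additive Gaussian noise model
#'
#' @param sd Standard deviation of the i.i.d. additive noise (same units as
#'   the signal it is added to); `sd >= 0`.
#' @param seed Optional integer seed making the realization reproducible.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sd = 0, seed = NULL) {
  if (!is.finite(sd) || sd < 0) stop("noise sd must be >= 0")
  structure(list(sd = sd, seed = seed), class = "noise_model")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.add_noise <- function(x, noise) {
  if (is.null(noise)) return(x)
  stopifnot(inherits(noise, "noise_model"))
  if (noise$sd == 0) return(x)
  x + .with_seed(noise$seed, stats::rnorm(length(x), sd = noise$sd))
}

#' Default species difference-spectrum basis
#'
#' Returns the per-species Gaussian band lists used to render synthetic
#' difference-absorbance cubes:
#' \describe{
#'   \item{ru3}{Positive pi->pi* band of the excited triplet dye at 370 nm.}
#'   \item{ru_bleach}{Negative ground-state dye bleach spanning the broad
#'     400-500 nm trough (centered 450 nm).}
#'   \item{fe2_hishis}{His/His Fe(II)-minus-Fe(III) difference: bisignate
#'     Soret (negative ~408 nm, positive ~421 nm) plus alpha/beta Q-bands at
#'     552 and 522 nm.}
#'   \item{fe2_hismet}{His/Met Fe(II) difference: positive Soret lobe broader
#'     and red-shifted relative to His/His, same Q-bands.}
#'   \item{ru3_ox}{Small positive absorbance of the oxidized Ru(III) dye near
#'     475 nm; disabled unless `include_ru3_ox = TRUE` (it reproduces the
#'     known artifact where the extracted population sum slightly exceeds 1
#'     while the charge-separated state is maximal).}
#' }
#'
#' @param include_ru3_ox Include the Ru(III) absorbance band (default FALSE).
#' @return A `spectral_basis`: named list of lists of [gaussian_band()]s.
#' @export
default_basis <- function(include_ru3_ox = FALSE) {
  b <- list(
    ru3 = list(gaussian_band(370, 40, 8)),
    ru_bleach = list(gaussian_band(450, 45, -10)),
    fe2_hishis = list(
      gaussian_band(408, 12, -6),
      gaussian_band(421, 12, 10),
      gaussian_band(522, 12, 1.5),
      gaussian_band(552, 10, 3)
    ),
    fe2_hismet = list(
      gaussian_band(409, 14, -5),
      gaussian_band(426, 22, 8),
      gaussian_band(522, 12, 1.5),
      gaussian_band(552, 10, 3)
    )
  )
  if (include_ru3_ox) b$ru3_ox <- list(gaussian_band(475, 40, 1))
  structure(b, class = "spectral_basis")
}

#' Render a species difference spectrum from a basis
#'
#' @param basis A `spectral_basis`.
#' @param species Species name present in `basis`.
#' @param wavelengths Wavelength grid (nm).
#' @return Numeric vector of mOD per unit population.
#' @export
render_species_spectrum <- function(basis, species, wavelengths) {
  stopifnot(inherits(basis, "spectral_basis"))
  bands <- basis[[species]]
  if (is.null(bands)) stop("unknown species: ", species)
  Reduce(`+`, lapply(bands, .eval_band, wavelengths = wavelengths))
}

#' Simulate a transient difference-absorbance cube
#'
#' Forward model of the corrected pump-probe data: species populations from
#' [simulate_populations()] are multiplied by their basis difference spectra
#' and summed,
#' `dA(lambda, t) = ru3(t) (S_ru3 + S_bleach) + cs_total(t) S_bleach +
#'  fe2_hishis(t) S_hishis + fe2_hismet(t) S_hismet [+ cs_total(t) S_ru3ox]`,
#' i.e. the dye ground state stays bleached while charge-separated, and each
#' reduced heme contributes the difference spectrum of its ligation type.
#' Additive i.i.d. Gaussian noise is applied last.
#'
#' @param model A [photocycle_model()].
#' @param basis A `spectral_basis` (default [default_basis()]).
#' @param wavelengths Increasing wavelength grid (nm).
#' @param times Increasing time grid (s); default log-spaced 5 ps - 1 ms.
#' @param noise A [noise_model()] (sd in mOD).
#' @return A `spectral_cube`: list with `wavelengths`, `times` and `dA`
#'   (matrix, wavelengths x times, mOD).
#' @export
simulate_transient_cube <- function(model, basis = default_basis(),
                                    wavelengths = seq(350, 600, by = 1),
                                    times = default_time_grid(),
                                    noise = noise_model(0)) {
  stopifnot(inherits(model, "photocycle_model"))
  rng <- range(unlist(lapply(basis, function(bl)
    vapply(bl, `[[`, 0, "center"))))
  if (rng[1] < min(wavelengths) || rng[2] > max(wavelengths))
    warning("wavelength grid does not cover all basis band centers")
  trace <- simulate_populations(model, times)
  obs <- project_observables(trace, normalize = FALSE)
  S <- list(
    ru3 = render_species_spectrum(basis, "ru3", wavelengths),
    bleach = render_species_spectrum(basis, "ru_bleach", wavelengths),
    hh = render_species_spectrum(basis, "fe2_hishis", wavelengths),
    hm = render_species_spectrum(basis, "fe2_hismet", wavelengths)
  )
  dA <- outer(S$ru3, obs$ru3) +
    outer(S$bleach, obs$ru3 + obs$cs_total) +
    outer(S$hh, obs$fe2_hishis) +
    outer(S$hm, obs$fe2_hismet)
  if (!is.null(basis$ru3_ox))
    dA <- dA + outer(render_species_spectrum(basis, "ru3_ox", wavelengths),
                     obs$cs_total)
  dA <- matrix(.add_noise(dA, noise), nrow = length(wavelengths))
  structure(list(wavelengths = wavelengths, times = times, dA = dA),
            class = "spectral_cube")
}

#' Default log-spaced pump-probe time grid (5 ps to 1 ms)
#'
#' @param n Number of points.
#' @param from,to Range in seconds.
#' @return Numeric vector of times (s).
#' @export
default_time_grid <- function(n = 120, from = 5e-12, to = 1e-3) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate a photoluminescence decay
#'
#' `I(t) = sum_x w_x exp(-(k_cs,x + k_intrinsic) t)`, normalized to
#' `I(0) = 1`, plus additive Gaussian noise.
#'
#' @param conformers List of [conformer_params()] (or a list with `weights`
#'   and `k_cs` vectors); weights must sum to 1.
#' @param k_intrinsic Intrinsic triplet decay rate (s^-1).
#' @param times Time grid (s).
#' @param noise A [noise_model()] (sd in fractional intensity units).
#' @return Data frame with columns `time_s` and `intensity`.
#' @export
simulate_pl_decay <- function(conformers, k_intrinsic = 0, times,
                              noise = noise_model(0)) {
  if (length(conformers) == 0) stop("empty conformer list")
  if (all(vapply(conformers, inherits, TRUE, "conformer_params"))) {
    w <- vapply(conformers, `[[`, 0, "weight")
    k <- vapply(conformers, `[[`, 0, "k_cs")
  } else {
    w <- conformers$weights; k <- conformers$k_cs
  }
  if (abs(sum(w) - 1) > 1e-9) stop("conformer weights must sum to 1")
  I <- as.vector(exp(-outer(times, k + k_intrinsic)) %*% w)
  data.frame(time_s = times, intensity = .add_noise(I, noise))
}

#' Simulate an optically monitored potentiometric titration
#'
#' Equal-weight multi-center Nernstian model: the fraction reduced at applied
#' potential E is the mean over centers of
#' `1 / (1 + 10^((E - E_m,i) n_i / 59.16))` (E in mV vs SHE), plus noise;
#' values are clipped to `[0, 1]` only on output.
#'
#' @param centers Data frame with columns `E_m` (mV vs SHE) and `n`
#'   (electrons, >= 1), one row per redox center.
#' @param potentials Applied potentials (mV vs SHE).
#' @param noise A [noise_model()].
#' @return Data frame with columns `potential_mV_SHE`, `fraction_reduced`.
#' @export
simulate_titration <- function(centers, potentials, noise = noise_model(0)) {
  if (NROW(centers) == 0) stop("empty center list")
  stopifnot(all(c("E_m", "n") %in% names(centers)), all(centers$n >= 1))
  f <- rowMeans(matrix(vapply(seq_len(nrow(centers)), function(i)
    nernst_fraction(potentials, centers$E_m[i], centers$n[i]),
    numeric(length(potentials))), nrow = length(potentials)))
  f <- pmin(1, pmax(0, .add_noise(f, noise)))
  data.frame(potential_mV_SHE = potentials, fraction_reduced = f)
}

#' Write / read a spectral cube as long-format CSV
#'
#' Columns: `wavelength_nm`, `time_s`, `dA_mOD`.
#'
#' @param cube A `spectral_cube`.
#' @param path File path.
#' @return `write_cube_csv()` returns `path` invisibly; `read_cube_csv()`
#'   returns a `spectral_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- data.frame(
    wavelength_nm = rep(cube$wavelengths, times = length(cube$times)),
    time_s = rep(cube$times, each = length(cube$wavelengths)),
    dA_mOD = as.vector(cube$dA)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "time_s", "dA_mOD") %in% names(d)))
  wl <- sort(unique(d$wavelength_nm))
  tt <- sort(unique(d$time_s))
  dA <- matrix(NA_real_, length(wl), length(tt))
  dA[cbind(match(d$wavelength_nm, wl), match(d$time_s, tt))] <- d$dA_mOD
  if (anyNA(dA)) stop("cube CSV does not define a complete wavelength x time grid")
  structure(list(wavelengths = wl, times = tt, dA = dA),
            class = "spectral_cube")
}
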