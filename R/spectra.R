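#' @title Population extraction from difference-absorbance cubes
#'
#' @description
#' Quantifies species populations the way the pump-probe analysis does:
#' the triplet dye at 370 nm, the charge-separated state from a single
#' Gaussian fitted to the 552 nm Q-band, ground-state recovery from the
#' 475 nm dye bleach, and the His/Met Fe(II) fraction from the half-height
#' width of the positive Soret lobe.
#'
#' @name spectra
NULL

.nearest_wl <- function(cube, wavelength) {
  if (wavelength < min(cube$wavelengths) || wavelength > max(cube$wavelengths))
    stop("wavelength ", wavelength, " nm outside the cube's grid")
  which.min(abs(cube$wavelengths - wavelength))
}

#' Extract the 3Ru population at 370 nm
#'
#' Takes the difference absorbance at the grid point nearest 370 nm and
#' normalizes so the first time point equals 1 (the earliest probe delay
#' defines 100% excitation).
#'
#' @param cube A `spectral_cube`.
#' @param wavelength Probe wavelength (nm, default 370).
#' @return Data frame with columns `time_s`, `ru3`.
#' @export
extract_3ru <- function(cube, wavelength = 370) {
  i <- .nearest_wl(cube, wavelength)
  y <- cube$dA[i, ]
  if (max(abs(y)) < .Machine$double.eps * 100)
    stop("no signal at ", wavelength, " nm: cannot quantify 3Ru")
  data.frame(time_s = cube$times, ru3 = y / y[1])
}

# straight-line baseline through the window endpoints
.local_baseline <- function(wl, y) {
  n <- length(wl)
  y[1] + (y[n] - y[1]) * (wl - wl[1]) / (wl[n] - wl[1])
}

.fit_qband_gaussian <- function(wl, y, center_init, center_tol, fwhm_init) {
  resid_fn <- function(p) {
    y - p[1] * exp(-4 * log(2) * ((wl - p[2]) / p[3])^2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(max(y), center_init, fwhm_init), fn = resid_fn,
      lower = c(-Inf, center_init - center_tol, 2),
      upper = c(Inf, center_init + center_tol, 40),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NA_real_)
  fit$par[1]
}

#' Extract the charge-separated population from the 552 nm Q-band
#'
#' For each time point, subtracts a straight-line baseline through the window
#' endpoints and fits a single Gaussian with center constrained to
#' `center_init +/- center_tol` nm. The fitted amplitude is converted to a
#' population by the same procedure applied to the pure Fe(II) spectrum of
#' the supplied basis (assuming equal Q-band extinction for His/His and
#' His/Met ferroheme), or by an explicit `amp_per_unit` calibration factor.
#' Time points where the fit fails are returned as `NA`.
#'
#' @param cube A `spectral_cube`.
#' @param window Wavelength window (nm), default `c(535, 570)`.
#' @param basis Basis used for amplitude calibration (default
#'   [default_basis()]).
#' @param amp_per_unit Optional explicit calibration: fitted Gaussian
#'   amplitude (mOD) per unit population; overrides `basis`.
#' @param center_init,center_tol Q-band center initialization and allowed
#'   shift (nm).
#' @return Data frame with columns `time_s`, `cs_total`.
#' @export
extract_cs_qband <- function(cube, window = c(535, 570),
                             basis = default_basis(), amp_per_unit = NULL,
                             center_init = 552, center_tol = 5) {
  stopifnot(inherits(cube, "spectral_cube"), length(window) == 2)
  if (window[1] < min(cube$wavelengths) || window[2] > max(cube$wavelengths))
    stop("Q-band window outside the cube's wavelength grid")
  sel <- cube$wavelengths >= window[1] & cube$wavelengths <= window[2]
  wl <- cube$wavelengths[sel]
  if (is.null(amp_per_unit)) {
    ref <- render_species_spectrum(basis, "fe2_hishis", wl)
    amp_per_unit <- .fit_qband_gaussian(wl, ref - .local_baseline(wl, ref),
                                        center_init, center_tol, 10)
    if (!is.finite(amp_per_unit) || amp_per_unit <= 0)
      stop("could not calibrate Q-band amplitude from the basis")
  }
  amps <- vapply(seq_along(cube$times), function(j) {
    y <- cube$dA[sel, j]
    .fit_qband_gaussian(wl, y - .local_baseline(wl, y),
                        center_init, center_tol, 10)
  }, numeric(1))
  data.frame(time_s = cube$times, cs_total = amps / amp_per_unit)
}

#' Extract ground-state recovery from the 475 nm bleach
#'
#' The dye ground-state population is depleted while the system is excited or
#' charge-separated; its recovery is `1 - dA(475, t) / dA_full`, where
#' `dA_full` is the (negative) bleach amplitude at full excitation. By
#' default `dA_full` is taken from the first time point, where the entire
#' population is excited.
#'
#' @param cube A `spectral_cube`.
#' @param wavelength Probe wavelength (nm, default 475).
#' @param bleach_full Bleach amplitude (mOD, negative) at full excitation.
#'   Defaults to the basis value at the probe wavelength when `basis` is
#'   supplied, else to `dA(475, first time)` (the earliest delay, where the
#'   population is fully excited).
#' @param basis Optional `spectral_basis` used to calibrate `bleach_full`.
#' @return Data frame with columns `time_s`, `gs`.
#' @export
extract_gs_bleach <- function(cube, wavelength = 475, bleach_full = NULL,
                              basis = NULL) {
  i <- .nearest_wl(cube, wavelength)
  y <- cube$dA[i, ]
  if (is.null(bleach_full))
    bleach_full <- if (!is.null(basis))
      render_species_spectrum(basis, "ru_bleach", cube$wavelengths[i])
    else y[1]
  if (!is.finite(bleach_full) || bleach_full >= 0)
    stop("bleach amplitude at full excitation must be negative")
  data.frame(time_s = cube$times, gs = 1 - y / bleach_full)
}

#' Half-height width of the positive Soret lobe
#'
#' Measures the full width at half maximum of the positive feature within the
#' Soret window by linear interpolation between grid points.
#'
#' @param wavelengths Wavelength grid (nm) covering the window.
#' @param values Difference absorbance on that grid.
#' @param window Soret window (nm), default `c(380, 450)`.
#' @return Width (nm).
#' @export
soret_lobe_fwhm <- function(wavelengths, values, window = c(380, 450)) {
  stopifnot(length(wavelengths) == length(values))
  if (min(wavelengths) > window[1] || max(wavelengths) < window[2])
    stop("spectrum must cover the Soret window ", window[1], "-", window[2], " nm")
  sel <- wavelengths >= window[1] & wavelengths <= window[2]
  wl <- wavelengths[sel]; y <- values[sel]
  imax <- which.max(y)
  if (y[imax] <= 0) stop("no positive Soret lobe in the window")
  half <- y[imax] / 2
  # left crossing: last point below half before the peak
  yy <- y[seq_len(imax)]; ww <- wl[seq_len(imax)]
  below <- yy < half
  left <- if (!any(below)) ww[1] else {
    j <- max(which(below))
    ww[j] + (half - yy[j]) * (ww[j + 1] - ww[j]) / (yy[j + 1] - yy[j])
  }
  # right crossing: first point below half after the peak
  yy <- y[imax:length(y)]; ww <- wl[imax:length(y)]
  below <- yy < half
  right <- if (!any(below)) ww[length(ww)] else {
    j <- min(which(below))
    ww[j - 1] + (half - yy[j - 1]) * (ww[j] - ww[j - 1]) / (yy[j] - yy[j - 1])
  }
  right - left
}

#' Soret-lobe width of a His/His + His/Met ferroheme mixture
#'
#' Renders `(1 - f) * S_hishis + f * S_hismet` from the basis on a fine grid
#' and measures [soret_lobe_fwhm()].
#'
#' @param fraction His/Met fraction in `[0, 1]` (vectorized).
#' @param basis A `spectral_basis`.
#' @param grid_step Rendering grid step (nm).
#' @return Width(s) in nm.
#' @export
soret_width_of_mixture <- function(fraction, basis = default_basis(),
                                   grid_step = 0.25) {
  wl <- seq(380, 450, by = grid_step)
  hh <- render_species_spectrum(basis, "fe2_hishis", wl)
  hm <- render_species_spectrum(basis, "fe2_hismet", wl)
  vapply(fraction, function(f)
    soret_lobe_fwhm(wl, (1 - f) * hh + f * hm), numeric(1))
}

#' His/Met Fe(II) fraction from a Soret-lobe width
#'
#' Numerically inverts the monotone width-versus-fraction curve implied by
#' the basis (bisection to 1e-6 in the fraction). Widths outside the pure
#' endpoint values are clipped with a warning. Reported relative to total
#' Fe(II); multiply by the total charge-separated population for the absolute
#' Heme-8 population.
#'
#' @param width Measured width (nm) (vectorized).
#' @param basis A `spectral_basis`.
#' @return Fraction(s) in `[0, 1]`.
#' @export
hismet_fraction_from_width <- function(width, basis = default_basis()) {
  w0 <- soret_width_of_mixture(0, basis)
  w1 <- soret_width_of_mixture(1, basis)
  if (w1 <= w0)
    stop("basis widths are non-monotone: pure His/Met lobe not wider than His/His")
  probe <- soret_width_of_mixture(seq(0, 1, by = 0.05), basis)
  if (any(diff(probe) <= 0))
    stop("width-versus-fraction curve is not strictly monotone for this basis")
  vapply(width, function(w) {
    if (is.na(w)) return(NA_real_)
    if (w <= w0 || w >= w1) {
      if (w < w0 - 1e-9 || w > w1 + 1e-9)
        warning("width ", format(w), " nm outside the pure-basis endpoints; clipped")
      return(if (w <= w0) 0 else 1)
    }
    lo <- 0; hi <- 1
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (soret_width_of_mixture(mid, basis) < w) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Run the full spectral extraction pipeline on a cube
#'
#' Convenience wrapper returning the 3Ru, charge-separated and ground-state
#' populations (and, for His/Met-containing proteins, the Heme 8 Fe(II)
#' population from the Soret width) as one tidy table compatible with the
#' fitting module.
#'
#' @param cube A `spectral_cube`.
#' @param basis Basis used for calibration.
#' @param heme8_ligation `"His/His"` or `"His/Met"`.
#' @return Data frame with columns `time_s`, `ru3`, `cs_total`, `gs` and
#'   (His/Met only) `hismet_fraction`, `fe2_heme8`.
#' @export
extract_populations <- function(cube, basis = default_basis(),
                                heme8_ligation = c("His/His", "His/Met")) {
  heme8_ligation <- match.arg(heme8_ligation)
  out <- data.frame(
    time_s = cube$times,
    ru3 = extract_3ru(cube)$ru3,
    cs_total = extract_cs_qband(cube, basis = basis)$cs_total,
    gs = extract_gs_bleach(cube, basis = basis)$gs
  )
  if (heme8_ligation == "His/Met") {
    # unmix the dye contributions (3Ru band and ground-state bleach) from the
    # Soret window so the residual is the pure ferroheme difference spectrum,
    # then measure the positive-lobe width on that residual
    sel <- cube$wavelengths >= 380 & cube$wavelengths <= 450
    wl <- cube$wavelengths[sel]
    S_ru3 <- render_species_spectrum(basis, "ru3", wl)
    S_bl <- render_species_spectrum(basis, "ru_bleach", wl)
    widths <- vapply(seq_along(cube$times), function(j) {
      dye <- out$ru3[j] * S_ru3 + (out$ru3[j] + out$cs_total[j]) * S_bl
      if (anyNA(dye)) dye <- 0
      tryCatch(soret_lobe_fwhm(wl, cube$dA[sel, j] - dye),
               error = function(e) NA_real_)
    }, numeric(1))
    suppressWarnings(
      out$hismet_fraction <- hismet_fraction_from_width(widths, basis))
    out$fe2_heme8 <- out$hismet_fraction * out$cs_total
  }
  out
}
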