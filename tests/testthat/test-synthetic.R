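test_that("default basis satisfies the qualitative spectroscopy orderings", {
  b <- default_basis()
  # His/Met positive Soret lobe broader and red-shifted vs His/His
  pos_hh <- Filter(function(x) x$amplitude > 0 && x$center < 500,
                   b$fe2_hishis)[[1]]
  pos_hm <- Filter(function(x) x$amplitude > 0 && x$center < 500,
                   b$fe2_hismet)[[1]]
  expect_gt(pos_hm$fwhm, pos_hh$fwhm)
  expect_gt(pos_hm$center, pos_hh$center)
  expect_gt(soret_width_of_mixture(1, b), soret_width_of_mixture(0, b))
  # alpha and beta Q-bands at 552 and 522 nm for both ligation types
  for (sp in c("fe2_hishis", "fe2_hismet")) {
    centers <- vapply(b[[sp]], `[[`, 0, "center")
    expect_true(all(c(552, 522) %in% centers))
  }
  expect_error(gaussian_band(400, -1, 1), "fwhm")
})

test_that("cube rendering is linear in basis amplitudes and populations", {
  m <- met8_model()
  tt <- quick_times(15)
  wl <- seq(350, 600, by = 2)
  b1 <- default_basis()
  b2 <- rapply(b1, function(x) x, how = "replace")
  b2 <- structure(lapply(b1, function(bl) lapply(bl, function(bd) {
    bd$amplitude <- 2 * bd$amplitude; bd
  })), class = "spectral_basis")
  c1 <- simulate_transient_cube(m, b1, wl, tt)
  c2 <- simulate_transient_cube(m, b2, wl, tt)
  expect_equal(c2$dA, 2 * c1$dA, tolerance = 1e-12)
})

test_that("an all-ground-state system renders a zero cube", {
  # inert excitation: by 1 s everything is in GS
  m <- single_conformer_model(k_cs = 1e9, k_cr = 1e9)
  cube <- simulate_transient_cube(m, wavelengths = seq(350, 600, 5),
                                  times = c(1, 2))
  expect_lt(max(abs(cube$dA)), 1e-8)
})

test_that("fixed seeds give bitwise-identical noisy outputs", {
  m <- met8_model(); tt <- quick_times(10); wl <- seq(350, 600, 5)
  c1 <- simulate_transient_cube(m, wavelengths = wl, times = tt,
                                noise = noise_model(0.1, seed = 5))
  c2 <- simulate_transient_cube(m, wavelengths = wl, times = tt,
                                noise = noise_model(0.1, seed = 5))
  expect_identical(c1$dA, c2$dA)
  d1 <- simulate_pl_decay(m$conformers, 0, tt, noise_model(0.01, 3))
  d2 <- simulate_pl_decay(m$conformers, 0, tt, noise_model(0.01, 3))
  expect_identical(d1$intensity, d2$intensity)
  E <- seq(-400, 400, 20)
  t1 <- simulate_titration(mtrc_titration_centers("met8"), E,
                           noise_model(0.01, 9))
  t2 <- simulate_titration(mtrc_titration_centers("met8"), E,
                           noise_model(0.01, 9))
  expect_identical(t1$fraction_reduced, t2$fraction_reduced)
})

test_that("noiseless cubes are exactly unmixable by least squares", {
  m <- met8_model()
  tt <- quick_times(25)
  wl <- seq(350, 600, by = 1)
  cube <- simulate_transient_cube(m, wavelengths = wl, times = tt)
  b <- default_basis()
  X <- cbind(
    ru3 = render_species_spectrum(b, "ru3", wl) +
      render_species_spectrum(b, "ru_bleach", wl),
    hh = render_species_spectrum(b, "fe2_hishis", wl) +
      render_species_spectrum(b, "ru_bleach", wl),
    hm = render_species_spectrum(b, "fe2_hismet", wl) +
      render_species_spectrum(b, "ru_bleach", wl))
  resid <- stats::lm.fit(X, cube$dA)$residuals
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("photoluminescence decays follow the stated closed forms", {
  tt <- quick_times(50, 1e-9, 2e-6)
  # single conformer: pure exponential at k_cs + k_intrinsic
  d <- simulate_pl_decay(list(conformer_params("a", 1, 5e7, 1)), 2e6, tt)
  expect_equal(d$intensity, exp(-(5e7 + 2e6) * tt), tolerance = 1e-12)
  # free dye: single exponential with the intrinsic rate only
  dye <- simulate_pl_decay(list(weights = 1, k_cs = 0), 2e6, tt)
  expect_equal(dye$intensity, exp(-2e6 * tt), tolerance = 1e-12)
  # published Met8 parameters: biexponential sum
  p <- ru_mtrc_params()$pl_conformers$met8
  d2 <- simulate_pl_decay(list(weights = p$weights, k_cs = p$k_cs), 0, tt)
  ref <- p$weights[["a"]] * exp(-p$k_cs[["a"]] * tt) +
    p$weights[["b"]] * exp(-p$k_cs[["b"]] * tt)
  expect_equal(d2$intensity, ref, tolerance = 1e-12)
  expect_error(simulate_pl_decay(list(), 0, tt), "empty")
})

test_that("titration curves equal the direct Nernst-sum oracle", {
  E <- seq(-400, 400, by = 5)
  centers <- mtrc_titration_centers("met8")
  got <- simulate_titration(centers, E)$fraction_reduced
  oracle <- sapply(E, function(e)
    mean(1 / (1 + 10^((e - centers$E_m) * centers$n / 59.16))))
  expect_equal(got, oracle, tolerance = 1e-12)
  # one high-potential center among nine low ones: at +100 mV the reduced
  # fraction is the high center's Nernst value (about 0.098), others inert
  ctrs <- data.frame(E_m = c(199, rep(-300, 9)), n = 1)
  f100 <- simulate_titration(ctrs, 100)$fraction_reduced
  direct <- mean(1 / (1 + 10^((100 - ctrs$E_m) / 59.16)))
  expect_equal(f100, direct, tolerance = 1e-9)
  expect_equal(f100, 0.1, tolerance = 0.03)
  expect_error(simulate_titration(data.frame(), E), "empty")
})

test_that("mixture Soret width increases strictly with His/Met fraction", {
  w <- soret_width_of_mixture(seq(0, 1, by = 0.01))
  expect_true(all(diff(w) > 0))
})

test_that("cube CSV round trip is lossless", {
  m <- met8_model()
  cube <- simulate_transient_cube(m, wavelengths = seq(350, 600, 10),
                                  times = quick_times(8),
                                  noise = noise_model(0.05, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cube_csv(cube, f)
  back <- read_cube_csv(f)
  expect_equal(back$wavelengths, cube$wavelengths)
  expect_equal(back$times, cube$times)
  expect_equal(back$dA, cube$dA, tolerance = 1e-12)
})
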