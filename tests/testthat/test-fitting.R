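test_that("r_squared matches brute-force arithmetic", {
  expect_equal(r_squared(1:5, 1:5), 1)
  obs <- c(2, 4, 3, 7, 5)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  mod <- c(2.2, 3.6, 3.1, 6.5, 5.4)
  expect_equal(r_squared(obs, mod),
               1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2))
  expect_error(r_squared(rep(1, 4), rep(1, 4)), "variance")
})

test_that("a noiseless single exponential is recovered exactly", {
  tt <- quick_times(60, 1e-9, 2e-6)
  d <- data.frame(time_s = tt, intensity = exp(-3e6 * tt))
  fit <- fit_multi_exponential(d, 1, multistart = 4, seed = 1)
  expect_equal(fit$components$rate, 3e6, tolerance = 1e-6)
  expect_equal(fit$components$contribution, 1)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("biexponential fits recover the published decay parameters", {
  p <- ru_mtrc_params()$pl_conformers$met8
  tt <- quick_times(80, 1e-9, 2e-6)
  doms <- vapply(1:5, function(s) {
    d <- simulate_pl_decay(list(weights = p$weights, k_cs = p$k_cs), 0, tt,
                           noise_model(0.01, s))
    fit <- fit_multi_exponential(d, 2, multistart = 8, seed = 100 + s)
    fit$components$contribution[which.max(fit$components$contribution)] * 100
  }, numeric(1))
  expect_lt(abs(stats::median(doms) - 91), 2)
  expect_true(all(abs(doms - 91) < 6))
})

test_that("component-count selection matches the generating truth", {
  tt <- quick_times(90, 5e-12, 2e-6)
  p2 <- ru_mtrc_params()$pl_conformers$met8
  bi <- simulate_pl_decay(list(weights = p2$weights, k_cs = p2$k_cs), 0, tt,
                          noise_model(0.005, 1))
  expect_equal(select_conformer_count(bi, n_max = 4, seed = 2), 2)

  ta <- ru_mtrc_params()$ta_conformers
  tri <- simulate_pl_decay(list(weights = ta$weights, k_cs = ta$k_cs), 0, tt,
                           noise_model(0.005, 3))
  f2 <- fit_multi_exponential(tri, 2, multistart = 8, seed = 4)
  f3 <- fit_multi_exponential(tri, 3, multistart = 8, seed = 5)
  expect_lt(f3$aic, f2$aic)
  expect_equal(select_conformer_count(tri, n_max = 4, seed = 6), 3)

  flat <- data.frame(time_s = tt, intensity = rep(1, length(tt)))
  expect_equal(select_conformer_count(flat, n_max = 3), 1L)
})

test_that("fits are invariant to time-unit rescaling", {
  tt <- quick_times(60, 1e-9, 2e-6)
  d <- simulate_pl_decay(list(weights = c(0.3, 0.7), k_cs = c(4e6, 6e7)),
                         0, tt, noise_model(0.005, 7))
  fit_s <- fit_multi_exponential(d, 2, multistart = 6, seed = 8)
  d_ns <- data.frame(time_s = d$time_s * 1e9, intensity = d$intensity)
  fit_ns <- fit_multi_exponential(d_ns, 2, multistart = 6, seed = 8,
                                  k_range = c(1e-4, 10))
  expect_equal(fit_ns$components$rate * 1e9, fit_s$components$rate,
               tolerance = 1e-3)
  expect_equal(fit_ns$components$contribution, fit_s$components$contribution,
               tolerance = 1e-3)
})

test_that("the Heme-8 reporter adds curvature against mis-set chain rates", {
  # residual sum at a co-scaled (k_9to10, k_9to8) perturbation: the flat
  # direction of the charge-separated objective gains information when the
  # His/Met Fe(II) curve is included
  times <- quick_times(60)
  m <- met8_model()
  truth_cs <- simulate_observable_curves(m, times)
  truth_h8 <- simulate_observable_curves(m, times, include_heme8 = TRUE)
  ch <- m$chain
  perturbed <- photocycle_model(
    m$conformers,
    chain_rates(ch$k_10to9, ch$k_9to10 * 0.03, ch$k_9to8 * 0.03, ch$k_8to9),
    heme8_ligation = "His/Met")
  ss <- function(obs) {
    sim <- project_observables(simulate_populations(perturbed, times))
    r <- 2 * (sim$cs_total - obs$cs_total)
    if (!is.null(obs$fe2_heme8)) r <- c(r, sim$fe2_heme8 - obs$fe2_heme8)
    sum(r^2)
  }
  expect_gt(ss(truth_h8), 10 * ss(truth_cs))
})

test_that("noiseless global fit is self-consistent", {
  times <- quick_times(80)
  om <- simulate_observable_curves(met8_model(), times,
                                   include_heme8 = TRUE)
  oh <- simulate_observable_curves(his8_model(), times)
  fit <- fit_photocycle_global(om, oh, multistart = 1, seed = 11,
                               polish = FALSE)
  # shared conformer structure recovered from the 3Ru decays
  ta <- ru_mtrc_params()$ta_conformers
  expect_equal(unname(fit$shared$weights), unname(ta$weights),
               tolerance = 0.05)
  expect_equal(unname(fit$shared$k_cs), unname(ta$k_cs), tolerance = 0.05)
  # with noiseless data and the His/Met reporter curve, the Met8 stage-2
  # minimum is the generating model; for the all-His/His protein only the
  # Heme 10 -> 9 rate and the recombination rates are structurally
  # identifiable from its charge-separated population (the remaining chain
  # rates lie on an observationally equivalent manifold)
  p <- ru_mtrc_params()
  expect_equal(unlist(fit$met8$model$chain), unlist(p$chain$met8),
               tolerance = 0.05)
  expect_equal(fit$his8$model$chain$k_10to9, p$chain$his8$k_10to9,
               tolerance = 0.05)
  for (prot in c("met8", "his8")) {
    kcr <- vapply(fit[[prot]]$model$conformers, `[[`, 0, "k_cr")
    expect_equal(unname(kcr), unname(p$ta_conformers$k_cr[[prot]]),
                 tolerance = 0.05)
    expect_gt(min(fit[[prot]]$r_squared), 0.999)
  }
})

test_that("the objective prefers true chain rates over perturbed ones", {
  times <- quick_times(60)
  m <- met8_model()
  obs <- simulate_observable_curves(m, times, noise_model(0.02, 21),
                                    include_heme8 = TRUE)
  ss_for <- function(model) {
    sim <- project_observables(simulate_populations(model, times))
    sum((2 * (sim$cs_total - obs$cs_total))^2) +
      sum((sim$fe2_heme8 - obs$fe2_heme8)^2) +
      sum((sim$ru3 - obs$ru3)^2)
  }
  ch <- m$chain
  worse <- photocycle_model(
    m$conformers,
    chain_rates(ch$k_10to9 * 10, ch$k_9to10 * 10, ch$k_9to8 * 10,
                ch$k_8to9 * 10),
    heme8_ligation = "His/Met")
  expect_lt(ss_for(m), ss_for(worse))
})
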