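test_that("rate matrix matches an independent transition-list assembly", {
  set.seed(1)
  for (rep in 1:5) {
    m <- random_model()
    for (lab in names(m$conformers)) {
      M <- build_rate_matrix(m, lab)
      # independent oracle: literal enumeration of the allowed transitions
      cf <- m$conformers[[lab]]; ch <- m$chain
      st <- c("Ru3", "CS10", "CS9", "CS8", "GS")
      trans <- list(
        list("Ru3", "CS10", cf$k_cs), list("Ru3", "GS", m$k_intrinsic),
        list("CS10", "CS9", ch$k_10to9), list("CS9", "CS10", ch$k_9to10),
        list("CS9", "CS8", ch$k_9to8), list("CS8", "CS9", ch$k_8to9),
        list("CS10", "GS", cf$k_cr))
      Mref <- matrix(0, 5, 5, dimnames = list(st, st))
      for (tr in trans) {
        Mref[tr[[2]], tr[[1]]] <- Mref[tr[[2]], tr[[1]]] + tr[[3]]
        Mref[tr[[1]], tr[[1]]] <- Mref[tr[[1]], tr[[1]]] - tr[[3]]
      }
      expect_equal(M, Mref, tolerance = 1e-14)
      expect_equal(max(abs(colSums(M))), 0, tolerance = 1e-12 * max(abs(M)))
      offdiag <- M[row(M) != col(M)]
      expect_true(all(offdiag >= 0))
    }
  }
})

test_that("single-channel matrix has only the charge-separation pair", {
  m <- single_conformer_model(k_cs = 5e6, k_cr = 1e-3, chain = rep(1e-3, 4))
  M <- build_rate_matrix(m, "a")
  expect_equal(M["CS10", "Ru3"], 5e6)
  expect_equal(M["Ru3", "Ru3"], -5e6)
  expect_lt(max(abs(M[, c("CS9", "CS8", "GS")])), 1e-2)
})

test_that("unknown conformer and invalid rates are rejected", {
  m <- met8_model()
  expect_error(build_rate_matrix(m, "zz"), "unknown conformer")
  expect_error(conformer_params("a", 0.5, -1, 1), "k_cs")
  expect_error(chain_rates(1, 1, 0, 1), "positive")
  expect_error(photocycle_model(
    list(conformer_params("a", 0.5, 1, 1)),
    chain_rates(1, 1, 1, 1)), "sum to 1")
})

test_that("populations start at the initial condition and obey closed forms", {
  m <- met8_model()
  tr <- simulate_populations(m, c(0, 1e-9))
  w <- vapply(m$conformers, `[[`, 0, "weight")
  expect_equal(unname(tr$pops[1, "Ru3", ]), unname(w), tolerance = 1e-12)
  expect_equal(sum(tr$pops[1, c("CS10", "CS9", "CS8", "GS"), ]), 0)

  # inert chain/CR: 3Ru and CS10 follow the textbook two-state solution
  k_cs <- 5e7; k_i <- 2e6
  ms <- single_conformer_model(k_cs = k_cs, k_intrinsic = k_i)
  tt <- quick_times(30, 1e-10, 1e-6)
  trs <- simulate_populations(ms, tt)
  ktot <- k_cs + k_i
  expect_equal(trs$pops[, "Ru3", 1], exp(-ktot * tt), tolerance = 1e-7)
  expect_equal(trs$pops[, "CS10", 1],
               k_cs / ktot * (1 - exp(-ktot * tt)), tolerance = 1e-6)
})

test_that("eigen solution agrees with the adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  tt <- quick_times(25, 1e-12, 1e-3)
  # the published Met8 model, then random rate sets
  models <- c(list(met8_model(), his8_model()),
              { set.seed(7); lapply(1:12, function(i) random_model()) })
  for (m in models) {
    ours <- simulate_populations(m, tt)$pops
    ref <- odesolve_populations(m, tt)
    expect_lt(max(abs(ours - ref)), 1e-8)
    rel <- abs(ours - ref) / pmax(abs(ref), 1e-3)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("probability is conserved and monotonicity holds", {
  set.seed(11)
  tt <- quick_times(40)
  for (i in 1:10) {
    m <- random_model()
    obs <- project_observables(simulate_populations(m, tt),
                               normalize = FALSE)
    expect_lt(max(abs(obs$ru3 + obs$cs_total + obs$gs - 1)), 1e-9)
    expect_true(all(diff(obs$ru3) <= 1e-12))
    expect_true(all(diff(obs$gs) >= -1e-12))
    expect_true(all(obs$ru3 >= -1e-12 & obs$ru3 <= 1 + 1e-12))
  }
})

test_that("inert-boundary equilibrium satisfies detailed balance ratios", {
  ch <- chain_rates(2e8, 1e8, 5e7, 2.5e8)
  m <- photocycle_model(
    list(conformer_params("a", 1, 1e-6, 1e-6)), ch,
    k_intrinsic = 0)
  tr <- simulate_populations(m, c(1e-4), initial_state = "CS10")
  p <- tr$pops[1, , 1]
  expect_equal(p[["CS9"]] / p[["CS10"]], ch$k_10to9 / ch$k_9to10,
               tolerance = 1e-6)
  expect_equal(p[["CS8"]] / p[["CS9"]], ch$k_9to8 / ch$k_8to9,
               tolerance = 1e-6)
})

test_that("a deeper Heme-8 sink prolongs the charge-separated state", {
  p <- ru_mtrc_params()
  base <- p$chain$met8
  ratios <- c(0.1, 1, 10, 100, 1000)
  lives <- vapply(ratios, function(r) {
    ch <- chain_rates(base$k_10to9, base$k_9to10, 1e9 * sqrt(r),
                      1e9 / sqrt(r))
    m <- photocycle_model(met8_model()$conformers, ch,
                          heme8_ligation = "His/Met")
    cs_half_life(m)
  }, numeric(1))
  expect_true(all(diff(lives) > 0))
  # the His/Met variant's ground-state recovery is slower than all-His/His
  expect_gt(cs_half_life(met8_model()), cs_half_life(his8_model()))
})

test_that("observable projection identities hold", {
  tt <- quick_times(30)
  tr <- simulate_populations(met8_model(), tt)
  obs <- project_observables(tr)
  expect_equal(obs$fe2_heme10 + obs$fe2_heme9 + obs$fe2_heme8,
               obs$cs_total, tolerance = 1e-12)
  expect_equal(obs$fe2_hishis + obs$fe2_hismet, obs$cs_total,
               tolerance = 1e-12)
  expect_equal(obs$ru3[1], 1)
  # His/Met Fe(II) is exactly the Heme 8 population for the Met8 protein
  expect_equal(obs$fe2_hismet, obs$fe2_heme8)
  # all-His/His projection puts everything in the His/His pool
  obs2 <- project_observables(tr, heme8_ligation = "His/His")
  expect_true(all(obs2$fe2_hismet == 0))
  expect_equal(obs2$fe2_hishis, obs2$cs_total, tolerance = 1e-12)
})

test_that("model JSON round trip preserves parameters", {
  m <- met8_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(unclass(m2$chain), unclass(m$chain))
  expect_equal(vapply(m2$conformers, `[[`, 0, "k_cr"),
               vapply(m$conformers, `[[`, 0, "k_cr"))
  expect_equal(m2$heme8_ligation, m$heme8_ligation)
})
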