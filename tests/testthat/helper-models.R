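# shared fixtures: published-parameter models and small grids

met8_model <- function() ru_mtrc_model("met8")
his8_model <- function() ru_mtrc_model("his8")

# coarse log time grid for quick simulations
quick_times <- function(n = 40, from = 5e-12, to = 1e-3)
  default_time_grid(n = n, from = from, to = to)

# a single-conformer model with near-inert chain/CR channels, for closed-form
# checks (rates must be positive; 1e-3 /s is inert on the sub-ms scale)
single_conformer_model <- function(k_cs = 5e7, k_cr = 1e-3, k_intrinsic = 0,
                                   chain = rep(1e-3, 4)) {
  photocycle_model(
    conformers = list(conformer_params("a", 1, k_cs, k_cr)),
    chain = chain_rates(chain[1], chain[2], chain[3], chain[4]),
    k_intrinsic = k_intrinsic
  )
}

# random photocycle model with log-uniform rates, for property tests
random_model <- function(lo = 1e5, hi = 1e11) {
  r <- function() exp(stats::runif(1, log(lo), log(hi)))
  w <- stats::runif(3); w <- w / sum(w)
  photocycle_model(
    conformers = list(conformer_params("a", w[1], r(), r()),
                      conformer_params("b", w[2], r(), r()),
                      conformer_params("c", w[3], r(), r())),
    chain = chain_rates(r(), r(), r(), r()),
    k_intrinsic = 0
  )
}

# independent ODE oracle: adaptive stiff integration with deSolve
odesolve_populations <- function(model, times) {
  labels <- names(model$conformers)
  out <- array(0, dim = c(length(times), 5L, length(labels)),
               dimnames = list(NULL, c("Ru3", "CS10", "CS9", "CS8", "GS"),
                               labels))
  for (lab in labels) {
    M <- build_rate_matrix(model, lab)
    p0 <- c(model$conformers[[lab]]$weight, 0, 0, 0, 0)
    sol <- deSolve::lsoda(
      y = p0, times = c(0, times),
      func = function(t, y, parms) list(as.vector(M %*% y)),
      rtol = 1e-10, atol = 1e-13)
    out[, , lab] <- sol[-1, -1, drop = FALSE]
  }
  out
}

# half-life of the total charge-separated population
cs_half_life <- function(model, times = default_time_grid(n = 400)) {
  obs <- project_observables(simulate_populations(model, times),
                             normalize = FALSE)
  peak <- which.max(obs$cs_total)
  after <- obs$cs_total[peak:length(times)]
  times[peak:length(times)][min(which(after <= obs$cs_total[peak] / 2))]
}
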