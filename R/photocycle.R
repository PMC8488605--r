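#' @title Photocycle kinetic network of a photosensitized heme chain
#'
#' @description
#' The photocycle couples photoexcitation of a surface-attached Ru(II) dye to
#' electron injection into a three-heme segment (Hemes 10, 9, 8) of a
#' multiheme cytochrome. Each long-lived dye conformer `x` runs its own copy
#' of the five-state network
#'
#' \preformatted{
#'   3Ru --k_cs--> CS10 <--> CS9 <--> CS8
#'    |              |
#'    k_intrinsic    k_cr
#'    v              v
#'    GS <-----------+
#' }
#'
#' where `CSi` is the charge-separated state with the electron on Heme i,
#' `GS` the recovered ground state. Heme-heme hopping rates are shared by all
#' conformers; charge separation and recombination are conformer-specific.
#' Charge recombination proceeds only from `CS10`, the heme adjacent to the
#' dye.
#'
#' @name photocycle
NULL

.PHOTO_STATES <- c("Ru3", "CS10", "CS9", "CS8", "GS")

#' Conformer parameters for the photocycle
#'
#' @param label Conformer label, e.g. `"a"`, `"b"`, `"c"`.
#' @param weight Fraction of the total excited population in this conformer,
#'   in `[0, 1]`.
#' @param k_cs Charge-separation rate constant (s^-1), > 0.
#' @param k_cr Charge-recombination rate constant (s^-1), > 0.
#' @return A `conformer_params` object.
#' @export
conformer_params <- function(label, weight, k_cs, k_cr) {
  stopifnot(is.character(label), nchar(label) > 0)
  if (!is.finite(weight) || weight < 0 || weight > 1)
    stop("conformer weight must be in [0, 1]")
  if (!is.finite(k_cs) || k_cs <= 0) stop("k_cs must be positive and finite")
  if (!is.finite(k_cr) || k_cr <= 0) stop("k_cr must be positive and finite")
  structure(list(label = label, weight = weight, k_cs = k_cs, k_cr = k_cr),
            class = "conformer_params")
}

#' Heme-chain ET rate constants
#'
#' Naming follows the direction of electron motion along the chain:
#' `k_10to9` is the Heme 10 -> Heme 9 ET rate (the literature convention for
#' this system writes it k_9,10: `k[i-1,i]` is Heme i -> Heme i-1 ET), and
#' correspondingly `k_9to10` = k_10,9, `k_9to8` = k_8,9, `k_8to9` = k_9,8.
#'
#' @param k_10to9,k_9to10,k_9to8,k_8to9 Rate constants in s^-1, all > 0.
#' @return A `chain_rates` object.
#' @export
chain_rates <- function(k_10to9, k_9to10, k_9to8, k_8to9) {
  k <- c(k_10to9 = k_10to9, k_9to10 = k_9to10,
         k_9to8 = k_9to8, k_8to9 = k_8to9)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all chain rate constants must be positive and finite")
  structure(as.list(k), class = "chain_rates")
}

#' Assemble a photocycle model
#'
#' @param conformers List of [conformer_params()] objects; weights must sum
#'   to 1 (tolerance 1e-12).
#' @param chain A [chain_rates()] object, shared by all conformers.
#' @param k_intrinsic Intrinsic 3Ru -> GS decay rate (s^-1, may be 0). The
#'   free dye decays at 2e6 s^-1; in kinetic fits of the labelled proteins
#'   charge separation is dominant and this channel defaults to 0.
#' @param heme8_ligation Axial ligation of Heme 8, `"His/His"` or
#'   `"His/Met"`; determines which difference spectrum the `CS8` state
#'   carries.
#' @return A `photocycle_model` object.
#' @export
photocycle_model <- function(conformers, chain, k_intrinsic = 0,
                             heme8_ligation = c("His/His", "His/Met")) {
  heme8_ligation <- match.arg(heme8_ligation)
  stopifnot(length(conformers) >= 1)
  stopifnot(all(vapply(conformers, inherits, TRUE, "conformer_params")))
  stopifnot(inherits(chain, "chain_rates"))
  if (!is.finite(k_intrinsic) || k_intrinsic < 0)
    stop("k_intrinsic must be >= 0 and finite")
  w <- vapply(conformers, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop("conformer weights must sum to 1 (got ", format(sum(w)), ")")
  labels <- vapply(conformers, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicated conformer labels")
  names(conformers) <- labels
  structure(list(conformers = conformers, chain = chain,
                 k_intrinsic = k_intrinsic, heme8_ligation = heme8_ligation),
            class = "photocycle_model")
}

#' @export
print.photocycle_model <- function(x, ...) {
  cat("photocycle model:", length(x$conformers), "conformer(s), Heme 8",
      x$heme8_ligation, "\n")
  for (cf in x$conformers)
    cat(sprintf("  conformer %s: weight %.3f, k_cs %.4g /s, k_cr %.4g /s\n",
                cf$label, cf$weight, cf$k_cs, cf$k_cr))
  ch <- x$chain
  cat(sprintf("  chain: k_10to9 %.4g, k_9to10 %.4g, k_9to8 %.4g, k_8to9 %.4g /s\n",
              ch$k_10to9, ch$k_9to10, ch$k_9to8, ch$k_8to9))
  cat(sprintf("  k_intrinsic: %.4g /s\n", x$k_intrinsic))
  invisible(x)
}

#' Generator matrix of the five-state photocycle for one conformer
#'
#' Builds the 5x5 first-order rate (generator) matrix `M` such that
#' `dP/dt = M P` for the state vector `P = (3Ru, CS10, CS9, CS8, GS)`.
#' Columns sum to zero (probability is conserved; GS is absorbing) and all
#' off-diagonal entries are the non-negative elementary rate constants:
#' 3Ru -> CS10 (`k_cs`), 3Ru -> GS (`k_intrinsic`), CS10 <-> CS9, CS9 <-> CS8
#' (chain rates) and CS10 -> GS (`k_cr`).
#'
#' @param model A [photocycle_model()].
#' @param conformer_label Label of the conformer whose matrix is requested.
#' @return A 5x5 numeric matrix with dimnames
#'   `c("Ru3","CS10","CS9","CS8","GS")`.
#' @export
build_rate_matrix <- function(model, conformer_label) {
  stopifnot(inherits(model, "photocycle_model"))
  cf <- model$conformers[[conformer_label]]
  if (is.null(cf)) stop("unknown conformer label: ", conformer_label)
  ch <- model$chain
  M <- matrix(0, 5, 5, dimnames = list(.PHOTO_STATES, .PHOTO_STATES))
  # M[to, from] = rate of from -> to
  M["CS10", "Ru3"] <- cf$k_cs
  M["GS",   "Ru3"] <- model$k_intrinsic
  M["CS9", "CS10"] <- ch$k_10to9
  M["CS10", "CS9"] <- ch$k_9to10
  M["CS8",  "CS9"] <- ch$k_9to8
  M["CS9",  "CS8"] <- ch$k_8to9
  M["GS",  "CS10"] <- cf$k_cr
  diag(M) <- -colSums(M)
  M
}

# matrix exponential by scaling-and-squaring with a (6,6) Pade approximant;
# used as a fallback when the eigenbasis is ill-conditioned (near-degenerate
# eigenvalues)
.expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  j <- max(0L, as.integer(ceiling(log2(max(nrmA, .Machine$double.xmin)))) + 1L)
  As <- A / 2^j
  # Pade (6,6)
  c_ <- 1
  X <- diag(n)
  N <- diag(n); D <- diag(n)
  q <- 6
  for (k in 1:q) {
    c_ <- c_ * (q - k + 1) / (k * (2 * q - k + 1))
    X <- As %*% X
    N <- N + c_ * X
    D <- D + (-1)^k * c_ * X
  }
  E <- solve(D, N)
  for (k in seq_len(j)) E <- E %*% E
  E
}

# solve dP/dt = M P with P(0) = p0 on the given times; returns length(times) x n
.solve_linear_kinetics <- function(M, p0, times) {
  eg <- eigen(M)
  V <- eg$vectors
  usable <- FALSE
  if (all(abs(Im(eg$values)) < 1e-8 * max(abs(eg$values), 1))) {
    V <- Re(V); lam <- Re(eg$values)
    if (kappa(V, exact = FALSE) < 1e10) {
      coef <- tryCatch(solve(V, p0), error = function(e) NULL)
      if (!is.null(coef)) {
        P <- t(V %*% (coef * exp(outer(lam, times))))
        usable <- TRUE
      }
    }
  }
  if (!usable) {
    # fall back to scaled-and-squared matrix exponentials (propagate between
    # successive time points to keep the scaling cheap)
    P <- matrix(0, length(times), nrow(M))
    p <- p0
    tprev <- 0
    for (i in seq_along(times)) {
      dt <- times[i] - tprev
      if (dt > 0) p <- .expm_pade(M * dt) %*% p
      P[i, ] <- p
      tprev <- times[i]
    }
  }
  colnames(P) <- rownames(M)
  P
}

#' Simulate photocycle state populations
#'
#' Solves the linear first-order kinetic network for every conformer by
#' eigen-decomposition of its generator matrix (matrix-exponential fallback
#' for ill-conditioned eigenbases). Excitation is instantaneous at t = 0:
#' the initial condition puts each conformer's weight entirely in its 3Ru
#' state.
#'
#' @param model A [photocycle_model()].
#' @param times Numeric vector of times (s), non-negative and strictly
#'   increasing.
#' @param initial_state State holding each conformer's weight at t = 0
#'   (default `"Ru3"`, i.e. photoexcitation; other states are useful for
#'   studying the chain in isolation).
#' @return A `population_trace`: list with `times`, `states`, `conformers`
#'   and `pops`, a `length(times) x 5 x n_conformer` array of populations
#'   (fractions of the total excited population).
#' @export
simulate_populations <- function(model, times, initial_state = "Ru3") {
  stopifnot(inherits(model, "photocycle_model"))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  initial_state <- match.arg(initial_state, .PHOTO_STATES)
  labels <- names(model$conformers)
  pops <- array(0, dim = c(length(times), 5L, length(labels)),
                dimnames = list(NULL, .PHOTO_STATES, labels))
  for (lab in labels) {
    M <- build_rate_matrix(model, lab)
    p0 <- numeric(5)
    p0[match(initial_state, .PHOTO_STATES)] <- model$conformers[[lab]]$weight
    pops[, , lab] <- .solve_linear_kinetics(M, p0, times)
  }
  # clip tiny numerical negatives
  pops[pops < 0 & pops > -1e-12] <- 0
  structure(list(times = times, states = .PHOTO_STATES, conformers = labels,
                 pops = pops, heme8_ligation = model$heme8_ligation),
            class = "population_trace")
}

#' @export
as.data.frame.population_trace <- function(x, ...) {
  d <- expand.grid(time_s = x$times, species = x$states,
                   conformer = x$conformers, stringsAsFactors = FALSE)
  d$population <- as.vector(x$pops)
  d
}

#' Project state populations onto experimental observables
#'
#' Sums the per-conformer state populations into the quantities quantified
#' spectroscopically: total 3Ru, total charge-separated population
#' (CS10 + CS9 + CS8 over conformers), recovered ground state, per-heme
#' Fe(II) populations, and the His/His versus His/Met Fe(II) split. By the
#' experimental convention, curves are normalized so that the 3Ru population
#' at the first time point equals 1 (the earliest probe delay defines 100%
#' excitation).
#'
#' @param trace A `population_trace` from [simulate_populations()].
#' @param heme8_ligation Ligation of Heme 8 (defaults to the value carried by
#'   the trace): when `"His/Met"`, `CS8` counts as His/Met Fe(II), otherwise
#'   all Fe(II) heme is His/His.
#' @param normalize Normalize so 3Ru at the first time = 1 (default TRUE).
#' @return An `observables` object: data frame with columns `time_s`, `ru3`,
#'   `cs_total`, `gs`, `fe2_heme10`, `fe2_heme9`, `fe2_heme8`, `fe2_hishis`,
#'   `fe2_hismet`.
#' @export
project_observables <- function(trace, heme8_ligation = NULL,
                                normalize = TRUE) {
  stopifnot(inherits(trace, "population_trace"))
  if (is.null(heme8_ligation)) heme8_ligation <- trace$heme8_ligation
  heme8_ligation <- match.arg(heme8_ligation, c("His/His", "His/Met"))
  tot <- function(state) rowSums(trace$pops[, state, , drop = FALSE])
  ru3 <- tot("Ru3"); cs10 <- tot("CS10"); cs9 <- tot("CS9")
  cs8 <- tot("CS8"); gs <- tot("GS")
  obs <- data.frame(
    time_s = trace$times,
    ru3 = ru3,
    cs_total = cs10 + cs9 + cs8,
    gs = gs,
    fe2_heme10 = cs10,
    fe2_heme9 = cs9,
    fe2_heme8 = cs8,
    fe2_hishis = if (heme8_ligation == "His/Met") cs10 + cs9 else
      cs10 + cs9 + cs8,
    fe2_hismet = if (heme8_ligation == "His/Met") cs8 else 0 * cs8
  )
  if (normalize) {
    scale <- obs$ru3[1]
    if (scale <= 0) stop("cannot normalize: 3Ru population at first time is 0")
    num <- setdiff(names(obs), "time_s")
    obs[num] <- obs[num] / scale
  }
  structure(obs, class = c("observables", "data.frame"),
            heme8_ligation = heme8_ligation)
}

#' Write populations or observables as tidy CSV
#'
#' @param x A `population_trace` or `observables` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_populations_csv <- function(x, path) {
  if (inherits(x, "population_trace")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "observables")) {
    d <- as.data.frame(x)
    long <- data.frame(
      time_s = rep(d$time_s, ncol(d) - 1L),
      species = rep(setdiff(names(d), "time_s"), each = nrow(d)),
      conformer = "all",
      population = unlist(d[setdiff(names(d), "time_s")], use.names = FALSE)
    )
    utils::write.csv(long, path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

#' Serialize / restore a photocycle model as JSON
#'
#' Rates are stored in s^-1.
#'
#' @param model A [photocycle_model()].
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `photocycle_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "photocycle_model"))
  x <- list(
    conformers = lapply(model$conformers, function(cf)
      list(label = cf$label, weight = cf$weight, k_cs = cf$k_cs,
           k_cr = cf$k_cr)),
    chain = unclass(model$chain),
    k_intrinsic = model$k_intrinsic,
    heme8_ligation = model$heme8_ligation
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- lapply(x$conformers, function(cf)
    conformer_params(cf$label, cf$weight, cf$k_cs, cf$k_cr))
  photocycle_model(
    conformers = unname(conf),
    chain = chain_rates(x$chain$k_10to9, x$chain$k_9to10,
                        x$chain$k_9to8, x$chain$k_8to9),
    k_intrinsic = x$k_intrinsic,
    heme8_ligation = x$heme8_ligation
  )
}
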