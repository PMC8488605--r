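---
title: "Extracting heme-to-heme electron-transfer rates from photosensitized pump-probe data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting heme-to-heme electron-transfer rates from photosensitized pump-probe data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeET)
```

## The system and the model

hemeET analyses the photocycle of a decaheme cytochrome (MtrC of
*Shewanella oneidensis*) carrying a covalently attached
Ru(II)-tris(bipyridine) photosensitizer next to Heme 10, the terminus of its
heme chain. Two engineered variants are compared throughout: one in which
Heme 8 keeps its native His/His iron ligation, and one in which the distal
histidine is replaced by methionine, making Heme 8 a spectroscopically
distinguishable His/Met heme with a much higher reduction potential
(+199 mV vs SHE).

Photoexcitation creates the triplet dye state `3Ru`, which injects an
electron into Heme 10 (charge separation, rate $k_{CS}$). The electron then
hops reversibly along the chain while charge recombination from Heme 10 to
the oxidized dye (rate $k_{CR}$) competes:

$$
{}^3\mathrm{Ru} \xrightarrow{k_{CS}} \mathrm{CS}_{10}
\underset{k_{10,9}}{\overset{k_{9,10}}{\rightleftharpoons}} \mathrm{CS}_9
\underset{k_{9,8}}{\overset{k_{8,9}}{\rightleftharpoons}} \mathrm{CS}_8,
\qquad \mathrm{CS}_{10} \xrightarrow{k_{CR}} \mathrm{GS}
$$

where $\mathrm{CS}_i$ is the charge-separated state with the electron on
Heme $i$ and `GS` the recovered ground state. In the field's convention
$k_{i-1,i}$ is the rate for Heme $i \to$ Heme $i-1$ ET; the package names
these by direction (`k_10to9` = $k_{9,10}$, etc.). The surface-attached dye
populates three long-lived conformers $x = a, b, c$ with distinct
$k_{CS,x}$ and $k_{CR,x}$; the heme-chain rates are common to all
conformers, because heme-heme coupling is a short-range property of the
protein interior that the dye position cannot perturb.

Each conformer's five-state network is a linear first-order system
$\dot{P} = M P$, solved by eigen-decomposition of the generator matrix
(`build_rate_matrix()`, `simulate_populations()`), with a
scaled-and-squared Pade matrix exponential as fallback when the eigenbasis
is ill-conditioned. Excitation is treated as a delta function at $t = 0$;
the experimental convention defines the `3Ru` population at the earliest
probe delay (5 ps) as 100%, and `project_observables()` applies the same
normalization.

### Key modeling assumptions

* **Recombination only from CS10.** The dye sits ~5 A from the Heme 10
  edge versus 14 and 18 A from Hemes 9 and 8; with an exponential distance
  attenuation of $\beta = 1.39\,\mathrm{\AA}^{-1}$, recombination from the
  farther hemes is $10^5$-$10^7$ slower and is omitted
  (`injection_ratio()`).
* **No intermolecular ET.** The proteins are treated as isolated monomers.
* **Intrinsic triplet decay** ($2 \times 10^6$ s$^{-1}$ for the free dye)
  is available as a configurable `3Ru -> GS` channel but defaults to 0 in
  fitting, since charge separation dominates in the labelled proteins.

## Synthetic data: what it emulates and what it does not

`simulate_transient_cube()` renders difference-absorbance cubes
$\Delta A(\lambda, t)$ as population-weighted sums of per-species Gaussian
band sets (`default_basis()`): the 370 nm triplet band, the negative
ground-state dye bleach across the 400-500 nm trough, and bisignate Soret
plus 552/522 nm Q-band difference spectra for His/His and His/Met
ferroheme. The His/Met positive Soret lobe is broader and red-shifted than
the His/His lobe - the property that lets the Soret half-height width
report the fraction of reduced Heme 8. Band centers, widths and amplitudes
are free constants chosen only to satisfy these qualitative orderings (no
published band-shape parameters exist); the defaults
(His/His positive lobe 421/12 nm, His/Met 426/22 nm) additionally make the
width-versus-composition curve strictly monotone, which the inversion
requires and the tests verify. Noise is additive i.i.d. Gaussian with
explicit seeds everywhere.

Not simulated: instrument response and chirp, scattering backgrounds, and
heme excited-state dynamics (synthetic cubes correspond to data from which
those have already been subtracted). Passing tests therefore demonstrate
correctness of the analysis chain, not robustness to those artifacts. An
optional small Ru(III) absorbance band near 475 nm reproduces a known
artifact in which the extracted population sum slightly exceeds 1 while
the charge-separated state is maximal.

Titrations are equal-weight sums of $n = 1$ Nernst curves
(slope 59.16 mV/decade at 298.15 K). The reference ("His8-like") protein
uses ten midpoints spread evenly from -50 to -275 mV - a generator
convention emulating the published low-potential envelope, not measured
values - and the His/Met variant replaces the highest with +199 mV
(`mtrc_titration_centers()`).

## Spectral quantification

`extract_populations()` mirrors the experimental procedure: `3Ru` from
$\Delta A$(370 nm) normalized to the first delay; the charge-separated
population from a single Gaussian fitted to the 552 nm Q-band over a
535-570 nm window after subtracting a straight-line baseline through the
window endpoints (center constrained to 552 +/- 5 nm; amplitude calibrated
by applying the identical procedure to the basis spectrum, assuming equal
Q-band extinction for both ligation types); ground-state recovery from the
475 nm bleach; and the His/Met Fe(II) fraction by bisection inversion (to
$10^{-6}$) of the monotone Soret width-composition curve. Single-wavelength
lookups use the nearest grid point, matching discrete probe pixels.

Before the width measurement the dye contributions (triplet band and
bleach) are unmixed out of the Soret window using the already-extracted
`3Ru` and CS populations, so the residual is the pure ferroheme difference
spectrum. On noiseless synthetic data the 3Ru/CS/GS round trip is accurate
to better than 1% wherever the signal exceeds 5% of its maximum; the
width-derived Heme 8 population carries a slightly larger (up to ~3%)
systematic at early times when the triplet is still alive, because the
unmixing then leans on two imperfect population estimates at once.

## Fitting strategy

`fit_multi_exponential()` fits $\sum_i a_i e^{-k_i t}$ with $a_i \ge 0$,
$\sum a_i = 1$ (softmax parameterization), rates in log space,
Levenberg-Marquardt least squares (minpack.lm) and seeded multistart
(default 32 starts); `select_conformer_count()` picks the smallest
component count that the Akaike criterion does not improve.

`fit_photocycle_global()` fits both proteins simultaneously under the
shared-parameter constraints (conformer weights and $k_{CS}$ common to
both proteins; chain rates common to all conformers; $k_{CR}$ free per
conformer and protein) in three stages: (1) the combined `3Ru` decays give
the shared conformer structure, with a free overall scale absorbing the
5-ps normalization; (2) per protein, chain and recombination rates are fit
to the charge-separated population (weight 2, the best signal-to-noise
curve) and, when supplied, the Heme 8 Fe(II) reporter curve; (3) a joint
polish refines everything. Rates are bounded to $[10^3, 10^{13}]$ s$^{-1}$
in log space. The chain-rate likelihood has extremely shallow valleys, so
the stage-2/3 optimizers run with generous iteration budgets (up to 1024
LM iterations); on noiseless data this drills to the exact generating
parameters for the His/Met variant.

### Identifiability: what these data can and cannot determine

The total charge-separated population is invariant to internal hopping -
electrons moving between $\mathrm{CS}_{10}$, $\mathrm{CS}_9$ and
$\mathrm{CS}_8$ leave $\mathrm{CS}_{total}$ unchanged - so individual
chain rates enter the `3Ru`/CS objective only through ratio and product
combinations (the branch ratio $k_{10,9}/k_{8,9}$ via the plateau level,
and the product $k_{9,8} \, k_{10,9}/k_{8,9}$ via the slow tail). Adding
the His/Met reporter curve bounds $k_{8,9}$ from below (the Heme 8 rise)
and is included in the default objective for exactly this reason; the
all-His/His protein has no reporter, and its chain rates beyond $k_{9,10}$
lie on an exactly degenerate manifold - observationally equivalent rate
sets reproduce its curves to machine precision.

A Fisher-information analysis at the generating parameters (2% additive
noise, 80-point log grid) quantifies this: the standard error of
$\ln k_{8,9}$ for the His/Met variant is about 6 - a one-sigma factor of
~400 - while the recombination rates are tight (a few percent). The
consequence, demonstrated by the package's own simulations, is that
single-experiment estimates of $k_{8,9}$ scatter over decades even though
every fit reproduces the data with $R^2 > 0.99$, and the 20-seed median
of the recovery experiment is itself unstable between seed sets. Noiseless
self-consistency (asserted in the unit tests) shows the estimator and
model are correct; the information is simply not in noisy
population curves of this kind. Users who need $k_{8,9}$ should treat the
fitted value as order-of-magnitude and consider constraining the
$k_{8,9}/k_{9,8}$ ratio thermodynamically from independently measured
midpoint potentials.

## ET-theory post-analysis

Driving forces come from detailed balance,
$\Delta G = -k_B T \ln(k_f/k_b)$ at 298.15 K
($k_B T = 0.025693$ eV), rounded to 0.01 eV before use - the rounding
convention that reproduces the published optimized-rate endpoints.
Measured exergonic-direction rates are converted to free-energy-optimized
(activationless) rates with the Hopfield one-mode term
$10^{3.1 (\Delta G + \lambda)^2 / \lambda}$, using computed reorganization
energies of 0.70 eV (Heme 10/9 pair) and 0.73 eV (Heme 9/8 pair). The
nonadiabatic Marcus expression, exponential distance scaling, and the
empirical Moser-Dutton (edge-to-edge; $\log_{10} k = 15 - 0.6 d$) and
Winkler-Gray (metal-to-metal) rulers are provided with all constants
configurable - the rulers are reference lines from the literature, not
results of this package.

## Geometry

`read_structure()` (bio3d) parses PDB files, ignores hydrogens, and
resolves alternate locations by occupancy. A heme macrocycle is the
explicit atom whitelist FE, NA-ND, C1A-C4D, CHA-CHD (propionates and
thioether substituents excluded); edge-to-edge distance is the minimum
pairwise distance between two macrocycle atom sets, and motifs are
classified as stacked (interplanar angle < 35 deg and edge distance
< 4.5 A) or T-shaped (angle > 55 deg), thresholds configurable. Heme
numbering is mapped from residue numbers per structure. Because deposited
structures cannot be fetched in an offline analysis,
`write_synthetic_decaheme_pdb()` builds a clearly-labelled synthetic
decaheme arrangement encoding the reference geometry (stacked pairs at
3.7 and 4.3 A, Fe-S(Met) at 2.3 A) so the measurement code is exercised
end to end.

## Numerical choices and degenerate inputs

* Eigen-decomposition is used when all eigenvalues are real and the
  eigenbasis has condition number < 1e10; otherwise the Pade
  matrix-exponential fallback propagates between time points.
* Tiny negative populations from roundoff (> -1e-12) are clipped to 0.
* Q-band fits that fail at a time point return `NA` for that point rather
  than aborting the series.
* Widths outside the pure-composition endpoints are clipped to 0 or 1 with
  a warning; a basis whose width-composition curve is not strictly
  monotone is rejected.
* A constant decay trace selects one component by definition; difference
  titration curves whose amplitude never exceeds the noise floor return
  "no distinct center" rather than a fit.
* The high-potential-center fit restricts itself to potentials where the
  reference protein is essentially oxidized and the difference wave is
  above its noise floor, and includes a small constant baseline - this
  absorbs the tail bias introduced by clipping measured fractions
  to [0, 1].

## Problem sizes

The test suite and the acceptance script use 20 random seeds for each
stochastic recovery experiment (photoluminescence, global kinetics,
titration), 80-120 point log-spaced time grids from 5 ps, 0.5-1 nm
wavelength grids, 12-20 random rate sets for the ODE-oracle
cross-validation against deSolve, and a 0.01-step composition sweep for
the width monotonicity property. These sizes were chosen so the full
suite characterizes every stage in a few minutes while keeping Monte-Carlo
errors well below the tolerances being asserted.

## Known limitations

* Only the three-heme terminal segment of the ten-heme chain is modeled;
  chain length is configurable in principle but untested beyond three.
* No instrument-response convolution; do not fit dynamics faster than a
  few picoseconds with this model.
* The global fit reports point estimates; no bootstrap/MCMC uncertainties.
* Band-shape defaults are qualitative stand-ins, not fitted instrument
  parameters.
* As discussed above, several chain rates are only weakly identifiable
  from realistic data; their fitted values should be interpreted through
  the identifiable combinations.
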