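# hemeET

Heme-to-heme electron-transfer (ET) kinetics in photosensitized multiheme
cytochromes: forward simulation, spectral quantification, global kinetic
fitting, and ET-theory post-analysis.

## The problem

Multiheme cytochromes such as MtrC of *Shewanella oneidensis* carry chains
of close-packed *c*-type hemes that wire electrons across the bacterial
cell envelope. Labeling the protein with a Ru(II)-tris(bipyridine)
photosensitizer next to Heme 10 and replacing one axial histidine of
Heme 8 with methionine creates a spectroscopically unique His/Met heme
that *reports* electron arrival two hemes away, letting pump-probe
spectroscopy resolve individual nanosecond heme-to-heme hopping rates.
hemeET implements the full analysis pipeline for that class of
experiment, for spectroscopists and modelers who want to simulate,
re-analyze, or design such measurements:

1. **Photocycle kinetics** — per-conformer five-state linear network
   (3Ru → CS10 ⇌ CS9 ⇌ CS8, recombination CS10 → GS), solved by
   eigen-decomposition:

   `3Ru --k_CS--> CS10 <--k_9,10/k_10,9--> CS9 <--k_8,9/k_9,8--> CS8`,
   with `CS10 --k_CR--> GS`,

   where `k_(i-1),i` is the Heme *i* → Heme *i−1* ET rate constant.
2. **Synthetic data** — seeded transient-absorbance cubes ΔA(λ, t)
   rendered from Gaussian species difference spectra, photoluminescence
   decays, and multi-center Nernstian titrations.
3. **Spectral quantification** — 3Ru at 370 nm, charge-separated
   population from a Gaussian fit to the 552 nm Q-band, ground-state
   recovery from the 475 nm dye bleach, and the His/Met Fe(II) fraction
   from the Soret positive-lobe half-height width.
4. **Fitting** — constrained multi-exponential decays with AIC component
   selection, and staged global fitting of both protein variants under
   shared-parameter constraints.
5. **ET theory** — detailed-balance driving forces
   (ΔG = −k_B·T·ln(k_f/k_b)), Hopfield free-energy-optimized rates
   (k_max = k_obs · 10^(3.1(ΔG+λ)²/λ)), the nonadiabatic Marcus equation,
   exponential distance scaling (β = 1.39 Å⁻¹), and the Moser–Dutton /
   Winkler–Gray distance rulers.
6. **Structure geometry** — heme macrocycle extraction from PDB files
   (bio3d), closest edge-to-edge distances, Fe–ligand distances, and
   stacked / T-shaped motif classification.

## Worked example

Convert the measured chain rates of the two protein variants into
free-energy-optimized ("activationless") rates for the stacked heme pairs:

```r
library(hemeET)
km <- mtrc_stacked_kmax()
km$k_max_1e9 <- round(km$k_max / 1e9, 1)
km[, c("protein", "pair", "k_f", "k_b", "lambda", "delta_g_eV",
       "opt_factor", "k_max_1e9")]
#>   protein   pair      k_f      k_b lambda delta_g_eV opt_factor k_max_1e9
#> 1    met8 10<->9 7.60e+07 6.60e+07   0.70       0.00     147.91      11.2
#> 2    met8  9<->8 1.11e+10 3.30e+06   0.73      -0.21      14.07     156.2
#> 3    his8 10<->9 2.19e+08 1.40e+07   0.70      -0.07      57.24      12.5
#> 4    his8  9<->8 1.05e+08 1.56e+09   0.73      -0.07      70.76     110.4
```

Each row takes the exergonic direction of one reversible heme pair,
computes its driving force from the forward/backward rate ratio at 298 K
(rounded to 0.01 eV), and removes the activation penalty with the Hopfield
term. The optimized rates span 11–156 ×10⁹ s⁻¹ — among the fastest
ground-state ET known in biology, even though the thermally activated
rates are orders of magnitude slower.

Recover the His/Met heme's midpoint potential from two noisy synthetic
titrations (the variant has one +199 mV center that the reference lacks):

```r
E <- seq(-420, 420, by = 10)
met8 <- simulate_titration(mtrc_titration_centers("met8"), E, noise_model(0.01, seed = 7))
his8 <- simulate_titration(mtrc_titration_centers("his8"), E, noise_model(0.01, seed = 8))
fit_high_potential_center(met8, his8)[c("found", "E_m", "scale")]
#> $found
#> [1] TRUE
#> $E_m
#> [1] 193.0026
#> $scale
#> [1] 0.09118641
```

The difference curve is fitted with a single scaled n = 1 Nernst wave: one
distinct high-potential center carrying ~1/10 of the optical amplitude,
with E_m within a few mV of the generating +199 mV at 1% noise.

`run_pipeline(demo_config())` runs every stage (simulate → extract → fit →
rulers → titration → geometry) from one seeded configuration and writes
CSV/JSON artifacts plus a run-information file with the config hash.

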