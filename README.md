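# hdospec

Solute-affected water analysis from FTIR spectra of HDO solutions.

When a solute dissolves in water it reorganises the hydrogen bonds of the
water around it. The decoupled OD stretch of dilute HDO in H2O reports that
reorganisation directly: stronger hydrogen bonds absorb at lower
wavenumber. `hdospec` is for spectroscopists and physical chemists who use
this probe to characterise hydration shells — of peptides, osmolytes,
cosolvents — and who need the full analysis chain from raw spectra to
hydration numbers and O···O distance distributions.

## What it computes

**Affected water and the affected number.** Water in solution is modelled
as bulk plus solute-affected populations. At molality *m*, the affected
spectrum follows from the two-state difference relation

    eps_a = (eps − eps_b) / (N·M·m) + eps_b

where *N* (the affected number) counts moles of water perturbed per mole of
solute and *M* is the solvent's mean molar mass. `affected_water()` fits a
molality series: per-wavenumber regression of eps against *m* gives the
slope spectrum, and *N* is fixed by the bulk-free criterion — the smallest
*N* keeping eps_a non-negative, estimated where the affected spectrum
vanishes on the blue flank of the OD band (there, slope = −N·M·eps_b).

**Ternary systems.** For two solutes A and B, the independent-solute
prediction is eps_theor = (N_A·eps_A + N_B·eps_B)/(N_A + N_B), and
ΔN = N_exp − N_theor diagnoses hydration-shell contact: negative = shared
(overlapping) waters, positive = extra perturbed or bridging waters.
`decompose_ternary()` splits an experimental ternary affected spectrum into
pure-A, pure-B and "changed-affected" shares by maximising removal of the
pure components subject to the residual staying a valid non-negative
spectrum (seeded stochastic search: random restarts + Nelder–Mead).

**O···O distances.** Band contours convert to distance distributions
through the empirical correlation nu = 2727 − exp(16.01 − 3.73·R) and the
change of variables P(R) = C·eps(nu(R))·(dnu/dR). Hydration-cluster
geometries (XYZ/PDB) are reduced to first-shell O···O distance lists and
normalized interaction curves for side-by-side comparison.

**ATR screen.** The concentration-difference protocol (vapor subtraction,
water-background subtraction with coefficient c_water/55.33, molar
spectra, averaged difference spectra) screens for direct solute–solute
interaction bands.

## Worked example

Synthetic data stand in for the (undeposited) experimental spectra; every
generator inverts one analysis stage, so ground truth is known.

```r
library(hdospec)

## binary system: recover the affected number from a noisy molality series
bulk     <- preset_band("bulk")              # OD band of bulk HDO
affected <- preset_band("binary_fixture")    # redshifted affected band
series <- make_binary_series(bulk, affected, N = 6, noise_sd = 0.005,
                             noise_type = "multiplicative", seed = 1)
fit <- affected_water(series, bulk)
fit
#> Affected-water fit (two-state HDO difference model)
#>   N = 5.7391 (estimated, bulk-free criterion)
#>   M = 0.0180849 kg/mol;  molalities: 0.1, 0.2, 0.3, 0.4, 0.5 mol/kg
```

The true N is 6; the estimate lands within 5% at this noise level (0.5%
multiplicative), and is exact for noiseless input.

```r
## ternary system: two pure shares plus an injected changed component
eA <- preset_band("diglycine"); eB <- preset_band("dmso")
eC <- preset_band("changed")
mix <- linear_combination(list(eA, eB, eC), c(2, 3, 2) / 7)
dec <- decompose_ternary(mix, N_exp = 7, eA, eB, N_theor = 5, seed = 42)
dec
#> Ternary affected-spectrum decomposition
#>   N_A = 2.06, N_B = 2.95, N_changed = 1.99 (N_exp = 7)
#> delta_N = 2 (excess_perturbation)
```

The decomposition recovers the constructed shares (2, 3, 2) and classifies
the system as excess perturbation (ΔN = +2: about two extra water molecules
perturbed per solute pair).

```r
## band contour to O...O distances
pd <- distance_distribution(bulk)
pd
#> <oo_distribution> 2001 points on [2.612011, 3.408623] Angstrom
#>   most probable R_OO: 2.82513   mean R_OO: 2.84779
```

A bulk-water OD band peaking at 2509 cm⁻¹ maps to a most probable O···O
distance of 2.825 Å — note the distribution maximum is *not* the direct
image of the band maximum (2.849 Å): the Jacobian of the wavenumber–distance
correlation shifts broad bands toward shorter distances.

A command-line front end (`inst/cli/hdo.R`) exposes the same pipeline as
`synth`, `affected`, `ternary`, `atr-diff`, `band`, `roo` and `shell`
subcommands with `--seed`, `--config` (YAML/JSON manifest) and `--out-dir`.

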