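---
title: "Monte Carlo finger PPG across skin pigmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo finger PPG across skin pigmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerppg)
```

## The question the simulation answers

Photoplethysmography (PPG) infers blood-volume pulsations from light
transmitted through, or reflected from, perfused tissue. Epidermal melanin
absorbs strongly at the red wavelength used by pulse oximeters (660 nm) and
much less in the near infrared (940 nm), so skin pigmentation is a suspected
confounder of PPG-derived measurements. `fingerppg` simulates photon
transport through a layered model of a human finger at three epidermal
melanosome volume fractions — light (2.55%), moderate (15.5%) and dark
(30.5%) skin on the Fitzpatrick scale (type III is not represented) — in
both PPG sensor geometries, and derives the signal statistics that quantify
the pigmentation effect: AC and DC components, their ratio, detected-photon
counts and convergence, per-layer absorbance, mean optical pathlength,
penetration depth and propagation profiles.

The simulation is entirely synthetic: all inputs are model parameters
(geometry, chromophore compositions and literature optical coefficients
exposed by `tissue_properties()`), and the scenario generator
(`scenario()`, `build_grid()`) *is* the data-generating process. Its
defaults are the study conditions; they are not adjusted per analysis.

## The finger model

`build_finger()` assembles a 13.0 mm slab stack along the depth axis z:
six skin sublayers (0.95 mm), fat (0.5 mm), muscle (10.1 mm) with an
embedded bone cylinder, fat (0.5 mm) and the mirrored skin stack. The bone
cylinder runs along the finger length at the mid-depth of the muscle slab
with a 2.5 mm default radius; the illustration the geometry follows shows
the bone but does not dimension it, so the radius is a configurable
reconstruction. The slab is laterally unbounded; photons wandering more
than 20 mm (configurable) from the source axis are terminated as
explicitly-tallied lost weight, which bounds runtime without biasing the
detector-scale statistics.

Skin sublayer composition (thickness mm / diastolic blood fraction / water
fraction): stratum corneum 0.02/0/0.05, epidermis 0.08/0/0.65, papillary
dermis 0.15/0.04/0.65, upper blood net 0.08/0.30/0.65, reticular dermis
0.40/0.04/0.65, deep blood net 0.22/0.10/0.65. These fractions are a
reconstruction of the usual six-layer skin model (the source design cites
them only indirectly); they live in one editable table
(`skin_sublayers()`), and the stratum corneum choice is corroborated
independently: with it, the largest uniform deviate whose first sampled
step crosses the stratum corneum is `exp(-mu_t * 0.02)` = 0.599 at 660 nm
and 0.730 at 940 nm, matching the published first-step gate to three
decimals.

### Optical properties

Absorption is built per region from chromophore volume fractions:

* **Melanin** follows the power law $\mu_a = 6.6\times10^{10}
  \lambda^{-3.33}$ mm$^{-1}$ (26.94 at 660 nm, 8.299 at 940 nm).
* **Epidermis**: $\mu_{a} = v_{mel}\,\mu_{a,mel} + v_W\,\mu_{a,W} +
  (1-v_{mel}-v_W)\,\mu_{a,base}$, the standard additive chromophore sum,
  with baseline $\mu_{a,base} = (0.244 + 85.3\,e^{-(\lambda-154)/66.2})/10$
  mm$^{-1}$ (the classic bloodless-skin baseline, tabulated in cm$^{-1}$
  and converted). A multiplicative grouping of the same factors cannot
  reproduce the published six-cell epidermal table; the additive sum
  reproduces all six cells to within 1% for moderate/dark skin and ~4% for
  light skin, where the unprinted non-melanin terms dominate.
* **Dermal sublayers**: the nested mixture $\mu_a = v_b\,\mu_{a,blood} +
  (1-v_b)\left[v_W \mu_{a,W} + (1-v_W)\mu_{a,base}\right]$, with
  $v_b$ the diastolic blood fraction, doubled during systole (the
  pulsatility protocol). Blood claims its volume first and the remainder
  is watery tissue; a flat sum $v_b \mu_{a,blood} + v_W \mu_{a,W} + \ldots$
  would make the doubled upper blood net (2×0.30 blood + 0.65 water)
  an invalid mixture, so the nested form is the only self-consistent
  reading of the stated fractions. Blood is fully oxygenated
  (SpO$_2$ = 1) by assumption.
* **Scattering**: the skin columns of the literature table (25.62/15.68
  mm$^{-1}$, g = 0.91/0.94 at 660/940 nm) apply to all six sublayers and
  both phases; only absorption is phase- and pigmentation-dependent. Fat,
  muscle and bone use their tabulated values.
* **Refractive index**: n = 1.4 for every tissue region, 1.0 outside. The
  source design lists no indices; index-matched interior boundaries (no
  internal Fresnel events) are the simplest contract consistent with its
  algorithm flow chart. Only the two outer surfaces reflect
  (unpolarised Fresnel; specular loss $((1-1.4)/(1+1.4))^2 \approx 2.78\%$
  deducted at launch).

## The transport engine

The engine (`run_transport()`, C++ under the hood) is the classic weighted
hop–drop–spin random walk:

1. **Launch**: orthogonal incidence at z = 0, lateral offset from a 2-D
   Gaussian of σ = 0.25 mm (a "Gaussian beam" is specified upstream, its
   width is not; 0.25 mm is a typical PPG LED half-width).
2. **Hop**: optical depth $-\ln \xi$ consumed piecewise through regions;
   steps truncate at slab planes and at the bone cylinder; the remaining
   depth is rescaled by the next region's $\mu_t$.
3. **Drop** (implicit capture): at each interaction the packet deposits
   $w\,\mu_a/\mu_t$ in the current region and keeps the rest.
4. **Spin**: deflection cosine sampled from the Henyey–Greenstein inverse
   CDF; azimuth uniform.
5. **Boundary**: unpolarised Fresnel at the outer surfaces, total internal
   reflection beyond the critical angle, Snell refraction on exit.
6. **Roulette**: packets below weight $10^{-4}$ survive with probability
   1/10 (weight ×10) or terminate. Implicit capture plus roulette — rather
   than analogue absorption — is what makes $10^{-5}$-scale transmittance
   intensities estimable at desk-scale photon budgets.

Detection accepts any exit angle within a 0.5 mm-radius disc: opposite the
source (transmittance) or offset `sds` along +x on the entry surface
(reflectance). Detector dimensions are another undimensioned reconstruction
(typical photodiode scale).

Weight bookkeeping is exact, not just in expectation: specular + absorbed +
detected + escaped-undetected + lateral loss + roulette net equals the
launched weight to within 10$^{-6}$ relative on every run (the roulette
tally records kills minus survivor boosts, so the ledger closes exactly).
Every photon draws from its own xoshiro256++ stream seeded from (run seed,
photon index), making runs bit-reproducible independent of batching.

## PPG statistics

A scenario pair runs systole and diastole **with the same seed** (common
random numbers). AC = $I_d - I_s$ is a difference of two nearly equal
intensities; with independent seeds its Monte Carlo error at desk-scale
budgets would exceed the signal, while paired launches cancel most of the
shared variance. `ac_dc()`, `convergence()` (Q = $1/\sqrt{N}$, pass at
N ≥ 10$^6$ detected packets, i.e. Q ≤ 0.001), `relative_absorbance()`
(detected photons only), `path_stats()` (means of total pathlength and of
maximum depth over detected photons), `percent_difference()` (symmetric,
mean-based denominator — no skin type is privileged as reference) and
`profile_histogram()` (200-bin occupancy grids of detected-photon
interaction vertices) reproduce the study's derived quantities.
`build_grid()`/`run_grid()` enumerate and execute the full 36-pair design
with disjoint pair seeds and a reproducibility manifest.

One definitional consequence of the weighted scheme deserves emphasis: the
**number of detected photons** is the detected *weight* (each packet
stands for $w$ photons), while the raw packet count only drives the
convergence diagnostic. Packet counts barely respond to epidermal
absorption at 940 nm — absorption there lowers weights, not trajectories —
so all relative-detection percentages in `relative_count_table()` and in
the acceptance outputs are intensity-based.

## Numerical choices

Geometric boundary crossings use a 10$^{-9}$ mm nudge past interfaces;
direction vectors are renormalised after every rotation; Henyey–Greenstein
cosines are clamped to $[-1, 1]$; the $|u_z| \to 1$ polar special case has
its own rotation branch. Degenerate inputs are contracts, not surprises:
zero launched photons give empty tallies, a zero systolic intensity marks
the AC/DC ratio undefined (non-converged) instead of dividing by zero, and
a pure absorber terminates packets at first interaction with the ledger
intact.

## Problem sizes

The default scenario budget is 10$^6$ launched photons (about one minute
per transmittance run on a laptop core), with the full-study 10$^7$ a
single argument away. The test suite runs its study-scale checks at 10$^6$
photons per run and its property checks at 10$^4$–10$^5$; the
reproduction script uses 4×10$^6$ photons per run for the
transmittance detection ratio (a heavy-tailed weight statistic whose
standard error at 10$^6$ is ±6 points) and 10$^6$ per run elsewhere.

## What the generator does and does not emulate

The generator reproduces the *design* of the study — its geometry grid,
pigmentation presets, pulsatility protocol and photon budgets — not real
fingers. Real tissue adds curved surfaces, refractive-index mismatches
between layers, heterogeneous melanin distribution, non-arterial
pulsatility, motion and sensor coupling, none of which are modelled (nor
were they upstream). Passing tests therefore demonstrate internal
correctness of the transport and statistics, and agreement with the
published deterministic anchors; they do not validate the model against
measured PPG data.

## Known limitations and open reconstructions

* Sublayer blood/water fractions, detector aperture, beam width and bone
  dimensions are unprinted upstream; they are fixed, documented defaults
  here. Absolute detected counts depend on them strongly; relative and
  trend statistics much less so.
* The AC/DC ratio's pigmentation sensitivity measured by the paired
  estimator is of the same order as the light–dark difference in mean
  optical pathlength (~10% at 660 nm, 3 mm separation). Reported headline
  contrasts far larger than that are not reproducible from this model
  class: under Beer–Lambert cancellation the epidermal attenuation common
  to both cardiac phases divides out of AC/DC, leaving only path-selection
  effects, which the pathlength statistics bound. An unpaired
  two-run estimate of so small a difference is noise-dominated even at
  10$^7$ photons, which is the package's explanation for published
  contrasts that exceed this bound; the paired design was chosen precisely
  to make the estimate stable, and the discrepancy is reported, not
  reconciled.
* Wavelengths other than 660/940 nm would need spectral tables the model
  does not carry; Fitzpatrick type III has no melanosome preset.

## A worked pair

```{r example, eval = FALSE}
light <- run_pair("light", 660, "reflectance", sds = 3,
                  n_photons = 1e6, seed = 21)
dark <- run_pair("dark", 660, "reflectance", sds = 3,
                 n_photons = 1e6, seed = 22)
light$ratio / dark$ratio - 1
```

See the README for the printed numbers this produces and
`scripts/acceptance.R` for the full reproduction run.
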