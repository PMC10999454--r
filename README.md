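# fingerppg

Monte Carlo simulation of red (660 nm) and infrared (940 nm) photon
transport through a layered human finger, built to quantify how epidermal
melanin — the primary determinant of skin pigmentation — affects
photoplethysmography (PPG) signals in the two sensor geometries used by
pulse oximeters and wearables: transmittance (detector opposite the
source) and reflectance (detector 1–9 mm from the source on the same
surface).

It is intended for biomedical-optics researchers and sensor designers who
want a reproducible, inspectable in-silico testbed for pigmentation
effects on PPG, rather than a clinical calibration tool.

## Model

A 13.0 mm finger: six skin sublayers (0.95 mm, stratum corneum to deep
blood net), fat (0.5 mm), muscle (10.1 mm) containing a cylindrical bone,
then the mirrored fat and skin stacks. Epidermal absorption follows the
additive chromophore sum

```
mua_epi = v_mel * 6.6e10 * lambda^-3.33  +  v_W * mua_W
          + (1 - v_mel - v_W) * mua_base(lambda)
```

with melanosome volume fractions v_mel = 2.55% / 15.5% / 30.5% for light,
moderate and dark skin (Fitzpatrick I–II / IV–V / VI). Dermal sublayers
mix fully oxygenated blood with watery tissue; systole doubles their blood
volume. Photon packets undergo the classic weighted random walk — free
paths `-ln(xi)/mu_t`, implicit capture, Henyey–Greenstein scattering,
Fresnel boundaries at the outer surfaces, Russian roulette — with exact
weight bookkeeping and per-photon RNG streams (bit-reproducible for a
given seed). Paired systole/diastole runs share seeds, so the pulsatile
component `AC = I_d - I_s` and baseline `DC = I_s` are common-random-number
estimates; `Q = 1/sqrt(N)` flags convergence.

## A worked example

Reflectance PPG at 660 nm, 3 mm source–detector separation, 10^6 photons
per phase:

```r
library(fingerppg)
light <- run_pair("light", 660, "reflectance", sds = 3,
                  n_photons = 1e6, seed = 17)
light[, c("n_detected_diastole", "ac", "dc", "ratio")]
#> # A tibble: 1 x 4
#>   n_detected_diastole        ac      dc  ratio
#>                 <dbl>     <dbl>   <dbl>  <dbl>
#> 1                3050 0.0000689 0.00103 0.0670
```

3050 detected packets; the baseline (DC) intensity is about 1.0 × 10⁻³ of
the launched light, the pulsatile (AC) component about 6.9 × 10⁻⁵, and
their ratio — the quantity pulse-oximeter signal quality rides on — about
0.067. Re-running with `"dark"` skin drops DC roughly eightfold (melanin
absorbs strongly at 660 nm) while the AC/DC ratio changes far less,
because attenuation common to both cardiac phases largely cancels in the
ratio.

Other entry points: `run_scenario()` for a single configured run
(`scenario()` validates the design space), `build_grid()`/`run_grid()` for
the full 36-pair study with manifest, `relative_absorbance()`,
`path_stats()`, `profile_histogram()` and the `plot_*()`/`autoplot()`
functions for the derived statistics, and `tissue_properties()` /
`skin_presets()` / `skin_sublayers()` for every model constant.

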