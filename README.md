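# luxrep

Retinally referenced light exposure metrology and reporting for human
chronobiology, sleep research and environmental psychology.

Light acts on human physiology through five retinal photoreceptor
classes — S, M and L cones, rods, and melanopsin-expressing ipRGCs — and
conventional photometry (lux, cd/m²) collapses all of that onto a single
luminous efficiency function. Two stimuli with identical illuminance can
differ hugely in melanopsin drive (*metamers*), so experiments that use
light as an intervention need to report the **spectral power
distribution (SPD)** and the quantities derived from it per
photoreceptor class:

E<sub>α</sub> = Σ<sub>λ</sub> E(λ) · s<sub>α</sub>(λ) · Δλ

the **α-opic (ir)radiance** for each class α with unit-peak sensitivity
s<sub>α</sub>(λ), in mW/m² (irradiance input) or mW/(m²·sr) (radiance
input), together with photopic illuminance/luminance computed with
K<sub>m</sub> = 683 lm/W. `luxrep` computes these from tabulated
spectra, plus photon irradiance, age-dependent pre-receptoral filtering
corrections, visual angle, model-predicted pupil diameter, retinal
illuminance in trolands, and a blue-light-hazard risk-group-0
pre-screen — and validates full exposure records against a seven-item
minimum reporting checklist, rendering standardized reports.

The shipped spectral sensitivity tables are **synthetic stand-ins**
constructed from published analytic forms (pigment templates × an
ocular-media model); structural results are exact, absolute α-opic
values are approximate. See
`vignette("light-exposure-reporting")`.

## What's in the box

| Area | Functions |
| --- | --- |
| SPD I/O and algebra | `read_spd()`, `write_spd_tabulated()`, `spd_resample()`, `spd_scale()` |
| Weighting functions | `load_reference_functions()`, `peak_wavelength()`, `lens_corrected_weighting()` |
| Reportable quantities | `alpha_opic_panel()`, `photon_report()`, `age_sensitivity_analysis()` |
| Observer geometry | `visual_angle()`, `predicted_pupil_diameter()`, `trolands()`, `retinal_illuminance()` |
| Safety pre-screen | `blue_light_weighted_radiance()`, `rg0_screen()` |
| Reporting | `exposure_record()`, `validate_record()`, `render_report()`, manifest I/O |
| Fixtures | `planckian_spd()`, `gaussian_led_spd()`, `monochromatic_spd()`, `metamer_pair()`, `deficient_record()` |

A thin command-line interface over the same functions ships at
`inst/cli/luxrep.R` (`compute`, `validate`, `report`, `simulate`
subcommands; `validate` exits 0 only for a 7/7 record).

## A worked example

A three-primary LED stimulus (peaks 455/545/620 nm, FWHM 25/35/25 nm,
band powers 0.4/0.7/0.5 W/m²):

```r
library(luxrep)
spd <- gaussian_led_spd(list(c(455, 25, 0.4), c(545, 35, 0.7), c(620, 25, 0.5)))
alpha_opic_panel(spd)
#> <alpha_opic_panel> observer age 32 y, input spectral_irradiance
#>   s_cone_opic       279.454 mW/m^2
#>   m_cone_opic       775.383 mW/m^2
#>   l_cone_opic       860.318 mW/m^2
#>   rhodopic           602.06 mW/m^2
#>   melanopic         475.995 mW/m^2
#>   photopic          596.063 lux (photopic illuminance)
photon_report(spd)
#> <photon_report> total 4.3973e+14 photons/cm^2/s (log10 14.6432)
```

The six panel numbers are what a complete report quotes for this
stimulus: the absolute drive available to each photoreceptor class (the
1.6 W/m² of radiant power delivers ~476 mW/m² of melanopic irradiance)
plus the familiar photopic illuminance (596 lux) for orientation; the
photon report restates the stimulus in quanta for comparison with
photon-based dose–response work.

A bright surface viewed directly, screened for blue-light hazard and
expressed retinally:

```r
panel_spd <- planckian_spd(6500, 2e-5, "spectral_radiance")
rg0_screen(panel_spd, exposure_duration = 20000)
#> <safety_screen_result> rg0_pass
#>   luminance 66506.2 cd/m^2, weighted radiance 64.2598 W/(m^2 sr), duration 20000 s
retinal_illuminance(panel_spd, observer_context(45, 2, 60))
#> <retinal_illuminance> 229812 Td (luminance 66506.2 cd/m^2, pupil 2.1 mm, modelled)
```

Compliance checking of a full exposure record:

```r
rec <- deficient_record("item2")   # synthetic record missing the background SPD
validate_record(rec)
#> <compliance_report> 6 pass / 0 warn / 1 fail
#>   ...
#>   [FAIL] 2. Background SPD from the observer's point of view - no background SPD present
```

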