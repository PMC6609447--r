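---
title: "Retinally referenced light exposure: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinally referenced light exposure: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxrep)
```

## Why retinally referenced quantities

Light acts on human physiology - melatonin suppression, circadian phase
shifts, pupil size, alertness - through five retinal photoreceptor
classes: S, M and L cones, rods, and melanopsin-expressing ipRGCs.
Conventional photometry (illuminance in lux, luminance in cd/m^2)
weights light by a single luminous efficiency function dominated by the
L and M cones, so two stimuli with identical illuminance can drive
melanopsin very differently (*metamers*; see `metamer_pair()` for a
constructive demonstration). A reproducible description of a light
stimulus therefore starts from the **spectral power distribution (SPD)**
- spectral irradiance at the cornea, or spectral radiance of the emitting
surface - and derives from it one value per photoreceptor class:

\[
E_\alpha = \sum_\lambda E(\lambda)\, s_\alpha(\lambda)\, \Delta\lambda ,
\]

the **alpha-opic (ir)radiance** for photoreceptor class \(\alpha\) with
unit-peak spectral sensitivity \(s_\alpha(\lambda)\), reported in
mW/m^2 (irradiance input) or mW/(m^2 sr) (radiance input), alongside the
photopic quantity \(K_m \sum E(\lambda) V(\lambda) \Delta\lambda\) with
\(K_m = 683\) lm/W. `alpha_opic_panel()` assembles all six numbers.

The package operationalizes a seven-item minimum reporting checklist for
light-exposure experiments - stimulus SPD, background SPD, tabulated
spectra, the alpha-opic panel, timing, spatial properties, and
measurement conditions - as an executable validator
(`validate_record()`) plus a report renderer (`render_report()`).

## The spectral data model

An SPD is a strictly increasing wavelength grid plus per-nm values, with
an explicit quantity kind that propagates into every derived unit.
Tabulated exchange follows the reporting convention: uncompressed
delimited ASCII, 380-780 nm at 1-10 nm spacing, `#`-prefixed key:value
headers (`read_spd()` / `write_spd_tabulated()`).

Numerical choices:

* **Interpolation is piecewise linear**, never spline: tabulated data
  carry no sub-sample information, linear interpolation is the
  convention for tabulated spectral data, and it makes oracle testing
  exact.
* **No extrapolation.** Wavelengths outside the measured support are
  zero-filled with a warning. Extrapolating a spectrum into the short
  wavelengths would silently manufacture melanopic and hazard signal.
* **Negative values** (instrument noise around zero) are retained and
  flagged; they are clipped only on explicit request, because the
  exported table should show what the instrument measured.
* **Export precision** is up to 17 significant digits (`%.17g`), so
  write -> read -> write is byte-stable and values survive a round trip
  bit-exactly.
* **Integration is a rectangle sum** with \(\Delta\lambda\) = 1 nm on
  the common grid - the convention used by tabulated-toolbox
  calculations, and identical to the trapezoid rule in the interior of
  the support. The test suite holds it against an independent 0.1-nm
  trapezoid oracle at relative error < 1e-3 for polychromatic LED
  mixtures. That agreement is a property of well-conditioned inputs:
  when a weighted integral is dominated by the far exponential tail of a
  sensitivity function (a lone 630 nm line weighted by the S-cone
  function, say), *any* 1-nm quadrature is ill-conditioned in relative
  terms, and such values are scientifically meaningless anyway.
* Sub-nm instrument data are resampled onto the 1-nm grid, not binned.

## The reference weighting functions are synthetic

The five alpha-opic sensitivities, \(V(\lambda)\) and the blue-light
hazard function ship as vendored ASCII tables with recorded checksums
(`load_reference_functions()`). They are **synthetic stand-ins**
generated in code (`data-raw/make-reference-tables.R`), not transcripts
of the standardized tabulations:

* photoreceptor functions: Govardovskii A1 pigment templates at the
  nominal pigment peaks (S 419, M 530, L 558, rods 500, melanopsin
  480 nm), multiplied by the ocular-media transmittance of the 32-year
  standard observer (two-component lens-density model, plus a small
  macular term for the cones as appropriate for a 10 degree field), then
  unit-peak normalized on the 1-nm 380-780 nm grid. The resulting
  corneally referenced peaks (about 440, 536, 565, 508, 487 nm) sit
  longward of the pigment peaks, as pre-receptoral filtering dictates.
* \(V(\lambda)\): a weighted L+M sum with the weight tuned once so the
  normalized curve peaks at exactly 555 nm.
* hazard function \(B(\lambda)\): the published piecewise structure - a
  tabulated rise to a unit plateau at 435-440 nm, a tabulated decline to
  500 nm, \(10^{(450-\lambda)/50}\) over 500-600 nm, and 0.001 to
  700 nm - on its native 5 nm grid, aligned to spectra by resampling.

Consequences: every *structural* property holds exactly (unit peaks,
supports, the 683 lux anchor at 555 nm, linearity, age-correction
identity, threshold locations), but **absolute alpha-opic values
computed with these tables are approximations** and should not be quoted
against values computed with the standardized tabulations. Swapping in
the standard's tables is a drop-in replacement of seven CSV files plus
checksums.

## Age-dependent pre-receptoral filtering

Lens yellowing attenuates short wavelengths progressively with age. The
correction (`lens_correction()`, `lens_corrected_weighting()`) uses the
two-component lens-density form: \(D(\lambda, A) = T_{L1}(\lambda)\,
(1 + 0.02\,(A-32)) + T_{L2}(\lambda)\) for ages 20-60 and
\(T_{L1}(\lambda)\,(1.56 + 0.0667\,(A-60)) + T_{L2}(\lambda)\) above 60.
The factor applied to a weighting function is the transmittance ratio
\(10^{-(D(\lambda,A) - D(\lambda,32))}\), in which the age-invariant
component cancels, so:

* at age 32 the correction is the identity, exactly;
* above 32 the factors at short wavelengths decrease monotonically with
  age and never exceed the long-wavelength factors;
* wavelengths above 650 nm are unaffected.

Ages outside 20-80 are errors, not clamps - extrapolating a group-mean
lens density is unsafe, and the model is a group average in any case
(individual densities differ). The correction is applied to the
*weighting functions*, never to the SPD: the stimulus is physical, the
observer changes. The photopic entry is never age-corrected, because
photometric units are defined for the standard observer; for
non-standard ages `age_sensitivity_analysis()` reports both, labelled
by age, with the age-32 row reproducing the standard panel exactly.

## Observer geometry

* **Visual angle**: \(\theta = 2\,\mathrm{atan}(0.5\,S/d)\), evaluated
  per dimension (horizontal, vertical); no solid-angle computation.
* **Pupil diameter** (`predicted_pupil_diameter()`): the unified
  light-adapted formula (Stanley-Davies base evaluated at effective
  corneal flux density \(F = L \cdot a \cdot M(e)\), with field area
  \(a\) in deg^2, monocular factor \(M(1)=0.1\), \(M(2)=1\), and a
  linear age term referenced to 28.58 years), clamped to 1-10 mm. The
  variant is recorded in the result's `model` attribute. The model
  ignores non-luminance contributions to pupil control; none are
  corrected for. A measured (or pharmacologically fixed) pupil always
  overrides the model and is tagged `"measured"` by
  `retinal_illuminance()`.
* **Trolands**: luminance times pupil area in mm^2. No age adjustment
  is applied to trolands.

## The safety pre-screen

`rg0_screen()` implements the risk-group-0 logic for the photochemical
(blue-light) retinal hazard: sources below **10,000 cd/m^2** are exempt
(detailed hazard measurement typically not required); brighter sources
at exposures longer than **10,000 s** are compared against the
**100 W/(m^2 sr)** blue-light-weighted radiance limit; brighter sources
at shorter exposures pass with a rationale noting that the long-exposure
limit was not triggered, because time-dependent short-exposure limits
are deliberately out of scope. Thermal hazard is not assessed. Every
result carries the caveat that this is a pre-screen and regulatory
compliance must be confirmed case by case. The verdict is monotone in
stimulus scale, so bisection on a scale factor localizes each verdict
flip at its configured threshold - the acceptance script
(`scripts/acceptance.R`) recomputes all three thresholds that way.

## The photon system

`photon_report()` converts spectral irradiance to photon irradiance via
\(E(\lambda)\,\lambda/(hc)\) with CODATA 2018 exact constants, reported
per cm^2 with a base-10 log transform (absent for an all-zero
spectrum). Radiance input is rejected; photon radiance is not a
reporting quantity here.

## Compliance semantics

`validate_record()` scores the seven checklist items independently:
a **missing** element fails its item, a **present but incomplete**
element warns (e.g. an SPD without measurement geometry, a
manufacturer-tabulated stimulus spectrum without a separately reported
in-situ photopic illuminance, metadata with named fields absent), and
verdicts are monotone - adding information never turns a pass into a
fail. There is deliberately **no lux threshold for "dim" background
light**: the checklist requires the background SPD itself, not a
brightness cut-off. Clock times require an explicit timezone.

## The fixture generator

`planckian_spd()` (Planck's law in double precision),
`gaussian_led_spd()` (Gaussian bands parameterized by peak/FWHM/
band-integrated power), `monochromatic_spd()` (single-bin lines, so
unit-peak pass-through identities are exact by construction) and
`deficient_record()` (a complete synthetic exposure record with exactly
the named checklist elements removed) emulate the stimuli these
experiments use - thermal radiators, multi-primary LED mixtures,
narrowband lines - and deliberately deficient reporting. They are
deterministic given their parameters, which are recorded in the output
metadata. They do **not** emulate instrument noise, stray light,
daylight models, or spectrometer bandpass: passing tests show the
computational pipeline is correct on clean tabulated data, not that any
instrument is characterized. Randomized sweeps in the test suite draw
trichromatic blue/green/red mixtures (peaks near 440-480, 500-560,
580-660 nm; FWHM 15-50 nm), the linewidths and layout of realistic
white-light LED sources.

Problem sizes throughout are those of the reporting convention itself:
401-sample spectra (380-780 nm at 1 nm), 50-fixture randomized sweeps,
and bisections run to ~30 significant bits, all of which complete in
seconds.

## Known limitations

* Absolute alpha-opic values depend on the synthetic tables (above).
* Field-of-view truncation by facial features, eye/head/trunk movement,
  percent-eyes-open estimation and individual photoreceptor differences
  are out of scope; the record carries free-text notes for some of them.
* The manifest schema checks presence and internal consistency, not the
  *precision* of reported geometry.
* Chromaticity, CCT and colour rendering are deliberately absent: they
  are named here only as insufficient sole specifications of a stimulus.

## A worked example

```{r example}
spd <- gaussian_led_spd(list(c(455, 25, 0.4), c(545, 35, 0.7),
                             c(620, 25, 0.5)))
alpha_opic_panel(spd)
photon_report(spd)
rec <- deficient_record()     # fully populated synthetic record
validate_record(rec)
```
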