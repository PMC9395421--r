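# rcflash

Kinetic analysis of light-induced cytochrome *c* oxidation in intact
photosynthetic purple bacteria.

In these organisms a photon closes the reaction center (RC) by oxidizing the
special bacteriochlorophyll pair (P → P⁺) and depositing the electron on the
primary quinone Q_A; the RC re-opens only when the acceptor side has passed
the electron on through the two-electron Q_B gate **and** the donor side has
re-reduced P⁺ from the cytochrome pool. Time-resolved difference-absorbance
spectroscopy at 551−540 nm (cytochrome) and 790−750 nm (P/P⁺) turns this
cycle into measurable staircases and saturation curves. `rcflash` provides,
for experimentalists and modellers working on such data:

* a mean-field **chain model** of RC turnover (48 discrete states: P redox ×
  Q_A × Q_B-site × donor docking site) integrated as one stiff ODE system,
  with an instantaneous saturating-flash operator;
* the closed-form **re-opening law**
  `[PQ_A](t) = (1 − e^(−k_A t)) (1 − e^(−k_D t))`
  and a nonlinear fit of delayed-flash damping curves that recovers the
  interquinone electron-transfer rates;
* the **step-damping model** linking per-flash cytochrome oxidation steps
  Δ1, Δ2, Δ3 to generalized donor and acceptor equilibrium constants,
  Δ1 = K_D1/(1+K_D1),
  Δ2 = [K_A1/(1+K_A1)] · Δ1 · K_D2/(1+K_D2), …, and its inversion
  K_D1 = Δ1/(1−Δ1), K_D2 = r₂/(1−r₂) with r₂ = Δ2/Δ1,
  K_D3 = r₃/(1−r₃) with r₃ = Δ3/Δ2;
* **trace processing**: Beer–Lambert conversion with the published
  difference extinction coefficients (Δε = 21.1 mM⁻¹cm⁻¹ for cytochrome at
  551−540 nm, 70 mM⁻¹cm⁻¹ for P/P⁺), plateau-window step extraction,
  three-phase segmented fitting of continuous-illumination kinetics, sweep
  averaging and single-turnover normalization;
* a **synthetic spectrometer** with calibrated strain presets
  (*Rubrivivax gelatinosus* wild type and its *pufC* mutant,
  *Rhodobacter sphaeroides* wild type and its cytochrome-less *cycA*
  mutant), inhibitor/redox treatments (terbutryne, myxothiazol, dithionite,
  ferricyanide, ferrocene) and seeded noise, so the entire pipeline is
  testable without instrument data;
* a config-driven pipeline (`run_pipeline()`) with YAML examples under
  `inst/examples/` and a thin CLI wrapper in `inst/scripts/rcflash.R`.

## Worked example

Simulate a three-flash experiment (400 µs spacing, 32-sweep averaging) for
wild-type *Rvx. gelatinosus*, reduce the trace to step heights, and invert
to donor equilibrium constants:

```r
library(rcflash)

preset <- strain_preset("rvx_wt")
ex <- generate_flash_experiment(
  preset, noise = noise_model(sigma = 1e-4, n_averages = 32, seed = 42))

conc  <- absorbance_to_concentration(ex$trace)
steps <- extract_steps(conc, attr(ex$trace, "protocol"))
steps
#> Cytochrome oxidation steps (cyt3+/RC): D1 = 0.9894, D2 = 0.9717, D3 = 0.7631

invert_steps(steps)
#> K_D = (93.38, 55.03, 3.658), K_A = (Inf, Inf)
```

The steps say: the first flash oxidizes essentially one cytochrome per RC,
the second nearly as much, the third noticeably less — the damping that
reports donor availability. The recovered constants agree with the preset's
K_D2 = 49 and K_D3 = 3.7 within the noise of a single 32-sweep average
(K_D2 is the most sensitive: at a step ratio of 0.98, a 0.1% ratio error
moves it by ~5).

Fitting a delayed-flash damping curve recovers the rate-limiting
(acceptor-side) rate:

```r
curve <- damping_vs_delay(k_A = 1.2e4, k_D = 1e6, R_inf = 0.98,
                          delays = 10^seq(-5, -2.5, length.out = 12))
fit_damping_curve(curve)
#> Delayed-flash damping fit: R_inf * (1-exp(-kA T))(1-exp(-kD T))
#>   k_slow (rate-limiting) = 1.2e+04 s^-1 (1/k = 8.33e-05 s, ln2/k = 5.78e-05 s)
#>   k_fast = 1e+06 s^-1, R_inf = 0.98
```

`vignettes/rcflash-methods.Rmd` documents the model, the preset
calibrations and their assumptions in detail.

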