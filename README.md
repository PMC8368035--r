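# oplflux

Simulation-backed analysis of **optical pulse labeling (OPL)** assays of
autophagic flux built on the green-to-red photoconvertible reporter
Dendra2-LC3. The package is aimed at screening and imaging groups who need
a tested, end-to-end reference implementation of the OPL analysis chain —
from raw two-channel intensities to hit lists and single-cell survival
models — together with synthetic-data generators that make every stage
verifiable against planted ground truth.

## The measurement

A violet pulse irreversibly converts a fraction φ of the Dendra2-LC3 pool
from green to red. No new red protein is made afterwards, so the red decay
isolates degradation from synthesis. With the preconversion background and
postconversion anchors, the red channel is modelled as

    I(t) = I_bg + (I_post − I_bg) · e^(−kt),      t½ = ln 2 / k

and the normalized signal R(t) = (I(t) − I_bg)/(I_post − I_bg) runs from 1
at the pulse toward 0 (or above 1 under late-stage inhibition with puncta
clustering). The green channel follows synthesis/turnover balance
dI_g/dt = s − k_g·I_g, dipping ~40% at the pulse and re-equilibrating.
Screening uses the 3 SD rule against within-plate DMSO controls on either
the 15 h/0 h GFP ratio (primary) or the 9 h normalized red ratio
(secondary), with Z′ = 1 − 3(σ_pos+σ_neg)/|μ_pos−μ_neg| as plate QC,
toxicity (cell-area) and autofluorescence (reporter-free counterscreen)
filters, and funnel bookkeeping across stages. Single-cell work fits
per-neuron half-lives and links them to death times with Cox proportional
hazards models (linear and penalized spline).

## Worked example

```r
library(oplflux)

# a 24-well vehicle calibration plate, imaged every 1.5 h after the pulse
lay <- plate_layout("demo", rep(LETTERS[1:4], each = 6), rep(1:6, 4),
                    "vehicle_control")
plate <- generate_plate(lay, schedule = opl_schedule(-0.5, seq(0, 13.5, 1.5)),
                        seed = 1, noise_cv = 0.05)
hl <- vapply(unique(plate$layout$well), function(w)
  fit_well_half_life(well_series(plate, w, "red"))$half_life_h, numeric(1))
mean(hl)
#> [1] 7.467337

# single-cell cortical cohort: generate, fit, call deaths, model risk
pip <- neuron_halflife_pipeline(500, "cortical", seed = 7)
pip$mean_half_life
#> [1] 33.07661
fit_cox_linear(pip$records)
#> Cox PH: HR 1.0220 per h of half-life (95% CI 0.9980-1.0466),
#>   beta 0.0218, p 0.0723, 108 events / 476 cells
```

The fitted well half-lives recover the vehicle calibration (7.5 h) within
sampling error; the Torin1 preset recovers the ~3-fold faster 2.5 h decay
the same way. In the neuron cohort the mean fitted single-cell half-life
matches the cortical calibration (33.2 h), and the hazard ratio above 1
per hour of half-life reproduces the planted direction of the link —
slower autophagic flux, higher risk of death. A single 500-cell cohort
sits at the edge of significance; pooling the cortical and spinal cohorts,
as `analysis/06_neuron_survival.R` does, sharpens the same estimate to
HR 1.041 per hour, p ≈ 1e-8.

The numbered scripts under `analysis/` run the full story — calibration
plate, flux metrics and Z′, a 320-compound demonstration screen through
the five-stage funnel, image-level puncta colocalization, dose–response
fits in both channels, and the two-population survival analysis — writing
their tables under `results/`:

```sh
Rscript analysis/01_simulate_plate.R --seed 1
Rscript analysis/02_flux_metrics.R   --seed 1
# ... through 06_neuron_survival.R
```

## Package layout

- `R/` — generators (`generate_plate`, `generate_images`,
  `generate_neuron_tracks`, `generate_dilution_series`), imaging
  (`subtract_background`, `segment_cells`, `detect_puncta`,
  `colocalize_puncta`), flux metrics (`fit_half_life`, `fit_4pl`,
  `torin1_equivalents`), screening (`zprime`, `call_hits`, `run_funnel`,
  `screen_library`) and survival (`call_death_time`, `fit_cox_linear`,
  `fit_cox_spline`).
- `vignettes/opl-methods.Rmd` — the model, calibrations, thresholds and
  design rationale.
- `inst/extdata/opl_config.yaml` — the shipped run configuration with all
  calibration presets.
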