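# hsrdyn

Single-cell heat shock response kinetics and model-based inference of
chaperone expression heterogeneity.

## The problem

Under hyperthermia, misfolded protein titrates the HSP70 chaperone pool
away from the transcription factor HSF1; freed HSF1 accumulates in nuclear
stress bodies — visible as fluorescent foci in HSF1:eGFP cells — and drives
chaperone synthesis. Activation is hypersensitive, so modest cell-to-cell
differences in chaperone and HSF1 expression spread an identical stress
into a continuum of single-cell responses: adaptation, plateau, continuing
increase, or no visible response at all. `hsrdyn` is for quantitative
biologists who want to simulate, describe and invert that heterogeneity:
it links time-lapse foci trajectories to the underlying expression levels
through a kinetic model of the network.

## The model

Each cell obeys a four-variable ODE system (temperature θ, misfolded
protein MFP, chaperone HSP, chaperone mRNA mHSP; time in hours,
concentrations in µM):

```
τ_θ    dθ/dt      = θ_c − θ
τ_MFP  d[MFP]/dt  = κ(θ) − [MFP]²/([HSP]+[MFP]) − k_r [MFP][HSP]/([HSP]+[MFP])
τ_HSP  d[HSP]/dt  = β H_free/(H0 + H_free) · [mHSP] − [HSP]
τ_mHSP d[mHSP]/dt = μ + λ S_free³/(S0³ + S_free³) − [mHSP]
```

with `H_free = [HSP]/([HSP]+[MFP])`,
`S_free = [HSF1]_tot / ([HSF1]_tot + [HSP]·H_free)`, the temperature input
`κ(θ) = k_d (1 − 0.4 e^(37−θ)) · 1.4^(θ−37)`, and the foci-fraction
readout `F = S_free³`. All rates are fixed at their published calibration
(`hsr_params()`); cells differ only in total HSF1 and in their chaperone
level at stress onset.

On top of the model the package provides:

* **`synthetic populations`** — `population_spec()` /
  `generate_population()`: log-normal expression heterogeneity, 10-minute
  sampling, transient 41–44 °C protocols, measurement noise with the 1 %
  foci detection limit.
* **response statistics** — responder calling (`call_responders()`), Hill
  summary of responder fraction vs. temperature, responder-restricted mean
  dynamics, amplitude percentile boxes, relaxation-index histograms, and
  the ratio-binned activation function.
* **chaperone inference** — `fit_cell()` scans the one free parameter
  (initial chaperone level) on a log grid against a cell's observed
  trajectory, gates fits at the 2 % measurement error, converts error
  profiles into per-cell likelihoods, and `population_distribution()` sums
  them into a population-level expression distribution.

## Worked example

```r
library(hsrdyn)

spec <- population_spec(n_cells = 50, stress_temperature = 43, seed = 7)
pop <- generate_population(spec)
calls <- call_responders(pop$trajectories)
sprintf("responder fraction at 43 degC: %.2f (n = %d cells)",
        responder_fraction(calls), nrow(calls))
#> "responder fraction at 43 degC: 0.88 (n = 50 cells)"

amplitude_distribution(pop$trajectories, calls)
#>   time_h   p09   p25   p50   p75   p91 n_cells
#> 1      1 0.015 0.038 0.091 0.173 0.248      44
#> 2      3 0.000 0.000 0.000 0.041 0.065      44

hsf1 <- fluorescence_to_hsf1(
  pop$trajectories$total_fluorescence[!duplicated(pop$trajectories$cell_id)])
names(hsf1) <- unique(pop$trajectories$cell_id)
fits <- lapply(split(pop$trajectories, pop$trajectories$cell_id),
               function(d) fit_cell(d, hsf1[[d$cell_id[1]]], pop$protocol))
sum(sapply(fits, `[[`, "satisfactory"))
#> 50
distribution_median(population_distribution(fits))
#> 0.527
```

Reading: 88 % of cells form detectable foci at 43 °C; the response peaks
near 1 h (median F ≈ 9 %) and has largely relaxed by 3 h; every cell's
trajectory is fitted within the 2 % error gate by adjusting only its
initial chaperone level; and the population-level distribution assembled
from per-cell likelihoods puts the chaperone median at 0.527 µM, against a
generating median of 0.507 µM.

## Analysis workflow

The `analysis/` scripts run the full study on simulated campaigns and
write tidy tables under `results/`:

1. `analysis/01_simulate_population.R` — 200-cell populations at
   41/42/43/44 °C plus a collagen-coated arm (1.5× chaperone median) at
   43 °C.
2. `analysis/02_response_statistics.R` — responder fractions + Hill
   eye-guide, mean dynamics, amplitude boxes, relaxation histograms,
   activation function.
3. `analysis/03_chaperone_inference.R` — per-cell fits, fit-success
   comparison with and without chaperone heterogeneity, and the inferred
   expression distributions for both culture conditions.

Run them in order from the repository root with `Rscript`.

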