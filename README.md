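# coffeevoc

Roasted coffee emits the alpha-dicarbonyl volatiles **diacetyl**
(2,3-butanedione) and **2,3-pentanedione**, both associated with the
irreversible lung disease obliterative bronchiolitis. Workers in coffee
roasting and packaging facilities are exposed to these compounds when they
handle — and especially when they grind — roasted coffee. `coffeevoc` is an
R package for industrial hygienists and exposure scientists that links
laboratory emission measurements to predicted workplace exposures:

1. **Chamber kinetics** — estimate specific emission rates (SERs, mg of
   analyte per kg of coffee per hour) from small-chamber emission trials by
   fitting a first-order decaying-source concentration model,
   `C(t) = L·EF₀·(e^(−kt) − e^(−Nt))/(N − k) + L·EF_ss·(1 − e^(−Nt))/N`,
   where `N` is the chamber air-exchange rate (1/hr) and `L` the loading
   factor (kg/m³), both fixed from measured trial geometry. The peak of the
   fitted curve gives `EF_max = C_max·Q/m`, and the transient mass balance
   at the peak gives the buildup-corrected
   `EF_buildup = EF_max/(1 − e^(−N·t_max)) ≥ EF_max`.
2. **Summaries** — replicate SER tables (mean, SD, CV%), storage-age trend
   regression with 95% CIs, lognormal particle-size summaries (GM/GSD) and
   Feret (caliper) diameters of particle outlines.
3. **Two-zone exposure model** — the near-field/far-field mass-balance
   model: a small zone of volume `V_N` around the worker and source
   exchanges air with the rest of the room at the inter-zone flow
   `β = ½·s·A_FS` (`s` = boundary air speed, `A_FS` = free-slip area);
   the room is ventilated at `Q` m³/min. The coupled balances
   `V_N·dC_N/dt = G + β(C_F − C_N)` and
   `V_F·dC_F/dt = β(C_N − C_F) − Q·C_F` are solved exactly
   (two-eigenvalue analytic form), with steady state
   `C_F = G/Q`, `C_N = G/Q + G/β`.
4. **Scenario engine and Monte Carlo** — cyclic 8-h work schedules
   (packaging/grinding presets), per-task and full-shift time-weighted
   averages (TWAs), NIOSH REL/STEL exceedance reports (5.0 / 25 ppb for
   diacetyl), seeded Monte Carlo propagation of input uncertainty, and a
   `1/β` sensitivity sweep.

A synthetic-data generator (`gen_chamber_series`, `gen_particle_sample`,
`gen_storage_series`) produces every input with known ground truth, so the
whole chain is testable end to end.

## Worked example

```r
library(coffeevoc)

# fit a packaged synthetic chamber trial (5% multiplicative noise;
# ground truth EF0 = 3.6, EF_ss = 0.4, k = 1.2)
trials <- read_chamber_trials(
  system.file("extdata", "synthetic-trials.csv", package = "coffeevoc"))
fit_emission_curve(trials$dark_fine_1)
#> Emission fit for trial 'dark_fine_1' (diacetyl)
#>   EF0 = 4.012, EF_ss = 0 mg/kg/hr, k = 0.9809 /hr (SSE 0.2056)
#>   N = 20.74 /hr, L = 45.61 kg/m3
#>   Cmax = 7.584 mg/m3 at t = 0.1544 hr; EF_max = 3.448, EF_buildup = 3.594 mg/kg/hr
```

The fitted `N = 20.74/hr` and `L = 45.61 kg/m³` come from the trial
geometry (39.4 mL/min through 114 mL; 5.2 g of coffee); `EF_buildup` is the
SER the trial supports after correcting for incomplete chamber response at
the concentration peak.

```r
# simulate a small-facility production shift: four cycles of three 15-min
# whole-bean packaging tasks and one 15-min grinding task on 10 kg of dark
# roast, with far-field gaps, cleaning, breaks and lunch
sys <- two_zone_system(room_volume = 7787,
                       nf_volume = near_field_geometry()$nf_volume,
                       supply_air = 73.2, beta = 10.6,
                       generation = 0, analyte = "diacetyl")
prof <- simulate_schedule(build_schedule("scenario_A"), sys)
prof
#> Exposure profile (diacetyl), 480-min shift, 43 segments
#>   full-shift TWA: 2.56 ppb; max instantaneous: 16.6 ppb
unlist(exceedance(prof, rel = 5, stel = 25)[
  c("full_shift_twa_ppb", "max_task_twa_ppb", "max_task_stel_ratio")])
#>  full_shift_twa_ppb    max_task_twa_ppb max_task_stel_ratio
#>           2.5615541          16.2851082           0.6514043
```

At a boundary air speed of 6 m/min (β = 10.6 m³/min) the worker's
full-shift TWA is 2.6 ppb — below the 5.0 ppb REL — and the worst task
(grinding, 16.3 ppb over 15 min) stays under the 25 ppb STEL.

```r
# how strongly does the near field depend on the inter-zone flow?
sens <- sensitivity_beta(
  two_zone_system(7787, 0.884, 73.2, 10.6, 0.6, "diacetyl"),
  beta_grid = c(1.77, 5.3, 10.6, 42.4))
sens$table
#>    beta   inv_beta  conc_ppb
#> 1  1.77 0.56497175 98.600830
#> 2  5.30 0.18867925 34.479433
#> 3 10.60 0.09433962 18.403672
#> 4 42.40 0.02358491  6.346851
```

Steady-state near-field concentration is exactly linear in `1/β`; going
from still air (β = 1.77) to lightly moving air (β = 5.3) drops the
concentration 2.9-fold.

```r
# propagate input uncertainty (supply air ±10%, grinding G from its 95% CI)
spec <- mc_spec(1000, seed = 42, distributions = list(
  Q = dist_uniform(65.9, 80.5),
  G_grinding = dist_normal(0.6, 0.14 / 1.96)))
run_mc(build_schedule("scenario_A"), sys, spec, dt = 1)
#> Monte Carlo exposure summary (1000 draws, seed 42, 0 failed)
#>   packaging: median 1.09 ppb (95th 1.12)
#>   grinding: median 15.8 ppb (95th 18.8)
#>   full shift: median 2.5 ppb (95th 2.9; batch SE 0.0084)
#>   P(full-shift TWA > REL) = 0.000; P(task TWA > STEL) = 0.000
```

`run_pipeline()` chains all stages (fit → summarize → simulate → Monte
Carlo) from a single YAML/JSON configuration
(see `inst/extdata/demo-config.yaml`) and writes a manifest with MD5
hashes of every artifact; the same configuration and seed always reproduce
identical hashes.

## Vignette

`vignettes/exposure-modelling.Rmd` documents the model assumptions, the
parameter choices and their defaults, what the synthetic-data generator
does and does not emulate, and known limitations.
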