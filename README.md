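# ecoforcing

Climate-effect analysis for paired eddy-covariance towers under nutrient
manipulation in a semi-arid tree–grass ecosystem. Given half-hourly tower
records for a control site (CT), a nitrogen-added site (NT) and a
nitrogen-plus-phosphorus site (NPT) — each measured at the ecosystem and
understory layers — the package quantifies how a gradual, nutrient-driven
vegetation change feeds back on climate:

- **Radiative forcing at top of atmosphere.** Monthly albedo differences
  Δα run through an ensemble of albedo radiative kernels,
  RF<sub>Δα</sub> = −K<sub>αs</sub> Δα A<sub>site</sub>/A<sub>Earth</sub>,
  and cumulative NEE differences propagate into a CO2 mole-fraction
  perturbation, RF<sub>ΔNEE</sub> = 5.35 Δχ/χ₀ (airborne fraction β = 0.44,
  χ₀ = 399.4 ppm). Forcing is reported in 10⁻¹⁴ W m⁻² (global) per m² of
  treated surface, with a GWP conversion of the albedo term to
  kg CO2e ha⁻¹ yr⁻¹.
- **Surface-temperature decomposition.** Radiometric surface temperature is
  retrieved from outgoing longwave (LWUR = σεT⁴, ε = −0.16α + 0.99) and the
  daily between-site difference is decomposed, via a first-order Taylor
  expansion about the control site's state, into contributions from albedo,
  incoming shortwave/longwave, emissivity, latent/sensible/soil heat flux,
  and the residual energy imbalance — all in °C, closing exactly on
  ΔTs,cal.
- **Ecophysiology.** Daily water-use efficiency, evaporative fraction,
  aerodynamic conductance G<sub>a</sub> = [u/u*² + 6.2 u*^(−2/3)]⁻¹,
  surface conductance by Penman–Monteith inversion, and the decoupling
  coefficient Ω.
- **Attribution.** Dynamic time warping ranks the eight decomposition
  components by temporal closeness to ΔTs,cal per season, and seasonal
  between-site differences are tested with ANOVA/Tukey or
  Kruskal–Wallis/Dunn depending on distributional checks.

A synthetic dual-layer tower generator with known injected treatment
effects (albedo offsets, NEE offsets, flux repartitioning, temperature
offsets, closure fractions, rain and gaps) provides the ground truth for
every stage; the data-selection rules of the source methodology (midday
11:00–14:30 clear-sky albedo, rain exclusion, 66% day/night missingness
budgets, the sign/2 °C agreement filter) are all implemented and tested.

## Worked example

```r
library(ecoforcing)

scenario <- scenario_spec(seed = 42, n_years = 2)   # CT/NT/NPT x 2 layers
records  <- generate_halfhourly(scenario)
kernels  <- kernel_ensemble(read_kernel_csv(
  system.file("extdata", "synthetic_albedo_kernels.csv",
              package = "ecoforcing")))

res <- run_pipeline(records, latitude = 39.94,
                    calendar = default_season_calendar(2013:2019),
                    kernels = kernels,
                    treatment_start = as.Date("2015-01-01"))

rf <- res$monthly_rf[["NT-CT.ecosystem"]]
mean(rf$rf_alpha_e14, na.rm = TRUE)   # -0.371  (10^-14 W m-2 m-2)
tail(rf$rf_nee_cum_e14, 1)            # -0.041

dc <- res$decomposition[["NT-CT.ecosystem"]]
mean(dc$dts_obs[dc$kept])             # -0.40 degC

res$closure[["CT.understory"]]$slope  # 0.60, the injected understory
                                      # closure fraction
```

The numbers read as: brightening the ecosystem by the injected Δα = +0.015
exerts a mean monthly cooling of −0.37×10⁻¹⁴ W m⁻² globally per treated
square metre through the kernel ensemble, roughly nine times the cumulative
CO2-uptake forcing after two years (−0.04×10⁻¹⁴); despite both forcing
terms cooling, the N-added ecosystem surface is itself ~0.4 °C cooler while
the treated understory warms — the scale dependence the decomposition and
DTW ranking then attribute to flux repartitioning (soil heat flux tracks
ΔTs,cal most closely at the understory).

The numbered scripts under `analysis/` run the same workflow as a staged
narrative (simulate → QC → forcing → decomposition → ecophysiology →
attribution), writing tidy CSVs under `results/`.

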