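# mixopH

Protist plankton physiology and seawater pH in closed batch systems.

## The problem

Photosynthesis by plankton consumes CO₂ and raises seawater pH
(*basification*); heterotrophy respires CO₂ and lowers it. Mixoplankton —
protists that photosynthesise *and* eat prey in the same cell — might be
expected to buffer their own pH environment by balancing the two.  Whether
they actually do depends on the cell-level plumbing: ingested food is
partly voided, ~30% of the retained fraction is lost to specific dynamic
action (SDA) as CO₂, NH₄⁺ and PO₄, and in a mixoplankton those SDA
releases are captured by the chloroplasts *before* they reach the water,
fuelling extra photosynthesis instead of acidifying the sea. `mixopH` is a
systems-biology simulator for exploring this question, for modellers and
plankton ecologists: it couples a mass-conserving, quota (Droop)
stoichiometric physiology model of the five protist functional types —
phytoplankton, zooplankton, and the GNCM, pSNCM and CM mixoplankton types
— one-way to a seawater carbonate-chemistry solver, in a nutrient-replete
coastal batch system closed to gas exchange and initialised at air–sea
equilibrium with either 300 µatm (early industrial) or 600 µatm
(end-of-century) atmospheric pCO₂.

## The model in brief

* **Physiology** (per functional type, shared constants µ_max = 0.693 d⁻¹,
  ESD = 20 µm): quota-controlled photosynthesis `P = P_max · f(I) ·
  (Chl:C) · u(Q)`, Michaelis–Menten NH₄/NO₃/PO₄ uptake, Holling type II
  grazing, digestion with assimilation efficiency AE = 0.75 and SDA = 0.30,
  internal recycling `recycled = min(SDA release, concurrent demand)`,
  basal respiration 0.15 µ_max with allied NH₄/PO₄ regeneration, DOC
  leakage and stoichiometric overflow.  C, N and P budgets close to
  numerical precision.
* **Carbonate chemistry**, strictly downstream (no feedback to biology):
  total-scale equilibrium constants at 15 °C, S 35; `[H⁺]` solved from the
  alkalinity balance `TA = [HCO₃⁻] + 2[CO₃²⁻] + [B(OH)₄⁻] + [OH⁻] − [H⁺]`;
  TA forced by nutrient fluxes (ΔTA = +NO₃ uptake − NH₄ uptake + PO₄
  uptake, release opposite).
* **Proximal [H⁺]**: near-cell offsets from spherical diffusion,
  `Δc = −F / (4π D r Sh)`, re-speciated at the cell surface — larger cells
  see larger departures from bulk.
* **Desk calculations**: the ingestion multiples at the carbon balance
  point, `1/(AE(1−SDA)) ≈ 1.9` for a pure phagotroph and `1/AE ≈ 1.3` for
  a mixoplankton at zero net DIC change, where phagotrophy brings in ≈3 C
  per unit gross fixation.

## Worked example

```r
library(mixopH)

k <- equilibrium_constants(15, 35)
equilibrate_with_atmosphere(600, 2300, k)
#> carbonate state: pH 7.8917  [H+] 1.283e-08 mol/kg  DIC 2150.1  TA 2300.0  pCO2 600.0 uatm

res <- run_scenario(make_scenario(config = make_config("CM")))
res
#> simulation result: CM - 1001 output steps over 20 d; pCO2 variants: 300, 600
#>   300 uatm: pH 8.150 -> 8.814, dDIC -476.9 umol/kg
#>   600 uatm: pH 7.892 -> 8.662, dDIC -476.9 umol/kg
```

The constitutive mixoplankton consumes all 20 µM of dissolved inorganic N
*and* the 132.5 µg atom C L⁻¹ of prey, drawing down 477 µmol kg⁻¹ of DIC —
far more than a phytoplankton in the same water (−277) — so its bloom
*raises* pH by ~0.7–0.8 units rather than stabilising it; feeding fuels
photosynthesis instead of offsetting it.  The same biology started at
600 µatm moves further in [H⁺] terms because the water is less buffered.
The converse, for a zooplankton:

```r
run_scenario(make_scenario(config = make_config("zooplankton")))
#> simulation result: zooplankton - 1001 output steps over 20 d; pCO2 variants: 300, 600
#>   300 uatm: pH 8.150 -> 8.015, dDIC +79.6 umol/kg
#>   600 uatm: pH 7.892 -> 7.705, dDIC +79.6 umol/kg

balance_point(AE = 0.75, SDA = 0.30, mode = "pure_phagotroph")        # 1.90
balance_point(AE = 0.75, SDA = 0.30, mode = "mixoplankton_zero_net_DIC") # 1.33
phago_to_fixation_ratio(0.75, 0.30, basal_respiration_multiple = 0.15)   # 2.96
```

Preset scenario catalogues reproduce the standard comparisons:
`scenario_presets("fig3")` (the five types at defaults),
`scenario_presets("fig4")` (CM and phytoplankton at 20 vs 250 µm with
near-cell [H⁺]), `scenario_presets("fig5")` (CM trophic-priority, light
and prey-quality variants).  See the methods vignette
(`vignettes/mixoplankton-ph.Rmd`) for the model description, parameter
choices and limitations.

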