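---
title: "Modelling protist trophic strategy and seawater pH: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protist trophic strategy and seawater pH: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixopH)
```

# Scope and design

`mixopH` simulates autecological batch growth of a single protist
population — phytoplankton, zooplankton, or one of three mixoplankton
functional types (generalist non-constitutive, GNCM; plastidic-specialist
non-constitutive, pSNCM; constitutive, CM) — in a closed water body, and
translates the resulting fluxes of CO₂, ammonium, nitrate and phosphate
into changes in dissolved inorganic carbon (DIC), total alkalinity (TA)
and hence [H⁺]/pH, for water initially equilibrated with either 300 or
600 µatm atmospheric CO₂.

Three structural assumptions define the scope:

1. **One-way coupling.** Carbonate chemistry runs strictly downstream of
   the biology.  There is no feedback from [H⁺] or DIC to physiology (DIC
   stays far in excess of limitation in all default scenarios), so the
   biological trajectory is computed once and is bit-identical across pCO₂
   variants; only the chemistry differs.
2. **Closed batch system.** No gas exchange, mixing or prey growth after
   initialisation.  Every element budget (C, N, P) then closes exactly,
   which the test suite enforces to 10⁻¹⁰ (instantaneous) and 10⁻⁶
   (integrated over 20 days).
3. **Single population, non-growing prey.** Succession, bacteria and DOM
   degradation are out of scope; voided and leaked organics accumulate as
   inert pools.

# The physiology model

## State and stoichiometry

The population carries C, N, P biomass (µg atom L⁻¹), a C-equivalent
chlorophyll pool indexing photosystem competence, and — for the
non-constitutive types — an acquired-phototrophy capacity $A \in [0,1]$.
Internal stoichiometry follows a Droop quota: N:C and P:C must stay within
[0.5×, 2×] Redfield (0.075–0.302 and 0.0047–0.019 g atom ratios).  The
normalized quota $s = (Q - Q_{\min})/(Q_{\max} - Q_{\min})$ of the most
limiting element defines the cell's nutrient *satiation*; $u = 1 - s$ is
its stress.

## De-repression controls

Phototrophy, phagotrophy and the inorganic transporters are repressed when
the cell is replete and de-repressed under stress, through a normalized
Hill sigmoid $c(u) = u^h (1 + k^h)/(u^h + k^h)$ that is exactly 0 at
satiation and exactly 1 at maximal stress ($k = 0.5$).  Two shape choices
matter and were set on dynamical grounds:

* The trophic controls use $h = 2$; the transporters use a steeper
  $h = 3$.  Transporters must satiate *faster* than photosynthesis as the
  quota fills, otherwise dark-phase nutrient uptake ratchets the quota to
  its maximum, where every acquisition route is repressed while basal
  respiration continues — an absorbing starvation state.  With the
  steeper transporter control the quota has a stable interior equilibrium
  at mid-stress and the population grows near µ_max while nutrients last.
* Trophic priority (the CM variants) leaves the prioritised mechanism at
  the default threshold and de-represses the *other* one only at stronger
  stress ($k + 0.25$).  This reproduces the observed phenomenology:
  a phagotrophy-prioritising CM is initially net heterotrophic (its
  photosynthesis is repressed until stress builds) before phototrophy
  takes over, while a phototrophy-prioritising CM behaves like the default
  with delayed feeding.

## Fluxes

Per day, with population carbon $C$:

* **Photosynthesis**: $P = 3\,\mu_{\max}\, c_{photo}(u)\, A\,
  \min(\mathrm{Chl{:}C}/0.06, 1)\, (1 - e^{-I/100})\, g(s)\, C$.  The
  saturation scale of 100 µmol photons m⁻² s⁻¹ makes the default
  PFD 500 fully saturating (>99%) and PFD 50 strongly limiting (39%).
  $g(s) = 1 - (1-s)^4$ shuts fixation down as the cell attains its
  maximum C:N/C:P — without it, post-bloom cells at minimum quota would
  fix and leak DOC without bound.
* **Inorganic uptake**: Michaelis–Menten (half-saturations 0.3/0.5/0.1 µM
  for NH₄/NO₃/PO₄) scaled by the per-element transporter control;
  ammonium represses nitrate uptake multiplicatively (half-inhibition
  0.5 µM).  Maximum capacity is 1.2 × the balanced-growth requirement
  ($1.2\,\mu_{\max} Q_{\max}$) — transporters sized much larger let
  night-time uptake push the quota into satiation and stall the bloom.
* **Grazing**: Holling type II in prey C (half-saturation 50 µM C),
  scaled by the phagotrophy control and an encounter factor ∝ predator
  ESD.  Maximum specific ingestion is 5 µ_max, sized so that a zooplankton
  at mid-stress sustains growth near µ_max given AE and SDA losses.
* **Digestion**: fraction 1 − AE voided (AE = 0.75); of the retained
  fraction, SDA = 0.30 released as CO₂/NH₄/PO₄; the rest is anabolate.
  Poor-quality (C-rich) food degrades the *carbon* assimilation
  efficiency by $\sqrt{\text{relative quality}}$ (stoichiometric
  ecology): halving prey N:C and P:C voids ~3.8× the default-run carbon,
  while N and P are always retained at AE.
* **SDA recycling**: $\text{recycled} = \min(\text{release},
  \text{concurrent demand})$ element-wise.  Photosynthetic CO₂ demand and
  transporter appetite absorb SDA releases before anything reaches the
  water, so an illuminated mixoplankton releases nothing while a
  zooplankton releases everything — the core mechanism distinguishing the
  trophic strategies' pH signatures.
* **Maintenance**: basal respiration 0.15 µ_max (chosen jointly with AE
  and SDA so the zero-net-DIC balance point sits at ≈3 C ingested per C
  fixed), carrying allied NH₄/PO₄ regeneration at the current quota so
  catabolism is stoichiometrically neutral; DOC leak = 10% of gross
  fixation plus 5% of anabolate; stoichiometric overflow (excess C to
  DOC) and excess regeneration (N/P to NH₄/PO₄) engage smoothly over the
  outer 5% of the quota range and exactly at its boundaries, so
  derivatives can never push a quota out of range.
* **Acquired phototrophy** (NCM types): capacity grows with ingested
  chloroplast material (plastids are sequestered whole, before digestion
  losses) and decays at 0.7 d⁻¹ (generalist) or 0.1 d⁻¹ (specialist);
  only the specialist synthesises Chl on retained plastids.  The decay
  magnitudes make generalist phototrophy fade within ~3 days of prey
  exhaustion while the specialist persists beyond run end; the gain rate
  (6) lets a feeding generalist reach ~95% capacity within half a day.
* **Zooplankton DOC recovery**: leaked DOC is slowly reabsorbed
  (first-order, 0.1 d⁻¹, biomass-scaled) by the zooplankton configuration
  only.

## Alkalinity and DIC forcing

Biological DIC change accumulates as respiration + external SDA CO₂ −
external CO₂ uptake.  TA changes by the standard nutrient charge balance:
+1 per mol NO₃ uptake, −1 per NH₄ uptake, +1 per PO₄ uptake, with release
as negative uptake (so heterotrophic ammonium regeneration raises TA and
damps the respiratory [H⁺] rise).  A pure CO₂ flux never moves TA.

# Carbonate chemistry

Constants on the total pH scale: CO₂ solubility (Weiss 1974), carbonic
acid (Lueker et al. 2000), borate (Dickson 1990), water (Millero 1995),
total borate ∝ salinity (Uppström 1974); validity enforced for T ∈ [0, 40]
°C, S ∈ [20, 40].  Speciation solves the alkalinity balance for [H⁺] with
Brent root-finding on pH over the fixed bracket [2, 12] plus a Newton
polish to a TA residual below 10⁻⁹ relative — deterministic and
bracket-safe.  Atmospheric equilibration fixes CO₂(aq) = K₀·pCO₂ and
solves the same balance for the equilibrium DIC.  The solver is validated
in the test suite against frozen values from an independent
implementation of the same published formulations (scipy-based,
`tools/carbonate_oracle.py`): pH agrees within 0.005 over DIC 1800–2400 ×
TA 2100–2500 µmol kg⁻¹, and equilibration round-trips pCO₂ to 10⁻⁶.
Biology (µg atom L⁻¹) and chemistry (µmol kg⁻¹) units are taken 1:1
(seawater density ≈ 1.025 ignored), keeping mass balance exact in a single
unit system.

# Proximal (near-cell) [H⁺]

Per-cell fluxes are population fluxes divided by cell abundance, with
cell carbon from ESD at a fixed 0.2 pg C µm⁻³ biovolume density.  Each
solute's surface offset follows the steady spherical-diffusion solution
$\Delta c = -F/(4\pi D r\, \mathrm{Sh})$ (diffusivities ~10⁻⁹ m² s⁻¹;
DIC treated with one effective value), applied to bulk DIC and — via the
nutrient charge balance — bulk TA, then re-speciated.  This is the pure
diffusion–Sherwood formulation; boundary-layer CO₂-hydration kinetics are
not modelled.  Sh = 1 represents the non-motile reference; the motile
default used in proximal-enabled runs is Sh = 2.  Because per-cell flux
scales with cell volume while the offset divides by radius, matched
biomass-specific physiology gives surface offsets ∝ ESD², which is why
250 µm cells see far larger proximal excursions than 20 µm cells.

# Scenarios: what the generator emulates

Defaults are the study conditions: NH₄ 10 µM, NO₃ 10 µM, PO₄ 1.25 µM
(Redfield DIN:DIP); non-growing 5 µm Redfield prey with 20 µg atom N L⁻¹
(hence 132.5 µg atom C L⁻¹) carrying chloroplast material equal to 10% of
prey C; PFD 500 (or 50 for the low-light variant) on a 0.7:0.3 light:dark
square wave; 15 °C, S 35, TA 2300 µmol kg⁻¹ (typical open-coast value;
not otherwise constrained, exposed as a parameter); pCO₂ ∈ {300, 600}
µatm; 20 days at 0.02 d output resolution.  The inoculum is 0.2 µg atom
C L⁻¹ at Redfield composition — with the default grazing capacity this
places prey exhaustion by the feeding types near day 10–12 of batch
growth, consistent with the multi-week bloom development the scenarios
represent.  The catalogue ids `fig3` (five types at defaults), `fig4`
(CM/phytoplankton × 20/250 µm with proximal output) and `fig5` (CM
priority, light and prey variants) assemble the standard comparisons.

What the generator does **not** emulate: community interactions and
succession, regrowing or multiple prey, bacterial remineralisation of the
DOC/VOC pools, diel vertical migration, calcification, osmotrophic DOM
use, and any [H⁺] feedback on physiology.  Passing tests therefore
demonstrate internal consistency and the trophic-strategy contrasts under
these idealised conditions, not predictive skill for natural bloom pH
trajectories.

# Numerical choices

* Integrator: `deSolve::lsoda`, rtol 10⁻⁸ / atol 10⁻¹⁰, restarted at
  every light/dark boundary so the square wave is never smeared across a
  step; the light level is constant within a segment.
* The solver may probe trial states slightly outside the quota bounds;
  rate evaluation clamps quotas (and capacity, and negative pools) for
  the flux computation only, preserving conservation exactly.
* Carbonate speciation is evaluated at output resolution only
  (downstream coupling); flux diagnostics are recomputed at output times
  from the stored states.
* Degenerate inputs: zero biomass returns zero fluxes; zero prey returns
  zero ingestion; a run is rejected if any conserved pool goes below
  −10⁻⁶ of the initial scale or the integrator fails, with the failing
  segment reported.

# Known limitations

* The exact functional forms (control sigmoids, P–I curve, encounter
  scaling, acquisition kinetics) are this package's own re-derivations of
  the behaviours the study system describes; trajectory details such as
  the precise day of prey exhaustion carry model-form uncertainty, and
  tests assert windows and orderings rather than exact days.
* DOC percentages across CM variants are emergent, not calibrated: the
  package reproduces the orderings (default > photo-priority >
  phago-priority; more voiding with more/poorer prey) but not the
  specific percent-of-default figures, which depend on unpublished model
  detail.  In the doubled-prey scenario this model produces *more* DOC
  than default (overflow from capped growth) rather than less.
* The low-light CM scenario develops only a weak bloom here: with both
  trophic modes under nutrient-status control, a C-starved (N-replete)
  cell also down-regulates feeding, so phagotrophy does not substitute
  for lost phototrophy as strongly as it might in nature.
* Proximal chemistry ignores reaction–diffusion corrections within the
  boundary layer and treats DIC with a single effective diffusivity.
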