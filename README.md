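# denitflux

Tools for quantifying denitrification-driven N₂O emission from flooded rice
paddies — for biogeochemists who measure dissolved greenhouse gases and
denitrification rates and want the whole calculation chain, from raw
headspace and incubation readings to annual areal emission and
functional-gene diagnostics, in one tested place.

## What it computes

**Dissolved-gas chemistry.** A water sample is equilibrated against a He
headspace; the original dissolved concentration is recovered from the
gas-phase reading by the static-headspace mass balance

    C_L = C_G (K₀ R T + V_G / V_L)

with K₀ the Weiss–Price N₂O solubility (a function of temperature and
salinity). The excess over air equilibrium, ΔN₂O = C_L − C_eq with
C_eq = F(T,S) · x_N₂O (x_N₂O = 331 ppb by default), drives the air–water
flux F = K · ΔN₂O, where K is a gas transfer velocity (constant, or a
wind-speed parameterization rescaled by the N₂O Schmidt number).

**Isotope pairing.** An anoxic slurry is spiked with ¹⁵NO₃⁻ so the nitrate
pool has ¹⁵N fraction f₁₅. Random pairing of N atoms during N₂ formation
implies ²⁹N₂/³⁰N₂ = 2(1−f₁₅)/f₁₅; the potential N₂ production rate is
R_N₂ = (D₂₉ + 2 P₃₀)/Δt, the N₂O emission rate is the vial N₂O accumulation
R_N₂O = (C_L2 − C_L0)/Δt converted to μmol N per kg of soil, and the
end-product ratio 100·R_N₂O/(R_N₂+R_N₂O) is the share of denitrification
leaving as N₂O rather than N₂.

**Upscaling.** Soil rates integrate over a 0.10 m surface layer
(bulk density 1.39 g cm⁻³ by default — a documented reconstruction, see the
vignette) and 8760 h; water fluxes over 365 d; both in mol and
g N₂O m⁻² yr⁻¹.

**Gene diagnostics.** qPCR standard curves gated on amplification
efficiency (90–110 %) and R² ≥ 0.97 before absolute quantification;
nirS/nirK, nosZ II/nosZ I and nir/nosZ abundance ratios; TPM-normalized
gene-centric metagenome profiles with nosZ clade I/II split by top-hit
majority vote; and per-taxon gene matrices that flag norB-carrying taxa
lacking nosZ — candidate net N₂O producers in a modular denitrifier
community.

**Synthetic data.** Seed-deterministic generators emit every input table
the pipeline consumes (field survey, incubation vials, qPCR plates,
annotated ORF tables) with ground-truth sidecars, so the full chain is
testable end to end.

## Worked example

```r
library(denitflux)

# highest-concentration paddy-water sample: 235.59 nmol/L at 33.8 degC, S = 2
ctx <- solubility_context(temperature_c = 33.8, salinity = 2)
delta_and_saturation(235.59, ctx)
#>   dissolved_nmol_l equilibrium_nmol_l delta_nmol_l saturation_pct
#> 1           235.59           6.079722     229.5103       3875.012

# flux at a piston velocity of 3.25 m/d, then annual water emission
f <- air_water_flux(229.5103, 3.25)   # 745.91 umol/m2/d
water_annual_emission(489.59)
#>   mol_m2_yr  g_m2_yr
#> 1 0.1787003 7.865139

# potential soil emission rate 0.51 umol N/kg/h -> annual soil emission
soil_annual_emission(0.51)
#>   mol_m2_yr  g_m2_yr
#> 1 0.3104982 13.66596
```

The water sample is ~39-fold supersaturated (ΔN₂O ≈ 229.5 nmol L⁻¹ above
equilibrium), and the two upscaling paths give ≈ 7.87 g (paddy water) and
≈ 13.67 g (surface soil) N₂O m⁻² yr⁻¹.

The full analysis chain lives under `analysis/` as numbered drivers
(`01_simulate.R` … `05_gene_profiles.R`); run them in order from the
repository root to regenerate every table under `results/`.

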