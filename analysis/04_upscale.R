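#!/usr/bin/env Rscript
# Stage 4: annual areal upscaling. Soil: the potential N2O emission rate is
# integrated over a 0.10 m surface layer at the documented bulk-density
# default (1.39 g/cm3) and 8760 h. Water: the daily air-water flux is scaled
# to 365 d. Both reported in mol and g N2O per m2 per year.

suppressPackageStartupMessages(library(denitflux))

rates <- read.csv("results/ipt_rates.csv")
flux <- read.csv("results/flux.csv")

soil <- soil_annual_emission(rates$r_n2o)
water <- water_annual_emission(flux$flux_umol_m2_d)
out <- data.frame(sample_id = rates$sample_id,
                  soil_mol_m2_yr = soil$mol_m2_yr,
                  soil_g_m2_yr = soil$g_m2_yr,
                  water_mol_m2_yr = water$mol_m2_yr,
                  water_g_m2_yr = water$g_m2_yr)
write.csv(out, "results/annual_upscaling.csv", row.names = FALSE)

cat(sprintf("soil:  %.2f +/- %.2f mol, %.2f +/- %.2f g N2O/m2/yr\n",
            mean(soil$mol_m2_yr), sd(soil$mol_m2_yr),
            mean(soil$g_m2_yr), sd(soil$g_m2_yr)))
cat(sprintf("water: %.2f +/- %.2f mol, %.2f +/- %.2f g N2O/m2/yr\n",
            mean(water$mol_m2_yr), sd(water$mol_m2_yr),
            mean(water$g_m2_yr), sd(water$g_m2_yr)))
cat("-> results/annual_upscaling.csv\n")
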