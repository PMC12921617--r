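#!/usr/bin/env Rscript
# Simulate the magnetic-field-cycling instrument backend: shield background
# scan, the nine shim-coil responses, and the solenoid / stray-field
# calibration tables, writing the interchange files the later steps read.

suppressPackageStartupMessages(library(fieldcycle))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 1)

## Unshimmed shield background: ~551 nT, mostly in the XY plane.
bg <- gen_shield_background(cfg)
write_field_profile(bg, "results/shield_background.csv")
h <- homogeneity_stats(bg)
cat(sprintf("background: mean %.1f nT, sd %.1f nT, rel SD %.1f%%\n",
            h$mean, h$sd, h$rel_sd))

## Solenoid field-to-current calibration at the 3.34% shield position:
## the layered-solenoid model gives ~6.8 mT/A.
currents <- seq(0, 3, length.out = 200)
fields_mT <- vapply(currents, gen_se_field, 1)
ctab <- build_field_to_current_table(fields_mT * 1e-3, currents)  # tesla
write_lookup_table(ctab, "results/field_to_current.json")
cat(sprintf("solenoid slope: %.2f mT/A (power at 3 A: %.1f W)\n",
            ctab$metadata$slope * 1e3, ohmic_power(3)))

## Stray-field flank of the NMR magnet: field-to-position table.
z <- seq(12000, 33000, length.out = 500)
stray <- field_profile(z, numeric(500), numeric(500),
                       9.4e9 * (z / 33000)^8)     # nT, steep monotone flank
ptab <- build_field_to_position_table(stray)
ptab$abscissa <- ptab$abscissa * 1e-9             # store in tesla
ptab$valid_range <- ptab$valid_range * 1e-9
write_lookup_table(ptab, "results/field_to_position.json")

## Field-setting plan across the three regimes.
targets <- c(1e-6, 5e-3, 1, 9.4)
plans <- lapply(targets, function(tg)
  plan_field_setting(tg, position_table = ptab, current_table = ctab))
plan_df <- data.frame(
  target_T = targets,
  regime = vapply(plans, `[[`, "", "regime"),
  position_usteps = round(vapply(plans, `[[`, 1, "position_usteps")),
  se_current_A = vapply(plans, `[[`, 1, "se_current_A"),
  zshim_offset_mA = vapply(plans, `[[`, 1, "zshim_offset_mA"))
write.csv(plan_df, "results/field_setting_plan.csv", row.names = FALSE)
print(plan_df)

## Shuttle kinematics: full 120.1 cm travel with the downward settings.
mp <- motion_profile(microsteps_to_mm(33000))
cat(sprintf("shuttle: %.1f mm in %.0f ms (idealized kinematic bound)\n",
            mp$distance, 1e3 * mp$total_time))
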