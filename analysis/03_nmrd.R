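#!/usr/bin/env Rscript
# NMRD of [1-13C]pyruvate: global biexponential decay fitting with a shared
# slow component, extraction of T1 per field, and the three-term
# dispersion-model fit, plus the INEPT time-saving bookkeeping.

suppressPackageStartupMessages(library(fieldcycle))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 1)
truth <- relax_model_params()     # canonical pyruvate parameter set

## Decay traces at 12 fields spanning 7.8 uT to 9.4 T, 1% noise.
fields <- 10^seq(log10(7.8e-6), log10(9.4), length.out = 12)
traces <- gen_nmrd_dataset(truth, fields = fields, noise = 0.01, cfg = cfg)
write_decay_csv(traces, "results/nmrd_decays.csv")

df <- fit_decays_global(traces)
cat(sprintf("global decay fit: shared tau2 = %.0f s, A2/A1 = %.3f\n",
            df$tau2_s, df$frac_A2))
curve <- nmrd_from_decay_fit(df)
write.csv(data.frame(field_T = curve$field_T, T1_s = curve$T1_s,
                     T1_err_s = curve$r1_err / curve$r1^2),
          "results/nmrd_curve.csv", row.names = FALSE)

## Dispersion-model fit (tau_CSA held: below ~10 T only delta^2 tau_CSA is
## identified).
fit <- fit_nmrd(curve)
pars <- fit$params
tab <- data.frame(
  parameter = c("domega1_rad_s", "domega2_rad_s", "tauc1_ns", "tauc2_ns",
                "delta_csa_ppm", "tau_csa_ps"),
  estimate = c(pars$domega1, pars$domega2, pars$tauc1 * 1e9,
               pars$tauc2 * 1e9, pars$delta_csa, pars$tau_csa * 1e12),
  ci95 = c(fit$ci95["domega1"], fit$ci95["domega2"],
           fit$ci95["tauc1"] * 1e9, fit$ci95["tauc2"] * 1e9,
           fit$ci95["delta_csa"], fit$ci95["tau_csa"] * 1e12))
write.csv(tab, "results/nmrd_fit_parameters.csv", row.names = FALSE)
print(tab, digits = 4)

## INEPT bookkeeping: signal gain 2.53, repeating at the 1H T1.
cat(sprintf("INEPT time reduction: %.1f-fold (gain 2.53, 45.5 s vs 4.9 s)\n",
            snr_time_reduction(2.53, 45.5, 4.9)))
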