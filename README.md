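# fieldcycle

Analysis toolkit for **magnetic field cycling (MFC) NMR** of hyperpolarized
tracers. An MFC instrument shuttles an NMR sample between the
spectrometer's 9.4 T isocenter and a shimmed mu-metal shield, so that
relaxation and polarization transfer can be studied at any field from a few
nanotesla to 9.4 T. This package implements the computations such a
platform needs, for spectroscopists working on dDNP and SABRE
hyperpolarization:

* **Shimming** — regularized least-squares optimization of nine shim-coil
  currents, minimizing `L = Σ‖B_b(z) + Σ I·μ_coil(z)‖² + α Σ I²` with its
  analytic gradient, Hessian-based 95% confidence intervals, and iterative
  X/Y/Z fine tuning against a field probe down to < 2 nT.
* **Field calibration** — field-to-position and field-to-current lookup
  tables, three-regime field planning (z-shim / solenoid / stray field),
  homogeneity statistics, and trapezoidal shuttle kinematics.
* **NMRD** — global biexponential decay fitting with a shared slow
  component, and the three-term dispersion model
  `R1(B) = Δω₁²τ_C1/(1+(ω τ_C1)²) + Δω₂²τ_C2/(1+(ω τ_C2)²) +
  (1/5)(ω δ_CSA)²τ_CSA/(1+(ω τ_CSA)²)`, with `ω = γ₁₃C·B`.
* **Transfer losses** — the retained-polarization integral
  `P(T)/P(0) = exp(−∫ dt/T1(B(t)))` over field-vs-time profiles, scenario
  comparison, and back-calculation of polarization at dissolution.
* **Exchange kinetics** — global shared-rate biexponential fitting of
  selective-inversion SABRE-SHEATH data and the two-equatorial-site rate
  constants `k_d = k/(0.5 + [Ir]/[Py]free)`, `k_a′ = ([Ir]/[Py]free)·k_d`.
* **Synthetic instrument** — seeded generators for every input kind, so
  the entire pipeline runs and is tested without hardware.

## Worked example

```r
library(fieldcycle)

## SABRE-SHEATH exchange: fit the shared biexponential, then the rate algebra
dat <- gen_exchange_traces(k = 5.77, R = 0.064, cfg = generator_config(seed = 1))
fit <- fit_exchange_global(dat)
rates <- derive_rate_constants(fit$k, conc_ir = 4, conc_py_total = 50,
                               k_se = fit$k_se)
sprintf("k = (%.2f ± %.2f) /s, k_d = (%.1f ± %.1f) /s, k_a' = (%.2f ± %.2f) /s",
        fit$k, fit$k_se, rates$k_d, rates$k_d_se,
        rates$k_a_prime, rates$k_a_prime_se)
#> "k = (5.86 ± 0.12) /s, k_d = (9.7 ± 0.2) /s, k_a' = (1.02 ± 0.02) /s"
```

The fitted effective exchange rate `k` is converted with the free-pyridine
concentration (50 − 3·4 = 38 mM): the pyridine dissociation rate constant
`k_d` and effective association rate `k_a′` follow from the two-equatorial-
site relations above.

```r
## Polarization bookkeeping
back_calculate_initial(27.3, 0.381)   # observed 27.3% after a 38.1% loss
#> 44.10339                            # % polarization at dissolution
snr_time_reduction(2.53, 45.5, 4.9)   # INEPT gain, 13C vs 1H repetition T1
#> 59.43693                            # ~60-fold shorter measurement
```

The numbered scripts under `analysis/` run the complete workflow on the
synthetic instrument (simulate + calibrate, shim, NMRD, transfer losses,
exchange) and write their tables under `results/`.

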