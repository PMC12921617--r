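## Seeded synthetic generators for every input kind the analysis consumes:
## shield background scans, shim-coil responses, NMRD decay data, transfer
## field profiles, exchange kinetics, and the solenoid field model. Each
## generator is a pure function of (config, seed): it derives a private
## substream seed and restores the caller's RNG state on exit.

#' Generator configuration
#'
#' One configuration object shared by all synthetic generators. The
#' defaults encode the study conditions the analysis assumes: a ~551 nT
#' background with ~8% relative SD mostly in the XY plane over a 36.4 cm
#' shield, a 108 nT/mA z-shim coil, 1 nT magnetometer noise, 2%
#' multiplicative relaxometry noise and 2% additive exchange noise.
#'
#' @param seed Root integer seed; per-generator substreams are derived
#'   from it, so one generator's draw count never perturbs another's.
#' @param background_nT Mean background field magnitude, nT.
#' @param background_rel_sd Target relative SD of the background
#'   magnitude (fraction).
#' @param shield_usteps Microstep extent of the shield scan (36.4 cm).
#' @param n_scan Points per scan (default 200).
#' @param noise_shield_nT Magnetometer noise per component, nT.
#' @param coil_nonlinearity Fractional response nonlinearity epsilon: the
#'   field at current I scales as mu*I*(1 + epsilon*I).
#' @param drift_nT_per_min Linear field drift during a scan, nT/min.
#' @param scan_minutes Duration ascribed to one scan (for drift).
#' @param noise_relax Multiplicative relaxometry noise (fraction).
#' @param noise_exchange Additive exchange noise (fraction of the maximum
#'   initial amplitude).
#' @param ambient_floor_T Ambient/Earth-field floor during transfer, T.
#' @param magnet_floor_T Field floor provided by transfer/receiver
#'   magnets, T.
#' @param polarizer_field_T Field at the polarizer exit, T.
#' @param transfer_total_s Total transfer duration, s.
#' @return Object of class `generator_config` (a list).
#' @export
generator_config <- function(seed = 1L,
                             background_nT = 551,
                             background_rel_sd = 0.08,
                             shield_usteps = 10000,
                             n_scan = 200L,
                             noise_shield_nT = 1,
                             coil_nonlinearity = 0,
                             drift_nT_per_min = 0,
                             scan_minutes = 5,
                             noise_relax = 0.02,
                             noise_exchange = 0.02,
                             ambient_floor_T = 50e-6,
                             magnet_floor_T = 10e-3,
                             polarizer_field_T = 3.35,
                             transfer_total_s = 19.5) {
  stopifnot(noise_shield_nT >= 0, noise_relax >= 0, noise_exchange >= 0,
            background_nT >= 0, background_rel_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

## Run expr under a derived substream seed, restoring the caller's RNG.
with_substream <- function(cfg, stream_id, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(cfg$seed) %% 20771L) * 100003L + stream_id)
  force(expr)
}

## smooth seeded unit-variance shape over a normalized coordinate
smooth_shape <- function(u, n_harm = 3L) {
  a <- stats::rnorm(n_harm) / seq_len(n_harm)
  ph <- stats::runif(n_harm, 0, 2 * pi)
  s <- rowSums(vapply(seq_len(n_harm), function(j)
    a[j] * sin(2 * pi * j * u + ph[j]), numeric(length(u))))
  sdv <- stats::sd(s)
  if (sdv == 0) s else s / sdv
}

#' Generate an unshimmed shield background profile
#'
#' Smooth low-order Fourier field components over the shield length with
#' most of the magnitude in the XY plane: component means ~(375, 395, 80)
#' nT scaled to `background_nT`, shared smooth variation sized so the
#' magnitude's relative SD is near `background_rel_sd`, plus per-component
#' magnetometer noise.
#'
#' @param cfg A [generator_config()].
#' @return A [field_profile()] with 200 samples over the shield.
#' @export
gen_shield_background <- function(cfg = generator_config()) {
  with_substream(cfg, 11L, {
    z <- seq(0, cfg$shield_usteps, length.out = cfg$n_scan)
    u <- z / cfg$shield_usteps
    scale <- cfg$background_nT / 551
    if (scale == 0)
      return(field_profile(z, rep(0, length(z)), rep(0, length(z)),
                           rep(0, length(z))))
    s_xy <- smooth_shape(u)          # shared XY-plane variation
    s_x <- smooth_shape(u); s_y <- smooth_shape(u); s_z <- smooth_shape(u)
    rv <- cfg$background_rel_sd
    bx <- 375 * (1 + rv * s_xy + 0.25 * rv * s_x) * scale
    by <- 395 * (1 + rv * s_xy + 0.25 * rv * s_y) * scale
    bz <- 80 * (1 + 2.5 * rv * s_z) * scale
    ns <- cfg$noise_shield_nT
    field_profile(z,
                  bx + stats::rnorm(length(z), 0, ns),
                  by + stats::rnorm(length(z), 0, ns),
                  bz + stats::rnorm(length(z), 0, ns))
  })
}

#' Generate the nine shim-coil unit responses
#'
#' Three near-uniform offset coils (one per component, the Z coil at
#' exactly 108 nT/mA), five gradient coils linear in z on their named
#' components (with small cross-components so the on-axis design matrix
#' stays full rank, as for real coils), and one quadratic Z coil with zero
#' mean over the shield length. Responses are the true (noise-free)
#' nT/mA profiles; use [gen_coil_scan()] for noisy calibration scans.
#'
#' @param cfg A [generator_config()].
#' @return Named list of nine [coil_response()]s.
#' @export
gen_coil_responses <- function(cfg = generator_config()) {
  z <- seq(0, cfg$shield_usteps, length.out = cfg$n_scan)
  u <- z / cfg$shield_usteps - 0.5           # centred coordinate
  zero <- numeric(length(z))
  quad <- u^2 - mean(u^2)                    # zero-mean quadratic
  resp <- list(
    "X"       = coil_response("X", z, 55 * (1 - 0.05 * u^2), zero, zero),
    "Y"       = coil_response("Y", z, zero, 50 * (1 - 0.05 * u^2), zero),
    "Z"       = coil_response("Z", z, zero, zero, rep(108, length(z))),
    "dY/dx"   = coil_response("dY/dx", z, 1.5 * u, 60 * u, zero),
    "dZ/dx"   = coil_response("dZ/dx", z, 20 * u, zero, 45 * u),
    "dZ/dy"   = coil_response("dZ/dy", z, zero, 20 * u, 55 * u),
    "dY/dy"   = coil_response("dY/dy", z, zero, 70 * u, 10 * u),
    "dZ/dz"   = coil_response("dZ/dz", z, zero, zero, 90 * u),
    "d2Z/dz2" = coil_response("d2Z/dz2", z, zero, zero, 400 * quad)
  )
  resp
}

#' Simulate a magnetometer scan with one coil energized
#'
#' Returns background + coil field at current `I` (with the configured
#' response nonlinearity: field = mu * I * (1 + epsilon * I)), plus
#' magnetometer noise and optional linear drift over the scan.
#'
#' @param response A [coil_response()] (true response).
#' @param background A [field_profile()] on the same grid.
#' @param current_mA Coil current, mA.
#' @param cfg A [generator_config()].
#' @param stream_id Substream discriminator so plus/minus scans differ.
#' @return A [field_profile()].
#' @export
gen_coil_scan <- function(response, background, current_mA,
                          cfg = generator_config(), stream_id = 21L) {
  stopifnot(inherits(response, "coil_response"),
            inherits(background, "field_profile"))
  with_substream(cfg, stream_id, {
    eff <- current_mA * (1 + cfg$coil_nonlinearity * current_mA)
    n <- length(background$position_usteps)
    drift <- cfg$drift_nT_per_min * cfg$scan_minutes *
      seq(0, 1, length.out = n)
    ns <- cfg$noise_shield_nT
    field_profile(background$position_usteps,
                  background$bx + response$mux * eff + drift +
                    stats::rnorm(n, 0, ns),
                  background$by + response$muy * eff + drift +
                    stats::rnorm(n, 0, ns),
                  background$bz + response$muz * eff + drift +
                    stats::rnorm(n, 0, ns))
  })
}

#' Simulated field probe at the sample position
#'
#' Closure emulating the vector magnetometer at z_sample for the
#' iterative X/Y/Z tuner: returns the 3-component field (nT) for given
#' X/Y/Z currents on top of a fixed residual field, with optional probe
#' noise and an optional constant solenoid-remanence offset.
#'
#' @param residual 3-vector residual field at z_sample after simulative
#'   shimming, nT.
#' @param sens 3x3 sensitivity matrix (nT/mA); default diagonal
#'   (55, 50, 108) as for the offset coils at the shield centre.
#' @param noise_nT Probe noise sd per component.
#' @param se_remanence_nT Constant additive z offset emulating residual
#'   solenoid magnetization (default 0; about 200 nT when enabled).
#' @param cfg A [generator_config()] (for the seed).
#' @return Function `currents3 -> field3` (nT).
#' @export
gen_probe <- function(residual, sens = diag(c(55, 50, 108)),
                      noise_nT = 0, se_remanence_nT = 0,
                      cfg = generator_config()) {
  offset <- c(0, 0, se_remanence_nT)
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  function(currents3) {
    b <- residual + as.vector(sens %*% currents3) + offset
    if (noise_nT > 0) {
      counter$i <- counter$i + 1L
      b <- b + with_substream(cfg, 31L + counter$i,
                              stats::rnorm(3, 0, noise_nT))
    }
    b
  }
}

#' Generate synthetic NMRD decay traces
#'
#' Per field B, the fast time constant is T1 = 1/[nmrd_model()](B); traces
#' follow A1 exp(-t/T1) + A2 exp(-t/tau2) + y0 with a shared slow tau2, a
#' shared A2/A1 fraction, thermal baseline y0 proportional to B, and
#' multiplicative Gaussian noise.
#'
#' @param params A [relax_model_params()] ground truth.
#' @param fields Fields, T (default 30 log-spaced from 7.8 uT to 9.4 T).
#' @param vd_grid Function `T1 -> delays` or fixed delay vector; default
#'   12 delays spanning 0--4 T1.
#' @param noise Multiplicative noise fraction (default from cfg).
#' @param cfg A [generator_config()].
#' @param A1 Initial amplitude.
#' @param frac_A2 Shared A2/A1 fraction.
#' @param tau2_s Shared slow time constant, s.
#' @param y0_per_T Thermal baseline per tesla (y0 = y0_per_T * B).
#' @return List of [decay_trace()]s.
#' @export
gen_nmrd_dataset <- function(params = relax_model_params(),
                             fields = 10^seq(log10(7.8e-6), log10(9.4),
                                             length.out = 30),
                             vd_grid = NULL,
                             noise = NULL,
                             cfg = generator_config(),
                             A1 = 1, frac_A2 = 0.05, tau2_s = 200,
                             y0_per_T = 0.002) {
  stopifnot(all(fields >= 1e-9), all(fields <= 20))
  if (is.null(noise)) noise <- cfg$noise_relax
  with_substream(cfg, 41L, {
    lapply(fields, function(B) {
      T1 <- 1 / nmrd_model(B, params)
      delays <- if (is.null(vd_grid))
        T1 * c(0, 0.1, 0.25, 0.45, 0.7, 1, 1.35, 1.75, 2.2, 2.7, 3.3, 4)
      else if (is.function(vd_grid)) vd_grid(T1) else vd_grid
      sig <- A1 * exp(-delays / T1) + frac_A2 * A1 * exp(-delays / tau2_s) +
        y0_per_T * B
      if (noise > 0)
        sig <- sig * (1 + stats::rnorm(length(sig), 0, noise))
      decay_trace(B, delays, sig,
                  signal_errors = if (noise > 0)
                    rep(noise * A1, length(sig)) else NULL)
    })
  })
}

#' Generate a noisy NMRD curve directly
#'
#' R1(B) from the three-term model with multiplicative Gaussian noise --
#' the direct input for dispersion-model recovery studies that bypass the
#' decay-fitting stage.
#'
#' @inheritParams gen_nmrd_dataset
#' @return An [nmrd_curve()].
#' @export
gen_nmrd_curve <- function(params = relax_model_params(),
                           fields = 10^seq(log10(7.8e-6), log10(9.4),
                                           length.out = 30),
                           noise = 0.02,
                           cfg = generator_config()) {
  with_substream(cfg, 43L, {
    r1 <- nmrd_model(fields, params)
    r1n <- r1 * (1 + stats::rnorm(length(r1), 0, noise))
    r1n <- pmax(r1n, 1e-12)
    nmrd_curve(fields, r1n,
               r1_err = if (noise > 0) noise * r1 else NULL)
  })
}

#' Generate a transfer field profile for a named scenario
#'
#' Piecewise-smooth stylized stand-in for the measured transfer profiles:
#' exponential decay from the polarizer stray field to the ambient floor,
#' a low-field transport segment, and an exponential rise into the NMR
#' stray field, over `transfer_total_s` (default 19.5 s). Magnet
#' scenarios floor designated segments at `magnet_floor_T`:
#' `transfer_magnet` covers the transport leg, `transfer_plus_receiver`
#' additionally covers the receiver/dissolution segment, so the three
#' scenarios dominate each other pointwise.
#'
#' @param scenario One of `"no_magnet"`, `"transfer_magnet"`,
#'   `"transfer_plus_receiver"`.
#' @param cfg A [generator_config()].
#' @param n Samples over the profile.
#' @return A [transfer_profile()].
#' @export
gen_transfer_profile <- function(scenario = c("no_magnet", "transfer_magnet",
                                              "transfer_plus_receiver"),
                                 cfg = generator_config(), n = 400L) {
  scenario <- match.arg(scenario)
  Ttot <- cfg$transfer_total_s
  t <- seq(0, Ttot, length.out = n)
  floor_T <- cfg$ambient_floor_T
  Bpol <- cfg$polarizer_field_T
  ## polarizer stray decay (tau 0.4 s) and NMR stray rise (tau 0.3 s)
  b <- floor_T + (Bpol - floor_T) * exp(-t / 0.4) +
    (9.4 - floor_T) * exp((t - Ttot) / 0.3)
  if (scenario %in% c("transfer_magnet", "transfer_plus_receiver")) {
    seg <- t >= 2.5 & t <= Ttot - 2
    b[seg] <- pmax(b[seg], cfg$magnet_floor_T)
  }
  if (scenario == "transfer_plus_receiver") {
    seg <- t < 2.5
    b[seg] <- pmax(b[seg], cfg$magnet_floor_T)
  }
  ## endpoints pinned to the polarizer and NMR fields
  b[1] <- max(b[1], Bpol)
  b[n] <- 9.4
  transfer_profile(t, b, label = scenario)
}

## default amplitudes from the two-site populations (38 mM free, 8 mM
## exchangeable bound): weighted mean after fast equilibration
default_exchange_amplitudes <- function(p_free = 38 / 46) {
  p_bound <- 1 - p_free
  mbar_f <- -p_free + p_bound   # after inverting free
  mbar_b <- p_free - p_bound    # after inverting bound
  list(free_inv_free   = c(A1 = -1 - mbar_f, A2 = mbar_f),
       free_inv_bound  = c(A1 = 1 - mbar_f, A2 = mbar_f),
       bound_inv_free  = c(A1 = 1 - mbar_b, A2 = mbar_b),
       bound_inv_bound = c(A1 = -1 - mbar_b, A2 = mbar_b))
}

#' Generate selective-inversion exchange kinetics
#'
#' Four series from the shared biexponential
#' A1 exp(-tau k) + A2 exp(-tau R) with per-series amplitudes (defaults
#' from the two-site populations at 38 mM free / 8 mM exchangeable bound
#' pyridine) and additive Gaussian noise scaled to the maximum initial
#' amplitude.
#'
#' @param k Effective exchange rate, s^-1 (> R).
#' @param R Effective relaxation rate, s^-1 (> 0).
#' @param amplitudes Named list of `c(A1, A2)` per series.
#' @param tau_grid Delays, s. The default is 16 delays over 0--50 s with
#'   geometric early spacing, so that both the fast exchange decay (1/k,
#'   sub-second) and the slow relaxation tail are sampled -- the design a
#'   selective-inversion experiment needs.
#' @param noise Additive noise fraction (default from cfg).
#' @param cfg A [generator_config()].
#' @return An [exchange_dataset()].
#' @export
gen_exchange_traces <- function(k = 5.77, R = 0.064,
                                amplitudes = default_exchange_amplitudes(),
                                tau_grid = c(0, 0.05, 0.1, 0.2, 0.35, 0.6,
                                             1, 1.6, 2.5, 4, 6.5, 10, 16,
                                             25, 38, 50),
                                noise = NULL,
                                cfg = generator_config()) {
  stopifnot(k > R, R > 0)
  if (is.null(noise)) noise <- cfg$noise_exchange
  with_substream(cfg, 51L, {
    amax <- max(vapply(amplitudes, function(a) abs(sum(a)), 1))
    series <- lapply(amplitudes, function(a) {
      s <- a[["A1"]] * exp(-tau_grid * k) + a[["A2"]] * exp(-tau_grid * R)
      if (noise > 0) s <- s + stats::rnorm(length(s), 0, noise * amax)
      s
    })
    exchange_dataset(tau_grid, series)
  })
}

#' On-axis field of the layered solenoid electromagnet
#'
#' Finite-solenoid on-axis formula summed over the winding layers
#' (default: length 300 mm, six layers of 273 turns, 1 mm wire on a
#' 15.7 mm inner radius). Linear in current.
#'
#' @param current Current, A.
#' @param z Axial offset from the solenoid centre, m (default 0).
#' @param length_m Winding length, m.
#' @param layers Number of layers.
#' @param turns_per_layer Turns per layer.
#' @param wire_d_m Wire diameter, m.
#' @param r_inner_m Innermost layer radius, m.
#' @return Field in mT.
#' @export
gen_se_field <- function(current, z = 0, length_m = 0.3, layers = 6L,
                         turns_per_layer = 273L, wire_d_m = 1e-3,
                         r_inner_m = 0.0157) {
  stopifnot(is.finite(current))
  n_lin <- turns_per_layer / length_m      # turns per metre per layer
  half <- length_m / 2
  b <- 0
  for (l in seq_len(layers)) {
    r <- r_inner_m + (l - 0.5) * wire_d_m
    b <- b + (MU0 * n_lin * current / 2) *
      ((z + half) / sqrt((z + half)^2 + r^2) -
         (z - half) / sqrt((z - half)^2 + r^2))
  }
  b * 1e3
}
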