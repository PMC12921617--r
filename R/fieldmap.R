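## Field-profile containers, calibration lookup tables, homogeneity
## statistics and shuttle kinematics.

#' Convert stepper microsteps to millimetres
#'
#' The shuttle drive is calibrated at 48000 microsteps per 1747.2 mm, so one
#' microstep is 1747.2/48000 mm (~0.0364 mm). The conversion uses the exact
#' rational factor, not a rounded constant.
#'
#' @param n Non-negative microstep count(s).
#' @return Length in mm.
#' @export
#' @examples
#' microsteps_to_mm(48000)   # 1747.2
#' microsteps_to_mm(33000)   # 1201.2 (the full shuttle travel, 120.12 cm)
microsteps_to_mm <- function(n) {
  stopifnot(is.numeric(n))
  if (any(n < 0)) stop("microstep counts must be non-negative")
  n * MM_PER_MICROSTEP
}

#' Construct a sampled magnetic field profile
#'
#' A `field_profile` stores 3-component field samples along the shuttle
#' axis. Positions are in microsteps (0 = outside/homing switch, 33000 = B0
#' isocenter); percent and mm coordinates and the field magnitude are
#' derived.
#'
#' @param position_usteps Strictly increasing axial positions, microsteps.
#' @param bx,by,bz Field components in nT.
#' @return A data frame of class `field_profile` with columns
#'   `position_usteps`, `percent`, `mm`, `bx`, `by`, `bz`, `magnitude`.
#' @export
field_profile <- function(position_usteps, bx, by, bz) {
  stopifnot(length(position_usteps) == length(bx),
            length(bx) == length(by), length(by) == length(bz))
  if (any(!is.finite(position_usteps))) stop("positions must be finite")
  if (is.unsorted(position_usteps, strictly = TRUE))
    stop("positions must be strictly increasing")
  out <- data.frame(
    position_usteps = position_usteps,
    percent = position_usteps / MICROSTEPS_TOTAL * 100,
    mm = position_usteps * MM_PER_MICROSTEP,
    bx = bx, by = by, bz = bz,
    magnitude = sqrt(bx^2 + by^2 + bz^2)
  )
  class(out) <- c("field_profile", class(out))
  out
}

#' Read / write field-profile CSV
#'
#' CSV dialect: header `position_usteps,bx_nT,by_nT,bz_nT`, '.' decimal.
#'
#' @param path File path.
#' @return `read_field_profile` returns a [field_profile()].
#' @export
read_field_profile <- function(path) {
  d <- utils::read.csv(path)
  need <- c("position_usteps", "bx_nT", "by_nT", "bz_nT")
  if (!all(need %in% names(d)))
    stop("field-profile CSV must have columns: ", paste(need, collapse = ", "))
  field_profile(d$position_usteps, d$bx_nT, d$by_nT, d$bz_nT)
}

#' @rdname read_field_profile
#' @param profile A [field_profile()].
#' @export
write_field_profile <- function(profile, path) {
  utils::write.csv(
    data.frame(position_usteps = profile$position_usteps,
               bx_nT = profile$bx, by_nT = profile$by, bz_nT = profile$bz),
    path, row.names = FALSE)
  invisible(path)
}

## Largest strictly monotone (in y) index run of a sequence.
largest_monotone_run <- function(y) {
  n <- length(y)
  if (n < 2L) return(seq_len(n))
  s <- sign(diff(y))
  best <- c(1L, 1L); start <- 1L
  for (i in seq_len(n - 1L)) {
    ok <- s[i] != 0 && (i == start || s[i] == s[start])
    if (!ok) {
      if (i - start >= best[2L] - best[1L]) best <- c(start, i)
      start <- i
    }
    if (i == n - 1L && ok) {
      if (i + 1L - start > best[2L] - best[1L]) best <- c(start, i + 1L)
    }
  }
  seq.int(best[1L], best[2L])
}

new_lookup_table <- function(kind, abscissa, ordinate, metadata = list()) {
  structure(list(kind = kind, abscissa = abscissa, ordinate = ordinate,
                 valid_range = range(abscissa), metadata = metadata),
            class = "lookup_table")
}

#' Build a field-to-position lookup table
#'
#' Inverts a measured field-vs-position profile over its largest strictly
#' monotone region (the stray-field flank). Plateaus -- such as the one near
#' the isocenter -- are excluded from the invertible range with a warning.
#' With a list of per-current profiles a table family is returned, one
#' invertible table per solenoid current.
#'
#' @param profiles A [field_profile()] or list of them.
#' @param currents Solenoid currents (A), one per profile; required when
#'   `profiles` is a list of length > 1.
#' @return A `lookup_table` (kind `field_to_position`), or a
#'   `lookup_family` when several currents are supplied.
#' @export
build_field_to_position_table <- function(profiles, currents = NULL) {
  if (inherits(profiles, "field_profile")) {
    prof <- profiles
    idx <- largest_monotone_run(prof$magnitude)
    if (length(idx) < length(prof$magnitude))
      warning("profile not monotone over its full range; ",
              "lookup restricted to the largest strictly monotone region")
    if (length(idx) < 2L) stop("no invertible region in profile")
    mag <- prof$magnitude[idx]; pos <- prof$position_usteps[idx]
    if (mag[1] > mag[length(mag)]) { mag <- rev(mag); pos <- rev(pos) }
    return(new_lookup_table("field_to_position", mag, pos,
                            metadata = list(units = c(abscissa = "nT",
                                                      ordinate = "usteps"))))
  }
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (length(profiles) == 1L) return(build_field_to_position_table(profiles[[1L]]))
  if (is.null(currents) || length(currents) != length(profiles))
    stop("one current per profile required")
  tabs <- lapply(profiles, build_field_to_position_table)
  structure(list(currents = currents, tables = tabs),
            class = "lookup_family")
}

#' Build a field-to-current lookup table
#'
#' Piecewise-linear inverse mapping from a solenoid calibration (field
#' measured at the fixed shield position for a ramp of currents). The fitted
#' linear slope (field per ampere) is stored as metadata.
#'
#' @param fields Calibrated field values (same units throughout, e.g. mT).
#' @param currents Strictly increasing currents (A).
#' @return A `lookup_table` of kind `field_to_current`.
#' @export
build_field_to_current_table <- function(fields, currents) {
  stopifnot(length(fields) == length(currents), length(currents) >= 2L)
  if (anyDuplicated(currents)) stop("duplicate currents in calibration")
  if (is.unsorted(currents, strictly = TRUE))
    stop("currents must be strictly increasing")
  slope <- unname(stats::coef(stats::lm(fields ~ currents))[2L])
  idx <- largest_monotone_run(fields)
  f <- fields[idx]; i <- currents[idx]
  if (f[1] > f[length(f)]) { f <- rev(f); i <- rev(i) }
  new_lookup_table("field_to_current", f, i,
                   metadata = list(slope = slope,
                                   units = c(slope = "field/A")))
}

#' Query a lookup table
#'
#' Monotone (Hermite) interpolation inside the calibrated range; queries
#' outside `valid_range` are rejected -- no extrapolation.
#'
#' @param table A `lookup_table`, or a `lookup_family` (then `current`
#'   selects the nearest calibrated member).
#' @param x Query value(s) on the abscissa (field).
#' @param current For a `lookup_family`: the solenoid current whose table to
#'   use.
#' @return Interpolated ordinate values (position or current).
#' @export
lookup_query <- function(table, x, current = NULL) {
  if (inherits(table, "lookup_family")) {
    if (is.null(current)) stop("a current must name the family member")
    k <- which.min(abs(table$currents - current))
    return(lookup_query(table$tables[[k]], x))
  }
  stopifnot(inherits(table, "lookup_table"))
  r <- table$valid_range
  if (any(x < r[1] | x > r[2]))
    stop(sprintf("query outside calibrated range [%g, %g]", r[1], r[2]))
  if (length(table$abscissa) == 2L)
    return(stats::approx(table$abscissa, table$ordinate, xout = x)$y)
  stats::splinefun(table$abscissa, table$ordinate, method = "monoH.FC")(x)
}

#' Plan actuator settings for a target field
#'
#' Three regimes cover nine decades of field: the shield z-shim coil for
#' |B| <= 3.16 uT, the solenoid electromagnet (at the fixed 3.34% shield
#' position) up to 12 mT, and the NMR stray field (position along the
#' shuttle axis) above that. Exactly one actuator departs from its default
#' per regime.
#'
#' @param target Target field, tesla.
#' @param position_table `lookup_table` of kind `field_to_position` with
#'   abscissa in tesla (stray-field flank).
#' @param current_table `lookup_table` of kind `field_to_current` with
#'   abscissa in tesla.
#' @param zshim_slope_nT_per_mA z-shim coil calibration (default 108).
#' @param zshim_position_usteps Shield sweet-spot position used in the
#'   z-shim regime (default 5.35% of travel).
#' @return List with `regime` (`"zshim"`, `"solenoid"` or `"stray"`),
#'   `position_usteps`, `se_current_A`, `zshim_offset_mA`.
#' @export
plan_field_setting <- function(target, position_table = NULL,
                               current_table = NULL,
                               zshim_slope_nT_per_mA = 108,
                               zshim_position_usteps = round(0.0535 * MICROSTEPS_TOTAL)) {
  stopifnot(is.numeric(target), length(target) == 1L, target >= 0)
  solenoid_position <- round(0.0334 * MICROSTEPS_TOTAL)
  if (target <= 3.16e-6) {
    list(regime = "zshim",
         position_usteps = zshim_position_usteps,
         se_current_A = 0,
         zshim_offset_mA = target * 1e9 / zshim_slope_nT_per_mA)
  } else if (target <= 12e-3) {
    if (is.null(current_table)) stop("solenoid regime requires current_table")
    list(regime = "solenoid",
         position_usteps = solenoid_position,
         se_current_A = lookup_query(current_table, target),
         zshim_offset_mA = 0)
  } else {
    if (is.null(position_table)) stop("stray regime requires position_table")
    if (target > position_table$valid_range[2])
      stop("target exceeds the maximum calibrated stray field")
    list(regime = "stray",
         position_usteps = lookup_query(position_table, target),
         se_current_A = 0,
         zshim_offset_mA = 0)
  }
}

#' Homogeneity statistics over a sample range
#'
#' Mean, median and standard deviation of the field magnitude over the
#' samples inside `sample_range`, plus the relative SD (sd/median, %) and
#' the median-mean deviation (|median-mean|/mean, %) used to characterize
#' sample-range homogeneity.
#'
#' @param profile A [field_profile()].
#' @param sample_range Inclusive `c(lo, hi)` interval in microsteps;
#'   defaults to the full profile.
#' @return List with `mean`, `median`, `sd`, `rel_sd`, `median_mean_dev`,
#'   `n`.
#' @export
homogeneity_stats <- function(profile, sample_range = NULL) {
  stopifnot(inherits(profile, "field_profile"))
  if (is.null(sample_range))
    sample_range <- range(profile$position_usteps)
  keep <- profile$position_usteps >= sample_range[1] &
    profile$position_usteps <= sample_range[2]
  m <- profile$magnitude[keep]
  if (length(m) < 3L) stop("need at least 3 samples inside sample_range")
  mu <- mean(m); md <- stats::median(m); s <- stats::sd(m)
  list(mean = mu, median = md, sd = s,
       rel_sd = s / md * 100,
       median_mean_dev = abs(md - mu) / mu * 100,
       n = length(m))
}

#' Trapezoidal shuttle motion profile
#'
#' Kinematics of the stepper-driven shuttle: constant acceleration up to
#' `vmax`, optional cruise, symmetric deceleration. If the distance is too
#' short to reach `vmax` the profile is triangular.
#'
#' @param distance Travel in mm (>= 0).
#' @param accel Acceleration, mm/s^2 (default 6552, the downward setting).
#' @param vmax Maximum velocity, mm/s (default 1747.2).
#' @return Object of class `motion_profile`: distance, accel, vmax,
#'   `phase_times` (ramp-up, cruise, ramp-down, s), `total_time`,
#'   `triangular` flag, and closed-form `position(t)`/`velocity(t)`
#'   functions.
#' @export
motion_profile <- function(distance, accel = 6552, vmax = 1747.2) {
  stopifnot(distance >= 0, accel > 0, vmax > 0)
  d_ramp <- vmax^2 / accel      # distance consumed by ramp-up + ramp-down
  if (distance < d_ramp) {
    v_peak <- sqrt(distance * accel)
    t_ramp <- v_peak / accel
    phase <- c(ramp_up = t_ramp, cruise = 0, ramp_down = t_ramp)
  } else {
    v_peak <- vmax
    t_ramp <- vmax / accel
    t_cruise <- (distance - d_ramp) / vmax
    phase <- c(ramp_up = t_ramp, cruise = t_cruise, ramp_down = t_ramp)
  }
  total <- sum(phase)
  t1 <- phase[["ramp_up"]]; t2 <- t1 + phase[["cruise"]]
  velocity <- function(t) {
    t <- pmin(pmax(t, 0), total)
    ifelse(t <= t1, accel * t,
           ifelse(t <= t2, v_peak, pmax(v_peak - accel * (t - t2), 0)))
  }
  position <- function(t) {
    t <- pmin(pmax(t, 0), total)
    p1 <- 0.5 * accel * pmin(t, t1)^2
    p2 <- v_peak * pmax(pmin(t, t2) - t1, 0)
    td <- pmax(t - t2, 0)
    p3 <- v_peak * td - 0.5 * accel * td^2
    p1 + p2 + p3
  }
  structure(list(distance = distance, accel = accel, vmax = vmax,
                 phase_times = phase, total_time = total,
                 triangular = distance < d_ramp,
                 position = position, velocity = velocity),
            class = "motion_profile")
}

#' Field experienced during shuttle motion
#'
#' Composes the motion profile's position(t) with a (spline-interpolated)
#' field-vs-position profile to give the field-vs-time profile experienced
#' by the sample -- the input to polarization-loss integrals.
#'
#' @param motion A [motion_profile()].
#' @param field_vs_position A [field_profile()] covering the travelled
#'   range.
#' @param dt Sampling step, s (> 0).
#' @param start_usteps Starting position, microsteps (default 0).
#' @param direction +1 for increasing positions, -1 for decreasing.
#' @return A [transfer_profile()] (times in s, fields in nT).
#' @export
field_during_motion <- function(motion, field_vs_position, dt,
                                start_usteps = 0, direction = 1) {
  stopifnot(inherits(motion, "motion_profile"),
            inherits(field_vs_position, "field_profile"))
  if (dt <= 0) stop("dt must be positive")
  tt <- unique(c(seq(0, motion$total_time, by = dt), motion$total_time))
  pos_mm <- motion$position(tt)
  pos_usteps <- start_usteps + direction * pos_mm / MM_PER_MICROSTEP
  pr <- range(field_vs_position$position_usteps)
  if (min(pos_usteps) < pr[1] - 1e-9 || max(pos_usteps) > pr[2] + 1e-9)
    stop("motion leaves the extent of the field profile")
  f <- stats::splinefun(field_vs_position$position_usteps,
                        field_vs_position$magnitude, method = "natural")
  b <- f(pos_usteps)
  ## endpoints exact: clamp the first/last samples to tabulated values
  hit <- function(p) {
    j <- which(abs(field_vs_position$position_usteps - p) < 1e-9)
    if (length(j)) field_vs_position$magnitude[j[1]] else NA_real_
  }
  b1 <- hit(pos_usteps[1]); bn <- hit(pos_usteps[length(pos_usteps)])
  if (!is.na(b1)) b[1] <- b1
  if (!is.na(bn)) b[length(b)] <- bn
  transfer_profile(tt, b * 1e-9, label = "motion")
}
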