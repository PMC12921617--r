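test_that("microstep-mm conversion uses the exact drive ratio and is linear", {
  expect_equal(microsteps_to_mm(48000), 1747.2)
  expect_equal(microsteps_to_mm(0), 0)
  expect_equal(microsteps_to_mm(33000), 1201.2)   # full travel, 120.12 cm
  # linearity f(a+b) = f(a) + f(b)
  set.seed(1)
  a <- sample(0:50000, 25); b <- sample(0:50000, 25)
  expect_equal(microsteps_to_mm(a + b),
               microsteps_to_mm(a) + microsteps_to_mm(b))
  expect_error(microsteps_to_mm(-1), "non-negative")
})

test_that("field profiles derive magnitude and percent and reject bad grids", {
  p <- field_profile(c(0, 16500, 33000), c(3, 0, 0), c(4, 0, 0), c(0, 5, 1))
  expect_equal(p$magnitude, c(5, 5, 1))
  expect_equal(p$percent, c(0, 50, 100))
  expect_equal(p$mm, c(0, 16500, 33000) * 1747.2 / 48000)
  expect_error(field_profile(c(0, 0, 1), 1:3, 1:3, 1:3), "strictly increasing")
})

test_that("field-to-position lookup inverts monotone profiles and excludes plateaus", {
  # identity inversion on a linear profile B(z) = z
  z <- seq(0, 1, length.out = 50)
  lin <- field_profile(z * 33000, rep(0, 50), rep(0, 50), z)
  tab <- build_field_to_position_table(lin)
  expect_equal(lookup_query(tab, 0.5), 0.5 * 33000, tolerance = 1e-9)

  # exponential stray profile: round trip against a dense brute-force oracle
  prof <- stray_field_profile()
  tab <- build_field_to_position_table(prof)
  zq <- seq(1000, 29000, length.out = 23)
  bq <- 100 * exp(zq / 6000)                     # oracle: forward map
  expect_lt(max(abs(lookup_query(tab, bq) - zq)), 0.5)

  # plateau near the isocenter is excluded from the invertible range
  zp <- seq(0, 33000, length.out = 100)
  bp <- pmin(100 * exp(zp / 5000), 100 * exp(28000 / 5000))
  plat <- field_profile(zp, rep(0, 100), rep(0, 100), bp)
  expect_warning(tabp <- build_field_to_position_table(plat), "monotone")
  expect_lt(tabp$valid_range[2], max(bp) + 1)
  expect_error(lookup_query(tabp, max(bp) * 1.5), "outside")
})

test_that("field-to-current lookup reports the solenoid slope and inverts", {
  cur <- seq(0, 3, length.out = 20)
  tab <- build_field_to_current_table(7.1 * cur, cur)
  expect_equal(tab$metadata$slope, 7.1, tolerance = 1e-9)
  expect_equal(lookup_query(tab, 12), 12 / 7.1, tolerance = 1e-6)
  expect_equal(lookup_query(tab, 0), 0, tolerance = 1e-12)
  tab2 <- build_field_to_current_table(c(0, 7.1), c(0, 1))
  expect_equal(tab2$metadata$slope, 7.1)
  expect_error(build_field_to_current_table(c(0, 1, 2), c(0, 0, 1)),
               "duplicate|increasing")
})

test_that("field planning picks the zshim / solenoid / stray regime", {
  cur <- seq(0, 3, length.out = 50)
  ctab <- build_field_to_current_table(7.1e-3 * cur, cur)   # tesla
  z <- seq(15000, 33000, length.out = 200)
  ptab <- build_field_to_position_table(
    field_profile(z, rep(0, 200), rep(0, 200),
                  9.4e9 * (z / 33000)^8))          # nT-scale stray flank
  # abscissa rescaled to tesla for planning
  ptab$abscissa <- ptab$abscissa * 1e-9
  ptab$valid_range <- ptab$valid_range * 1e-9

  hi <- plan_field_setting(9.4, position_table = ptab)
  expect_identical(hi$regime, "stray")
  expect_equal(hi$position_usteps, 33000, tolerance = 1e-3)

  lo <- plan_field_setting(1e-6)
  expect_identical(lo$regime, "zshim")
  expect_equal(lo$position_usteps, round(0.0535 * 33000))
  expect_equal(lo$zshim_offset_mA, 1000 / 108, tolerance = 1e-9)

  mid <- plan_field_setting(5e-3, current_table = ctab)
  expect_identical(mid$regime, "solenoid")
  expect_equal(mid$se_current_A, 5 / 7.1, tolerance = 1e-3)
  expect_equal(mid$position_usteps, round(0.0334 * 33000))

  expect_error(plan_field_setting(20, position_table = ptab), "exceeds")
})

test_that("homogeneity statistics match their definitions", {
  # symmetric three-point magnitude set: sd = 42.4, mean = median = 551.4
  p <- field_profile(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0),
                     551.4 + 42.4 * c(-1, 0, 1))
  h <- homogeneity_stats(p)
  expect_equal(h$rel_sd, 42.4 / 551.4 * 100, tolerance = 1e-12)
  expect_equal(round(h$rel_sd), 8)         # the ~8% relative SD regime
  expect_equal(h$median_mean_dev, 0)

  pc <- field_profile(1:5, rep(0, 5), rep(0, 5), rep(100, 5))
  hc <- homogeneity_stats(pc)
  expect_equal(hc$sd, 0)
  expect_equal(hc$rel_sd, 0)
  expect_equal(hc$median_mean_dev, 0)

  # symmetric linear ramp (odd length): median equals mean exactly
  pr <- field_profile(1:11, rep(0, 11), rep(0, 11), seq(10, 20, 1))
  hr <- homogeneity_stats(pr)
  expect_identical(hr$median, hr$mean)

  expect_error(homogeneity_stats(pc, c(100, 200)), "3 samples")
})

test_that("relative SD converges to the population value on iid samples", {
  set.seed(7)
  n <- 1e4
  mu <- 500; sigma <- 25
  p <- field_profile(seq_len(n), rep(0, n), rep(0, n), rnorm(n, mu, sigma))
  h <- homogeneity_stats(p)
  # cv estimator SE ~ cv/sqrt(2n); 3 SE band (generous for the median in
  # the denominator)
  se3 <- 3 * (sigma / mu) / sqrt(2 * n) * 100 * 2
  expect_lt(abs(h$rel_sd - sigma / mu * 100), se3)
})

test_that("motion profiles respect trapezoid kinematics", {
  expect_equal(motion_profile(0)$total_time, 0)

  mp <- motion_profile(1201.2, 6552, 1747.2)
  closed <- 2 * 1747.2 / 6552 + (1201.2 - 1747.2^2 / 6552) / 1747.2
  expect_equal(mp$total_time, closed, tolerance = 1e-12)
  expect_equal(mp$total_time, 0.9541667, tolerance = 1e-6)
  expect_false(mp$triangular)
  expect_equal(mp$position(mp$total_time), 1201.2, tolerance = 1e-9)

  # boundary distance = vmax^2/accel: triangular with zero cruise
  db <- 1747.2^2 / 6552
  mb <- motion_profile(db, 6552, 1747.2)
  expect_equal(unname(mb$phase_times["cruise"]), 0)

  # distance conservation: numerical velocity integral equals distance
  for (d in c(5, 120, 1201.2, 3000)) {
    m <- motion_profile(d, 6552, 1747.2)
    tt <- seq(0, m$total_time, length.out = 20001)
    v <- m$velocity(tt)
    integral <- sum(diff(tt) * (v[-1] + v[-length(v)]) / 2)
    expect_equal(integral, d, tolerance = 1e-6)
    expect_lte(max(v), 1747.2 + 1e-9)
  }
})

test_that("field during motion composes position(t) with the field map", {
  n <- 100
  z <- seq(0, 33000, length.out = n)
  const <- field_profile(z, rep(0, n), rep(0, n), rep(5e8, n))
  mp <- motion_profile(1201.2)
  tp <- field_during_motion(mp, const, dt = 0.01)
  expect_equal(unique(tp$field_T), 0.5)

  # linear field: B(t) must equal a + b * position(t) exactly
  lin <- field_profile(z, rep(0, n), rep(0, n), 10 + 3 * z)
  tp2 <- field_during_motion(mp, lin, dt = 0.005)
  pos_usteps <- mp$position(tp2$time_s) / (1747.2 / 48000)
  expect_equal(tp2$field_T * 1e9, 10 + 3 * pos_usteps, tolerance = 1e-6)

  # monotone profile + monotone motion: B(t) monotone during cruise
  stray <- stray_field_profile()
  mp3 <- motion_profile(microsteps_to_mm(28000))
  tp3 <- field_during_motion(mp3, stray, dt = 0.002)
  cruise <- tp3$time_s > mp3$phase_times[["ramp_up"]] &
    tp3$time_s < mp3$total_time - mp3$phase_times[["ramp_down"]]
  expect_true(all(diff(tp3$field_T[cruise]) > 0))

  expect_error(field_during_motion(mp, const, dt = 0), "positive")
})

test_that("lookup round trip stays within interpolation error", {
  prof <- stray_field_profile(200)
  tab <- build_field_to_position_table(prof)
  # field -> position -> field on a fine query grid
  bq <- seq(min(tab$abscissa) * 1.01, max(tab$abscissa) * 0.99,
            length.out = 57)
  zq <- lookup_query(tab, bq)
  f_fwd <- splinefun(prof$position_usteps, prof$magnitude, method = "monoH.FC")
  bound <- max(abs(diff(prof$magnitude, differences = 2)))
  expect_lt(max(abs(f_fwd(zq) - bq)), bound)
})
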