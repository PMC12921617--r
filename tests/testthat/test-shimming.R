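test_that("coil calibration recovers the unit response from +/-I scans", {
  z <- seq(0, 10000, length.out = 200)
  zero <- numeric(200)
  bg <- field_profile(z, 300 + 0.01 * z / 100, rep(320, 200), rep(50, 200))

  # identical plus/minus profiles: zero response
  r0 <- calibrate_coil_response("X", bg, bg, 20)
  expect_true(all(r0$mux == 0 & r0$muy == 0 & r0$muz == 0))

  # uniform Z coil at 108 nT/mA probed at +/-20 mA: exact constant
  zc <- field_profile(z, bg$bx, bg$by, bg$bz + 108 * 20)
  zm <- field_profile(z, bg$bx, bg$by, bg$bz - 108 * 20)
  rz <- calibrate_coil_response("Z", zc, zm, 20)
  expect_equal(rz$muz, rep(108, 200))
  expect_equal(rz$mux, zero)

  # noisy scans: the per-point estimator sd is sqrt(2) sigma / (2*20);
  # check the error distribution against that linear propagation
  set.seed(11)
  u <- sin(z / 2000)
  noisy_p <- field_profile(z, bg$bx, bg$by, bg$bz + 30 * u * 20 + rnorm(200))
  noisy_m <- field_profile(z, bg$bx, bg$by, bg$bz - 30 * u * 20 + rnorm(200))
  rn <- calibrate_coil_response("dZ/dz", noisy_p, noisy_m, 20)
  sd_pt <- sqrt(2) * 1 / 40
  expect_lt(quantile(abs(rn$muz - 30 * u), 0.95), 2.5 * sd_pt)
  expect_lt(max(abs(rn$muz - 30 * u)), 4.5 * sd_pt)

  bg2 <- field_profile(z + 1, bg$bx, bg$by, bg$bz)
  expect_error(calibrate_coil_response("X", bg, bg2, 20), "identical")
  expect_error(calibrate_coil_response("X", bg, bg, 0), "nonzero")
})

test_that("field simulation is an exact linear superposition", {
  set.seed(21)
  inst <- random_shim_instance()
  bg <- inst$background; resp <- inst$responses

  expect_equal(simulate_field(bg, resp, rep(0, 9))$magnitude, bg$magnitude)

  e1 <- c(1, rep(0, 8))
  s1 <- simulate_field(bg, resp, e1)
  expect_equal(s1$bx, bg$bx + resp[[1]]$mux, tolerance = 1e-12)

  # random currents vs an independent per-point summation oracle
  cur <- rnorm(9)
  sim <- simulate_field(bg, resp, cur)
  oracle_bz <- bg$bz
  for (j in 1:9) oracle_bz <- oracle_bz + cur[j] * resp[[j]]$muz
  expect_equal(sim$bz, oracle_bz, tolerance = 1e-9)

  # superposition: sim(b, c1+c2) = sim(b, c1) + sim(0, c2)
  c1 <- rnorm(9); c2 <- rnorm(9)
  zero_bg <- field_profile(inst$z, numeric(30), numeric(30), numeric(30))
  lhs <- simulate_field(bg, resp, c1 + c2)
  rhs1 <- simulate_field(bg, resp, c1)
  rhs2 <- simulate_field(zero_bg, resp, c2)
  expect_equal(lhs$by, rhs1$by + rhs2$by, tolerance = 1e-9)

  expect_error(simulate_field(bg, resp[1:8], rep(0, 8)), "nine")
})

test_that("shim loss matches its definition and its analytic gradient", {
  set.seed(31)
  inst <- random_shim_instance()
  l0 <- shim_loss(inst$background, inst$responses, rep(0, 9), alpha = 0)
  expect_equal(l0$loss, sum(inst$background$magnitude^2), tolerance = 1e-9)

  # analytic gradient vs central finite differences, 20 random configs
  for (i in 1:20) {
    cur <- rnorm(9); alpha <- runif(1, 0, 5)
    g <- shim_loss(inst$background, inst$responses, cur, alpha)$gradient
    fd <- vapply(1:9, function(j) {
      h <- 1e-5 * max(abs(cur[j]), 1)
      up <- dn <- cur; up[j] <- cur[j] + h; dn[j] <- cur[j] - h
      (shim_loss(inst$background, inst$responses, up, alpha)$loss -
         shim_loss(inst$background, inst$responses, dn, alpha)$loss) / (2 * h)
    }, 1)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-6)
  }

  expect_error(shim_loss(inst$background, inst$responses, rep(0, 9), -1),
               "non-negative")

  # penalty dominance: huge alpha drives the optimum to zero currents
  stA <- optimize_shims(inst$background, inst$responses, alpha = 1e9)
  expect_lt(max(abs(stA$currents)), 1e-3)
})

test_that("simulative tuning equals the normal-equations solution at alpha = 0", {
  set.seed(41)
  for (i in 1:200) {
    inst <- random_shim_instance(noise = 0.3)
    st <- optimize_shims(inst$background, inst$responses, alpha = 0)
    oracle <- solve(crossprod(inst$X), -crossprod(inst$X, inst$b))
    expect_equal(st$currents, as.vector(oracle), tolerance = 1e-6)
  }
})

test_that("zero background yields zero currents and zero residual", {
  set.seed(43)
  inst <- random_shim_instance()
  zero_bg <- field_profile(inst$z, numeric(30), numeric(30), numeric(30))
  st <- optimize_shims(zero_bg, inst$responses, alpha = 1e-2)
  expect_lt(max(abs(st$currents)), 1e-9)
  expect_lt(st$residual_stats$mean, 1e-9)
})

test_that("regularization path is monotone and the optimum is a minimum", {
  set.seed(47)
  inst <- random_shim_instance(noise = 0.2)
  norms <- vapply(10^seq(-4, 4, 1), function(a)
    sqrt(sum(optimize_shims(inst$background, inst$responses,
                            alpha = a)$currents^2)), 1)
  expect_true(all(diff(norms) <= 1e-9))

  st <- optimize_shims(inst$background, inst$responses, alpha = 0.5)
  l_opt <- shim_loss(inst$background, inst$responses, st$currents, 0.5)$loss
  for (j in 1:9) {
    for (f in c(0.99, 1.01)) {
      pert <- st$currents; pert[j] <- pert[j] * f
      expect_gte(shim_loss(inst$background, inst$responses, pert, 0.5)$loss,
                 l_opt - 1e-9 * l_opt)
    }
  }
})

test_that("95% confidence intervals are calibrated on linear-Gaussian data", {
  set.seed(53)
  inst <- random_shim_instance()
  hits <- 0L; total <- 0L
  for (i in 1:1000) {
    b <- -as.vector(inst$X %*% inst$c_true) + rnorm(90, 0, 0.5)
    bg <- field_profile(inst$z, b[1:30], b[31:60], b[61:90])
    st <- optimize_shims(bg, inst$responses, alpha = 0)
    hits <- hits + sum(abs(st$currents - inst$c_true) <= st$ci95)
    total <- total + 9L
  }
  expect_gte(hits / total, 0.92)
  expect_lte(hits / total, 0.98)
})

test_that("shimming the synthetic shield reaches the target residual scale", {
  cfg <- generator_config(seed = 5)
  bg <- gen_shield_background(cfg)
  resp <- gen_coil_responses(cfg)
  z_sample <- round(0.0535 * 33000)
  half <- 25 / (1747.2 / 48000)           # 2.5 cm in microsteps
  st <- optimize_shims(bg, resp, alpha = 1e-2,
                       sample_positions = z_sample + c(-half, half))
  expect_true(st$converged)
  expect_lt(st$residual_stats$mean, 30)   # nT over the 5 cm sample region
  expect_true(all(st$ci95 >= 0))
})

test_that("a dead coil is dropped from the design with a warning", {
  set.seed(59)
  inst <- random_shim_instance()
  resp <- inst$responses
  n <- length(inst$z)
  resp[[4]] <- coil_response(SHIM_COIL_IDS[4], inst$z,
                             numeric(n), numeric(n), numeric(n))
  expect_warning(st <- optimize_shims(inst$background, resp, alpha = 1e-3),
                 "all-zero")
  expect_identical(st$currents[4], 0)
})

test_that("iterative tuning reduces the probed field below threshold", {
  # already below threshold: untouched
  it0 <- iterative_tune(function(c3) c(0.5, 0.5, 0.5), start = c(1, 2, 3))
  expect_identical(it0$iterations, 0L)
  expect_identical(it0$currents, c(1, 2, 3))

  # linear noiseless probe: converges below 2 nT, monotone descent
  probe <- gen_probe(c(17, -11, 23))
  it <- iterative_tune(probe)
  expect_true(it$converged)
  expect_lt(it$field_nT, 2)
  # closed form: exact nulling currents exist; solution should be near them
  exact <- solve(diag(c(55, 50, 108)), -c(17, -11, 23))
  expect_lt(max(abs(it$currents - exact)), 0.1)

  # noisy probe (0.5 nT sd), 100 seeded repeats: bounded final field
  finals <- vapply(1:100, function(s) {
    p <- gen_probe(c(10, -6, 8), noise_nT = 0.5,
                   cfg = generator_config(seed = s))
    iterative_tune(p, stop_threshold = 2, max_iter = 300)$field_nT
  }, 1)
  expect_true(all(finals < 2 + 3 * 0.5))
})

test_that("z-shim schedules invert the fitted calibration line", {
  cal_i <- seq(-30, 30, length.out = 25)
  sch <- zshim_schedule(cal_i, 108 * cal_i, targets = c(3000, 0, -3000))
  expect_equal(sch$slope_nT_per_mA, 108, tolerance = 1e-9)
  expect_equal(sch$currents_mA, c(3000 / 108, 0, -3000 / 108),
               tolerance = 1e-9)
  expect_equal(sch$currents_mA[1], 27.78, tolerance = 1e-3)

  set.seed(61)
  noisy <- 108 * cal_i + rnorm(25, 0, 5)
  schn <- zshim_schedule(cal_i, noisy, targets = 1000)
  expect_lt(abs(schn$slope_nT_per_mA - 108) / 108, 0.02)

  expect_error(zshim_schedule(c(0, 1), c(5, 5), 10), "slope")
})
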