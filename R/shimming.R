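## Two-stage ultralow-field shimming of the mu-metal shield: regularized
## least squares over 9 coil currents (simulative tuning), then iterative
## X/Y/Z fine tuning against a field probe.

#' Names of the nine shim coils
#' @export
SHIM_COIL_IDS <- c("X", "Y", "Z", "dY/dx", "dZ/dx", "dZ/dy",
                   "dY/dy", "dZ/dz", "d2Z/dz2")

#' Construct a coil response
#'
#' Field produced per unit current (nT/mA), per component, on the same
#' axial grid as the background profile.
#'
#' @param coil_id One of [SHIM_COIL_IDS].
#' @param position_usteps Axial grid, microsteps.
#' @param mux,muy,muz Per-component response, nT/mA.
#' @return Object of class `coil_response`.
#' @export
coil_response <- function(coil_id, position_usteps, mux, muy, muz) {
  coil_id <- match.arg(coil_id, SHIM_COIL_IDS)
  stopifnot(length(position_usteps) == length(mux),
            length(mux) == length(muy), length(muy) == length(muz),
            all(is.finite(c(mux, muy, muz))))
  structure(list(coil_id = coil_id, position_usteps = position_usteps,
                 mux = mux, muy = muy, muz = muz),
            class = "coil_response")
}

#' Calibrate a coil response from a +/-I profile pair
#'
#' mu(z) = (B_plus(z) - B_minus(z)) / (2 |I|) per component, in nT/mA. The
#' symmetric difference cancels the background and any odd response
#' nonlinearity. Grids must match exactly; no silent resampling here.
#'
#' @param coil_id One of [SHIM_COIL_IDS].
#' @param profile_plus,profile_minus [field_profile()]s measured at +I and
#'   -I.
#' @param delta_current |I| in mA (nonzero).
#' @return A [coil_response()].
#' @export
calibrate_coil_response <- function(coil_id, profile_plus, profile_minus,
                                    delta_current) {
  stopifnot(inherits(profile_plus, "field_profile"),
            inherits(profile_minus, "field_profile"))
  if (delta_current == 0) stop("delta_current must be nonzero")
  if (length(profile_plus$position_usteps) != length(profile_minus$position_usteps) ||
      any(profile_plus$position_usteps != profile_minus$position_usteps))
    stop("profiles must share an identical position grid")
  d <- 2 * abs(delta_current)
  coil_response(coil_id, profile_plus$position_usteps,
                (profile_plus$bx - profile_minus$bx) / d,
                (profile_plus$by - profile_minus$by) / d,
                (profile_plus$bz - profile_minus$bz) / d)
}

## Spline-resample background and responses to the densest common grid and
## return stacked component matrices restricted to sample positions.
## Columns of the design matrix are the 9 coils; rows are (position x
## component) pairs.
shim_design <- function(background, responses, sample_positions = NULL) {
  stopifnot(inherits(background, "field_profile"))
  if (length(responses) != 9L) stop("nine coil responses are required")
  grids <- c(list(background$position_usteps),
             lapply(responses, `[[`, "position_usteps"))
  dens <- grids[[which.max(vapply(grids, length, 1L))]]
  lo <- max(vapply(grids, min, 1)); hi <- min(vapply(grids, max, 1))
  grid <- dens[dens >= lo & dens <= hi]
  if (is.null(sample_positions)) sample_positions <- grid
  keep <- grid >= min(sample_positions) & grid <= max(sample_positions)
  grid <- grid[keep]
  if (!length(grid)) stop("no grid points inside sample_positions")
  res <- function(x, y) stats::splinefun(x, y, method = "natural")(grid)
  b <- c(res(background$position_usteps, background$bx),
         res(background$position_usteps, background$by),
         res(background$position_usteps, background$bz))
  X <- vapply(responses, function(r) {
    c(res(r$position_usteps, r$mux),
      res(r$position_usteps, r$muy),
      res(r$position_usteps, r$muz))
  }, numeric(3L * length(grid)))
  zero <- apply(X, 2L, function(col) all(col == 0))
  list(grid = grid, b = b, X = X, zero = zero)
}

#' Superpose background and coil fields
#'
#' B_sim(z) = B_b(z) + sum_coil I_coil * mu_coil(z), componentwise, after
#' cubic-spline resampling all inputs to the densest common grid.
#'
#' @param background A [field_profile()].
#' @param responses List of nine [coil_response()]s.
#' @param currents Nine currents, mA.
#' @return A [field_profile()] on the common grid.
#' @export
simulate_field <- function(background, responses, currents) {
  if (length(responses) != 9L || length(currents) != 9L)
    stop("nine coil responses and nine currents are required")
  d <- shim_design(background, responses)
  v <- d$b + as.vector(d$X %*% currents)
  n <- length(d$grid)
  field_profile(d$grid, v[seq_len(n)], v[n + seq_len(n)], v[2L * n + seq_len(n)])
}

#' Shim loss and its analytic gradient
#'
#' L = sum_sample ||B||^2 + alpha * sum_coil I^2 with
#' B = B_b + sum I mu, and dL/dI_coil = 2 sum_sample B . mu_coil +
#' 2 alpha I_coil. Units: nT^2 (with alpha in nT^2/mA^2).
#'
#' @param background A [field_profile()].
#' @param responses List of nine [coil_response()]s.
#' @param currents Nine currents, mA.
#' @param alpha Regularization weight, nT^2/mA^2 (>= 0).
#' @param sample_positions Range of positions (microsteps) over which the
#'   field norm is summed; default full common grid.
#' @return List with `loss` and 9-vector `gradient`.
#' @export
shim_loss <- function(background, responses, currents, alpha = 0,
                      sample_positions = NULL) {
  if (alpha < 0) stop("alpha must be non-negative")
  d <- shim_design(background, responses, sample_positions)
  B <- d$b + as.vector(d$X %*% currents)
  list(loss = sum(B^2) + alpha * sum(currents^2),
       gradient = as.vector(2 * crossprod(d$X, B)) + 2 * alpha * currents)
}

#' Simulative shim tuning: minimize the regularized field norm
#'
#' Minimizes L(I) = sum ||B_b + sum I mu||^2 + alpha sum I^2 over the nine
#' coil currents with a gradient-based quasi-Newton minimizer and the
#' analytic gradient. The problem is linear-quadratic, so the optimum also
#' satisfies the normal equations (X'X + alpha I) c = -X'b; the iterative
#' route is kept because it generalizes to constrained variants, and its
#' solution is polished by one closed-form step. 95% confidence intervals
#' come from the inverse Hessian with a t-quantile (n - 9 df).
#'
#' @inheritParams shim_loss
#' @param sample_positions Interval (microsteps) defining the sample
#'   region.
#' @return Object of class `shim_state`: `currents` (mA), `ci95` (mA),
#'   `alpha`, `residual_profile`, `residual_stats`, `loss`, `converged`,
#'   `ci_reliable`.
#' @export
optimize_shims <- function(background, responses, alpha = 1e-2,
                           sample_positions = NULL) {
  if (alpha < 0) stop("alpha must be non-negative")
  d <- shim_design(background, responses, sample_positions)
  X <- d$X; b <- d$b
  if (any(d$zero)) {
    warning("all-zero coil response(s) dropped from the design: ",
            paste(which(d$zero), collapse = ", "))
    X[, d$zero] <- 0
  }
  fn <- function(c9) sum((b + X %*% c9)^2) + alpha * sum(c9^2)
  gr <- function(c9) as.vector(2 * crossprod(X, b + X %*% c9)) + 2 * alpha * c9
  opt <- stats::optim(rep(0, 9L), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  ## polish: the loss is quadratic, so one Newton step lands on the optimum
  act <- !d$zero
  Xa <- X[, act, drop = FALSE]
  H2 <- crossprod(X) + diag(alpha, 9L)
  cur <- opt$par
  cur[act] <- tryCatch(
    as.vector(solve(crossprod(Xa) + diag(alpha, sum(act)),
                    -crossprod(Xa, b))),
    error = function(e) opt$par[act])
  cur[d$zero] <- 0
  loss <- fn(cur)
  gnorm <- sqrt(sum(gr(cur)^2))
  converged <- gnorm <= 1e-6 * max(loss, 1)

  ## Hessian of L is 2 (X'X + alpha I); residual variance from the fit
  n <- length(b); p <- 9L
  rss <- sum((b + X %*% cur)^2)
  sigma2 <- rss / max(n - p, 1L)
  H <- 2 * H2
  ci_reliable <- TRUE
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0) ||
      kappa(H2) > 1e12) {
    ci_reliable <- FALSE
    warning("near-singular Hessian: ridge fallback used for confidence intervals")
    cov <- 2 * sigma2 * solve(H + diag(1e-8 * max(diag(H)), 9L))
  }
  tq <- stats::qt(0.975, df = max(n - p, 1L))
  ci95 <- tq * sqrt(pmax(diag(cov), 0))

  v <- b + as.vector(X %*% cur)
  m <- length(d$grid)
  resid_prof <- field_profile(d$grid, v[seq_len(m)], v[m + seq_len(m)],
                              v[2L * m + seq_len(m)])
  structure(list(currents = cur, ci95 = ci95, alpha = alpha,
                 residual_profile = resid_prof,
                 residual_stats = homogeneity_stats(resid_prof),
                 loss = loss, gradient_norm = gnorm,
                 converged = converged, ci_reliable = ci_reliable),
            class = "shim_state")
}

#' Iterative X/Y/Z fine tuning against a field probe
#'
#' Coordinate descent on the three first-order shim currents, probing the
#' field vector at the sample position after each trial step. Step sizes
#' sweep from `step_range[2]` down to `step_range[1]` mA; a step is
#' accepted only if it reduces the probed field magnitude, so the magnitude
#' never increases between accepted steps. Terminates when the magnitude
#' falls below `stop_threshold` (default 2 nT) or after `max_iter` probes.
#'
#' @param probe Function `(currents3)` returning the 3-component field (nT)
#'   at z_sample for the given X/Y/Z currents (mA).
#' @param start Numeric length-3 starting currents, mA.
#' @param step_range `c(min, max)` step sizes, mA (default 0.01--0.1).
#' @param stop_threshold Field-magnitude target, nT.
#' @param max_iter Probe budget.
#' @return List: `currents`, `field_nT` (final magnitude), `iterations`,
#'   `converged`.
#' @export
iterative_tune <- function(probe, start = c(0, 0, 0),
                           step_range = c(0.01, 0.1),
                           stop_threshold = 2, max_iter = 500L) {
  cur <- as.numeric(start)
  stopifnot(length(cur) == 3L)
  magn <- function(c3) sqrt(sum(probe(c3)^2))
  best <- magn(cur)
  iter <- 1L
  if (best < stop_threshold)
    return(list(currents = cur, field_nT = best, iterations = 0L,
                converged = TRUE))
  steps <- sort(unique(c(step_range[2], step_range[2] / 2,
                         step_range[2] / 5, step_range[1])),
                decreasing = TRUE)
  for (step in steps) {
    improved <- TRUE
    while (improved && iter < max_iter && best >= stop_threshold) {
      improved <- FALSE
      for (k in 1:3) {
        for (sgn in c(1, -1)) {
          trial <- cur; trial[k] <- trial[k] + sgn * step
          m <- magn(trial); iter <- iter + 1L
          if (m < best) { cur <- trial; best <- m; improved <- TRUE }
          if (iter >= max_iter || best < stop_threshold) break
        }
        if (iter >= max_iter || best < stop_threshold) break
      }
    }
    if (best < stop_threshold || iter >= max_iter) break
  }
  list(currents = cur, field_nT = best, iterations = iter,
       converged = best < stop_threshold)
}

#' Z-shim current schedule from a linear calibration
#'
#' Ordinary least-squares line through (current, field) calibration points
#' (the z-shim coil responds at ~108 nT/mA); target fields are converted to
#' currents by inverting the fitted line.
#'
#' @param calibration_currents Currents, mA (>= 2 points).
#' @param measured_fields Fields, nT.
#' @param targets Target fields, nT.
#' @return List: `currents_mA` (one per target), `slope_nT_per_mA`,
#'   `intercept_nT`.
#' @export
zshim_schedule <- function(calibration_currents, measured_fields, targets) {
  stopifnot(length(calibration_currents) == length(measured_fields),
            length(calibration_currents) >= 2L)
  fit <- stats::lm(measured_fields ~ calibration_currents)
  co <- stats::coef(fit)
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  if (!is.finite(slope) ||
      abs(slope) <= 1e-9 * max(abs(measured_fields), 1) /
        max(abs(calibration_currents)))
    stop("zero calibration slope")
  list(currents_mA = (targets - intercept) / slope,
       slope_nT_per_mA = slope, intercept_nT = intercept)
}
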