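# Shared fixtures, built in code.

# random small shim instance: 9 coils x n positions on a common grid,
# returning the raw design matrix alongside the package objects so tests
# can run an independent normal-equations oracle
random_shim_instance <- function(n = 30L, noise = 0) {
  z <- seq(0, 100, length.out = n)
  resp <- lapply(seq_along(SHIM_COIL_IDS), function(i)
    coil_response(SHIM_COIL_IDS[i], z,
                  stats::rnorm(n), stats::rnorm(n), stats::rnorm(n)))
  X <- sapply(resp, function(r) c(r$mux, r$muy, r$muz))
  c_true <- stats::rnorm(9)
  b <- -as.vector(X %*% c_true)
  if (noise > 0) b <- b + stats::rnorm(3L * n, 0, noise)
  bg <- field_profile(z, b[seq_len(n)], b[n + seq_len(n)],
                      b[2L * n + seq_len(n)])
  list(z = z, responses = resp, X = X, b = b, c_true = c_true,
       background = bg)
}

# exponential stray-field profile along the shuttle axis (nT), strictly
# monotone: the invertible flank used for field-to-position lookups
stray_field_profile <- function(n = 400L) {
  z <- seq(0, 30000, length.out = n)
  b <- 100 * exp(z / 6000)     # 100 nT at the shield, ~1.5e4 nT at 30000
  field_profile(z, rep(0, n), rep(0, n), b)
}

table1_params <- function() relax_model_params()
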