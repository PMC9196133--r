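# Shared helpers: tiny networks and independent oracles used across tests.

# single-population network with optional recurrence and external drive
tiny_net <- function(K = 0, J = 0.2e-3, K_ext = 100, J_ext = 0.2e-3,
                     nu_ext = 8, tau_m = 20e-3, tau_s = 0, tau_r = 2e-3,
                     V_th = 20e-3, V_0 = 0) {
  population_network(
    labels = "A", n = 1000, J = matrix(J), K = matrix(K),
    J_ext = matrix(J_ext), K_ext = matrix(K_ext), nu_ext = nu_ext,
    tau_m = tau_m, tau_s = tau_s, tau_r = tau_r,
    V_th_rel = V_th, V_0_rel = V_0,
    delay_mean = 1e-3
  )
}

# raw-integrand adaptive-quadrature oracle for the Siegert rate (overflows
# deliberately outside |y| <~ 26, where callers must not use it)
siegert_oracle <- function(mu, sigma, tau_m, tau_r, V_th, V_0) {
  y0 <- (V_0 - mu) / sigma
  yth <- (V_th - mu) / sigma
  f <- function(s) exp(s^2) * 2 * stats::pnorm(s * sqrt(2))
  I <- stats::integrate(f, y0, yth, rel.tol = 1e-13, abs.tol = 0)$value
  1 / (tau_r + tau_m * sqrt(pi) * I)
}

# random small network with reproducible parameters: a jittered balanced
# E/I circuit whose populations all stay active at moderate rates
random_net <- function(P, seed) {
  set.seed(seed)
  stopifnot(P == 4)
  signs <- rep(c(1, -5), length.out = P)
  J <- matrix(runif(P * P, 0.09e-3, 0.11e-3), P, P) *
    matrix(signs, P, P, byrow = TRUE)
  # two weakly coupled, internally balanced EI modules (E1 I1 E2 I2) with
  # fixed zero entries exercising the zero-structure invariant
  K <- matrix(c(350, 130, 80, 0,
                350, 130, 0, 30,
                80, 0, 350, 130,
                0, 30, 350, 130), 4, 4, byrow = TRUE) *
    matrix(runif(P * P, 0.9, 1.1), P, P)
  population_network(
    labels = paste0("P", seq_len(P)), n = sample(500:5000, P),
    J = J, K = round(K),
    J_ext = matrix(0.1e-3, P, 1),
    K_ext = matrix(sample(1500:1700, P), P, 1), nu_ext = 10,
    tau_m = 10e-3, tau_s = 0.5e-3, tau_r = 2e-3,
    V_th_rel = 15e-3, V_0_rel = 0,
    delay_mean = matrix(runif(P * P, 0.5e-3, 2e-3), P, P)
  )
}

# conjugate-pair structure of Lambert-W branch spectra for real c(k).
# With the principal-log branch convention, conj(W_B(z)) = W_{-B}(z) for
# z >= 0 but W_{-B-1}(z) for z < 0 (the branch cut lies on the negative
# real axis), so the pairing is branch-aware.
expect_conjugate_pairs <- function(spec, tol = 1e-9) {
  z <- spec$c_k * (spec$d / spec$tau) * exp(spec$d / spec$tau)
  for (j in seq_along(z)) {
    for (B in 0:max(spec$branches)) {
      partner <- if (z[j] >= 0) -B else -B - 1
      if (!(B %in% spec$branches) || !(partner %in% spec$branches)) next
      lb <- spec$lambda[spec$branches == B, j]
      lp <- spec$lambda[spec$branches == partner, j]
      if (is.na(lb) || is.na(lp)) next
      expect_lt(Mod(lb - Conj(lp)), tol * max(1, Mod(lb)))
    }
  }
}

expect_rel_equal <- function(got, want, tol, info = NULL) {
  rel <- abs(got - want) / pmax(abs(want), .Machine$double.xmin)
  expect_lt(max(rel), tol)
}
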