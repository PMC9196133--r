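# Linear-response machinery: parabolic-cylinder functions, transfer
# functions, delay kernels, power spectra, sensitivity measure.

test_that("phi_omega satisfies reflection, boundary values, and its ODE", {
  tau_m <- 20e-3
  xs <- c(-8, -2.5, 0, 1.3, 6)
  for (f in c(7, 90)) {
    om <- 2 * pi * f
    a <- phi_omega(xs, om, tau_m)
    b <- phi_omega(xs, -om, tau_m)
    expect_equal(a$phi, Conj(b$phi), tolerance = 1e-12)
    expect_equal(a$dphi, Conj(b$dphi), tolerance = 1e-12)
    # boundary values at x = 0 against the closed form with complex gamma
    av <- complex(real = -0.5, imaginary = om * tau_m)
    want_phi <- sqrt(pi) * 2^(-av / 2 - 0.25) / mfnet:::cgamma(0.75 + av / 2)
    want_dphi <- -sqrt(pi) * 2^(-av / 2 + 0.25) / mfnet:::cgamma(0.25 + av / 2)
    at0 <- phi_omega(0, om, tau_m)
    expect_lt(Mod(at0$phi - want_phi) / Mod(want_phi), 1e-9)
    expect_lt(Mod(at0$dphi - want_dphi) / Mod(want_dphi), 1e-9)
    # derivative consistency: central difference of phi matches dphi
    h <- 1e-5
    for (x in c(-3.2, 0.7, 4.4)) {
      pp <- phi_omega(c(x - h, x, x + h), om, tau_m)
      fd <- (pp$phi[3] - pp$phi[1]) / (2 * h)
      expect_lt(Mod(fd - pp$dphi[2]) / Mod(pp$dphi[2]), 1e-6)
      # local ODE residual: phi'' = x phi' + i om tau_m phi
      d2 <- (pp$phi[3] - 2 * pp$phi[2] + pp$phi[1]) / h^2
      rhs <- x * pp$dphi[2] + 1i * om * tau_m * pp$phi[2]
      expect_lt(Mod(d2 - rhs) / Mod(rhs), 1e-4)
    }
  }
  # omega = 0: U(-1/2, x) = exp(-x^2/4), so phi == 1 identically
  at <- phi_omega(c(-5, 0, 2, 9), 0, tau_m)
  expect_equal(at$phi, rep(1 + 0i, 4), tolerance = 1e-10)
  expect_equal(Mod(at$dphi), rep(0, 4), tolerance = 1e-10)
  expect_error(phi_omega(150, 1, tau_m), "precision box")
})

fig4_net <- function(sigma, target_rate) {
  tau_m <- 20e-3; tau_s <- 0.5e-3; tau_r <- 2e-3
  Vth <- 20e-3; V0 <- 15e-3
  f <- function(m) siegert_rate_exp(m, sigma, tau_m, tau_s, tau_r,
                                    Vth, V0) - target_rate
  mu <- uniroot(f, c(-30e-3, 40e-3), tol = 1e-13)$root
  net <- tiny_net(tau_m = tau_m, tau_s = tau_s, tau_r = tau_r,
                  V_th = Vth, V_0 = V0, K = 0, K_ext = 0, J_ext = 0,
                  nu_ext = 0)
  wp <- structure(list(nu = target_rate, mu = mu, sigma = sigma),
                  class = "working_point")
  list(net = net, wp = wp)
}

test_that("transfer function: DC gain, low-pass, conjugation, variants", {
  s <- fig4_net(4e-3, 10)
  freqs <- c(0, 1, 10, 100, 1000)
  tf <- transfer_function(s$net, s$wp, freqs, variant = "cn_shift")
  h <- 1e-6
  cd <- (siegert_rate_exp(s$wp$mu + h, 4e-3, 20e-3, 0.5e-3, 2e-3, 20e-3,
                          15e-3) -
         siegert_rate_exp(s$wp$mu - h, 4e-3, 20e-3, 0.5e-3, 2e-3, 20e-3,
                          15e-3)) / (2 * h)
  expect_lt(abs(Re(tf$values[1, 1]) - cd) / cd, 5e-3)
  expect_lt(abs(Im(tf$values[1, 1])), 1e-8 * abs(Re(tf$values[1, 1])))
  # low-pass with phase lag at high frequencies
  amps <- Mod(tf$values[1, ])
  expect_lt(amps[4], amps[2])
  expect_lt(amps[5], amps[4])
  expect_lt(Arg(tf$values[1, 4]), 0)
  # N(-omega) = conj(N(omega))
  tfneg <- transfer_function(s$net, s$wp, 25, variant = "cn_shift")
  tfpos <- transfer_function(s$net, s$wp, -25, variant = "cn_shift")
  expect_equal(tfpos$values[1, 1], Conj(tfneg$values[1, 1]),
               tolerance = 1e-12)
  # filtered variant multiplies by the synaptic low-pass
  tff <- transfer_function(s$net, s$wp, 25, variant = "cn_shift_filtered")
  expect_equal(tff$values[1, 1],
               tfneg$values[1, 1] / (1 + 2i * pi * 25 * 0.5e-3),
               tolerance = 1e-10)
  expect_error(transfer_function(s$net, s$wp, 1, variant = "taylor"),
               "not implemented")
})

test_that("delta synapse variant reduces to unshifted boundaries", {
  s <- fig4_net(4e-3, 10)
  net0 <- s$net; net0$tau_s <- 0
  tfd <- transfer_function(s$net, s$wp, c(5, 50), variant = "delta")
  tf0 <- transfer_function(net0, s$wp, c(5, 50), variant = "cn_shift")
  expect_equal(tfd$values, tf0$values, tolerance = 1e-12)
})

test_that("delay kernel: normalization, pure phase, quadrature oracle", {
  net <- make_network("ei_exp") # truncated-gaussian delays
  freqs <- c(0, 13, 67, 211)
  dk <- delay_kernel(net, freqs)
  expect_equal(dk$values[, , 1], matrix(1 + 0i, 2, 2), tolerance = 1e-12)
  expect_true(all(Mod(dk$values) <= 1 + 1e-12))
  # quadrature oracle for the truncated-normal characteristic function
  d <- net$delay_mean[1, 1]; s <- net$delay_sd[1, 1]
  for (f in freqs[-1]) {
    om <- 2 * pi * f
    re <- integrate(function(t) cos(om * t) * dnorm(t, d, s), 0, Inf,
                    rel.tol = 1e-12)$value
    im <- integrate(function(t) -sin(om * t) * dnorm(t, d, s), 0, Inf,
                    rel.tol = 1e-12)$value
    Z <- integrate(function(t) dnorm(t, d, s), 0, Inf,
                   rel.tol = 1e-12)$value
    want <- complex(real = re, imaginary = im) / Z
    j <- which(freqs == f)
    expect_lt(Mod(dk$values[1, 1, j] - want), 1e-8)
  }
  # delta kind: |D| = 1 everywhere
  netd <- make_network("ei_delta")
  dkd <- delay_kernel(netd, freqs)
  expect_equal(Mod(dkd$values), array(1, c(2, 2, 4)), tolerance = 1e-12)
  netbad <- netd; netbad$delay_sd <- matrix(-1, 2, 2)
  expect_error(delay_kernel(netbad, 1), "nonnegative")
})

test_that("power spectra: shot-noise floor, realness, dense-inverse oracle", {
  net <- make_network("ei_exp")
  wp <- solve_rates_ode(net)
  freqs <- c(1, 20, 80, 250)
  dk <- delay_kernel(net, freqs)
  # J = 0 -> P_a = nu_a / n_a at every frequency
  net0 <- net; net0$J <- matrix(0, 2, 2)
  tf0 <- transfer_function(net0, wp, freqs)
  ps0 <- power_spectra(net0, wp, tf0, dk)
  expect_rel_equal(ps0$values, matrix(wp$nu / net$n, 2, length(freqs)),
                   1e-12)
  # small-coupling regime: explicit dense-inverse evaluation agrees
  tf <- transfer_function(net, wp, freqs)
  ps <- power_spectra(net, wp, tf, dk)
  expect_true(all(ps$values > 0))
  M <- effective_connectivity(net, tf, dk)
  for (j in seq_along(freqs)) {
    A <- solve(diag(2) - M[, , j]) # oracle: explicit inverse
    C <- A %*% diag(wp$nu / net$n) %*% t(Conj(A))
    expect_rel_equal(ps$values[, j], Re(diag(C)), 1e-10)
    expect_lt(max(abs(Im(diag(C)))) / max(Re(diag(C))), 1e-12)
  }
})

test_that("power spectrum diverges as an eigenvalue approaches 1 + 0i", {
  net <- make_network("ei_exp")
  wp <- solve_rates_ode(net)
  freqs <- seq(10, 400, by = 10)
  dk <- delay_kernel(net, freqs)
  tf <- transfer_function(net, wp, freqs)
  M <- effective_connectivity(net, tf, dk)
  dist1 <- function(scale) {
    sapply(seq_along(freqs), function(j)
      min(Mod(1 - eigen(scale * M[, , j], only.values = TRUE)$values)))
  }
  scl_net <- function(scale) { n2 <- net; n2$J <- scale * net$J; n2 }
  base <- power_spectra(net, wp, tf, dk)
  # scaling J toward instability: peak power grows like 1/|1-lambda|^2
  d0 <- min(dist1(1))
  for (scale in c(1.5, 2.2)) {
    n2 <- scl_net(scale)
    ps2 <- power_spectra(n2, wp, tf, delay_kernel(n2, freqs))
    d2 <- min(dist1(scale))
    if (d2 < d0) expect_gt(max(ps2$values), max(base$values))
  }
})

test_that("sensitivity measure equals the eigenvalue derivative", {
  # P = 1: Z is the scalar effective connectivity itself
  net1 <- tiny_net(K = 50, J = 0.2e-3)
  wp1 <- solve_rates_ode(net1)
  f1 <- c(10, 30)
  tf1 <- transfer_function(net1, wp1, f1)
  dk1 <- delay_kernel(net1, f1)
  M1 <- effective_connectivity(net1, tf1, dk1)
  s1 <- sensitivity_measure(net1, wp1, tf1, dk1, 30)
  expect_equal(s1$Z[1, 1], M1[1, 1, 2], tolerance = 1e-12)
  # random 4-population networks: finite-difference eigenvalue perturbation
  for (seed in 1:4) {
    net <- random_net(4, seed)
    wp <- solve_rates_ode(net, analysis_params(t_max = 200))
    tf <- transfer_function(net, wp, 40)
    dk <- delay_kernel(net, 40)
    M <- effective_connectivity(net, tf, dk)[, , 1]
    sens <- mfnet:::sensitivity_from_M(M, 40)
    b <- sens$mode_index
    eps <- 1e-6
    for (cc in 1:4) for (dd in 1:4) {
      if (net$K[cc, dd] == 0) {
        expect_identical(sens$Z[cc, dd], 0 + 0i)
        next
      }
      Mp <- M; Mp[cc, dd] <- (1 + eps) * Mp[cc, dd]
      lp <- eigen(Mp, only.values = TRUE)$values
      dl <- (lp[which.min(Mod(lp - sens$eigenvalue))] - sens$eigenvalue) / eps
      expect_lt(Mod(dl - sens$Z[cc, dd]) /
                  max(Mod(sens$Z[cc, dd]), 1e-12), 1e-3)
    }
    # orthogonal projections recover the modulus
    expect_equal(sens$Z_amp^2 + sens$Z_freq^2, Mod(sens$Z)^2,
                 tolerance = 1e-10)
  }
})

test_that("sensitivity across eigenmodes: blocks and refined minima", {
  # decoupled block-diagonal network = two independent populations
  net <- population_network(
    labels = c("A", "B"), n = c(1000, 2000),
    J = diag(c(0.3e-3, -0.4e-3)), K = diag(c(80, 120)),
    J_ext = matrix(0.1e-3, 2, 1), K_ext = matrix(400, 2, 1), nu_ext = 15,
    tau_m = 10e-3, tau_s = 0.5e-3, tau_r = 2e-3,
    V_th_rel = 15e-3, V_0_rel = 0,
    delay_mean = matrix(c(1e-3, 0, 0, 2e-3), 2, 2))
  wp <- solve_rates_ode(net)
  freqs <- seq(5, 300, by = 5)
  tf <- transfer_function(net, wp, freqs)
  dk <- delay_kernel(net, freqs)
  all_modes <- sensitivity_all_eigenmodes(net, wp, tf, dk)
  expect_length(all_modes, 2)
  # each tracked mode of the diagonal system is a diagonal entry of M
  M <- effective_connectivity(net, tf, dk)
  for (mode in all_modes) {
    offdiag <- mode$Z[1, 2] + mode$Z[2, 1]
    expect_lt(Mod(offdiag), 1e-10)
    # reported critical frequency is a grid minimum of |1 - lambda|;
    # refining the grid x10 locally does not find a deeper minimum beyond
    # one refined step
    jc <- which(freqs == mode$critical_frequency)
    lamfun <- function(f) {
      tfl <- transfer_function(net, wp, f)
      dkl <- delay_kernel(net, f)
      Ml <- effective_connectivity(net, tfl, dkl)[, , 1]
      min(Mod(1 - eigen(Ml, only.values = TRUE)$values[
        which.min(Mod(eigen(Ml, only.values = TRUE)$values -
                        mode$eigenvalue))]))
    }
    lo <- max(min(freqs), mode$critical_frequency - 5)
    hi <- min(max(freqs), mode$critical_frequency + 5)
    fine <- seq(lo, hi, length.out = 21)
    vals <- vapply(fine, lamfun, numeric(1))
    expect_lt(min(Mod(1 - mode$lambda_track)),
              min(vals) + 0.2 * abs(min(vals)) + 1e-9)
  }
})
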