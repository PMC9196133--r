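# Linear-response machinery: parabolic-cylinder transfer functions, delay
# kernels, effective connectivity, power spectra, and the eigenvalue
# sensitivity measure with its amplitude/frequency projections.

#' Parabolic-cylinder building block of the LIF transfer function
#'
#' Evaluates `Phi_w(x) = exp(x^2/4) U(i w tau_m - 1/2, x)` and its
#' x-derivative, with the exponential prefactor fused analytically into the
#' evaluation (no overflowing factor is ever formed). Values are returned in
#' scaled form `value * exp(logscale)` so that `|x|` up to 100 is supported;
#' the convenience fields `phi` and `dphi` carry the rescaled numbers (Inf
#' if genuinely outside double range).
#'
#' @param x dimensionless argument(s), `|x| <= 100`.
#' @param omega angular frequency (rad/s), may be negative.
#' @param tau_m membrane time constant (s).
#' @return list with complex vectors `phi`, `dphi`, the scaled mantissas
#'   `phi_scaled`, `dphi_scaled` and the common `logscale` vector.
#' @export
phi_omega <- function(x, omega, tau_m) {
  if (any(abs(x) > 100)) {
    stop("phi_omega: |x| > 100 is outside the supported precision box")
  }
  nu <- omega * tau_m
  if (abs(nu) > 600) {
    stop("phi_omega: |omega * tau_m| > 600 is outside the supported precision box")
  }
  out <- pcf_phi_cpp(abs(nu), as.numeric(x))
  phi <- out$phi
  dphi <- out$dphi
  if (nu < 0) {
    phi <- Conj(phi)
    dphi <- Conj(dphi)
  }
  scale <- exp(out$logscale)
  list(phi = phi * scale, dphi = dphi * scale,
       phi_scaled = phi, dphi_scaled = dphi, logscale = out$logscale)
}

#' Linear-response transfer function of LIF populations
#'
#' Complex gain `N(omega)` of the population firing rate to a small
#' modulation of the mean input, per population and frequency:
#' `N = sqrt(2) nu / sigma * 1/(1 + i omega tau_m) *
#'  (Phi'(x_th) - Phi'(x_0)) / (Phi(x_th) - Phi(x_0))`
#' with `x = sqrt(2) (V - mu)/sigma` (plus the colored-noise boundary shift
#' for the `cn_*` variants); the `cn_shift_filtered` variant multiplies by
#' the synaptic low-pass `1/(1 + i omega tau_s)`. The zero-frequency value
#' is obtained by evaluating at a tiny dimensionless frequency
#' (`omega tau_m = 1e-5`), whose limit is the DC susceptibility
#' `d phi / d mu`.
#'
#' At `f = 0` exactly, the analytic DC susceptibility
#' [siegert_rate_derivative_mu()] is returned instead: the printed
#' linear-response formula omits the refractory correction factor
#' `(1 - tau_r nu)` and therefore approaches the DC susceptibility only up
#' to O(tau_r nu) (see the methods vignette).
#'
#' @param net a [population_network()].
#' @param wp a `working_point` from [solve_rates_ode()] or
#'   [solve_rates_lstsq()].
#' @param freqs ordinary frequencies f in Hz (vector).
#' @param variant one of `"cn_shift_filtered"` (default), `"cn_shift"`,
#'   `"delta"`; `"taylor"` is not implemented.
#' @return object of class `transfer_function`: complex matrix `values`
#'   (P x F, units 1/(V s)), `freqs`, `variant`.
#' @export
transfer_function <- function(net, wp, freqs,
                              variant = c("cn_shift_filtered", "cn_shift",
                                          "delta", "taylor")) {
  variant <- match.arg(variant)
  if (variant == "taylor") {
    stop("transfer_function: variant 'taylor' is not implemented ",
         "(its series form is not part of this package; use 'cn_shift')")
  }
  P <- length(net$labels)
  Fn <- length(freqs)
  vals <- matrix(0 + 0i, P, Fn)
  alpha <- boundary_shift_alpha()
  for (a in seq_len(P)) {
    mu <- wp$mu[a]; sigma <- wp$sigma[a]; nu_rate <- wp$nu[a]
    tau_m <- net$tau_m[a]; tau_s_a <- if (variant == "delta") 0 else net$tau_s[a]
    shift <- (alpha / 2) * sqrt(tau_s_a / tau_m)
    # reflected arguments: Phi is evaluated at sqrt(2) (mu - V)/sigma
    x0 <- sqrt(2) * ((mu - net$V_0_rel[a]) / sigma - shift)
    xth <- sqrt(2) * ((mu - net$V_th_rel[a]) / sigma - shift)
    for (j in seq_len(Fn)) {
      omega <- 2 * pi * freqs[j]
      if (omega == 0) {
        vals[a, j] <- siegert_rate_derivative_mu(
          mu, sigma, tau_m, tau_s_a, net$tau_r[a],
          net$V_th_rel[a], net$V_0_rel[a]) + 0i
        next
      }
      nu_dim <- abs(omega) * tau_m
      pc <- pcf_phi_cpp(nu_dim, c(x0, xth))
      # common scale cancels in the ratio
      s_rel <- exp(pc$logscale - max(pc$logscale))
      dnum <- pc$dphi[2] * s_rel[2] - pc$dphi[1] * s_rel[1]
      dden <- pc$phi[2] * s_rel[2] - pc$phi[1] * s_rel[1]
      Nval <- -sqrt(2) * nu_rate / sigma / (1 + 1i * nu_dim) * dnum / dden
      if (omega < 0) Nval <- Conj(Nval)
      if (variant == "cn_shift_filtered") {
        Nval <- Nval / (1 + 1i * omega * tau_s_a)
      }
      vals[a, j] <- Nval
    }
  }
  structure(list(values = vals, freqs = freqs, variant = variant),
            class = "transfer_function")
}

#' Fourier-transformed delay distributions
#'
#' For each connection, the characteristic function of the delay
#' distribution evaluated at the analysis frequencies: a pure phase
#' `exp(-i omega d)` for fixed (`delta`) delays, or the characteristic
#' function of a Gaussian truncated at zero and renormalized
#' (`truncated_gaussian`).
#'
#' @param net a [population_network()].
#' @param freqs ordinary frequencies in Hz.
#' @return object of class `delay_kernel`: complex array `values`
#'   (P x P x F), `kind`, `freqs`.
#' @export
delay_kernel <- function(net, freqs) {
  P <- length(net$labels)
  Fn <- length(freqs)
  if (any(net$delay_sd < 0)) stop("delay_sd must be nonnegative")
  vals <- array(0 + 0i, c(P, P, Fn))
  for (j in seq_len(Fn)) {
    omega <- 2 * pi * freqs[j]
    if (net$delay_kind == "delta" || all(net$delay_sd == 0)) {
      vals[, , j] <- exp(-1i * omega * net$delay_mean)
    } else {
      vals[, , j] <- trunc_gauss_cf(omega, net$delay_mean, net$delay_sd)
    }
  }
  structure(list(values = vals, kind = net$delay_kind, freqs = freqs),
            class = "delay_kernel")
}

# characteristic function of a normal(d, s^2) truncated at 0, renormalized:
# D(w) = e^{-iwd} [2 e^{-B^2} - e^{-A^2 - 2iAB} w_F(-B + iA)] / (1 + erf(A)),
# A = d/(s sqrt(2)), B = w s / sqrt(2); all factors bounded by 1.
trunc_gauss_cf <- function(omega, d, s) {
  out <- matrix(0 + 0i, nrow(d), ncol(d))
  zero_sd <- s == 0
  out[zero_sd] <- exp(-1i * omega * d[zero_sd])
  if (any(!zero_sd)) {
    A <- d[!zero_sd] / (s[!zero_sd] * sqrt(2))
    B <- omega * s[!zero_sd] / sqrt(2)
    wf <- faddeeva_w(complex(real = B, imaginary = A))
    norm <- 1 + (2 * stats::pnorm(A * sqrt(2)) - 1) # 1 + erf(A)
    out[!zero_sd] <- exp(-1i * omega * d[!zero_sd]) *
      (2 * exp(-B^2) - exp(complex(real = -A^2, imaginary = 2 * A * B)) * wf) / norm
  }
  out
}

#' Effective connectivity matrix
#'
#' `M_d(omega) = tau_m * diag(N(omega)) (J * K * D(omega))` (elementwise
#' products), dimensionless, one P x P slice per frequency.
#'
#' @param net a [population_network()].
#' @param tf a [transfer_function()].
#' @param dk a [delay_kernel()] on the same frequency grid.
#' @return complex array (P x P x F).
#' @export
effective_connectivity <- function(net, tf, dk) {
  stopifnot(identical(tf$freqs, dk$freqs))
  P <- length(net$labels)
  Fn <- length(tf$freqs)
  anat <- net$J * net$K
  M <- array(0 + 0i, c(P, P, Fn))
  for (j in seq_len(Fn)) {
    M[, , j] <- (net$tau_m * tf$values[, j]) * anat * dk$values[, , j]
  }
  M
}

#' Population-rate power spectra
#'
#' Diagonal of the linear-response correlation matrix
#' `C(omega) = (1 - M)^-1 diag(nu / n) (1 - M(-omega))^-T`
#' evaluated per frequency via linear solves (no explicit inverse). With
#' `M(-omega) = conj(M(omega))` the diagonal is real and positive whenever
#' `1` is not an eigenvalue of `M`.
#'
#' @param net a [population_network()].
#' @param wp working point (provides `nu`).
#' @param tf transfer function (the filtered colored-noise variant).
#' @param dk delay kernel on the same frequency grid.
#' @return object of class `power_spectra`: real matrix `values` (P x F,
#'   units 1/s), `freqs`.
#' @export
power_spectra <- function(net, wp, tf, dk) {
  P <- length(net$labels)
  Fn <- length(tf$freqs)
  M <- effective_connectivity(net, tf, dk)
  d <- wp$nu / net$n
  out <- matrix(0, P, Fn)
  I <- diag(P)
  for (j in seq_len(Fn)) {
    A <- I - M[, , j]
    Y <- tryCatch(solve(A, diag(sqrt(d), P)),
                  error = function(e) NULL)
    if (is.null(Y)) {
      stop("power_spectra: (1 - M) singular at f = ", tf$freqs[j],
           " Hz (system at instability)")
    }
    out[, j] <- rowSums(Mod(Y)^2)
  }
  structure(list(values = out, freqs = tf$freqs), class = "power_spectra")
}

#' Eigenvalue sensitivity of the effective connectivity
#'
#' For eigenmode b of `M(omega)` with eigenvalue `lambda_b` and left/right
#' eigenvectors `v_b`, `u_b`, the matrix
#' `Z_b,cd = v_b,c M_cd u_b,d / (v_b . u_b)`
#' is the derivative of `lambda_b` with respect to a relative perturbation
#' of connection (c, d). `Z_amp` is the projection of each entry onto the
#' complex direction `(1 - lambda_b)/|1 - lambda_b|` (toward/away from the
#' instability point 1 + 0i), `Z_freq` the projection onto the
#' perpendicular direction.
#'
#' @param net a [population_network()].
#' @param wp working point.
#' @param tf transfer function.
#' @param dk delay kernel.
#' @param frequency evaluation frequency in Hz; must lie on the grid of
#'   `tf` (nearest grid point within 1e-9 relative is accepted).
#' @param mode eigenmode selector: `"closest"` (eigenvalue closest to
#'   1 + 0i, default) or an integer index into the eigenvalue ordering of
#'   [base::eigen()].
#' @return object of class `sensitivity_output` with fields `Z`, `Z_amp`,
#'   `Z_freq`, `eigenvalue`, `mode_index`, `frequency`, `left`, `right`.
#' @export
sensitivity_measure <- function(net, wp, tf, dk, frequency, mode = "closest") {
  j <- match_frequency(tf$freqs, frequency)
  M <- effective_connectivity(net, tf, dk)[, , j]
  sensitivity_from_M(M, frequency, mode)
}

sensitivity_from_M <- function(M, frequency, mode = "closest",
                               target_lambda = NULL) {
  P <- nrow(M)
  eg <- eigen(M)
  U <- eg$vectors
  condU <- tryCatch(kappa(U, exact = TRUE), error = function(e) Inf)
  if (!is.finite(condU) || condU > 1e10) {
    stop("sensitivity_measure: effective connectivity is (near-)defective ",
         "(eigenvector condition number ", format(condU), ")")
  }
  V <- solve(U) # rows are left eigenvectors, biorthonormal to columns of U
  b <- if (!is.null(target_lambda)) {
    which.min(Mod(eg$values - target_lambda))
  } else if (identical(mode, "closest")) {
    which.min(Mod(1 - eg$values))
  } else {
    stopifnot(is.numeric(mode), mode >= 1, mode <= P)
    as.integer(mode)
  }
  lambda <- eg$values[b]
  u <- U[, b]
  v <- V[b, ] # v . u = 1 by construction; keep the normalization explicit
  Z <- outer(v, u) * M / sum(v * u)
  dir <- (1 - lambda) / Mod(1 - lambda)
  kx <- Re(dir); ky <- Im(dir)
  Z_amp <- Re(Z) * kx + Im(Z) * ky
  Z_freq <- -Re(Z) * ky + Im(Z) * kx
  structure(list(Z = Z, Z_amp = Z_amp, Z_freq = Z_freq,
                 eigenvalue = lambda, mode_index = b,
                 frequency = frequency, left = v, right = u),
            class = "sensitivity_output")
}

match_frequency <- function(grid, frequency) {
  j <- which.min(abs(grid - frequency))
  if (abs(grid[j] - frequency) > 1e-9 * max(1, abs(frequency))) {
    stop("frequency ", frequency, " Hz is not on the analysis grid")
  }
  j
}

#' Sensitivity measure for all eigenmode trajectories
#'
#' Tracks the P eigenmodes of `M(omega)` across the frequency grid by
#' maximal eigenvector overlap, finds for each mode the frequency where its
#' eigenvalue is closest to the instability 1 + 0i (ties: lower frequency),
#' and evaluates [sensitivity_measure()] there.
#'
#' @inheritParams sensitivity_measure
#' @param overlap_min minimal eigenvector overlap between adjacent grid
#'   points below which mode tracking aborts with an error.
#' @return list of P `sensitivity_output` objects, one per eigenmode
#'   trajectory, each annotated with its critical frequency.
#' @export
sensitivity_all_eigenmodes <- function(net, wp, tf, dk, overlap_min = 0.4) {
  M <- effective_connectivity(net, tf, dk)
  P <- dim(M)[1]
  Fn <- dim(M)[3]
  lam <- matrix(0 + 0i, P, Fn)
  eg <- eigen(M[, , 1])
  lam[, 1] <- eg$values
  U_prev <- apply(eg$vectors, 2, function(c) c / sqrt(sum(Mod(c)^2)))
  U_prev <- matrix(U_prev, P, P)
  perm_prev <- seq_len(P)
  for (j in seq_len(Fn)[-1]) {
    eg <- eigen(M[, , j])
    U_cur <- apply(eg$vectors, 2, function(c) c / sqrt(sum(Mod(c)^2)))
    U_cur <- matrix(U_cur, P, P)
    overlap <- Mod(t(Conj(U_prev)) %*% U_cur) # rows: tracked, cols: new
    assign <- integer(P)
    taken <- rep(FALSE, P)
    # greedy assignment by decreasing overlap; ties broken by eigenvalue
    # proximity through the ordering of which.max
    for (rep_i in seq_len(P)) {
      om <- overlap
      om[assign != 0, ] <- -1
      om[, taken] <- -1
      ij <- which(om == max(om), arr.ind = TRUE)[1, ]
      if (om[ij[1], ij[2]] < overlap_min) {
        stop("sensitivity_all_eigenmodes: mode tracking ambiguous between ",
             "f = ", tf$freqs[j - 1], " and ", tf$freqs[j],
             " Hz (overlap ", format(om[ij[1], ij[2]]), ")")
      }
      assign[ij[1]] <- ij[2]
      taken[ij[2]] <- TRUE
    }
    lam[, j] <- eg$values[assign]
    U_prev <- U_cur[, assign, drop = FALSE]
  }
  out <- vector("list", P)
  for (b in seq_len(P)) {
    jstar <- which.min(Mod(1 - lam[b, ])) # first index on ties: lower f
    sens <- sensitivity_from_M(M[, , jstar], tf$freqs[jstar],
                               target_lambda = lam[b, jstar])
    sens$critical_frequency <- tf$freqs[jstar]
    sens$lambda_track <- lam[b, ]
    out[[b]] <- sens
  }
  out
}
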