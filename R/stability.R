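# Spiking-to-rate-model mapping and linear stability of the delayed,
# spatially structured rate network: working-point fixing via external
# rates, low-pass fit of the transfer function, boxcar profile transforms,
# and the Lambert-W characteristic equation on a ring.

#' External rates required to reach a target working point
#'
#' For a homogeneous network with one excitatory and one inhibitory
#' external Poisson source (relative inhibition g as in the recurrent
#' connectivity), solves the 2 x 2 linear system obtained from the input
#' statistics for the two unknown external rates such that the mean input
#' equals `target_mu` and the noise intensity `target_sigma`, given the
#' recurrent contributions at the self-consistent internal rates for that
#' working point.
#'
#' @param net a [population_network()] whose `J_ext`/`K_ext` have exactly
#'   two columns (excitatory first, inhibitory second) and whose rows are
#'   homogeneous across populations.
#' @param target_mu,target_sigma target working point (V).
#' @return list with `nu_ext` (Hz, length 2), the internal rates `nu_int`
#'   (Hz) and the recurrent-only contributions `mu_rec`, `sigma_rec`.
#' @export
external_rates_for_working_point <- function(net, target_mu, target_sigma) {
  P <- length(net$labels)
  if (ncol(net$J_ext) != 2) {
    stop("external_rates_for_working_point: network must have exactly two ",
         "external sources (excitatory, inhibitory)")
  }
  # internal rates are pinned by the target working point itself
  nu_int <- siegert_rate_exp(rep(target_mu, P), rep(target_sigma, P),
                             net$tau_m, net$tau_s, net$tau_r,
                             net$V_th_rel, net$V_0_rel)
  mu_rec <- net$tau_m * drop((net$J * net$K) %*% nu_int)
  var_rec <- net$tau_m * drop((net$J^2 * net$K) %*% nu_int)
  # per-population linear systems must agree for a homogeneous network
  JK1 <- net$tau_m * net$J_ext[, 1] * net$K_ext[, 1]
  JK2 <- net$tau_m * net$J_ext[, 2] * net$K_ext[, 2]
  J2K1 <- net$tau_m * net$J_ext[, 1]^2 * net$K_ext[, 1]
  J2K2 <- net$tau_m * net$J_ext[, 2]^2 * net$K_ext[, 2]
  b1 <- target_mu - mu_rec
  b2 <- target_sigma^2 - var_rec
  sol <- solve(matrix(c(JK1[1], J2K1[1], JK2[1], J2K2[1]), 2, 2),
               c(b1[1], b2[1]))
  # consistency across rows
  resid_mu <- JK1 * sol[1] + JK2 * sol[2] - b1
  resid_sg <- J2K1 * sol[1] + J2K2 * sol[2] - b2
  if (max(abs(resid_mu)) > 1e-9 * max(abs(target_mu), 1e-12) ||
      max(abs(resid_sg)) > 1e-9 * max(target_sigma^2, 1e-15)) {
    stop("external_rates_for_working_point: network rows are not ",
         "homogeneous; the target working point is not reachable for all ",
         "populations simultaneously")
  }
  if (any(sol < 0)) {
    stop("external_rates_for_working_point: target working point ",
         "unreachable; signed solution nu_ext = (",
         paste(format(sol), collapse = ", "), ") Hz")
  }
  list(nu_ext = sol, nu_int = nu_int,
       mu_rec = mu_rec, sigma_rec = sqrt(pmax(var_rec, 0)))
}

#' Fit a low-pass rate-model transfer function
#'
#' Fits the amplitude of `N_LP(omega) w_b = w_b / (1 + i omega tau)` to the
#' amplitude of the spiking model's effective transfer
#' `tau_m N(omega) J_ab K_ab`, jointly over presynaptic populations with the
#' structural constraint `w_I = -g w_E` (weights depend only on the
#' presynaptic population). The fit is amplitude-only, by nonlinear least
#' squares over `(tau, w_E)`. The combined fit error `eta` is the
#' root-mean-square relative amplitude error over the frequency grid
#' (a convention of this package).
#'
#' @param tf a [transfer_function()] computed at the working point.
#' @param net the corresponding [population_network()].
#' @param g ratio of inhibitory to excitatory weight magnitude.
#' @return object of class `lowpass_fit`: `tau` (s), `w_E`, `w_I = -g w_E`,
#'   `eta`, `fitted` (amplitude matrix 2 x F), `freqs`.
#' @export
fit_transfer_function <- function(tf, net, g) {
  P <- length(net$labels)
  if (P != 2) stop("fit_transfer_function: expects a 2-population network")
  target <- matrix(0 + 0i, 0, 0)
  Fn <- length(tf$freqs)
  # effective target tau_m * N_a * J_ab * K_ab, reduced to presynaptic columns
  cols <- vector("list", P)
  for (b in seq_len(P)) {
    rows <- sapply(seq_len(P), function(a) {
      net$tau_m[a] * tf$values[a, ] * net$J[a, b] * net$K[a, b]
    })
    rows <- t(rows) # P x F
    spread <- max(abs(sweep(rows, 2, rows[1, ], "-"))) /
      max(max(abs(rows)), 1e-300)
    if (spread > 1e-6) {
      stop("fit_transfer_function: postsynaptic rows differ by ",
           format(spread), " relative; select a row explicitly")
    }
    cols[[b]] <- rows[1, ]
  }
  amp <- rbind(Mod(cols[[1]]), Mod(cols[[2]])) # E and I presynaptic columns
  omegas <- 2 * pi * tf$freqs
  model_amp <- function(tau, w_E) {
    wmag <- c(w_E, g * w_E)
    outer(wmag, 1 / sqrt(1 + (omegas * tau)^2))
  }
  obj <- function(par) {
    m <- model_amp(par[1], par[2])
    sum((m - amp)^2)
  }
  # optimize in log space (tau and w_E are positive and live on very
  # different scales), then polish with damped Gauss-Newton
  obj_log <- function(lp) obj(exp(lp))
  init <- c(net$tau_m[1], max(amp[1, 1], 1e-12))
  opt <- stats::optim(log(init), obj_log, method = "L-BFGS-B",
                      lower = log(c(1e-6, 1e-12)), upper = log(c(1, 1e3)),
                      control = list(factr = 1e7, maxit = 1000))
  if (opt$convergence != 0 && !is.finite(opt$value)) {
    stop("fit_transfer_function: optimizer did not converge (code ",
         opt$convergence, "); last iterate tau = ",
         format(exp(opt$par[1])), ", w_E = ", format(exp(opt$par[2])))
  }
  par <- exp(opt$par)
  resid <- function(p) as.vector(model_amp(p[1], p[2]) - amp)
  for (gn in 1:40) {
    r0 <- resid(par)
    Jm <- sapply(1:2, function(j) {
      hp <- par; hm <- par
      h <- 1e-7 * max(abs(par[j]), 1e-9)
      hp[j] <- hp[j] + h; hm[j] <- hm[j] - h
      (resid(hp) - resid(hm)) / (2 * h)
    })
    delta <- tryCatch(qr.solve(Jm, -r0), error = function(e) NULL)
    if (is.null(delta)) break
    lam <- 1
    for (ls in 1:20) {
      cand <- pmax(par + lam * delta, c(1e-6, 1e-12))
      if (sum(resid(cand)^2) <= sum(r0^2)) break
      lam <- lam / 2
    }
    newpar <- pmax(par + lam * delta, c(1e-6, 1e-12))
    if (max(abs(newpar - par) / pmax(abs(par), 1e-12)) < 1e-14) {
      par <- newpar; break
    }
    par <- newpar
  }
  tau <- par[1]; w_E <- par[2]
  if (tau <= 0) stop("fit_transfer_function: nonpositive fitted tau rejected")
  fitted <- model_amp(tau, w_E)
  eta <- sqrt(mean(((fitted - amp) / amp)^2))
  structure(list(tau = tau, w_E = w_E, w_I = -g * w_E, g = g, eta = eta,
                 fitted = fitted, target_amp = amp, freqs = tf$freqs),
            class = "lowpass_fit")
}

#' Fourier transform of the spatial connectivity profile
#'
#' Boxcar of halfwidth R (normalized density on `[-R, R]`):
#' `p_hat(k) = sin(kR)/(kR)`, with the limit 1 at `k = 0`.
#'
#' @param profile a [spatial_profile()].
#' @param k wavenumber grid (1/m).
#' @return matrix (length(k) x P), one column per presynaptic population.
#' @export
profile_ft <- function(profile, k) {
  stopifnot(inherits(profile, "spatial_profile"))
  R <- profile$halfwidth
  out <- sapply(R, function(r) {
    x <- k * r
    ifelse(x == 0, 1, sin(x) / x)
  })
  matrix(out, nrow = length(k))
}

#' Temporal eigenvalues of the delayed spatial rate model
#'
#' Solves the characteristic equation `(1 + lambda tau) = c(k) exp(-lambda d)`
#' for each wavenumber and each requested Lambert-W branch:
#' `lambda_B(k) = -1/tau + W_B(c(k) (d/tau) exp(d/tau)) / d`,
#' where `c(k) = sum_b w_b p_hat_b(k)` is the effective connectivity
#' profile. The rightmost eigenvalue (over the principal branch) determines
#' stability; its imaginary part the oscillation frequency, and
#' `Im(lambda*)/k*` the phase velocity of predicted wave trains.
#'
#' @param fit a [fit_transfer_function()] result (fields `tau`, `w_E`, `w_I`).
#' @param profile a [spatial_profile()] with one halfwidth per presynaptic
#'   population (E, I).
#' @param d delay (s), common to all connections.
#' @param k wavenumber grid (1/m).
#' @param branches integer vector of Lambert-W branches.
#' @return object of class `branch_spectrum`: complex matrix `lambda`
#'   (branches x k, 1/s), `branches`, `k`, `c_k`, `lambda_star`, `k_star`,
#'   `oscillation_frequency` (Hz), `phase_velocity` (m/s), `tau`, `d`.
#' @export
characteristic_eigenvalues <- function(fit, profile, d, k, branches = -3:3) {
  stopifnot(d > 0, fit$tau > 0)
  if (!0L %in% branches) branches <- sort(c(0L, as.integer(branches)))
  tau <- fit$tau
  w <- c(fit$w_E, fit$w_I)
  phat <- profile_ft(profile, k)
  c_k <- drop(phat %*% w)
  z <- c_k * (d / tau) * exp(d / tau)
  lam <- matrix(NA_complex_, length(branches), length(k),
                dimnames = list(paste0("B", branches), NULL))
  for (bi in seq_along(branches)) {
    B <- branches[bi]
    for (j in seq_along(z)) {
      lam[bi, j] <- tryCatch(
        -1 / tau + lambert_w(z[j], B) / d,
        error = function(e) NA_complex_)
    }
    if (anyNA(lam[bi, ])) {
      warning("characteristic_eigenvalues: branch ", B,
              " undefined at ", sum(is.na(lam[bi, ])),
              " wavenumber(s); values masked")
    }
  }
  principal <- lam[branches == 0L, ]
  jstar <- which.max(Re(principal))
  lambda_star <- principal[jstar]
  k_star <- k[jstar]
  structure(list(
    lambda = lam, branches = branches, k = k, c_k = c_k,
    lambda_star = lambda_star, k_star = k_star,
    oscillation_frequency = Im(lambda_star) / (2 * pi),
    phase_velocity = if (k_star != 0) Im(lambda_star) / k_star else NA_real_,
    tau = tau, d = d
  ), class = "branch_spectrum")
}

#' Stability classification of a branch spectrum
#'
#' Classifies the rightmost principal-branch eigenvalue: `stable`
#' (`Re < 0`), `oscillatory instability` (`Re > 0`, `Im != 0`; wave trains
#' with the reported phase velocity when `k* > 0`), or `static instability`.
#'
#' @param spectrum a [characteristic_eigenvalues()] result.
#' @return list with `verdict`, `lambda_star`, `k_star`,
#'   `oscillation_frequency` (Hz), `phase_velocity` (m/s).
#' @export
stability_verdict <- function(spectrum) {
  ls <- spectrum$lambda_star
  verdict <- if (Re(ls) < 0) {
    "stable"
  } else if (abs(Im(ls)) > 1e-12 * max(1, abs(Re(ls)))) {
    "oscillatory instability"
  } else {
    "static instability"
  }
  list(verdict = verdict, lambda_star = ls, k_star = spectrum$k_star,
       oscillation_frequency = spectrum$oscillation_frequency,
       phase_velocity = spectrum$phase_velocity)
}

#' @export
print.branch_spectrum <- function(x, ...) {
  v <- stability_verdict(x)
  cat("branch spectrum on", length(x$k), "wavenumbers x",
      length(x$branches), "branches\n")
  cat("  lambda* =", format(x$lambda_star), "1/s at k* =",
      format(x$k_star), "1/m ->", v$verdict, "\n")
  if (!is.na(x$phase_velocity)) {
    cat("  oscillation", format(x$oscillation_frequency), "Hz, phase velocity",
        format(x$phase_velocity), "m/s\n")
  }
  invisible(x)
}

#' @export
print.lowpass_fit <- function(x, ...) {
  cat("low-pass fit: tau =", format(x$tau * 1e3), "ms, w_E =",
      format(x$w_E), ", w_I =", format(x$w_I),
      " (eta =", format(x$eta), ")\n")
  invisible(x)
}
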