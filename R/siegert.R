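# Stationary mean-field theory for LIF networks: Gaussian input statistics,
# the Siegert first-passage firing rate for white (delta-synapse) and fast
# colored (exponential-synapse) noise, and two self-consistency solvers.

#' Mean and noise intensity of the input to each population
#'
#' With signed weights J (inhibitory entries negative),
#' `mu_a = tau_m_a (sum_b J_ab K_ab nu_b + sum_x Jext_ax Kext_ax nuext_x)` and
#' `sigma_a^2 = tau_m_a (sum_b J_ab^2 K_ab nu_b + sum_x Jext_ax^2 Kext_ax nuext_x)`.
#'
#' @param net a [population_network()].
#' @param nu stationary rates in Hz (length P, nonnegative).
#' @return list with components `mu` (V) and `sigma` (V), each length P.
#' @export
input_stats <- function(net, nu) {
  P <- length(net$labels)
  if (length(nu) != P) stop("nu must have length ", P)
  if (any(nu < 0)) stop("rates must be nonnegative")
  mu <- net$tau_m * (drop((net$J * net$K) %*% nu) +
                       drop((net$J_ext * net$K_ext) %*% net$nu_ext))
  var <- net$tau_m * (drop((net$J^2 * net$K) %*% nu) +
                        drop((net$J_ext^2 * net$K_ext) %*% net$nu_ext))
  list(mu = as.numeric(mu), sigma = sqrt(as.numeric(var)))
}

# core of the stationary rate: I(y0, yth) = int_{y0}^{yth} erfcx(-s) ds,
# evaluated without ever forming exp(s^2) explicitly except inside the
# Dawson-based antiderivative of the suprathreshold piece:
#   s < 0:  erfcx(-s) = erfcx(|s|), bounded, smooth -> Gauss-Legendre panels
#   s > 0:  erfcx(-s) = 2 exp(s^2) - erfcx(s);
#           int 2 exp(s^2) ds = 2 [exp(b^2) D(b) - exp(a^2) D(a)]  (D = Dawson)
# Deep subthreshold bounds (yth large) genuinely overflow the double range
# when the rate underflows; the rate then returns 0.
siegert_integral <- function(y0, yth) {
  stopifnot(y0 < yth)
  total <- 0
  if (y0 < 0) {
    b <- min(yth, 0)
    total <- total + gl_integrate(function(s) erfcx(-s), y0, b, panel = 1)
  }
  if (yth > 0) {
    a <- max(y0, 0)
    total <- total + 2 * (exp(yth^2) * dawson(yth) - exp(a^2) * dawson(a)) -
      gl_integrate(erfcx, a, yth, panel = 1)
  }
  total
}

#' Stationary firing rate of a LIF neuron with instantaneous synapses
#'
#' Siegert first-passage rate
#' `phi(mu, sigma) = 1 / (tau_r + tau_m sqrt(pi) * I)` with
#' `I = int_{(V0-mu)/sigma}^{(Vth-mu)/sigma} exp(s^2)(1 + erf(s)) ds`,
#' evaluated with a numerically stabilized scheme (see the methods
#' vignette). All arguments are vectorized over populations.
#'
#' @param mu mean input (V).
#' @param sigma noise intensity (V), strictly positive.
#' @param tau_m,tau_r membrane and refractory time constants (s).
#' @param V_th_rel,V_0_rel threshold and reset relative to rest (V).
#' @return firing rate(s) in Hz, in `[0, 1/tau_r)`.
#' @export
siegert_rate_delta <- function(mu, sigma, tau_m, tau_r, V_th_rel, V_0_rel) {
  n <- max(length(mu), length(sigma), length(tau_m), length(tau_r),
           length(V_th_rel), length(V_0_rel))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  tau_m <- rep_len(tau_m, n); tau_r <- rep_len(tau_r, n)
  V_th_rel <- rep_len(V_th_rel, n); V_0_rel <- rep_len(V_0_rel, n)
  if (any(sigma <= 0)) {
    stop("sigma must be > 0 (the deterministic limit sigma -> 0 is not treated)")
  }
  if (any(V_th_rel <= V_0_rel)) stop("V_th_rel must exceed V_0_rel")
  out <- numeric(n)
  for (i in seq_len(n)) {
    y0 <- (V_0_rel[i] - mu[i]) / sigma[i]
    yth <- (V_th_rel[i] - mu[i]) / sigma[i]
    I <- siegert_integral(y0, yth)
    denom <- tau_r[i] + tau_m[i] * sqrt(pi) * I
    out[i] <- if (is.finite(denom)) 1 / denom else 0
  }
  out
}

#' Stationary firing rate with fast exponential synapses
#'
#' Same first-passage integral with both rescaled boundaries shifted by
#' `(alpha/2) sqrt(tau_s/tau_m)`, `alpha = sqrt(2) |zeta(1/2)| ~ 2.07`,
#' valid for `tau_s << tau_m` (a warning is issued above `tau_s/tau_m = 0.1`).
#'
#' @inheritParams siegert_rate_delta
#' @param tau_s synaptic time constant (s); `tau_s = 0` reduces exactly to
#'   [siegert_rate_delta()].
#' @return firing rate(s) in Hz.
#' @export
siegert_rate_exp <- function(mu, sigma, tau_m, tau_s, tau_r, V_th_rel, V_0_rel) {
  if (any(tau_s < 0)) stop("tau_s must be >= 0")
  if (any(tau_s / tau_m > 0.1)) {
    warning("tau_s/tau_m > 0.1: the boundary-shift approximation assumes ",
            "tau_s much smaller than tau_m")
  }
  shift <- boundary_shift_alpha() / 2 * sqrt(tau_s / tau_m) * sigma
  siegert_rate_delta(mu, sigma, tau_m, tau_r,
                     V_th_rel + shift, V_0_rel + shift)
}

#' Analytic derivative of the Siegert rate with respect to the mean input
#'
#' `d phi / d mu = phi^2 tau_m sqrt(pi) (erfcx(-y_th) - erfcx(-y_0)) / sigma`
#' with the (optionally shifted) rescaled boundaries `y = (V - mu)/sigma`.
#' This is the DC susceptibility: the exact zero-frequency limit of the
#' linear response, including the refractory correction.
#'
#' @inheritParams siegert_rate_exp
#' @return derivative in Hz/V, vectorized.
#' @export
siegert_rate_derivative_mu <- function(mu, sigma, tau_m, tau_s, tau_r,
                                       V_th_rel, V_0_rel) {
  shift <- boundary_shift_alpha() / 2 * sqrt(tau_s / tau_m) * sigma
  phi <- siegert_rate_exp(mu, sigma, tau_m, tau_s, tau_r, V_th_rel, V_0_rel)
  yth <- (V_th_rel + shift - mu) / sigma
  y0 <- (V_0_rel + shift - mu) / sigma
  phi^2 * tau_m * sqrt(pi) * (erfcx(-yth) - erfcx(-y0)) / sigma
}

# network-level rate map nu -> phi(mu(nu), sigma(nu)); uses the exponential
# synapse shift whenever the network declares tau_s > 0
network_rate_map <- function(net) {
  force(net)
  function(nu) {
    st <- input_stats(net, nu)
    out <- numeric(length(st$mu))
    live <- st$sigma > 0
    if (any(live)) {
      out[live] <- siegert_rate_exp(st$mu[live], st$sigma[live],
                                    net$tau_m[live], net$tau_s[live],
                                    net$tau_r[live], net$V_th_rel[live],
                                    net$V_0_rel[live])
    }
    # sigma = 0 means no input at all (all presynaptic rates zero); the
    # membrane then sits at rest below threshold and cannot fire
    if (any(!live & st$mu > net$V_th_rel)) {
      stop("deterministic suprathreshold drive with sigma = 0 is not treated")
    }
    out
  }
}

# damped Newton iteration on g(x) = x - phi(x) with box projection;
# returns the polished point or NULL if it fails to reach tol
newton_polish <- function(phi, x, upper, tol, maxit = 40) {
  P <- length(x)
  obj <- function(x) sum((x - phi(x))^2)
  res0 <- max(abs(x - phi(x)))
  for (it in seq_len(maxit)) {
    g <- x - phi(x)
    if (max(abs(g)) < tol) return(x)
    if (it == 12 && max(abs(g)) > 0.3 * res0) return(NULL) # not productive
    Jac <- diag(P)
    for (j in seq_len(P)) {
      h <- max(1e-7, 1e-7 * abs(x[j]))
      hi <- min(x[j] + h, upper[j]); lo <- max(x[j] - h, 0)
      e <- x; e[j] <- hi; f_hi <- phi(e)
      e[j] <- lo; f_lo <- phi(e)
      Jac[, j] <- Jac[, j] - (f_hi - f_lo) / (hi - lo)
    }
    step <- tryCatch(solve(Jac, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    for (ls in 1:25) {
      cand <- pmin(pmax(x - lambda * step, 0), upper)
      if (obj(cand) < obj(x)) break
      lambda <- lambda / 2
    }
    x_new <- pmin(pmax(x - lambda * step, 0), upper)
    if (max(abs(x_new - x)) < 1e-16 * max(1, max(abs(x)))) {
      x <- x_new
      break
    }
    x <- x_new
  }
  if (max(abs(x - phi(x))) < tol) x else NULL
}

new_working_point <- function(nu, net) {
  st <- input_stats(net, nu)
  structure(list(nu = nu, mu = st$mu, sigma = st$sigma), class = "working_point")
}

#' @export
print.working_point <- function(x, ...) {
  cat("working point:\n")
  cat("  nu    =", paste(format(x$nu, digits = 6), collapse = ", "), "Hz\n")
  cat("  mu    =", paste(format(x$mu * 1e3, digits = 6), collapse = ", "), "mV\n")
  cat("  sigma =", paste(format(x$sigma * 1e3, digits = 6), collapse = ", "), "mV\n")
  invisible(x)
}

#' Self-consistent rates via the auxiliary ODE
#'
#' Integrates `dnu/dt = -nu + phi(mu(nu), sigma(nu))` (dimensionless
#' auxiliary time) with an exponential-Euler scheme, which treats the stiff
#' linear decay exactly, until the residual `max |phi - nu|` drops below
#' `tol_ode` or `t_max` is reached (then an error carrying the trajectory
#' endpoint is raised).
#'
#' @param net a [population_network()].
#' @param analysis an [analysis_params()] (fields `nu_init`, `tol_ode`,
#'   `t_max` are used); may be `NULL` for defaults.
#' @return object of class `working_point` with fields `nu` (Hz), `mu` (V),
#'   `sigma` (V).
#' @export
solve_rates_ode <- function(net, analysis = NULL) {
  if (is.null(analysis)) analysis <- analysis_params()
  P <- length(net$labels)
  nu <- rep_len(analysis$nu_init, P)
  tol <- analysis$tol_ode
  t_max <- analysis$t_max
  phi <- network_rate_map(net)
  # exponential-Euler steps with adaptive step size: the stationary map of
  # stiff (strongly coupled) networks is not a contraction at large h, so
  # the step is halved whenever the residual grows and cautiously enlarged
  # while it shrinks
  h <- 0.2
  t <- 0
  upper <- 1 / pmax(net$tau_r, 1e-12)
  res_prev <- Inf
  res_scale <- NULL
  hist <- rep(Inf, 30) # rolling residual window for stall detection
  iter <- 0
  newton_budget <- 8
  repeat {
    iter <- iter + 1
    target <- phi(nu)
    res <- max(abs(target - nu))
    if (res < tol) break
    if (is.null(res_scale)) res_scale <- max(res, 1)
    stalled <- iter > 30 && res > 0.8 * hist[1]
    near <- res < max(1e-4 * res_scale, 0.5)
    if ((near || (stalled && res < 5)) && newton_budget > 0) {
      # endgame / rescue: Newton steps on the same fixed-point equation
      polished <- newton_polish(phi, nu, upper, tol)
      if (!is.null(polished)) { nu <- polished; break }
      newton_budget <- newton_budget - 1
    }
    if (stalled) {
      h <- max(h / 2, 1e-3) # oscillating around a stiff fixed point
      hist <- rep(Inf, 30)
    }
    hist <- c(hist[-1], res)
    if (res > res_prev * 1.000001 && h > 1e-3) {
      h <- h / 2
    } else if (res < 0.9 * res_prev) {
      h <- min(h * 1.2, 0.2)
    }
    res_prev <- res
    nu <- target + (nu - target) * exp(-h)
    nu <- pmin(pmax(nu, 0), upper)
    t <- t + h
    if (t > t_max) {
      cond <- simpleError(paste0(
        "ODE method did not converge within t_max = ", t_max,
        "; residual = ", format(max(abs(phi(nu) - nu)))))
      cond$nu <- nu
      stop(cond)
    }
  }
  new_working_point(nu, net)
}

#' Self-consistent rates via bounded least squares
#'
#' Minimizes `sum_a (nu_a - phi_a(nu))^2` with box bounds `[0, 1/tau_r]`
#' starting from `nu_init`, then polishes with a damped Newton iteration.
#' Raises an error if the final quadratic deviation exceeds `tol_lstsq`
#' (a local minimum that is not a self-consistent solution is never
#' returned silently).
#'
#' @inheritParams solve_rates_ode
#' @return object of class `working_point`.
#' @export
solve_rates_lstsq <- function(net, analysis = NULL) {
  if (is.null(analysis)) analysis <- analysis_params()
  P <- length(net$labels)
  nu0 <- rep_len(analysis$nu_init, P)
  phi <- network_rate_map(net)
  upper <- 1 / pmax(net$tau_r, 1e-12)
  # clamp: optim's finite-difference gradient may step just outside the box
  obj <- function(nu) {
    nu <- pmin(pmax(nu, 0), upper)
    sum((nu - phi(nu))^2)
  }
  opt <- stats::optim(nu0, obj, method = "L-BFGS-B",
                      lower = rep(0, P), upper = upper,
                      control = list(factr = 10, maxit = 500))
  nu <- opt$par
  polished <- newton_polish(phi, nu, upper, 1e-10)
  if (!is.null(polished)) nu <- polished
  dev <- obj(nu)
  if (!is.finite(dev) || dev > analysis$tol_lstsq) {
    stop("LSTSQ method converged to a non-self-consistent local minimum ",
         "(quadratic deviation ", format(dev), " > tol ",
         format(analysis$tol_lstsq), "); provide a better initial guess")
  }
  new_working_point(nu, net)
}
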