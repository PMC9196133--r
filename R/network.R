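#' Population-level network description
#'
#' Container for the full parameter set of a P-population network of LIF
#' neurons: per-population neuron constants, signed synaptic weight matrix
#' (volts), in-degree matrix, transmission delays, population sizes, and
#' external Poisson drive. All quantities are stored in SI units.
#'
#' The sign convention stores inhibitory weights as negative entries of `J`,
#' so the input statistics read mu = tau_m (sum J K nu + ext) and
#' sigma^2 = tau_m (sum J^2 K nu + ext) without case splits.
#'
#' @param labels character vector of P population names.
#' @param n population sizes (counts, length P).
#' @param J signed synaptic weight matrix (V, P x P), presynaptic in columns.
#' @param K in-degree matrix (counts, P x P).
#' @param J_ext signed external weights (V, P x E).
#' @param K_ext external in-degrees (P x E).
#' @param nu_ext external rates (Hz, length E).
#' @param tau_m,tau_s,tau_r membrane, synaptic, refractory time constants
#'   (s, scalar or length P). `tau_s = 0` selects instantaneous synapses.
#' @param V_th_rel,V_0_rel threshold and reset relative to rest (V, scalar
#'   or length P).
#' @param delay_mean,delay_sd delay distribution parameters (s, scalar or
#'   P x P).
#' @param delay_kind `"delta"` or `"truncated_gaussian"`.
#' @param spatial optional list of spatial boxcar profiles, see
#'   [spatial_profile()].
#' @return object of class `population_network`.
#' @export
population_network <- function(labels, n, J, K, J_ext, K_ext, nu_ext,
                               tau_m, tau_s = 0, tau_r,
                               V_th_rel, V_0_rel,
                               delay_mean = 0, delay_sd = 0,
                               delay_kind = c("delta", "truncated_gaussian"),
                               spatial = NULL) {
  P <- length(labels)
  delay_kind <- match.arg(delay_kind)
  as_mat <- function(x, nr, nc, what) {
    if (length(x) == 1) x <- matrix(x, nr, nc)
    x <- as.matrix(x)
    if (!all(dim(x) == c(nr, nc))) {
      stop("field '", what, "': expected ", nr, "x", nc, " matrix, got ",
           paste(dim(x), collapse = "x"))
    }
    x
  }
  as_pop <- function(x, what) {
    if (length(x) == 1) x <- rep(x, P)
    if (length(x) != P) stop("field '", what, "': expected length ", P)
    as.numeric(x)
  }
  J <- as_mat(J, P, P, "J")
  K <- as_mat(K, P, P, "K")
  J_ext <- as.matrix(J_ext)
  if (nrow(J_ext) != P) stop("field 'J_ext': expected ", P, " rows")
  E <- ncol(J_ext)
  K_ext <- as_mat(K_ext, P, E, "K_ext")
  if (length(nu_ext) != E) stop("field 'nu_ext': expected length ", E)
  net <- structure(list(
    labels = as.character(labels),
    n = as_pop(n, "n"),
    J = J, K = K, J_ext = J_ext, K_ext = K_ext,
    nu_ext = as.numeric(nu_ext),
    tau_m = as_pop(tau_m, "tau_m"),
    tau_s = as_pop(tau_s, "tau_s"),
    tau_r = as_pop(tau_r, "tau_r"),
    V_th_rel = as_pop(V_th_rel, "V_th_rel"),
    V_0_rel = as_pop(V_0_rel, "V_0_rel"),
    delay_mean = as_mat(delay_mean, P, P, "delay_mean"),
    delay_sd = as_mat(delay_sd, P, P, "delay_sd"),
    delay_kind = delay_kind,
    spatial = spatial
  ), class = "population_network")
  validate_network(net)
  net
}

#' Validate a population network
#'
#' Checks every structural invariant (positive time constants, threshold
#' above reset, nonnegative in-degrees and sizes, shape consistency) and
#' raises an error naming the offending field.
#'
#' @param net a [population_network()].
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  P <- length(net$labels)
  fail <- function(...) stop("invalid network: ", ..., call. = FALSE)
  if (any(net$tau_m <= 0)) fail("tau_m must be > 0")
  if (any(net$tau_s < 0)) fail("tau_s must be >= 0")
  if (any(net$tau_r < 0)) fail("tau_r must be >= 0")
  if (any(net$V_th_rel <= net$V_0_rel)) fail("V_th_rel must exceed V_0_rel")
  if (any(net$n <= 0)) fail("population sizes n must be > 0")
  if (any(net$K < 0)) fail("in-degrees K must be nonnegative")
  if (any(net$K_ext < 0)) fail("external in-degrees K_ext must be nonnegative")
  if (any(net$nu_ext < 0)) fail("external rates nu_ext must be nonnegative")
  if (any(net$delay_mean < 0)) fail("delay_mean must be nonnegative")
  if (any(net$delay_sd < 0)) fail("delay_sd must be nonnegative")
  if (!all(dim(net$J) == c(P, P))) fail("J shape inconsistent with P")
  invisible(net)
}

#' @export
print.population_network <- function(x, ...) {
  cat("population_network with", length(x$labels), "populations:",
      paste(x$labels, collapse = ", "), "\n")
  cat("  n =", paste(format(x$n), collapse = ", "), "\n")
  cat("  tau_m =", paste(format(x$tau_m * 1e3), collapse = ", "), "ms;",
      "tau_s =", paste(format(unique(x$tau_s) * 1e3), collapse = ", "), "ms;",
      "tau_r =", paste(format(unique(x$tau_r) * 1e3), collapse = ", "), "ms\n")
  cat("  V_th_rel =", paste(format(unique(x$V_th_rel) * 1e3), collapse = ", "),
      "mV; V_0_rel =", paste(format(unique(x$V_0_rel) * 1e3), collapse = ", "), "mV\n")
  cat("  delays:", x$delay_kind, "\n")
  invisible(x)
}

#' Analysis parameters
#'
#' Frequency and wavenumber grids plus solver options used by the dynamical
#' and stability tools.
#'
#' @param frequencies ordinary frequencies f in Hz (nonnegative, strictly
#'   increasing).
#' @param wavenumbers wavenumber grid in 1/m.
#' @param branches integer Lambert-W branch indices.
#' @param solver `"ode"` or `"lstsq"` for the rate self-consistency.
#' @param nu_init initial rates (Hz).
#' @param tol_ode residual tolerance for the ODE method (Hz).
#' @param t_max maximum dimensionless integration time for the ODE method.
#' @param tol_lstsq tolerance on the final quadratic deviation (Hz^2).
#' @return object of class `analysis_params`.
#' @export
analysis_params <- function(frequencies = NULL, wavenumbers = NULL,
                            branches = -3:3,
                            solver = c("ode", "lstsq"),
                            nu_init = 0,
                            tol_ode = 1e-9, t_max = 50,
                            tol_lstsq = 1e-12) {
  solver <- match.arg(solver)
  if (!is.null(frequencies)) {
    if (any(frequencies < 0)) stop("frequencies must be >= 0")
    if (is.unsorted(frequencies, strictly = TRUE)) {
      stop("frequencies must be strictly increasing")
    }
  }
  if (!is.null(wavenumbers) && any(!is.finite(wavenumbers))) {
    stop("wavenumber grid must be finite")
  }
  structure(list(
    frequencies = frequencies, wavenumbers = wavenumbers,
    branches = as.integer(branches), solver = solver,
    nu_init = nu_init, tol_ode = tol_ode, t_max = t_max,
    tol_lstsq = tol_lstsq
  ), class = "analysis_params")
}

#' Spatial connectivity profile
#'
#' Normalized symmetric boxcar connection-probability profile with
#' per-presynaptic-population halfwidth.
#'
#' @param halfwidth halfwidths R in meters (length P, one per presynaptic
#'   population).
#' @param kind only `"boxcar"` is implemented.
#' @return object of class `spatial_profile`.
#' @export
spatial_profile <- function(halfwidth, kind = "boxcar") {
  kind <- match.arg(kind, "boxcar")
  if (any(halfwidth <= 0)) stop("profile halfwidth must be > 0")
  structure(list(kind = kind, halfwidth = as.numeric(halfwidth)),
            class = "spatial_profile")
}
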