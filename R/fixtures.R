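# Deterministic parameter-set generators for tests and examples: EI
# networks (delta and exponential synapses), an 8-population
# microcircuit-like network, and a spatially structured ring network.
# All fixtures are pure functions of (flavor, seed, overrides).

#' Fixture specification
#'
#' @param flavor one of `"ei_delta"`, `"ei_exp"`, `"microcircuit_like"`,
#'   `"ring_spatial"`.
#' @param seed integer stored with the spec (fixtures are deterministic;
#'   the seed is recorded for provenance and used by parameter sweeps that
#'   request jitter).
#' @param overrides named list replacing individual default parameters
#'   (unknown names are an error).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(flavor = c("ei_delta", "ei_exp",
                                    "microcircuit_like", "ring_spatial"),
                         seed = 1L, overrides = list()) {
  flavor <- match.arg(flavor)
  structure(list(flavor = flavor, seed = as.integer(seed),
                 overrides = overrides), class = "fixture_spec")
}

fixture_defaults <- function(flavor) {
  switch(flavor,
    ei_delta = list(
      labels = c("E", "I"), n = c(4000, 1000),
      J_E = 0.1e-3, g = 5,
      K = matrix(c(400, 400, 100, 100), 2, 2),
      K_ext = matrix(c(400, 400), 2, 1),
      nu_ext = 30,
      tau_m = 20e-3, tau_s = 0, tau_r = 2e-3,
      V_th_rel = 20e-3, V_0_rel = 0,
      delay_mean = 1.5e-3, delay_sd = 0, delay_kind = "delta"
    ),
    ei_exp = list(
      labels = c("E", "I"), n = c(4000, 1000),
      J_E = 0.1e-3, g = 5,
      K = matrix(c(400, 400, 100, 100), 2, 2),
      K_ext = matrix(c(400, 400), 2, 1),
      nu_ext = 30,
      tau_m = 20e-3, tau_s = 0.5e-3, tau_r = 2e-3,
      V_th_rel = 20e-3, V_0_rel = 0,
      delay_mean = 1.5e-3, delay_sd = 0.75e-3, delay_kind = "truncated_gaussian"
    ),
    microcircuit_like = list(
      # 8-population cortical-microcircuit-like structure. The values are
      # plausible and documented, NOT a transcription of any published
      # parameter table; use load_network() with a user-supplied yaml file
      # for exact reproduction of a published circuit.
      labels = c("2/3E", "2/3I", "4E", "4I", "5E", "5I", "6E", "6I"),
      n = c(20683, 5834, 21915, 5479, 4850, 1065, 14395, 2948),
      J_E = 0.15e-3, g = 5,
      conn_prob = matrix(c(
        0.101, 0.169, 0.044, 0.082, 0.032, 0.000, 0.008, 0.000,
        0.135, 0.137, 0.032, 0.052, 0.075, 0.000, 0.004, 0.000,
        0.008, 0.006, 0.050, 0.135, 0.007, 0.000, 0.045, 0.000,
        0.069, 0.003, 0.079, 0.160, 0.003, 0.000, 0.106, 0.000,
        0.100, 0.062, 0.051, 0.006, 0.083, 0.373, 0.020, 0.000,
        0.055, 0.027, 0.026, 0.002, 0.060, 0.316, 0.009, 0.000,
        0.016, 0.007, 0.021, 0.017, 0.057, 0.020, 0.040, 0.225,
        0.036, 0.001, 0.003, 0.001, 0.028, 0.008, 0.066, 0.144),
        8, 8, byrow = TRUE),
      K_ext = matrix(c(2000, 1500, 2100, 1900, 2000, 1900, 2900, 2100), 8, 1),
      nu_ext = 8,
      tau_m = 10e-3, tau_s = 0.5e-3, tau_r = 2e-3,
      V_th_rel = 15e-3, V_0_rel = 0,
      delay_mean_E = 1.5e-3, delay_mean_I = 0.75e-3,
      delay_rel_sd = 0.5, delay_kind = "truncated_gaussian"
    ),
    ring_spatial = list(
      labels = c("E", "I"), n = c(20000, 5000),
      # many weak synapses: J K is large enough for delay-induced pattern
      # formation while J^2 K keeps the recurrent noise small, so the whole
      # working-point grid (6-14) x (4-14) mV stays reachable by external
      # drive
      J_E = 0.015e-3, g = 5,
      # equal in-degrees from E and I: rate-model weights then satisfy
      # w_I = -g w_E exactly (weights depend on the presynaptic population)
      K = matrix(5200, 2, 2),
      # one excitatory and one inhibitory external Poisson source (pooled
      # rates); defaults put the network close to the (10, 10) mV working
      # point (use external_rates_for_working_point() to hit it exactly)
      K_ext = matrix(1, 2, 2),
      nu_ext = c(3.7e6, 7.0e5),
      tau_m = 20e-3, tau_s = 0.5e-3, tau_r = 2e-3,
      V_th_rel = 20e-3, V_0_rel = 0,
      delay_mean = 1.5e-3, delay_sd = 0, delay_kind = "delta",
      # boxcar halfwidths (m): wider excitation than inhibition
      R_E = 0.5e-3, R_I = 0.1e-3
    ),
    stop("unknown fixture flavor '", flavor, "'")
  )
}

#' Build a network fixture
#'
#' Deterministic construction of a fully valid [population_network()] from
#' a [fixture_spec()]. `microcircuit_like` has 8 populations labeled
#' 2/3E ... 6I with alternating E/I sign structure; `ring_spatial` attaches
#' a boxcar [spatial_profile()] with wider excitation than inhibition.
#'
#' @param spec a [fixture_spec()], or a flavor string.
#' @param ... passed to [fixture_spec()] when `spec` is a string.
#' @return a [population_network()].
#' @export
make_network <- function(spec, ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  stopifnot(inherits(spec, "fixture_spec"))
  par <- fixture_defaults(spec$flavor)
  if (length(spec$overrides)) {
    bad <- setdiff(names(spec$overrides), names(par))
    if (length(bad)) {
      stop("unknown override key(s) for flavor '", spec$flavor, "': ",
           paste(bad, collapse = ", "))
    }
    par[names(spec$overrides)] <- spec$overrides
  }
  P <- length(par$labels)
  sign_col <- rep(c(1, -par$g), P / 2)
  J <- matrix(par$J_E, P, P) * matrix(sign_col, P, P, byrow = TRUE)
  if (spec$flavor == "microcircuit_like") {
    # in-degree: expected presynaptic partners under pairwise Bernoulli
    K <- sweep(par$conn_prob, 2, par$n, "*")
    dmean <- matrix(rep(rep(c(par$delay_mean_E, par$delay_mean_I), P / 2),
                        each = P), P, P)
    dsd <- dmean * par$delay_rel_sd
  } else {
    K <- par$K
    dmean <- matrix(par$delay_mean, P, P)
    dsd <- matrix(par$delay_sd, P, P)
  }
  E <- ncol(par$K_ext)
  J_ext <- matrix(par$J_E, P, E)
  if (E == 2) J_ext[, 2] <- -par$g * par$J_E # inhibitory external source
  spatial <- NULL
  if (spec$flavor == "ring_spatial") {
    spatial <- spatial_profile(c(par$R_E, par$R_I))
  }
  population_network(
    labels = par$labels, n = par$n, J = J, K = K,
    J_ext = J_ext, K_ext = par$K_ext, nu_ext = par$nu_ext,
    tau_m = par$tau_m, tau_s = par$tau_s, tau_r = par$tau_r,
    V_th_rel = par$V_th_rel, V_0_rel = par$V_0_rel,
    delay_mean = dmean, delay_sd = dsd, delay_kind = par$delay_kind,
    spatial = spatial
  )
}

#' Parameter sweep over a fixture
#'
#' One network per value, all other parameters fixed; the parameter path
#' must name a default parameter of the flavor (e.g. `"nu_ext"`, `"J_E"`).
#'
#' @param spec a [fixture_spec()].
#' @param path parameter name to vary.
#' @param values list or vector of replacement values.
#' @return list of [population_network()] objects (possibly empty).
#' @export
sweep_networks <- function(spec, path, values) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!path %in% names(fixture_defaults(spec$flavor))) {
    stop("sweep: parameter path '", path, "' not found for flavor '",
         spec$flavor, "'")
  }
  lapply(values, function(v) {
    ov <- spec$overrides
    ov[[path]] <- v
    make_network(fixture_spec(spec$flavor, spec$seed, ov))
  })
}

#' Write a fixture to a yaml parameter file
#'
#' Serializes a fixture network in the `explicit` flavor of the yaml
#' dialect (matrices as nested lists, quantities with `val`/`unit` keys).
#'
#' @param net a [population_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  mat2list <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  q <- function(v, unit) list(val = if (is.matrix(v)) mat2list(v) else as.numeric(v),
                              unit = unit)
  doc <- list(
    flavor = "explicit",
    labels = as.list(net$labels),
    n = as.list(net$n),
    J = q(net$J, "V"), K = mat2list(net$K),
    J_ext = q(net$J_ext, "V"), K_ext = mat2list(net$K_ext),
    nu_ext = q(net$nu_ext, "Hz"),
    tau_m = q(net$tau_m, "s"), tau_s = q(net$tau_s, "s"),
    tau_r = q(net$tau_r, "s"),
    V_th_rel = q(net$V_th_rel, "V"), V_0_rel = q(net$V_0_rel, "V"),
    delay_mean = q(net$delay_mean, "s"), delay_sd = q(net$delay_sd, "s"),
    delay_kind = net$delay_kind
  )
  if (!is.null(net$spatial)) {
    doc$spatial_halfwidth <- list(val = as.numeric(net$spatial$halfwidth),
                                  unit = "m")
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
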