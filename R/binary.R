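# Mean-field activity of binary-neuron networks, reusing the LIF
# self-consistency solvers.

#' Binary-neuron network
#'
#' In-degrees `K`, signed dimensionless weights `J`, thresholds `theta`.
#' Columns beyond the P internal populations represent external populations
#' with fixed activities `m_ext`.
#'
#' @param K in-degree matrix (P x (P + E)).
#' @param J signed weight matrix (dimensionless, P x (P + E)).
#' @param theta thresholds (length P).
#' @param m_ext fixed activities of the E external columns (in `[0, 1]`).
#' @return object of class `binary_network`.
#' @export
binary_network <- function(K, J, theta, m_ext = numeric(0)) {
  K <- as.matrix(K); J <- as.matrix(J)
  P <- nrow(K)
  if (!all(dim(K) == dim(J))) stop("K and J shapes differ")
  if (ncol(K) != P + length(m_ext)) {
    stop("K must have P + length(m_ext) columns")
  }
  if (length(theta) != P) stop("theta must have length P")
  if (length(m_ext) && (any(m_ext < 0) || any(m_ext > 1))) {
    stop("external activities must lie in [0, 1]")
  }
  structure(list(K = K, J = J, theta = as.numeric(theta),
                 m_ext = as.numeric(m_ext), P = P),
            class = "binary_network")
}

#' Mean activity map of a binary network
#'
#' `mu_a = sum_b K_ab J_ab m_b`, `sigma_a^2 = sum_b K_ab J_ab^2 m_b (1 - m_b)`,
#' `m_a = erfc((theta_a - mu_a) / (sqrt(2) sigma_a)) / 2`. The
#' deterministic limit `sigma_a = 0` returns the Heaviside step with value
#' 1/2 at equality.
#'
#' @param bnet a [binary_network()].
#' @param m internal activities (length P, in `[0, 1]`).
#' @return updated activities (length P).
#' @export
binary_mean_activity <- function(bnet, m) {
  if (length(m) != bnet$P) stop("m must have length ", bnet$P)
  if (any(m < 0) || any(m > 1)) stop("activities must lie in [0, 1]")
  mall <- c(m, bnet$m_ext)
  mu <- drop((bnet$K * bnet$J) %*% mall)
  var <- drop((bnet$K * bnet$J^2) %*% (mall * (1 - mall)))
  sigma <- sqrt(pmax(var, 0))
  out <- numeric(bnet$P)
  pos <- sigma > 0
  # erfc(x)/2 = pnorm(-x sqrt(2))
  out[pos] <- stats::pnorm(-(bnet$theta[pos] - mu[pos]) / sigma[pos])
  out[!pos] <- 0.5 * (1 + sign(mu[!pos] - bnet$theta[!pos]))
  out
}

#' Self-consistent binary mean activities
#'
#' Solves `m = m(mu(m), sigma(m))` with the same two methods as the LIF
#' rate solvers: damped fixed-point iteration of the auxiliary ODE
#' (`method = "ode"`) or bounded least squares with Newton polish
#' (`method = "lstsq"`), activities constrained to `[0, 1]`.
#'
#' @param bnet a [binary_network()].
#' @param method `"ode"` or `"lstsq"`.
#' @param m_init initial activities.
#' @param tol residual tolerance.
#' @param t_max maximum auxiliary time for the ODE method.
#' @return self-consistent activities (length P).
#' @export
solve_binary_activity <- function(bnet, method = c("ode", "lstsq"),
                                  m_init = 0.5, tol = 1e-12, t_max = 200) {
  method <- match.arg(method)
  P <- bnet$P
  m <- pmin(pmax(rep_len(m_init, P), 0), 1)
  phi <- function(m) binary_mean_activity(bnet, m)
  if (method == "ode") {
    h <- 0.5; decay <- exp(-h); t <- 0
    repeat {
      target <- phi(m)
      if (max(abs(target - m)) < tol) break
      m <- pmin(pmax(target + (m - target) * decay, 0), 1)
      t <- t + h
      if (t > t_max) {
        stop("binary ODE method did not converge; residual = ",
             format(max(abs(phi(m) - m))))
      }
    }
  } else {
    obj <- function(m) sum((m - phi(m))^2)
    opt <- stats::optim(m, obj, method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(factr = 10, maxit = 500))
    m <- opt$par
    for (it in 1:50) {
      g <- m - phi(m)
      if (max(abs(g)) < tol) break
      Jac <- diag(P)
      for (j in seq_len(P)) {
        h <- 1e-7
        hi <- min(m[j] + h, 1); lo <- max(m[j] - h, 0)
        e <- m; e[j] <- hi; fhi <- phi(e)
        e[j] <- lo; flo <- phi(e)
        Jac[, j] <- Jac[, j] - (fhi - flo) / (hi - lo)
      }
      step <- tryCatch(solve(Jac, g), error = function(e) NULL)
      if (is.null(step)) break
      m <- pmin(pmax(m - step, 0), 1)
    }
    if (obj(m) > max(tol^2, 1e-18)) {
      stop("binary LSTSQ method converged to a non-self-consistent local ",
           "minimum (deviation ", format(obj(m)), ")")
    }
  }
  m
}
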