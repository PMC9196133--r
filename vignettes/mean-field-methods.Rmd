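---
title: "Mean-field methods for LIF and binary networks: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field methods for LIF and binary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mfnet)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic fixtures do and do not establish, and the design
decisions taken where the design was genuinely open.

## 1. The diffusion approximation and its assumptions

All LIF tools rest on one approximation: a neuron embedded in a large,
sparsely and randomly connected network receives so many small, weakly
correlated inputs that its total input current is well described by Gaussian
noise with mean $\mu_a$ and intensity $\sigma_a$, both set by the
population-resolved connectivity (in-degrees $K$, weights $J$ in volts) and
the presynaptic rates. This is accurate for asynchronous–irregular states
and degrades when activity is strongly correlated, when single inputs are
large, or when common external drive dominates. With signed weights stored
directly (inhibitory entries of $J$ negative), the input statistics are

$$\mu_a = \tau_m\Big(\sum_b J_{ab}K_{ab}\nu_b + \text{ext}\Big),\qquad
\sigma_a^2 = \tau_m\Big(\sum_b J_{ab}^2K_{ab}\nu_b + \text{ext}\Big),$$

a single code path with no excitatory/inhibitory case split (`input_stats()`).

## 2. The stationary rate and its stabilized evaluation

The white-noise LIF rate is the inverse mean first-passage time

$$\phi(\mu,\sigma)=\Big(\tau_r+\tau_m\sqrt{\pi}
\int_{\tilde V_0}^{\tilde V_{th}} e^{s^2}(1+\mathrm{erf}(s))\,ds\Big)^{-1},
\qquad \tilde V = \frac{V-\mu}{\sigma}.$$

The integrand equals $\mathrm{erfcx}(-s)$, which is the key to a stable
scheme: for $s<0$ it is bounded by ~1.13 and integrated directly with
Gauss–Legendre panels; for $s>0$ it is split as
$2e^{s^2}-\mathrm{erfcx}(s)$, whose first part has the closed antiderivative
$2e^{b^2}D(b)$ (Dawson function) and whose second part is again bounded.
No factor $e^{s^2}$ is ever formed at an argument where it could overflow
*relative to the result*; when the first-passage integral genuinely exceeds
the double range (deeply subthreshold, $\tilde V_{th}\gtrsim 27$) the rate
underflows to 0, which is the mathematically correct double. A separate
subthreshold asymptotic branch proved unnecessary: the erfcx/Dawson scheme
is uniformly accurate (checked against raw-integrand adaptive quadrature to
better than $10^{-12}$ relative wherever that oracle is representable).
$\sigma = 0$ with nonzero drive is rejected — the deterministic, mean-driven
limit obeys a different formula that this package does not implement; a
fully silent network ($\sigma = 0$ because *nothing* fires and no drive) is
the zero rate.

**Fast colored noise.** Exponential synapses with $\tau_s \ll \tau_m$ shift
both integration boundaries by $\frac{\alpha}{2}\sqrt{\tau_s/\tau_m}$ with
$\alpha = \sqrt{2}\,|\zeta(1/2)| \approx 2.0653$ (the package computes
$\zeta$ itself, by Borwein's alternating-series algorithm). The
approximation is first order in $\sqrt{\tau_s/\tau_m}$; the package warns —
deliberately does not refuse — above $\tau_s/\tau_m = 0.1$.

## 3. Solving the self-consistency problem

`solve_rates_ode()` integrates $\dot\nu = -\nu + \phi(\mu(\nu),\sigma(\nu))$
with an exponential-Euler step (exact on the linear decay), adaptive step
size, stall detection, and a damped-Newton endgame on the *same* fixed-point
residual; it stops only when $\|\nu-\phi\|_\infty <$ `tol_ode` (default
$10^{-9}$ Hz) and errors out, carrying the trajectory endpoint, if `t_max`
is exhausted. Strong coupling makes the map stiff: the plain damped
iteration then orbits the fixed point, which is why the stall rescue exists.
`solve_rates_lstsq()` minimizes $\sum_a(\nu_a-\phi_a)^2$ with box bounds
$[0, 1/\tau_r]$, polishes by Newton, and *refuses* to return when the final
deviation exceeds `tol_lstsq` — a local minimum is not a solution. It exists
because the ODE method cannot reach self-consistent states that are unstable
fixed points of the auxiliary dynamics; it needs a good initial guess, which
remains the caller's responsibility.

## 4. The transfer function and the parabolic cylinder evaluator

The linear response of the rate to a mean-input modulation at angular
frequency $\omega$ is, in the shift approximation,

$$N(\omega)=\frac{\sqrt2\,\nu}{\sigma}\,\frac{1}{1+i\omega\tau_m}\,
\frac{\Phi_\omega'\big|_{x_0}^{x_{th}}}{\Phi_\omega\big|_{x_0}^{x_{th}}},
\qquad \Phi_\omega(x)=e^{x^2/4}U(i\omega\tau_m-\tfrac12,x),$$

with arguments $x = \sqrt2\,\big((\mu-V)/\sigma - \text{shift}\big)$
(the reflected convention; the unreflected reading produces a *negative*
DC gain and is excluded by the susceptibility oracle below). The filtered
variant multiplies by the synaptic low-pass $1/(1+i\omega\tau_s)$; the
`taylor` series variant is a documented not-implemented error.

**Numerics.** No R package evaluates $U(a,x)$ with complex order, and the
naive prefactor $e^{x^2/4}$ overflows exactly where the formula needs it.
The compiled evaluator exploits that $\Phi$ solves
$\Phi'' = x\Phi' + i\omega\tau_m\Phi$ and is *recessive* at $x\to+\infty$
(where $\Phi \sim x^{-i\omega\tau_m}$, modulus ~1): it starts from the
asymptotic series at a point right of all requested arguments (retreating
further right until the series converges to $10^{-16}$), then integrates
backward with an adaptive Dormand–Prince RK45 step. Backward integration is
stable because the contaminating solution ($\sim e^{x^2/2}$) decays toward
smaller $x$; for $x<0$, $\Phi$ itself becomes the dominant solution and
grows like $e^{x^2/2}$, so the state is renormalized on the fly and a log
scale factor is carried separately — ratios of $\Phi$ values at different
arguments (all the transfer function needs) remain exact. The supported box
$|x|\le 100$, $|\omega\tau_m|\le 600$ is enforced with a hard error rather
than silent precision loss. In-repo validation: the closed form at $x=0$
via the complex gamma function, the identity $\Phi_0 \equiv 1$ (since
$U(-\tfrac12,x)=e^{-x^2/4}$), Schwarz reflection $\Phi_{-\omega} =
\overline{\Phi_\omega}$, finite-difference derivative consistency, and the
defining ODE as a local residual.

**The zero-frequency special case.** The printed formula's $\omega\to 0$
limit is *not* the DC susceptibility when $\tau_r>0$: it equals
$\frac{d\phi}{d\mu}\cdot(1-\tau_r\nu)^{-1}$ exactly (the prefactor carries
the full rate $\nu$ while the first-passage ratio describes the
non-refractory process — verified numerically to $10^{-8}$ across working
points). Since the physically correct DC gain is $d\phi/d\mu$ by the chain
rule, `transfer_function()` returns the *analytic* derivative
`siegert_rate_derivative_mu()` at exactly $f=0$ —
$\phi^2\tau_m\sqrt{\pi}\,(\mathrm{erfcx}(-\tilde V_{th})-
\mathrm{erfcx}(-\tilde V_0))/\sigma$, a closed form, not a finite
difference — and the printed formula for every $f>0$. The discontinuity is
$O(\tau_r\nu)$ and documented here rather than hidden.

## 5. Delays, spectra, sensitivity

Delay distributions enter as their characteristic functions: a pure phase
$e^{-i\omega d}$ for fixed delays, and for Gaussian delays truncated at zero
the renormalized form

$$D(\omega)=e^{-i\omega d}\,
\frac{2e^{-B^2}-e^{-A^2+2iAB}\,w(B+iA)}{1+\mathrm{erf}(A)},\quad
A=\frac{d}{s\sqrt2},\ B=\frac{\omega s}{\sqrt2},$$

derived from first principles and written so every factor is bounded by 1
($w$ is the Faddeeva function, evaluated by Weideman's rational
approximation). Validated against direct quadrature of the truncated
density.

Power spectra follow the linear-response correlation matrix; the solver
factorizes $(1-M(\omega))$ per frequency (explicit inverses appear only in
test oracles), returns the strictly positive real diagonal, and names the
frequency if the system sits at an instability. The sensitivity measure is
first-order eigenvalue perturbation theory — left/right eigenvectors from
one `eigen()` call plus a linear solve, with a degeneracy error when the
eigenvector condition number exceeds $10^{10}$. Mode identity across a
frequency grid is tracked by maximal eigenvector overlap (plain sorting by
eigenvalue scrambles crossing modes); tracking aborts with an error when the
best overlap falls below 0.4. Ties in "closest to instability" resolve to
the lower frequency.

## 6. Rate-model mapping and delayed spatial stability

Pinning a homogeneous two-population network to a target $(\mu,\sigma)$ is a
linear problem: the internal rates at the target are known
($\nu = \phi(\mu,\sigma)$), so the two unknown external rates solve a
$2\times2$ system; a negative solution means the target is unreachable and
is reported as such, with the signed rates. The transfer-function fit is
amplitude-only nonlinear least squares of $|w_b/(1+i\omega\tau)|$ against
$|\tau_m N(\omega) J_{ab}K_{ab}|$ with the structural constraint
$w_I=-g\,w_E$ (weights depend only on the presynaptic population; if the
postsynaptic rows of the target differ beyond $10^{-6}$ relative the fit
refuses). Optimization runs in log-parameters (τ and $w_E$ live on very
different scales) and is polished by damped Gauss–Newton to recover
manufactured ground truth at machine precision. The combined fit error
$\eta$ is defined *in this package* as the root-mean-square relative
amplitude error over the frequency grid — the source material names but
does not define it.

The delayed ring model's characteristic equation
$(1+\lambda\tau) = c(k)e^{-\lambda d}$ is solved exactly on each Lambert-W
branch. The Lambert evaluator uses branch-appropriate starting points
(branch-point series near $-1/e$, Maclaurin series near 0, $\log$-based
guesses elsewhere) and Halley iteration to $\sim10^{-15}$ residual; every
returned $\lambda$ is verified against the characteristic relation itself,
a residual that is independent of branch bookkeeping. One subtlety: with the
standard principal-log branch convention, complex-conjugate partners are
branches $(B,-B)$ for $c(k)\ge0$ but $(B,-B-1)$ for $c(k)<0$ (the branch
cut); "eigenvalues come in conjugate pairs" holds, but branch-aware. The
verdict classifier reads the principal branch only: $\mathrm{Re}\,\lambda^*>0$
with $\mathrm{Im}\,\lambda^*\ne0$ at $k^*>0$ predicts wave trains with phase
velocity $\mathrm{Im}\,\lambda^*/k^*$.

## 7. Binary neurons

Mean activities $m_a=\tfrac12\mathrm{erfc}\big((\theta_a-\mu_a)/
(\sqrt2\sigma_a)\big)$ with $\mu_a=\sum_bK_{ab}J_{ab}m_b$ and
$\sigma_a^2=\sum_bK_{ab}J_{ab}^2m_b(1-m_b)$ reuse the same two solvers with
activities confined to $[0,1]$. The $\sigma_a=0$ limit is the Heaviside step
with value $\tfrac12$ at equality (the pointwise limit). External
populations are extra columns with fixed activities.

## 8. What the fixtures emulate — and what a green test does not establish

The fixture generators are pure functions of (flavor, seed, overrides) and
produce the *structure* of four archetypes:

* `ei_delta` / `ei_exp`: inhibition-dominated two-population networks
  (J_E = 0.1 mV, g = 5, K_E = 400, K_I = 100, 30 Hz external drive) in an
  asynchronous-irregular-like operating point around 17–19 Hz.
* `microcircuit_like`: eight populations (2/3E … 6I) with literature-style
  sizes and connection probabilities, g = 5, J_E = 0.15 mV, external
  in-degrees chosen so all populations are active and the operating point is
  linearly stable (spectral margin $\min|1-\lambda|\approx0.06$). It is
  **not** a transcription of any published parameter table; reproducing a
  published circuit's spectra (e.g. a specific low-γ peak frequency)
  requires loading that table via the yaml `microcircuit8` flavor.
* `ring_spatial`: a two-population ring with boxcar profiles (wider
  excitation, 0.5 mm vs 0.1 mm), many weak synapses (K = 5200,
  J_E = 0.015 mV) so that the whole working-point grid
  (6–14) × (4–14) mV is reachable by nonnegative external rates *and* the
  fitted rate model crosses its delay-induced Hopf bifurcation at
  d = 1.5 ms.

These choices were made once, on the grounds above, and are not tuned to
tests. A green suite establishes that the implemented formulas are
internally consistent and match their independent oracles on these
structures — not that any specific published network's numbers are
reproduced, which requires that network's exact parameters as input.

## 9. Numerical conventions and degenerate inputs

* Public frequency interfaces take ordinary frequency $f$ in Hz;
  $\omega=2\pi f$ internally.
* Unit handling is a closed table (s/ms, V/mV, A/nA/pA, Hz, 1/mm, 1/m,
  m/mm, dimensionless); anything else is an error. m/mm were added to the
  set because spatial halfwidths are lengths.
* Cache keys are canonical full-precision serializations of the SI
  parameters (order-independent, no hashing) — collisions are impossible by
  construction, and float tolerance in keys is deliberately absent: silent
  staleness is worse than recomputation.
* HDF5 export writes one group per quantity, one subgroup per parameter
  digest, complex arrays as `.re`/`.im` dataset pairs, units and digests as
  attributes; the layout is this package's own and documented, not claimed
  identical to any other tool's.
* Yaml keys that look like YAML 1.1 booleans (notably the population-size
  key `n`) are preserved as strings by explicit parser handlers.
* Empty wavenumber/frequency edge cases: $\hat p(0)=1$ (boxcar limit),
  $D(0)=1$ (normalization), $W_0(0)=0$ and an error for other branches at 0.

## 10. Known limitations

* The transfer function is a low-frequency approximation; spectra are
  systematically overestimated at high frequencies, and harmonics of strong
  peaks are outside linear response.
* No response to noise-intensity ($\sigma$) modulation; mean modulation only.
* The colored-noise rate and transfer function require
  $\tau_s \ll \tau_m$; no large-$\tau_s$ complement is implemented.
* The deterministic $\sigma\to0$, mean-driven limit is out of scope.
* The `taylor` transfer-function variant is intentionally unimplemented.
* No numerical bifurcation continuation; the stability module evaluates the
  characteristic equation on user grids.
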