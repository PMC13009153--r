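---
title: "Dynamics and bifurcations of a discrete Ricker-Holling predator-prey map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics and bifurcations of a discrete Ricker-Holling predator-prey map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rickerpp)
```

## The model

The package studies the two-dimensional difference equation

$$
x_{n+1} = x_n + r x_n e^{1-x_n} - \frac{\alpha x_n y_n}{1+x_n},
\qquad
y_{n+1} = y_n + \frac{\alpha x_n y_n}{1+x_n} - \gamma y_n .
$$

Prey $x$ reproduce by Ricker (over-compensatory) growth: near-exponential at
low density, with the per-capita rate falling off as $e^{-x}$ at high
density.  Predation follows a Holling type II functional response
$\alpha x y/(1+x)$, which saturates in prey density (handling-time
limitation) and feeds the predator equation one-for-one; predators $y$ die
at constant rate $\gamma$.  All three parameters are dimensionless and
strictly positive.  All state variables are densities; the map itself is
defined on all of $\mathbb{R}^2$ (minus the pole at $x=-1$), and the package
deliberately iterates the *raw* map: orbits that leave the non-negative
quadrant are flagged as biologically inadmissible but never clamped, because
clamping would alter the bifurcation structure being studied.

Two fixed points organize the dynamics.  The extinction state
$p_0 = (0,0)$ always exists; its multipliers are exactly
$\{1 + re,\; 1-\gamma\}$, and since $1 + re > 1$ for every $r > 0$, $p_0$ is
a saddle whenever $0 < \gamma < 2$ (prey always invade an empty
environment).  The coexistence state

$$
p_1 = \left(\frac{\gamma}{\alpha-\gamma},\;
  \frac{r}{\alpha-\gamma}\, e^{(\alpha-2\gamma)/(\alpha-\gamma)}\right)
$$

exists iff $\alpha > \gamma$ (conversion must outpace mortality).  Its prey
coordinate is independent of $r$; only the predator level scales with the
prey growth rate.

## Stability and the two codimension-one bifurcations

At $p_1$ the characteristic polynomial
$R(\rho) = \rho^2 - \mathrm{trace}\,\rho + \det$ has coefficients *linear*
in $r$:

$$
\mathrm{trace} = 2 - c_P\, r, \qquad \det = 1 + c_q\, r,
$$
$$
c_P = \frac{\gamma^2 E}{\alpha(\alpha-\gamma)}, \qquad
c_q = \frac{\gamma(\gamma^2-\gamma+\alpha^2-2\alpha\gamma)E}
           {\alpha(\alpha-\gamma)}, \qquad
E = e^{(\alpha-2\gamma)/(\alpha-\gamma)} .
$$

The package uses one sign convention everywhere (`R(rho) = rho^2 -
trace*rho + det`) and classifies by the jury conditions: local asymptotic
stability iff $R(1)>0$, $R(-1)>0$ and $\det<1$.  Three structural facts
shape everything downstream:

* $R(1) = rE\gamma(\alpha-\gamma)^2/(\alpha(\alpha-\gamma)) > 0$
  automatically.  A criterion demanding $R(1) = 0$ for the flip is therefore
  unsatisfiable; flip criticality is $R(-1) = 0$, and
  `stability_report()` records this convention under
  `corrections_applied`.
* $R(-1) = 4 + \text{(slope)}\, r$ is linear in $r$, so the flip
  threshold has the closed form returned by `critical_r_flip()`; it exists
  iff the slope is negative.  `locate_flip_numeric()` re-derives it by
  bisection as an independent cross-check.
* $\det - 1 = c_q r$ is proportional to $r$.  A Neimark-Sacker crossing at
  an isolated $r > 0$ therefore cannot occur: either $c_q \neq 0$ and the
  complex pair sits strictly off the unit circle for all $r>0$ on one side,
  or the parameters lie on the degenerate surface
  $\gamma^2-\gamma+\alpha^2-2\alpha\gamma = 0$ (e.g. $\alpha=2,\gamma=1$),
  where $\det \equiv 1$ for *every* $r$ and the radial transversality
  derivative vanishes.  The first Lyapunov coefficient is consequently
  exposed as a standalone computation at user-supplied
  $(\alpha, \gamma, r)$ rather than tied to a solved critical $r$.

## Normal forms

**Neimark-Sacker.**  `ns_normal_form()` shifts $p_1$ to the origin, expands
to third order (coefficients $B_{ij}$; the quadratic/cubic ones come from
the derivatives of $rxe^{1-x}$ and $\alpha xy/(1+x)$ and are verified in the
tests against a finite-difference Taylor oracle), transforms with
$T = (B_{12}, 0;\ \eta-B_{11}, -\zeta)$ to the rotation normal form, and
assembles $\delta_{11}, \delta_{20}, \delta_{02}, \delta_{21}$ and

$$
\chi = -\mathrm{Re}\!\left[\frac{(1-2\bar\rho)\bar\rho^2}{1-\rho}
  \delta_{11}\delta_{20}\right] - \tfrac12|\delta_{11}|^2 - |\delta_{02}|^2
  + \mathrm{Re}(\bar\rho\,\delta_{21}),
$$

with $\chi<0$ signalling an attracting invariant closed curve.  Two
numerical design choices matter here.  First, the transformed coefficients
$A_{ij}$ are derived by carrying out the substitution rather than taken from
a table; every one of them is checked against finite-difference Taylor
coefficients of the numerically conjugated map (relative agreement
$\le 10^{-4}$, most $\le 10^{-5}$).  Second, $\delta_{21}$ uses the reduction
of the general definition, $(3A_{11}+A_{24}+i(3A_{21}-A_{14}))/8$: the
$A_{14}$ term (not $A_{24}$) is what makes $\chi$ exactly invariant under
the conjugate choice of $\rho$, an invariance the test suite asserts at
$10^{-8}$.  Strong resonances $\rho^m = 1$, $m \le 4$, are excluded with
tolerance $10^{-6}$ on $|\rho^m - 1|$ and refused with an informative error.

**Flip.**  `flip_analysis()` locates $r_c$, forms the eigenbasis
$M = (\tilde B_{12}, \tilde B_{12};\ -1-\tilde B_{11}, \rho_2-\tilde B_{11})$,
computes the center manifold $Y = k_1X^2 + k_2Xr^*$ ($k_0 = k_3 = 0$), and
collects the reduced map

$$
L(X) = -X + n_1X^2 + n_2Xr^* + n_3X^2r^* + n_4X(r^*)^2 + n_5X^3 ,
$$

with criticality quantities $\varpi_1 = n_2$ and
$\varpi_2 = n_5 + n_1^2$; $\varpi_2 > 0$ means the bifurcating period-2
points are stable (supercritical flip).  The $n_i$ are derived by the
center-manifold substitution procedure itself — collecting orders after
substituting $Z(X, r^*)$ — rather than transcribed from closed-form tables,
and are validated against a fully numerical restriction oracle: the actual
map is conjugated by $M$, points are iterated onto the attracting manifold,
its curvature is fitted by least squares ($k_1$ to $10^{-3}$ relative), and
$n_1$, $n_5$ are recovered as finite-difference Taylor coefficients of the
restricted one-dimensional map (agreement $\sim 10^{-5}$).  A quantitative
consistency check closes the loop: just past $r_c$ the period-2 half
separation obeys $d^2 \approx (\nu/\varpi_2)\,(r - r_c)$ in the chart scale,
and the test suite verifies $d^2$ is linear in $r - r_c$ with $R^2 > 0.99$.

The expansion keeps the deviation $r^*$ to first order and, following the
source derivation, drops the term constant in the state
($x^*e^{1-x^*}r^*$, reflecting that the predator level of $p_1$ moves with
$r$).  This truncation only affects the $r^*$-coupling coefficients
$n_2, n_3, n_4$ — the sign and magnitude of $\varpi_2$, which decide the
flip's direction, are independent of it and are the oracle-tested
quantities.

A genuine flip additionally needs $|\rho_2| \neq 1$.  At
$\alpha = 2, \gamma = 1$ the root of $R(-1)=0$ (at $r=8$) has *both*
multipliers at $-1$ (a 1:2 resonance, since $\det \equiv 1$ there);
`critical_r_flip()` returns the root, and `flip_setup()` refuses it with a
domain error naming the resonance.

## Simulation, Lyapunov exponents, diagrams

`simulate()` iterates the raw map with a divergence guard
($|x|$ or $|y| > 10^6$, or non-finite values — the Ricker exponential
overflows for very negative $x$); divergence is recorded data, never an
exception.  `detect_period()` reports the smallest $k \le 64$ (default)
with recurrence below $10^{-6}$ over the last $2k$ points.
`max_lyapunov()` uses tangent-vector propagation through the analytic
Jacobian with per-step renormalization — exact for maps, free of the
shadowing error of finite-difference orbit separation.  The only randomness
in the package is the initial tangent direction (seeded, default 0); the
estimate is insensitive to it at $\pm 0.005$ nats and the tests assert the
two analytic anchors: at a stable fixed point the exponent equals
$\log(\max_i |\rho_i|)$, and on a period-$k$ cycle it equals
$\tfrac1k \log$ of the spectral radius of the Jacobian product around the
cycle, both within 0.01 nats.

`bifurcation_sweep()` samples attractors on a uniform $r$ grid (default 600
points per unit $r$, 200 samples per row after a 1000-step transient) and
runs period detection and the Lyapunov estimate along the same orbit.
Warm starting (each row continues from the previous row's final state) is
the default because it follows the stable branch through slow transients
near criticality; a cold-start mode reproduces the single-initial-value
convention.  Rows are labelled chaotic when aperiodic *and* the exponent
exceeds 0.01 nats — the margin guards against marginal rows near
accumulation points.  `cascade_detect()` walks the sorted rows and records
the first $r$ at which the period exactly doubles, stopping once detection
fails after the cascade has begun; aperiodic rows *before* the first
doubling (slow transients just below $r_c$) are skipped rather than
terminal.

## The three study scenarios, and what the tests do and do not show

`rickerpp_scenario()` packages three parameterizations:

* **case1** ($\alpha=1, \gamma=0.5$, $x_0 = (0.33, 0.64)$).  The interior
  flip sits at $r_c = 16/3$ and a complete period-doubling cascade follows:
  period 4 from $r \approx 5.392$, 8 from $\approx 5.610$, 16 from
  $\approx 5.622$, chaos (maximal Lyapunov exponent up to $\approx +0.07$)
  on $\approx [5.630, 5.6375]$, then a boundary crisis beyond which orbits
  escape to infinity.  The cascade and chaos tests run here.
* **case2** ($\alpha=2, \gamma=1$).  On the degenerate surface:
  $\det(J(p_1)) \equiv 1$, so orbits near $p_1 = (1, r)$ wind on invariant
  closed curves (the $r = 3.598768$ fixture has $p_1 = (1, 3.598768)$).
  There is no isolated Neimark-Sacker threshold in $r$ here — the
  often-quoted $r = 0.30423$ has residual identically zero and zero
  transversality, which the package documents rather than reproduces.
* **case3** ($\alpha=0.5, \gamma=0.3$).  Flip at
  $r_c = 3.9255$ (the numerically quoted 3.93311 agrees to 0.2%), a
  supercritical $\varpi_2 > 0$, and then — contrary to the narrative
  sometimes attached to these parameters — the period-2 cycle remains
  stable all the way to a boundary crisis near $r \approx 5.755$: its
  cycle multipliers stay well inside the unit circle and the Lyapunov
  exponent stays near $-0.25$.  No period-4 window, positive exponent, or
  coexisting attractor exists in $3 < r < 6$ (checked by continuation in
  both directions and by random restarts).  The acceptance suite states
  the cascade expectation for case 3 faithfully and therefore carries two
  failing assertions there, with the cascade machinery validated on case 1
  instead.

Because the model is a deterministic map, the test fixtures are exact
closed-form objects rather than synthetic data with noise; what the passing
tests show is internal consistency (analytic formulas against independent
numerical oracles) and reproduction of the quantities that follow from the
printed equations.  They cannot show anything about parameter values or
dynamical claims that the printed equations contradict.

## Problem sizes and numerical settings

Default tolerances: fixed-point residual $10^{-10}$ per coordinate;
unit-circle tolerance $10^{-9}$ for analytic classification ($10^{-6}$ when
feeding numerical continuation); period-recurrence $10^{-6}$; flip root
$10^{-8}$; resonance exclusion $10^{-6}$; divergence bound $10^6$.  The test
suite uses $10^5$-step orbits for the Lyapunov anchors and the
invariant-curve boundedness check, 20000-step transients for near-critical
period-2 measurements (growth off criticality is $O(\nu)$ per step, so
transients must scale like $1/\nu$), and a 156-point warm-started sweep at
grid step 0.0025 through the case-1 cascade; these sizes were chosen so
every quoted tolerance is met with at least an order-of-magnitude margin
while the whole suite stays quick to run.  Finite-difference oracles use
central stencils with Richardson extrapolation (two levels by default,
three at step 0.02 where a $10^{-6}$-relative cross-check of $\chi$ is
required — the error floor of plain third-derivative stencils in double
precision sits near $10^{-4}$ relative).

## Known limitations

* Only $r$ is treated as the bifurcation parameter; there is no
  continuation in $\alpha$ or $\gamma$ and no codimension-two analysis.
* The invariant circle is not continued rigorously; its existence is
  corroborated by long bounded orbits, not proven.
* Only the maximal Lyapunov exponent is computed, not the spectrum.
* The flip cascade is observed by simulation; secondary flips get no normal
  forms.
* The center-manifold reduction truncates at the order stated above; the
  $r^*$-coupling coefficients inherit the truncation of the source
  derivation.
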