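---
title: "Helix-coil transitions with an exactly summable water model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix-coil transitions with an exactly summable water model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zbwater)
```

## The model

The classical Zimm-Bragg description of the helix-coil transition assigns
each of the $N$ peptide units a conformational spin $\gamma_i \in
\{1,\dots,Q\}$: state 1 is helical, the remaining $Q-1$ states are coil,
so $Q$ measures the entropic cost of ordering and $\sigma = 1/Q$ is the
familiar nucleation (cooperativity) parameter. An intramolecular H-bond of
energy $U$ forms when two neighbours are both helical,
$\delta_i = [\gamma_i = 1][\gamma_{i+1} = 1]$:

$$H_\text{chain} = -U \sum_{i=1}^{N} \delta_i .$$

`zbwater` adds water explicitly. Each broken bond exposes two binding
sites (the N–H and C=O groups), and the water molecule at each site
carries an orientational spin $\mu \in \{1,\dots,q\}$ of which exactly one
orientation can donate an H-bond of energy $E$:

$$H_\text{water} = -E \sum_{i=1}^{N} (1-\delta_i)\,
  \bigl([\mu_i^{(1)} = 1] + [\mu_i^{(2)} = 1]\bigr).$$

Because the water spins are independent given the conformation, they can
be summed out of the partition function *exactly*. With $W = e^{U/T}$ and
$K = e^{E/T}$ (we set $k_B = 1$), the only trace water leaves is the
replacement

$$W \;\to\; \widetilde W = \frac{q^2 W}{(q + K - 1)^2},$$

implemented in `effective_weight()`. The cooperativity $\sigma$ is
untouched; the stability parameter becomes
$\tilde s = (\widetilde W - 1)/Q$. This is the package's central exact
statement, and `partition_explicit()` / `partition_implicit()` verify it
to machine precision on enumerable chains (`cli_verify()` runs the same
suite from the command line).

The equivalent temperature-dependent effective energy
$\widetilde U(T) = T \ln \widetilde W(T)$ (`effective_energy()`) makes the
physics transparent: water binding *weakens* helix stability, and when the
water-peptide bond outcompetes the intramolecular one the stability curve
becomes non-monotonic in temperature — the origin of cold denaturation in
this model.

## Order parameter

What a CD melt experiment reports is the helicity degree $\theta$, the
mean fraction of intact intramolecular bonds. In the thermodynamic limit
the largest eigenvalue of the reduced $2\times 2$ transfer matrix gives

$$\theta(\tilde s, \sigma) = \frac{\tilde s + \sigma}{1 + \tilde s + r}
  \left(1 + \frac{2\sigma - 1 + \tilde s}{r}\right), \qquad
  r = \sqrt{(1-\tilde s)^2 + 4\sigma\tilde s},$$

with the analytic anchors $\theta(\tilde s \to 0) = \sigma^2$,
$\theta(1, \sigma) = (1+\sigma)/2$, $\theta(\tilde s \to \infty) = 1$, and
$\theta \equiv 1$ at $\sigma = 1$. `transfer_matrix_theta()` computes the
finite-$N$ value from the same matrix (trace form for periodic chains, an
exact $2\times2$ recursion for open ones) and converges to
`order_parameter()` as $N$ grows; `theta_finite()` cross-checks it by
exhaustive enumeration at small $N$.

## Laboratory units and the temperature shift

For fitting, energies move to J/mol ($h = U/2$ per intramolecular H-bond,
$h_{ps} = E$) and temperature enters as $t = RT$. Hydration water in
proteins shows super-Arrhenius, glass-like relaxation, which motivates an
Adam-Gibbs-style shift: every Boltzmann denominator is $R(T - t_0)$, with
$t_0$ a glass-transition-like temperature. The fit-facing stability
parameter (`s_tilde_lab()`) is then

$$\tilde s(T) = \frac{1}{Q}\left[\left(e^{-h/d} +
  \frac{e^{(h_{ps}-h)/d} - e^{-h/d}}{q}\right)^{-2} - 1\right],
  \qquad d = R\,(T - t_0),$$

and $\theta(T) = \theta(\tilde s(T), 1/Q)$ (`theta_curve()`) is the
four-parameter model $(t_0, h, h_{ps}, Q)$ fitted to melt data. The
`fit_without_shift()` diagnostic refits with $t_0$ frozen at 0; on data
carrying a genuine shift this collapses the fit quality, which is the
empirical case for keeping $t_0$.

A note on unit conventions: $t = RT$ is an energy per mole, yet $t_0$ is
reported in Kelvin; the only dimensionally consistent reading, and the one
that puts $\tilde s \approx 1$ at observed melting temperatures, is
$d = R(T - T_0)$ with both temperatures in Kelvin. The package uses that
convention throughout, with $R = 8.314462618$ J mol$^{-1}$ K$^{-1}$
configurable in every function that needs it.

Two reduced quantities organise the phase behavior:
$\alpha = (h_{ps} - h)/h$, the inter/intra H-bond balance, and
$\tau = T \ln Q / U$. `s_tilde_internal()` evaluates the reduced-unit
stability surface exactly as conventionally written (the $\tau$ convention
absorbs $\ln Q$ into the temperature unit and is kept as-is rather than
re-derived from $W = e^{U/T}$; it is used only for the qualitative
phase-diagram analysis, never for fitting). For $\alpha < 0$ the curve
$\tilde s(\tau)$ is monotone — heat denaturation only; for $\alpha > 0$ it
is single-peaked, so the chain can denature on *cooling* as well, and if
the peak stays below 1 the system is disordered at every temperature.
`phase_boundary_internal()` traces the resulting dome, with the closed
form $\tau^* = 1/\ln(Q+1)$ at $\alpha = -1$ as an anchor.

## Parameters that matter

* `q` — water orientations per binding site. Fixed, not fitted: an
  H-bond tolerates roughly a 40° cone, giving
  $q = \lfloor 360/(2\cdot 40)\rfloor^2 = 16$ (`q_from_angle()`). Exposed
  as a configuration override only.
* `Q` — conformational states per unit; $\sigma = 1/Q$. Published fits
  range from ~19 (small designed proteins) to ~300 (long
  homopolypeptides).
* `h`, `h_ps` — single-H-bond energies, J/mol. Realistic fits sit at
  1–6 kJ/mol with $h_{ps}/h$ close to 1; cold denaturation requires
  $h_{ps} > h$.
* `t0` — Kelvin; must stay below the coldest data point. Fitted values
  cluster 50–100 K below the melting temperature, consistent with the
  empirical $t_2 - t_0 \approx 50$ K rule for glass formers.

## Fitting: design choices

`fit_melt_curve()` minimizes the residual sum of squares with bounded
Levenberg-Marquardt (`minpack.lm::nls.lm`). The surface has a narrow
curved ridge (strong $t_0$–$h$–$Q$ correlation), so a single start is
unreliable: the default design uses 20 seeded Latin-hypercube starts plus
a fixed grid of starts on the physically expected ridge
$h_{ps} \approx h$, and keeps the best solution. Default bounds are
$t_0 \in [150, \min T - 5]$ K, $h \in [100, 20000]$,
$h_{ps} \in [0, 20000]$ J/mol, $Q \in [2, 2000]$ — wide margins around all
published values. The $-5$ K margin on $t_0$ is a robustness default; when
a generating $t_0$ is known to sit within 5 K of the coldest point, pass
explicit bounds (the hard requirement is only $t_0 < \min T - 1$).

Percent standard errors use the standard linearized approximation
$100\sqrt{\mathrm{diag}((J^\top J)^{-1} s^2)}/|\hat\theta|$ with
$s^2 = SS_\text{res}/(n-k)$ and a central-difference Jacobian at the
optimum. $\sigma$ and $\alpha$ are always recomputed from the estimates.
Flat input ($\mathrm{sd}(\theta) < 10^{-6}$) and singular information
matrices set `degenerate = TRUE` and `converged = FALSE` — a fit is never
silently "good".

Identifiability deserves honesty: with noise of 0.005–0.01 on $\theta$,
parameters are recovered to a few percent when *both* the cold and the
heat branch are visible in the scanned window (non-monotonic curves with
deep tails). For one-sided sigmoids the global least-squares optimum can
sit far from the generating values along the ridge — that is a property
of the data, not of the optimizer, and it mirrors the large printed
uncertainties of published one-sided fits.

## Synthetic data

`generate_melt_curve()` adds i.i.d. Gaussian noise to the model curve on
a uniform grid — the simplest error model consistent with unweighted
least squares; defaults are 60 points (a dense CD melt) and unclipped
noise (real normalized data also stray slightly outside $[0,1]$). What it
does *not* emulate: baseline drifts, CD-to-helicity normalization error,
heteroscedastic noise near the baselines, or correlated residuals. Passing
recovery tests on this generator therefore validates the estimator under
its own assumptions, not those experimental nuisances; the `theta` input
to `fit_melt_curve()` is assumed pre-normalized to helicity, since the
published analyses do not document their normalization.

## Numerical choices

* All stability-parameter evaluations run in log space; as
  $T \to t_0^+$ (or $\tau \to 0^+$) they return the analytic limit
  ($+\infty$ for $\alpha < 0$, $-1/Q$ for $\alpha > 0$) instead of NaN.
* `order_parameter()` accepts the mathematically reachable range
  $\tilde s \in (-\sigma, \infty]$, clamps rounding excursions into
  $[0,1]$, and short-circuits $\tilde s > 10^{100}$ to 1.
* Transition temperatures are defined by $\tilde s = 1$ (the transfer
  matrix midpoint), located by grid bracketing plus bisection to
  $10^{-6}$ K over a default scan of $[\max(t_0 + 5, 230), 400]$ K with
  2000 points. At a crossing $\theta = (1+\sigma)/2$, slightly above the
  $\theta = 1/2$ midpoint convention at finite $\sigma$.
* A single *rising* crossing is classified `cold_and_heat`: since
  $\tilde s \to 0$ as $T \to \infty$, a heat-side root always exists above
  the window.
* Exhaustive enumeration refuses conformation spaces beyond $2^{24}$
  states (and $2^{22}$ for the literal joint conformation-water sum); the
  test oracles use $N \le 6$, where the identity checks take seconds.

## Problem sizes used in the shipped checks

Enumeration identities run over $N \in [2,6]$, $Q, q \in \{2,3\}$, both
boundary conventions, 50 random energy draws. Recovery experiments use
60-point curves with noise SD 0.01 and 20 multi-starts (the reference
heat+cold set on $[265, 330]$ K, the strongly water-favoring set on
$[240, 360]$ K), and a 10-set random sweep at noise SD 0.005 restricted
to two-branch shapes as discussed above.

## Limitations

Pressure and volume effects are outside the model (no elliptic $p$–$T$
phase diagram), bulk water enters only through $q$ and $h_{ps}$,
H-bond cooperativity and electrostatic screening are not represented, and
calorimetric (heat-capacity) data are not fitted — the order parameter
here is strictly the helicity degree that CD-style experiments track.
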