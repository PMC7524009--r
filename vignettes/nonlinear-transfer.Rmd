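---
title: "Nonlinear transfer functions of E-I spiking networks: methods"
author: "lifnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear transfer functions of E-I spiking networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifnet)
```

## The model

`lifnet` computes the stationary population response of recurrent networks
of leaky integrate-and-fire (LIF) neurons as a function of the external
drive, and classifies the nonlinearities of that response at finite
coupling strength. A LIF neuron integrates its input current with membrane
time constant $\tau$, fires when its potential reaches the threshold
$\theta$, resets to $V_r$ and stays there for an absolute refractory
period $\tau_{rp}$. Under the diffusion approximation — many small,
temporally uncorrelated synaptic inputs — the input is summarized by its
mean $\mu$ and noise amplitude $\sigma$ (both in mV), and the stationary
rate is the Ricciardi transfer function

$$\nu = \left[\tau_{rp} + \tau\sqrt{\pi}\int_{u_{min}}^{u_{max}}
  e^{u^2}\bigl(1+\mathrm{erf}(u)\bigr)\,du\right]^{-1},
  \qquad u_{max} = \frac{\theta-\mu}{\sigma},\;
  u_{min} = \frac{V_r-\mu}{\sigma},$$

implemented by `phi_ricciardi()`. Firing irregularity is quantified by the
coefficient of variation (CV) of inter-spike intervals, a nested double
integral over the same operating-point variables (`cv_isi()`): it
approaches 1 in the fluctuation-driven (subthreshold) regime and 0 in the
drift-dominated regime. Defaults are $\theta = 20$ mV, $V_r = 10$ mV,
$\tau = 20$ ms, $\tau_{rp} = 2$ ms; the public interface uses mV and ms
(rates in spikes/s), with all internal computation in SI units.

Two network models are provided. In the one-population parametrization
(**model A**, `model_a_params()`) every neuron has in-degree $K$ from
excitatory cells ($\gamma K$ from inhibitory cells), efficacy $J$ for
excitation, $-gJ$ for inhibition and $g_X J$ for external inputs, so the
input moments at network rate $\nu$ and drive $\nu_X$ are

$$\mu = \tau J K\,[\nu_X + (1-g\gamma)\nu],\qquad
  \sigma^2 = \tau J^2 K\,[g_X\nu_X + (1+g^2\gamma)\nu].$$

In the two-population parametrization (**model B**,
`model_b_params()`) the excitatory and inhibitory populations have
distinct efficacy ratios $g_E, g_I$, drive gains $\alpha_E, \alpha_I$
(with $\nu_{AX} = \alpha_A \nu_X$) and in-degrees $K_{EE}, K_{IE}$.
Two derived constants organize everything:

* $\epsilon = (\theta - V_r)/(K_{EE} J_{EE})$, the fraction of
  simultaneous recurrent excitatory inputs needed to traverse
  reset-to-threshold. $\epsilon \to 0$ is the strong-coupling (balanced)
  limit with a linear network transfer function; at finite $\epsilon$
  nonlinearities appear at response onset and near saturation.
* $\nu_{th} = \theta/(K J \tau)$, the drive at which the mean feedforward
  input alone reaches threshold; drive grids are naturally expressed in
  units of $\nu_{th}$.

Self-consistent network states solve $\nu_A = \phi(\mu_A, \sigma_A)$;
`solve_model_a()` and `solve_model_b()` return *all* coexisting fixed
points with stability labels, `transfer_curve()` links them into branches
across a drive grid, and `ablation_flags()` lets the recurrent
contribution to the input mean or variance be removed to identify which
feedback pathway generates multistability at response onset
(`onset_feedback()` gives the analytic decomposition of $du_{max}/d\nu$
into a mean term and a noise term).

## The expansion families and the onset taxonomy

Above response onset the transfer function is governed by the high-rate
(drift-dominated) reduction of the self-consistency, polynomial in the
rates (`model_a_highrate_roots()`, `solve_highrate_b()`). Expanding in
$\epsilon$ around the strong-coupling limit yields five zeroth-order
solution families for model B (`model_b_epsilon_solutions()`):

* **s1 (regular)** — both populations balanced, rates linear in the drive;
  the first-order correction makes the excitatory response supralinear or
  sublinear depending on $\beta = K_{EE}J_{EE}/(K_{IE}J_{IE})$
  (`supralinearity_threshold()`). The critical value is
  $\beta^* = \gamma g_I(\alpha_E g_I - g_E \alpha_I)/
  (g_E(\alpha_E - \alpha_I))$; the inhibitory in-degree ratio $\gamma$
  enters through the zeroth-order inhibitory rate and is required for the
  threshold to coincide with the sign change of the printed first-order
  coefficient — the package treats that internal consistency as
  authoritative.
* **s2 (supersaturated)** — the excitatory population is silenced by
  overwhelming inhibition while the inhibitory rate grows linearly; only
  sublinear finite-coupling corrections are possible.
* **s3, s4, s5 (saturated)** — both populations, only I, or only E pinned
  at the refractory ceiling $1/\tau_{rp}$.

Admissibility of a family at a given drive requires both first-order
rates in $[0, 1/\tau_{rp}]$ plus branch consistency (a silent population
must have subthreshold mean drive; a saturated population must have its
first-order correction at or below the ceiling, equivalently a
suprathreshold mean drive). At vanishing drive these conditions reduce to
closed-form sign rules on
$(g_E - g_I,\; \alpha_E g_I - g_E \alpha_I,\; \alpha_E - \alpha_I,\;
\gamma g_E - 1,\; \gamma g_I - 1)$, implemented in
`admissibility_scan()` and scanned exhaustively by
`scenario_enumeration()` over a lattice that realizes every sign pattern.
The scan finds four three-family scenarios
($\{s1,s2,s3\}$, $\{s1,s2,s5\}$, $\{s1,s3,s4\}$, $\{s2,s3,s4\}$),
no two-family scenarios, and four singletons: $\{s1\}$, $\{s2\}$,
$\{s3\}$ and additionally $\{s5\}$ in the region
$\gamma g_I > 1$, $g_I > g_E$, $\alpha_E g_I > g_E \alpha_I$ (strong
excitatory drive with dominant inhibitory wiring: the excitatory
population saturates while the inhibitory population balances). The
$\{s5\}$ singleton follows from the same sign rules that produce the
other scenarios, and full mean-field numerics in that region indeed show
a unique saturation-scale state of that type, so the scan reports it as
a first-class scenario. `uniqueness_conditions()` provides the closed-form
regions in which s1 or s2 is the only admissible family.

```{r, eval = FALSE}
scenario_enumeration()
admissibility_scan(fixture_params("modelB_s1s2s3"), nu_X = 0)
```

## Rate models

Two rate-model counterparts isolate what the spiking theory adds
(`solve_rate_network()`, `compare_models()`):

* the **fixed-noise Ricciardi model** uses the same f–$\mu$ curve with
  $\sigma$ frozen (default: the spiking network's noise at the drive where
  the mean excitatory input crosses threshold, `sigma_at_threshold()`),
  removing the noise-feedback pathway while keeping the refractory
  ceiling;
* the **SSN** (supralinear stabilized network) uses the rectified power
  law $f(\mu) = k[\mu]_+^n$ (defaults $k = 0.04$, $n = 2$) with weights
  $W_{EE} = W_{IE} = 1$, $W_{AI} = \gamma g_A$. The mapping fixes only
  relative weights; the package feeds the SSN the same mean-input
  expression (in mV) as the spiking network, which makes the balanced
  large-drive solutions of all three models coincide so that differences
  are confined to the nonlinear regions. This input-scale convention is a
  package choice, recorded in the comparison output.

Saturation nonlinearities (generated by the refractory period) are
reproduced quantitatively by the fixed-noise Ricciardi model and not by
the SSN; noise-generated onset multistability is reproduced by neither.

## The spiking simulator

`build_network()` + `simulate_network()`/`ramp_protocol()` provide a
clock-driven simulation of the full network: exact exponential decay
between steps ($dt = 0.05$ ms by default), delta synapses applied after
per-synapse delays drawn uniformly from $[0, 100]$ ms (excitatory) and
$[0, 1]$ ms (inhibitory) and rounded up to whole steps, threshold/reset
with refractory clamping, and external drive as independent Poisson input
(one aggregate Poisson count of rate $K_{AX}\nu_{AX}$ per neuron per
step; an explicit shared-unit pool is available via
`external_mode = "replica"` for correlation-sensitive questions).
Population sizes are $N_A = 11 K$ per in-degree unit; wiring is either
uniform (exact in-degrees) or Erdős–Rényi (independent Bernoulli
synapses), the latter producing wide rate distributions and, at
supersaturation parameters, a silent excitatory subpopulation instead of
population-level suppression. All randomness derives from one integer
seed; builds and runs are bit-reproducible.

The ramp protocol warm-starts each drive step from the previous state and
flags hysteresis where up- and down-sweep rates differ beyond a noise
band — the observable signature of coexisting stable states; an
oscillation index (spectral peak over background of the 1-ms binned
population rate) screens for synchrony, which the wide delay
distributions are chosen to suppress.

What the simulator emulates — and what it does not: delta synapses, no
conductance effects, no synaptic filtering, no plasticity, stationary
drive only. One caveat matters when comparing with the mean field: the
theory treats presynaptic spike trains as Poisson, but recurrently driven
LIF neurons fire sub-Poisson (CV < 1) in the drift regime, so when
*recurrent* spikes dominate the input variance the theory overestimates
the effective noise and hence the CV. Validation runs therefore use an
operating regime in which external noise dominates ($g_X = 10$, as also
used for the onset analyses), where simulated rates agree with the mean
field to within a few percent and CVs to within ~10%. The reduced
validation scale — $K = 400$, 5,500 neurons, 10 s measurement per drive
step after a 1 s warm-started transient — keeps a full drive sweep at
desk scale; $K = 10^3$ and longer windows are configuration options.

## Numerical choices

* **Scaled-erfc evaluation.** $e^{u^2}(1+\mathrm{erf}(u))$ is always
  evaluated as $\mathrm{erfcx}(-u)$; forming $e^{u^2}$ directly overflows
  for $|u| > 26$. The package ships its own `erfcx()`:
  $e^{x^2}\mathrm{erfc}(x)$ via the accurate normal tail for
  $0 \le x < 7$, a 14-term asymptotic series beyond, reflection for
  $x < 0$.
* **Quadrature.** Adaptive Gauss–Kronrod (G7/K15 with bisection of the
  worst panel), tolerance $10^{-12}$ for the rate and $10^{-10}$/$10^{-8}$
  for the inner/outer CV integrals. For $u_{max} > 8$ the rate integral is
  rescaled by $e^{-u_{max}^2}$ analytically so the Kramers-escape regime
  is computed at full precision down to underflow. The CV integrand
  exceeds double range for $u_{max} > 15$; there the Poisson limit
  CV = 1 is returned (exponentially accurate in that regime). The inner
  CV integral is truncated at $-\sqrt{u^2 + 140}$, where the integrand is
  below $10^{-60}$ of its peak.
* **Root finding.** Model A: 2000-point bracketing grid on
  $[0, 1/\tau_{rp}]$ plus bisection to $10^{-12}$ relative; stability
  from the sign of $dF/d\nu$. Model B: Newton with finite-difference
  Jacobian and backtracking line search, seeded from a 25×25 lattice,
  log-spaced near-origin seeds (onset roots sit far below the linear
  lattice spacing) and the five expansion families; duplicate roots
  merged at $10^{-4}/\tau_{rp}$; seeds entering an already-explored basin
  are abandoned early. Stability uses the Jacobian of the relaxation
  dynamics $\tau_A\,d\nu_A/dt = -\nu_A + \phi_A$ — for two populations
  this is a heuristic proxy (labelled `"unknown"` near marginal
  eigenvalues), with the simulator as the final arbiter.
* **Branch linking.** Nearest-neighbour matching across consecutive
  drives; saddle-node events are resolved only at grid resolution.
* **Degenerate inputs.** $\sigma = 0$ routes to the closed-form drift
  rate (the deterministic limit is well defined); $g_E = g_I$ makes the
  regular family singular and is treated via the one-population model;
  exact threshold ties in the admissibility rules are broken by the
  first non-vanishing order in the drive.
* **Relative-coupling convention.** Sweeps of $\beta$ at fixed overall
  coupling use $K_{EE} = \sqrt{\beta}K_0$, $K_{IE} = K_0/\sqrt{\beta}$,
  which keeps the derived $\beta$ parameter equal to the requested value
  (`with_beta()`; the literal convention is available and yields the
  square of the label).

## Limitations

Stationary responses only: no time-dependent drive, no analysis of
delay-induced oscillatory instabilities (the simulator's oscillation
index only screens for them), and no corrections beyond the diffusion
approximation (shot-noise effects, synaptic filtering, colored noise).
Finite-size fluctuations in the simulator cause spontaneous transitions
between closely spaced attractors, so hysteresis detection near fold
points is conservative. The two-population stability labels are
heuristic. Scenario classification at finite drive relies on first-order
expansion rates and degrades for $\epsilon \gtrsim 0.2$ (a warning is
issued).
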