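# lifnet

Stationary transfer functions of excitatory–inhibitory spiking networks
at finite coupling.

Cortical network models in the strong-coupling ("balanced") limit respond
*linearly* to their inputs, yet real cortex sums inputs nonlinearly. At
finite coupling strength, networks of leaky integrate-and-fire (LIF)
neurons develop two kinds of response nonlinearity: at **response onset**
(fluctuation-driven firing, where feedback through the recurrent input
*noise* can create multiple coexisting states) and near **saturation**
(where the refractory period bends the response sublinearly — or, with two
populations, produces supralinear and supersaturating behavior).
`lifnet` is a toolbox for computational neuroscientists to compute,
classify and validate these responses:

* **Single-neuron theory** — the Ricciardi transfer function
  `phi_ricciardi()` and ISI coefficient of variation `cv_isi()` under the
  diffusion approximation,

  ν = [τ_rp + τ√π ∫_{u_min}^{u_max} e^{u²}(1+erf(u)) du]⁻¹,
  u_max = (θ−μ)/σ, u_min = (V_r−μ)/σ,

  evaluated in numerically stable scaled-erfc form, plus the
  drift-dominated, subthreshold-escape and high-rate-CV closed forms.
* **Mean-field networks** — all coexisting fixed points of one- and
  two-population E–I networks (`solve_model_a()`, `solve_model_b()`,
  `transfer_curve()`), with stability labels and ablation switches that
  remove the recurrent mean or noise pathway (`ablation_flags()`,
  `onset_feedback()`, `solution_count_map()`).
* **Perturbative classification** — the expansion in the coupling
  smallness ε = (θ−V_r)/(KJ): solution families s1 (regular/balanced),
  s2 (supersaturated), s3–s5 (saturated), their admissibility and the
  exhaustive onset-scenario taxonomy (`model_b_epsilon_solutions()`,
  `admissibility_scan()`, `scenario_enumeration()`,
  `uniqueness_conditions()`, `supralinearity_threshold()`).
* **Rate-model counterparts** — fixed-noise Ricciardi model and the
  supralinear stabilized network (SSN, `f(μ) = k[μ]₊ⁿ`), with a
  comparison harness (`compare_models()`).
* **Spiking simulator** — a fast clock-driven simulation of the full LIF
  network with Poisson drive, per-synapse delays, uniform or Erdős–Rényi
  wiring, and a ramp protocol with hysteresis detection
  (`build_network()`, `simulate_network()`, `ramp_protocol()`,
  `estimate_cv()`).

## Worked example

```r
library(lifnet)

pa <- model_a_params(J = 0.2, g = 5, K = 1000)
pa
#> Model A: J = 0.2 mV, g = 5, g_X = 1, gamma = 0.25, K = 1000
#>   derived: epsilon = 0.05, nu_th = 5 spk/s

phi_ricciardi(mu = 25, sigma = 5)   # spk/s
#> [1] 47.21744
cv_isi(mu = 25, sigma = 5)
#> [1] 0.4363544

solve_model_a(nu_X = 2 * pa$nu_th, pa)
#>       nu_E     nu_I   u_max_E   u_max_I stability branch_id
#> 1 26.92059 26.92059 0.5401775 0.5401775    stable         1
```

`epsilon = 0.05` says that 5% of this neuron's excitatory inputs firing
together traverse reset-to-threshold: coupling is finite and the network
response deviates visibly from the balanced (linear) prediction
`(nu_X - nu_th)/(g*gamma - 1) = 20` spk/s — here the self-consistent rate
is 26.9 spk/s with the mean input about half a noise unit below threshold
(`u_max = 0.54`).

With two populations, parameter sets exist where several states coexist
at the same drive. At a drive of 5 spk/s this set has three (low E-silent,
intermediate unstable, saturated):

```r
pb <- fixture_params("modelB_s1s2s3")   # g_E = 3, g_I = 4, alpha_E = 2, alpha_I = 5
admissibility_scan(pb, nu_X = 0)
#> Scenario at nu_X = 0: {s1, s2, s3}
solve_model_b(nu_X = 5, pb, n_lattice = 12)
#>           nu_E      nu_I     u_max_E    u_max_I stability branch_id
#> 1 1.097616e-16  21.38725   6.4763985  0.5900545    stable         1
#> 2 3.642796e+01  56.09279   0.2183932 -0.0886626  unstable         2
#> 3 4.304300e+02 376.27892 -19.1000212 -7.4893509    stable         3
```

A YAML-configured runner (`lifnet_run()`, thin CLI at
`inst/cli/lifnet.R`) dispatches `transfer`, `solve`, `classify`, `scan`,
`simulate` and `compare` runs and writes CSV artifacts with a JSON
manifest.

## Documentation

The methods vignette (`vignettes/nonlinear-transfer.Rmd`) describes the
model and its assumptions, the expansion families and admissibility
rules, the rate-model mappings, the simulator, and all numerical choices
and limitations.
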