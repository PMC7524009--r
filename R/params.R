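#' Leaky integrate-and-fire neuron parameters
#'
#' Container for the biophysical constants of a LIF neuron. Defaults are the
#' values used throughout the package's worked examples: threshold 20 mV,
#' reset 10 mV, membrane time constant 20 ms, refractory period 2 ms.
#'
#' @param theta Firing threshold (mV).
#' @param v_reset Reset potential (mV); must be below `theta`.
#' @param tau_m Membrane time constant (ms); positive.
#' @param tau_rp Absolute refractory period (ms); non-negative. The maximum
#'   attainable firing rate is `1000 / tau_rp` spikes/s.
#' @return An object of class `lif_neuron`.
#' @examples
#' neuron_params()
#' neuron_params(tau_rp = 1)
#' @export
neuron_params <- function(theta = 20, v_reset = 10, tau_m = 20, tau_rp = 2) {
  stopifnot(is.numeric(theta), is.numeric(v_reset), is.numeric(tau_m),
            is.numeric(tau_rp), length(theta) == 1L, length(v_reset) == 1L,
            length(tau_m) == 1L, length(tau_rp) == 1L)
  if (!is.finite(theta) || !is.finite(v_reset) || theta <= v_reset)
    stop("'theta' must exceed 'v_reset' and both must be finite")
  if (!is.finite(tau_m) || tau_m <= 0) stop("'tau_m' must be positive")
  if (!is.finite(tau_rp) || tau_rp < 0) stop("'tau_rp' must be non-negative")
  structure(list(theta = theta, v_reset = v_reset, tau_m = tau_m,
                 tau_rp = tau_rp),
            class = "lif_neuron")
}

#' @export
print.lif_neuron <- function(x, ...) {
  cat(sprintf("LIF neuron: theta = %g mV, V_r = %g mV, tau_m = %g ms, tau_rp = %g ms\n",
              x$theta, x$v_reset, x$tau_m, x$tau_rp))
  invisible(x)
}

#' Gaussian (diffusion-approximation) input statistics
#'
#' Mean and noise amplitude of the synaptic input current in voltage units,
#' as used by the diffusion approximation. The operating-point variables
#' `u_max = (theta - mu)/sigma` and `u_min = (V_r - mu)/sigma` measure the
#' distance of the mean input from threshold and reset in units of noise.
#'
#' @param mu Mean input (mV); may be a vector.
#' @param sigma Input noise amplitude (mV); non-negative, recycled against
#'   `mu`. `sigma = 0` is accepted only by the deterministic-drift rate.
#' @return An object of class `gaussian_input` (a list with vectors `mu`,
#'   `sigma`).
#' @examples
#' gaussian_input(mu = 15, sigma = 5)
#' @export
gaussian_input <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma))
  if (any(!is.finite(mu))) stop("'mu' must be finite")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be finite and non-negative")
  n <- max(length(mu), length(sigma))
  structure(list(mu = rep_len(mu, n), sigma = rep_len(sigma, n)),
            class = "gaussian_input")
}

#' @export
print.gaussian_input <- function(x, ...) {
  cat(sprintf("Gaussian input: %d point(s); mu in [%g, %g] mV, sigma in [%g, %g] mV\n",
              length(x$mu), min(x$mu), max(x$mu), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Operating-point variables of a Gaussian input
#'
#' @param inp A [gaussian_input()].
#' @param neuron A [neuron_params()].
#' @return A list with vectors `u_max` and `u_min`.
#' @export
operating_point <- function(inp, neuron = neuron_params()) {
  list(u_max = (neuron$theta - inp$mu) / inp$sigma,
       u_min = (neuron$v_reset - inp$mu) / inp$sigma)
}

#' One-population (model A) network parameters
#'
#' Parametrization of a homogeneous excitatory-inhibitory network in which
#' both populations share biophysics and in-degrees, so that a single rate
#' describes the network: recurrent efficacy `J` (E synapses, mV),
#' inhibition/excitation efficacy ratio `g`, external efficacy ratio `g_X`,
#' inhibitory in-degree ratio `gamma`, and in-degree `K`.
#'
#' Two derived constants control the response structure: the coupling
#' smallness `epsilon = (theta - V_r)/(K J)` (fraction of simultaneous
#' recurrent E inputs needed to traverse reset-to-threshold) and the drive
#' scale `nu_th = theta/(K J tau)` (external rate that brings the mean input
#' to threshold in the absence of noise and recurrence).
#'
#' @param J Recurrent excitatory efficacy (mV), positive.
#' @param g Inhibitory/excitatory efficacy ratio, positive.
#' @param g_X External/recurrent efficacy ratio, positive.
#' @param gamma Inhibitory in-degree ratio, positive.
#' @param K Excitatory in-degree (count), at least 1.
#' @param neuron A [neuron_params()].
#' @return An object of class `model_a_params` with derived fields `epsilon`
#'   and `nu_th` (spikes/s).
#' @examples
#' pa <- model_a_params(J = 0.2, g = 5, K = 1000)
#' pa$epsilon   # 0.05
#' pa$nu_th     # 5 spk/s
#' @export
model_a_params <- function(J, g, g_X = 1, gamma = 0.25, K,
                           neuron = neuron_params()) {
  stopifnot(inherits(neuron, "lif_neuron"))
  if (!is.numeric(J) || length(J) != 1L || J <= 0) stop("'J' must be positive")
  if (!is.numeric(g) || g <= 0 || !is.numeric(g_X) || g_X <= 0 ||
      !is.numeric(gamma) || gamma <= 0)
    stop("'g', 'g_X' and 'gamma' must be positive")
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("'K' must be an integer >= 1")
  tau_s <- neuron$tau_m / 1000
  structure(list(J = J, g = g, g_X = g_X, gamma = gamma, K = K,
                 neuron = neuron,
                 epsilon = (neuron$theta - neuron$v_reset) / (K * J),
                 nu_th = neuron$theta / (K * J * tau_s)),
            class = "model_a_params")
}

#' @export
print.model_a_params <- function(x, ...) {
  cat(sprintf("Model A: J = %g mV, g = %g, g_X = %g, gamma = %g, K = %d\n",
              x$J, x$g, x$g_X, x$gamma, x$K))
  cat(sprintf("  derived: epsilon = %g, nu_th = %g spk/s\n", x$epsilon, x$nu_th))
  invisible(x)
}

#' Two-population (model B) network parameters
#'
#' Excitatory and inhibitory populations with distinct efficacies, external
#' drives and (optionally) biophysics. Synaptic efficacies follow
#' `J_EX = g_EX * J_EE`, `J_IX = g_IX * J_IE`, `J_EI = g_E * J_EE`,
#' `J_II = g_I * J_IE`; in-degrees follow `K_EX = K_EE`, `K_IX = K_IE`,
#' `K_AI = gamma * K_AE`. External drives are `nu_AX = alpha_A * nu_X`.
#'
#' Derived constants: `epsilon = (theta - V_r)/(K_EE J_EE)`,
#' `beta = K_EE J_EE / (K_IE J_IE)` (ratio of total recurrent excitatory
#' strength onto E vs I), and per-population threshold drives
#' `nu_th_E`, `nu_th_I`.
#'
#' @param J_EE,J_IE Recurrent E efficacies onto E and I (mV).
#' @param g_E,g_I Inhibitory efficacy ratios for the E and I populations.
#' @param g_EX,g_IX External noise-efficacy ratios.
#' @param alpha_E,alpha_I External drive multipliers.
#' @param gamma Inhibitory in-degree ratio.
#' @param K_EE,K_IE Excitatory in-degrees of E and I neurons.
#' @param neuron_E,neuron_I [neuron_params()] per population.
#' @return An object of class `model_b_params` with derived fields `epsilon`,
#'   `beta`, `nu_th_E`, `nu_th_I`.
#' @examples
#' pb <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = 8, g_I = 7,
#'                      alpha_E = 4, alpha_I = 2, K_EE = 1000, K_IE = 1000)
#' pb$beta
#' @export
model_b_params <- function(J_EE, J_IE, g_E, g_I, g_EX = 1, g_IX = 1,
                           alpha_E = 1, alpha_I = 1, gamma = 0.25,
                           K_EE, K_IE,
                           neuron_E = neuron_params(),
                           neuron_I = neuron_params()) {
  stopifnot(inherits(neuron_E, "lif_neuron"), inherits(neuron_I, "lif_neuron"))
  vals <- c(J_EE = J_EE, J_IE = J_IE, g_E = g_E, g_I = g_I,
            g_EX = g_EX, g_IX = g_IX, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("efficacies and ratios must be positive and finite")
  if (any(c(alpha_E, alpha_I) < 0)) stop("'alpha_E'/'alpha_I' must be >= 0")
  if (K_EE < 1 || K_IE < 1) stop("in-degrees must be >= 1")
  tau_E <- neuron_E$tau_m / 1000
  tau_I <- neuron_I$tau_m / 1000
  structure(list(J_EE = J_EE, J_IE = J_IE, g_E = g_E, g_I = g_I,
                 g_EX = g_EX, g_IX = g_IX, alpha_E = alpha_E,
                 alpha_I = alpha_I, gamma = gamma,
                 K_EE = round(K_EE), K_IE = round(K_IE),
                 neuron_E = neuron_E, neuron_I = neuron_I,
                 epsilon = (neuron_E$theta - neuron_E$v_reset) / (K_EE * J_EE),
                 beta = (K_EE * J_EE) / (K_IE * J_IE),
                 nu_th_E = neuron_E$theta / (K_EE * J_EE * tau_E),
                 nu_th_I = neuron_I$theta / (K_IE * J_IE * tau_I)),
            class = "model_b_params")
}

#' @export
print.model_b_params <- function(x, ...) {
  cat(sprintf("Model B: J_EE = %g, J_IE = %g mV; g_E = %g, g_I = %g; alpha_E = %g, alpha_I = %g\n",
              x$J_EE, x$J_IE, x$g_E, x$g_I, x$alpha_E, x$alpha_I))
  cat(sprintf("  K_EE = %d, K_IE = %d, gamma = %g; epsilon = %g, beta = %g\n",
              x$K_EE, x$K_IE, x$gamma, x$epsilon, x$beta))
  cat(sprintf("  nu_th_E = %g, nu_th_I = %g spk/s\n", x$nu_th_E, x$nu_th_I))
  invisible(x)
}

#' Promote model A parameters to the two-population parametrization
#'
#' The symmetric reduction: identical efficacies, drives and in-degrees for
#' both populations, under which the two-population solver must reproduce the
#' one-population solutions.
#'
#' @param pA A [model_a_params()].
#' @return A [model_b_params()].
#' @export
model_b_from_a <- function(pA) {
  stopifnot(inherits(pA, "model_a_params"))
  model_b_params(J_EE = pA$J, J_IE = pA$J, g_E = pA$g, g_I = pA$g,
                 g_EX = pA$g_X, g_IX = pA$g_X, alpha_E = 1, alpha_I = 1,
                 gamma = pA$gamma, K_EE = pA$K, K_IE = pA$K,
                 neuron_E = pA$neuron, neuron_I = pA$neuron)
}

#' Ablation switches for recurrent input statistics
#'
#' Independent toggles that remove the recurrent contribution to the input
#' mean and/or to the input variance in the mean-field moment equations.
#' Used to dissect which feedback pathway (mean vs fluctuations) generates
#' multistability at response onset.
#'
#' @param drop_recurrent_mean Zero the recurrent term in the input mean.
#' @param drop_recurrent_noise Zero the recurrent term in the input variance.
#' @return An object of class `ablation_flags`.
#' @export
ablation_flags <- function(drop_recurrent_mean = FALSE,
                           drop_recurrent_noise = FALSE) {
  stopifnot(is.logical(drop_recurrent_mean), is.logical(drop_recurrent_noise))
  structure(list(drop_recurrent_mean = isTRUE(drop_recurrent_mean),
                 drop_recurrent_noise = isTRUE(drop_recurrent_noise)),
            class = "ablation_flags")
}

# rate ceiling 1/tau_rp in spk/s (Inf if tau_rp = 0)
nu_max_of <- function(neuron) {
  if (neuron$tau_rp > 0) 1000 / neuron$tau_rp else Inf
}
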