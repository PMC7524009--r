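#' Scaled complementary error function
#'
#' `erfcx(x) = exp(x^2) * erfc(x)`, evaluated without forming `exp(x^2)`
#' directly, so that it is usable throughout the range where the result is
#' representable. This is the numerically stable building block of the
#' diffusion-approximation transfer function, via the identity
#' `e^{u^2}(1 + erf(u)) = erfcx(-u)`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of `erfcx(x)`.
#' @examples
#' erfcx(c(-1, 0, 1, 30))
#' @export
erfcx <- function(x) {
  stopifnot(is.numeric(x))
  erfcx_cpp(as.numeric(x))
}

unpack_input <- function(mu, sigma) {
  if (inherits(mu, "gaussian_input")) {
    list(mu = mu$mu, sigma = mu$sigma)
  } else {
    n <- max(length(mu), length(sigma))
    list(mu = rep_len(as.numeric(mu), n), sigma = rep_len(as.numeric(sigma), n))
  }
}

#' Ricciardi transfer function: LIF firing rate under Gaussian input
#'
#' Stationary firing rate of a leaky integrate-and-fire neuron receiving
#' input with mean `mu` and noise amplitude `sigma` (diffusion
#' approximation):
#' \deqn{\nu = \left[\tau_{rp} + \tau\sqrt{\pi}\int_{u_{min}}^{u_{max}}
#'   e^{u^2}(1+\mathrm{erf}(u))\,du\right]^{-1}}
#' with \eqn{u_{max} = (\theta-\mu)/\sigma}, \eqn{u_{min} = (V_r-\mu)/\sigma}.
#' The integrand is evaluated in scaled-erfc form and the deep-subthreshold
#' tail is rescaled analytically, so the rate is accurate from the
#' Kramers-escape regime to saturation. `sigma = 0` falls back to the
#' deterministic drift rate [phi_drift()].
#'
#' @param mu Mean input (mV), or a [gaussian_input()] (then `sigma` is
#'   ignored).
#' @param sigma Input noise amplitude (mV); non-negative.
#' @param neuron A [neuron_params()].
#' @return Firing rate(s) in spikes/s, in `(0, 1000/tau_rp]`.
#' @examples
#' phi_ricciardi(mu = 25, sigma = 5)
#' phi_ricciardi(gaussian_input(c(10, 20, 30), 5))
#' @export
phi_ricciardi <- function(mu, sigma = NULL, neuron = neuron_params()) {
  inp <- unpack_input(mu, sigma)
  if (any(!is.finite(inp$mu))) stop("'mu' must be finite")
  if (any(!is.finite(inp$sigma)) || any(inp$sigma < 0))
    stop("'sigma' must be finite and non-negative")
  phi_ricciardi_cpp(inp$mu, inp$sigma, neuron$theta, neuron$v_reset,
                    neuron$tau_m / 1000, neuron$tau_rp / 1000)
}

#' Deterministic-drift LIF rate (noiseless limit)
#'
#' Rate of a LIF neuron driven by a constant suprathreshold input:
#' \deqn{\nu = [\tau_{rp} + \tau\ln((\mu-V_r)/(\mu-\theta))]^{-1}}
#' and zero for `mu <= theta`. This is the `sigma -> 0` limit of
#' [phi_ricciardi()].
#'
#' @param mu Mean input (mV).
#' @param neuron A [neuron_params()].
#' @return Firing rate(s) in spikes/s.
#' @examples
#' phi_drift(30)  # 1/(2 ms + 20 ms * ln 2)
#' @export
phi_drift <- function(mu, neuron = neuron_params()) {
  stopifnot(is.numeric(mu))
  phi_drift_cpp(as.numeric(mu), neuron$theta, neuron$v_reset,
                neuron$tau_m / 1000, neuron$tau_rp / 1000)
}

#' Subthreshold (Kramers-escape) rate approximation
#'
#' In the fluctuation-driven regime (`u_max >> 1`) the transfer function is
#' well approximated by
#' \deqn{\tau\nu = \frac{\theta-\mu}{\sigma\sqrt{\pi}}
#'   \exp\left(-\left(\frac{\theta-\mu}{\sigma}\right)^2\right).}
#' A warning is emitted when called outside its regime (`u_max < 1`); the
#' value is still returned.
#'
#' @inheritParams phi_ricciardi
#' @return Approximate firing rate(s) in spikes/s.
#' @export
phi_subthreshold <- function(mu, sigma = NULL, neuron = neuron_params()) {
  inp <- unpack_input(mu, sigma)
  if (any(inp$sigma < 0)) stop("'sigma' must be non-negative")
  u_max <- ifelse(inp$sigma > 0, (neuron$theta - inp$mu) / inp$sigma, Inf)
  if (any(u_max < 1))
    warning("phi_subthreshold called with u_max < 1: outside its regime of validity")
  tau_s <- neuron$tau_m / 1000
  out <- ifelse(is.finite(u_max),
                u_max * exp(-u_max^2) / (tau_s * sqrt(pi)),
                0)
  pmax(out, 0)
}

#' Coefficient of variation of LIF inter-spike intervals
#'
#' CV of the first-passage-time distribution under Gaussian input,
#' \deqn{CV^2 = 2\pi\tau^2\nu^2 \int_{u_{min}}^{u_{max}} du\, e^{u^2}
#'   \int_{-\infty}^{u} dx\, e^{x^2}(1+\mathrm{erf}(x))^2,}
#' with both integrands rewritten in scaled-erfc form. Approaches 1 in the
#' deep-subthreshold (Poisson) limit and 0 in the drift-dominated limit.
#' For `u_max > 15` the nested integral exceeds double range and the
#' fluctuation-driven limit CV = 1 is returned (exponentially accurate
#' there).
#'
#' @inheritParams phi_ricciardi
#' @return CV value(s), non-negative and dimensionless.
#' @examples
#' cv_isi(mu = 0, sigma = 5)    # ~1 (Poisson-like)
#' cv_isi(mu = 40, sigma = 0.5) # ~0 (regular firing)
#' @export
cv_isi <- function(mu, sigma = NULL, neuron = neuron_params()) {
  inp <- unpack_input(mu, sigma)
  if (any(!is.finite(inp$mu))) stop("'mu' must be finite")
  if (any(inp$sigma <= 0)) stop("'sigma' must be positive for cv_isi")
  cv_isi_cpp(inp$mu, inp$sigma, neuron$theta, neuron$v_reset,
             neuron$tau_m / 1000, neuron$tau_rp / 1000)
}

#' High-rate closed-form approximation of the CV
#'
#' Near saturation (`u_max << -1`) the CV of a model-A network neuron firing
#' at rate `nu` is approximated by
#' \deqn{CV^2 = \frac{KJ^2}{(\theta-V_r)^2}(1-\tau_{rp}\nu)^3
#'   \left[(1+g^2\gamma) + \frac{\theta-V_r}{KJ}\frac{1}{1-\tau_{rp}\nu}
#'   + \frac{\nu_{th}}{\nu}\right],}
#' which vanishes linearly in \eqn{1-\tau_{rp}\nu} as the rate approaches
#' its ceiling.
#'
#' @param nu Network firing rate (spikes/s), below the refractory ceiling.
#' @param pA A [model_a_params()].
#' @param warn_regime Warn when `1 - tau_rp*nu > 0.5`, i.e. far from the
#'   high-rate regime where the expression is accurate.
#' @return CV value(s).
#' @export
cv_suprathreshold_approx <- function(nu, pA, warn_regime = TRUE) {
  stopifnot(inherits(pA, "model_a_params"), is.numeric(nu))
  nrn <- pA$neuron
  trp_s <- nrn$tau_rp / 1000
  if (any(nu * trp_s >= 1)) stop("'nu' must be below the refractory ceiling 1/tau_rp")
  if (any(nu <= 0)) stop("'nu' must be positive")
  if (warn_regime && any(1 - trp_s * nu > 0.5))
    warning("cv_suprathreshold_approx is a high-rate (u_max << -1) approximation")
  dv <- nrn$theta - nrn$v_reset
  occ <- 1 - trp_s * nu
  cv2 <- (pA$K * pA$J^2 / dv^2) * occ^3 *
    ((1 + pA$g^2 * pA$gamma) + (dv / (pA$K * pA$J)) / occ + pA$nu_th / nu)
  sqrt(pmax(cv2, 0))
}
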