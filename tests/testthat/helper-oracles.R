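# Independent oracles built on base R / stats::integrate, deliberately
# sharing no code with the package's C++ quadrature.

erfcx_oracle <- function(x) {
  out <- numeric(length(x))
  mid <- x >= 0 & x < 7
  big <- x >= 7
  neg <- x < 0
  out[mid] <- exp(x[mid]^2) * 2 * pnorm(-x[mid] * sqrt(2))
  if (any(big)) {
    xb <- x[big]
    inv2 <- 1 / (2 * xb^2)
    s <- 1
    term <- rep(1, length(xb))
    for (k in 1:14) {
      term <- term * -(2 * k - 1) * inv2
      s <- s + term
    }
    out[big] <- s / (xb * sqrt(pi))
  }
  if (any(neg)) out[neg] <- 2 * exp(x[neg]^2) - erfcx_oracle(-x[neg])
  out
}

# adaptive-quadrature reference for the firing rate (spk/s); ms/mV units
phi_oracle <- function(mu, sigma, theta = 20, vr = 10, tau = 20, trp = 2) {
  tau_s <- tau / 1000
  trp_s <- trp / 1000
  if (sigma <= 0) {
    if (mu <= theta) return(0)
    return(1 / (trp_s + tau_s * log((mu - vr) / (mu - theta))))
  }
  umax <- (theta - mu) / sigma
  umin <- (vr - mu) / sigma
  I <- stats::integrate(function(u) erfcx_oracle(-u), umin, umax,
                        rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 500L)$value
  1 / (trp_s + tau_s * sqrt(pi) * I)
}

# nested-quadrature reference for the ISI CV
cv_oracle <- function(mu, sigma, theta = 20, vr = 10, tau = 20, trp = 2) {
  tau_s <- tau / 1000
  umax <- (theta - mu) / sigma
  umin <- (vr - mu) / sigma
  nu <- phi_oracle(mu, sigma, theta, vr, tau, trp)
  inner <- function(u) {
    vapply(u, function(ui)
      stats::integrate(function(x) erfcx_oracle(-x)^2 * exp(ui^2 - x^2),
                       lower = min(-40, -sqrt(ui^2 + 140)), upper = ui,
                       rel.tol = 1e-10, abs.tol = 1e-300)$value, 0)
  }
  I2 <- stats::integrate(inner, umin, umax, rel.tol = 1e-8, abs.tol = 0)$value
  sqrt(2 * pi * tau_s^2 * nu^2 * I2)
}

# brute-force fine-grid trapezoid references (no adaptive machinery at all)
phi_trapezoid <- function(mu, sigma, theta = 20, vr = 10, tau = 20, trp = 2,
                          n = 200001L) {
  tau_s <- tau / 1000
  trp_s <- trp / 1000
  u <- seq((vr - mu) / sigma, (theta - mu) / sigma, length.out = n)
  f <- erfcx_oracle(-u)
  I <- sum((f[-1] + f[-n]) / 2) * (u[2] - u[1])
  1 / (trp_s + tau_s * sqrt(pi) * I)
}

cv_trapezoid <- function(mu, sigma, theta = 20, vr = 10, tau = 20, trp = 2,
                         n_out = 150001L, n_in = 150001L) {
  tau_s <- tau / 1000
  umax <- (theta - mu) / sigma
  umin <- (vr - mu) / sigma
  nu <- phi_trapezoid(mu, sigma, theta, vr, tau, trp)
  lo <- min(-40, -sqrt(umax^2 + 140))
  # inner cumulative-trapezoid grid built so the outer nodes are a subset
  x <- c(seq(lo, umin, length.out = n_in)[-n_in],
         seq(umin, umax, length.out = n_out))
  gx <- erfcx_oracle(-x)^2 * exp(-x^2)
  G <- c(0, cumsum(diff(x) * (gx[-1] + gx[-length(x)]) / 2))
  iu <- seq(n_in, length(x))
  u <- x[iu]
  fu <- exp(u^2) * G[iu]
  I2 <- sum(diff(u) * (fu[-1] + fu[-length(fu)]) / 2)
  sqrt(2 * pi * tau_s^2 * nu^2 * I2)
}

# brute-force 2-D residual-grid oracle for the two-population mean field:
# counts well-separated self-consistency roots as grid-local minima of the
# residual norm on a mixed log/linear lattice, refined by coordinate-wise
# bisection-free damped fixed-point iteration (no Newton machinery shared
# with the package solver)
count_roots_grid_b <- function(nu_X, pB, thresh = 20) {
  nu_max <- 1000 / pB$neuron_E$tau_rp
  ax <- unique(sort(c(0, 10^seq(-4, log10(nu_max), length.out = 40),
                      seq(0, nu_max, length.out = 25))))
  n <- length(ax)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    m <- model_b_moments(rep(ax[i], n), ax, nu_X, pB)
    fE <- ax[i] - phi_ricciardi(m$E, neuron = pB$neuron_E)
    fI <- ax - phi_ricciardi(m$I, neuron = pB$neuron_I)
    R[i, ] <- pmax(abs(fE), abs(fI))
  }
  mins <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (R[i, j] > thresh) next
    nb <- R[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(n, j + 1)]
    if (R[i, j] <= min(nb)) mins[[length(mins) + 1]] <- c(ax[i], ax[j])
  }
  if (!length(mins)) return(0L)
  # refine each candidate by direct minimization of the residual norm
  # (Nelder-Mead finds unstable roots too: any root is a zero of R)
  Rfun <- function(v) {
    if (any(v < 0) || any(v > nu_max)) return(1e6)
    m <- model_b_moments(v[1], v[2], nu_X, pB)
    max(abs(v[1] - phi_ricciardi(m$E, neuron = pB$neuron_E)),
        abs(v[2] - phi_ricciardi(m$I, neuron = pB$neuron_I)))
  }
  locs <- list()
  for (p in mins) {
    o <- stats::optim(p, Rfun, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-14))
    o <- stats::optim(o$par, Rfun, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-14))
    if (o$value > 1e-3) next
    dup <- FALSE
    for (q in locs)
      if (max(abs(q - o$par)) < 0.02 * max(1, max(o$par))) dup <- TRUE
    if (!dup) locs[[length(locs) + 1]] <- o$par
  }
  length(locs)
}
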