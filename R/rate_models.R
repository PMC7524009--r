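#' Fixed-noise Ricciardi rate-model parameters
#'
#' A rate model whose single-unit f-mu curve is the Ricciardi transfer
#' function evaluated at a frozen noise amplitude per population. Recurrent
#' connectivity, drives and time constants are inherited from a
#' two-population parameter set, so that the balanced-regime response is
#' identical to the spiking mean field; only the noise feedback pathway is
#' removed.
#'
#' @param sigma_E,sigma_I Fixed noise amplitudes (mV), positive.
#' @param pB A [model_b_params()] supplying connectivity and biophysics.
#' @return An object of class `ricciardi_rate_params`.
#' @export
ricciardi_rate_params <- function(sigma_E, sigma_I, pB) {
  stopifnot(inherits(pB, "model_b_params"), sigma_E > 0, sigma_I > 0)
  structure(list(sigma_E = sigma_E, sigma_I = sigma_I, pB = pB),
            class = "ricciardi_rate_params")
}

#' Supralinear stabilized network (SSN) parameters
#'
#' Power-law rate model `f(mu) = k * max(mu, 0)^n` with weights mapped from
#' a two-population parameter set: `W_EE = W_IE = 1`, `W_AI = gamma * g_A`
#' by default, drives entering as `alpha_A * nu_X`. The absolute input scale
#' is chosen so units enter through the same mean-input expression as the
#' spiking network (in mV), which fixes the large-drive balanced solution to
#' coincide across models; only relative weights are constrained by the
#' mapping itself.
#'
#' @param k Gain constant (spikes/s per mV^n), positive.
#' @param n Power-law exponent, greater than 1.
#' @param pB A [model_b_params()] supplying drives and the weight mapping.
#' @param W_EE,W_IE,W_EI,W_II Optional weight overrides (non-negative;
#'   inhibitory weights enter the input sum with negative sign).
#' @return An object of class `ssn_params`.
#' @export
ssn_params <- function(k = 0.04, n = 2, pB,
                       W_EE = 1, W_IE = 1,
                       W_EI = pB$gamma * pB$g_E,
                       W_II = pB$gamma * pB$g_I) {
  stopifnot(inherits(pB, "model_b_params"), k > 0, n > 1,
            W_EE >= 0, W_IE >= 0, W_EI >= 0, W_II >= 0)
  structure(list(k = k, n = n, pB = pB, W_EE = W_EE, W_IE = W_IE,
                 W_EI = W_EI, W_II = W_II),
            class = "ssn_params")
}

#' f-mu curve of the fixed-noise Ricciardi rate model
#'
#' @param mu Mean input (mV).
#' @param rp A [ricciardi_rate_params()].
#' @param pop `"E"` or `"I"`.
#' @return Firing rate(s), spikes/s.
#' @export
f_mu_ricciardi <- function(mu, rp, pop = c("E", "I")) {
  stopifnot(inherits(rp, "ricciardi_rate_params"))
  pop <- match.arg(pop)
  sig <- if (pop == "E") rp$sigma_E else rp$sigma_I
  nrn <- if (pop == "E") rp$pB$neuron_E else rp$pB$neuron_I
  phi_ricciardi(mu, sig, neuron = nrn)
}

#' f-mu curve of the SSN rate model
#'
#' `f(mu) = k * max(mu, 0)^n`: rectified power law, unbounded above.
#'
#' @param mu Mean input (mV).
#' @param sp An [ssn_params()].
#' @return Firing rate(s), spikes/s.
#' @examples
#' pb <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = 8, g_I = 7,
#'                      K_EE = 400, K_IE = 400)
#' f_mu_ssn(5, ssn_params(k = 0.04, n = 2, pb))  # 0.04 * 25 = 1
#' @export
f_mu_ssn <- function(mu, sp) {
  stopifnot(inherits(sp, "ssn_params"))
  sp$k * pmax(mu, 0)^sp$n
}

# mean inputs (mV) for the rate models; same expression as the spiking mean
# field for the Ricciardi model, weight-mapped for the SSN
rate_model_mu <- function(model, nu_E, nu_I, nu_X, params) {
  nu_E <- unname(nu_E)
  nu_I <- unname(nu_I)
  if (inherits(params, "ricciardi_rate_params")) {
    pB <- params$pB
    m <- model_b_moments(nu_E, nu_I, nu_X, pB)
    c(E = m$E$mu, I = m$I$mu)
  } else {
    pB <- params$pB
    tau_E <- pB$neuron_E$tau_m / 1000
    tau_I <- pB$neuron_I$tau_m / 1000
    c(E = tau_E * pB$J_EE * pB$K_EE *
        (pB$alpha_E * nu_X + params$W_EE * nu_E - params$W_EI * nu_I),
      I = tau_I * pB$J_IE * pB$K_IE *
        (pB$alpha_I * nu_X + params$W_IE * nu_E - params$W_II * nu_I))
  }
}

#' Fixed points of a rate-model network
#'
#' Self-consistent rates `nu_A = f_A(mu_A(nu_E, nu_I, nu_X))` for the
#' fixed-noise Ricciardi model or the SSN, found with the same grid-seeded
#' Newton machinery as the spiking mean field, with stability from the
#' relaxation-dynamics Jacobian. An SSN whose supralinear growth is not
#' stabilized has no finite fixed point along some directions; such runaway
#' is reported via the `divergent` attribute.
#'
#' @param nu_X External drive (spikes/s), scalar.
#' @param params A [ricciardi_rate_params()] or [ssn_params()].
#' @param n_lattice Seeding lattice resolution.
#' @param nu_cap Search ceiling for the unbounded SSN (spikes/s).
#' @return A data frame of fixed points as in [solve_model_b()]; the SSN
#'   result carries `attr(, "divergent")`.
#' @export
solve_rate_network <- function(nu_X, params, n_lattice = 25, nu_cap = 2000) {
  stopifnot(length(nu_X) == 1L, nu_X >= 0)
  is_ssn <- inherits(params, "ssn_params")
  if (!is_ssn) stopifnot(inherits(params, "ricciardi_rate_params"))
  pB <- params$pB
  f_of <- function(v) {
    mu <- rate_model_mu(NULL, v[1], v[2], nu_X, params)
    if (is_ssn) c(f_mu_ssn(mu[["E"]], params), f_mu_ssn(mu[["I"]], params))
    else c(f_mu_ricciardi(mu[["E"]], params, "E"),
           f_mu_ricciardi(mu[["I"]], params, "I"))
  }
  top <- if (is_ssn) nu_cap else
    max(nu_max_of(pB$neuron_E), nu_max_of(pB$neuron_I))
  ax <- seq(0, top, length.out = n_lattice)
  seeds <- as.matrix(expand.grid(ax, ax))
  roots <- list()
  divergent <- FALSE
  for (i in seq_len(nrow(seeds))) {
    v <- seeds[i, ]
    ok <- FALSE
    for (it in 1:100) {
      f <- v - f_of(v)
      if (!all(is.finite(f))) break
      if (max(abs(f)) < 1e-10 * max(1, top)) { ok <- TRUE; break }
      if (it > 3 && length(roots) &&
          any(vapply(roots, function(k) max(abs(k - v)) < 0.02 * top, TRUE)))
        break
      h <- 1e-7 * top
      Jm <- matrix(0, 2, 2)
      for (j in 1:2) {
        vp <- v; vp[j] <- vp[j] + h
        Jm[, j] <- (vp - f_of(vp) - f) / h
      }
      dv <- tryCatch(solve(Jm, f), error = function(e) NULL)
      if (is.null(dv)) break
      v <- v - dv
      if (any(v > 2 * top)) { divergent <- is_ssn; break }
      v <- pmin(pmax(v, 0), 2 * top)
    }
    if (!ok) next
    if (is_ssn && any(v > nu_cap)) { divergent <- TRUE; next }
    dup <- any(vapply(roots, function(k) max(abs(k - v)) < 1e-4 * top, TRUE))
    if (!dup) roots[[length(roots) + 1]] <- unname(v)
  }
  if (length(roots) == 0) {
    out <- fixed_point_frame(numeric(0), numeric(0), numeric(0), numeric(0),
                             character(0))
  } else {
    ord <- order(vapply(roots, sum, 0))
    roots <- roots[ord]
    stab <- vapply(roots, function(v) {
      h <- 1e-5 * max(1, sum(abs(v)))
      Jm <- matrix(0, 2, 2)
      f0 <- f_of(v)
      for (j in 1:2) {
        vp <- v; vp[j] <- vp[j] + h
        Jm[, j] <- (f_of(vp) - f0) / h
      }
      tau <- c(pB$neuron_E$tau_m, pB$neuron_I$tau_m) / 1000
      ev <- Re(eigen(diag(1 / tau) %*% (Jm - diag(2)),
                     only.values = TRUE)$values)
      if (any(abs(ev) * max(tau) < 1e-6)) "unknown"
      else if (all(ev < 0)) "stable" else "unstable"
    }, "")
    out <- fixed_point_frame(vapply(roots, `[`, 0, 1),
                             vapply(roots, `[`, 0, 2),
                             NA_real_, NA_real_, stab, seq_along(roots))
  }
  attr(out, "divergent") <- divergent
  out
}

#' Noise amplitude of the spiking network at threshold crossing
#'
#' Finds the drive at which the mean excitatory input of the spiking mean
#' field crosses threshold along its (lowest-branch) solution and returns
#' the per-population noise amplitudes there. This is the default rule for
#' fixing the frozen noise of the Ricciardi rate model, ensuring both
#' models share an operating point at response onset.
#'
#' @param pB A [model_b_params()].
#' @param nu_X_range Search interval for the threshold crossing, in units
#'   of `nu_th_E`.
#' @return A list with `sigma_E`, `sigma_I` (mV) and the crossing drive
#'   `nu_X` (spikes/s).
#' @export
sigma_at_threshold <- function(pB, nu_X_range = c(0.05, 4)) {
  stopifnot(inherits(pB, "model_b_params"))
  u_of <- function(nx) {
    fp <- solve_model_b(nx, pB, n_lattice = 9)
    fp <- fp[which.min(fp$nu_E + fp$nu_I), ]
    m <- model_b_moments(fp$nu_E, fp$nu_I, nx, pB)
    list(u = pB$neuron_E$theta - m$E$mu, m = m)
  }
  lo <- nu_X_range[1] * pB$nu_th_E
  hi <- nu_X_range[2] * pB$nu_th_E
  f <- function(nx) u_of(nx)$u
  if (f(lo) < 0 || f(hi) > 0)
    stop("threshold crossing not bracketed in 'nu_X_range'")
  nx <- stats::uniroot(f, c(lo, hi), tol = 1e-6 * pB$nu_th_E)$root
  m <- u_of(nx)$m
  list(sigma_E = m$E$sigma, sigma_I = m$I$sigma, nu_X = nx)
}

#' Compare spiking mean field with rate models on a drive grid
#'
#' Aligned transfer curves for the spiking mean field, the fixed-noise
#' Ricciardi rate model and the SSN on one drive grid, with per-point
#' discrepancy of each rate model against the nearest spiking-mean-field
#' branch. By construction (shared weights and drives) all three models
#' have the same balanced-regime solution; differences isolate the
#' nonlinear onset and saturation regions.
#'
#' @param pB A [model_b_params()].
#' @param nu_X_grid Drive grid (spikes/s).
#' @param sigma_rule `"threshold"` (default: freeze the Ricciardi noise at
#'   the spiking network's threshold-crossing value) or a numeric
#'   `c(sigma_E, sigma_I)`.
#' @param ssn A [ssn_params()] or `NULL` for the default mapping.
#' @param ... Passed to the solvers.
#' @return A data frame with columns `model`, `nu_X`, `branch_id`, `nu_E`,
#'   `nu_I`, `stability`, `dev_E`, `dev_I` (deviation from the nearest
#'   spiking branch; `NA` for the spiking rows). The frozen noise used is
#'   attached as `attr(, "sigma")`.
#' @export
compare_models <- function(pB, nu_X_grid, sigma_rule = "threshold",
                           ssn = NULL, ...) {
  stopifnot(inherits(pB, "model_b_params"))
  if (identical(sigma_rule, "threshold")) {
    s <- sigma_at_threshold(pB)
    sigma <- c(s$sigma_E, s$sigma_I)
  } else {
    sigma <- as.numeric(sigma_rule)
    stopifnot(length(sigma) == 2L)
  }
  rp <- ricciardi_rate_params(sigma[1], sigma[2], pB)
  if (is.null(ssn)) ssn <- ssn_params(pB = pB)
  spik <- transfer_curve(pB, nu_X_grid, ...)
  spik$model <- "spiking_mf"
  spik$dev_E <- NA_real_
  spik$dev_I <- NA_real_
  one_rate <- function(params, label) {
    rows <- lapply(nu_X_grid, function(nx) {
      fp <- solve_rate_network(nx, params)
      if (nrow(fp) == 0) return(NULL)
      fp$nu_X <- nx
      fp
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out$model <- label
    ref <- spik
    out$dev_E <- NA_real_
    out$dev_I <- NA_real_
    for (i in seq_len(nrow(out))) {
      cand <- ref[ref$nu_X == out$nu_X[i], ]
      k <- which.min(abs(cand$nu_E - out$nu_E[i]) + abs(cand$nu_I - out$nu_I[i]))
      out$dev_E[i] <- out$nu_E[i] - cand$nu_E[k]
      out$dev_I[i] <- out$nu_I[i] - cand$nu_I[k]
    }
    out
  }
  ric <- one_rate(rp, "ricciardi_rate")
  ssn_tab <- one_rate(ssn, "ssn")
  cols <- c("model", "nu_X", "branch_id", "nu_E", "nu_I", "stability",
            "dev_E", "dev_I")
  out <- rbind(spik[, cols], ric[, cols], ssn_tab[, cols])
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  out
}
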