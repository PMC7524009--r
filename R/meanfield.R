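#' Input moments for the one-population network (model A)
#'
#' Mean and noise of the synaptic input to a neuron when the network fires
#' at rate `nu` and the external drive is `nu_X`:
#' \deqn{\mu = \tau J K[\nu_X + (1-g\gamma)\nu], \qquad
#'       \sigma^2 = \tau J^2 K[g_X\nu_X + (1+g^2\gamma)\nu].}
#' Ablation flags zero the recurrent term in the mean and/or the variance,
#' isolating the mean- and noise-mediated feedback pathways.
#'
#' @param nu Network rate (spikes/s), non-negative.
#' @param nu_X External drive (spikes/s), non-negative.
#' @param pA A [model_a_params()].
#' @param flags An [ablation_flags()].
#' @return A [gaussian_input()] with `mu`, `sigma` in mV.
#' @export
model_a_moments <- function(nu, nu_X, pA, flags = ablation_flags()) {
  stopifnot(inherits(pA, "model_a_params"), inherits(flags, "ablation_flags"))
  if (any(nu < 0) || any(nu_X < 0)) stop("rates must be non-negative")
  tau_s <- pA$neuron$tau_m / 1000
  rec_mu <- if (flags$drop_recurrent_mean) 0 else (1 - pA$g * pA$gamma) * nu
  rec_s2 <- if (flags$drop_recurrent_noise) 0 else (1 + pA$g^2 * pA$gamma) * nu
  mu <- tau_s * pA$J * pA$K * (nu_X + rec_mu)
  s2 <- tau_s * pA$J^2 * pA$K * (pA$g_X * nu_X + rec_s2)
  gaussian_input(mu = mu, sigma = sqrt(pmax(s2, 0)))
}

#' Input moments for the two-population network (model B)
#'
#' Per-population moments with external drives `nu_AX = alpha_A * nu_X`:
#' \deqn{\mu_A = \tau_A J_{AE} K_{AE}[\alpha_A\nu_X + \nu_E - g_A\gamma\nu_I]}
#' \deqn{\sigma_A^2 = \tau_A J_{AE}^2 K_{AE}[g_{AX}\alpha_A\nu_X + \nu_E +
#'   g_A^2\gamma\nu_I].}
#'
#' @param nu_E,nu_I Population rates (spikes/s).
#' @param nu_X External drive intensity (spikes/s).
#' @param pB A [model_b_params()].
#' @param flags An [ablation_flags()].
#' @return A list with [gaussian_input()] elements `E` and `I`.
#' @export
model_b_moments <- function(nu_E, nu_I, nu_X, pB, flags = ablation_flags()) {
  stopifnot(inherits(pB, "model_b_params"), inherits(flags, "ablation_flags"))
  if (any(c(nu_E, nu_I, nu_X) < 0)) stop("rates must be non-negative")
  one <- function(J, K, g, gX, alpha, neuron) {
    tau_s <- neuron$tau_m / 1000
    rec_mu <- if (flags$drop_recurrent_mean) 0 else nu_E - g * pB$gamma * nu_I
    rec_s2 <- if (flags$drop_recurrent_noise) 0 else nu_E + g^2 * pB$gamma * nu_I
    mu <- tau_s * J * K * (alpha * nu_X + rec_mu)
    s2 <- tau_s * J^2 * K * (gX * alpha * nu_X + rec_s2)
    gaussian_input(mu = mu, sigma = sqrt(pmax(s2, 0)))
  }
  list(E = one(pB$J_EE, pB$K_EE, pB$g_E, pB$g_EX, pB$alpha_E, pB$neuron_E),
       I = one(pB$J_IE, pB$K_IE, pB$g_I, pB$g_IX, pB$alpha_I, pB$neuron_I))
}

# rate predicted for each population given current rates (internal)
phi_of_rates_b <- function(nu_E, nu_I, nu_X, pB, flags) {
  m <- model_b_moments(nu_E, nu_I, nu_X, pB, flags)
  c(E = phi_ricciardi(m$E, neuron = pB$neuron_E),
    I = phi_ricciardi(m$I, neuron = pB$neuron_I))
}

fixed_point_frame <- function(nu_E, nu_I, u_max_E, u_max_I, stability,
                              branch_id = NA_integer_) {
  data.frame(nu_E = nu_E, nu_I = nu_I, u_max_E = u_max_E, u_max_I = u_max_I,
             stability = stability, branch_id = branch_id,
             stringsAsFactors = FALSE)
}

#' All mean-field fixed points of model A
#'
#' Finds every self-consistent rate, i.e. every root of
#' `F(nu) = nu - phi(mu(nu), sigma(nu))` on `[0, 1/tau_rp]`, by dense-grid
#' sign-change bracketing followed by bisection refinement. Each root is
#' annotated `stable`/`unstable` from the sign of `dF/dnu` (the fixed point
#' of the relaxation dynamics `tau dnu/dt = -nu + phi` is stable when
#' `dF/dnu > 0`).
#'
#' @param nu_X External drive (spikes/s), scalar.
#' @param pA A [model_a_params()].
#' @param flags An [ablation_flags()].
#' @param n_grid Bracketing grid size (default 2000).
#' @return A data frame of fixed points (columns `nu_E`, `nu_I`, `u_max_E`,
#'   `u_max_I`, `stability`, `branch_id`), ordered by rate. For model A the
#'   two populations share one rate, so `nu_E == nu_I`.
#' @examples
#' pa <- model_a_params(J = 0.2, g = 5, K = 1000)
#' solve_model_a(nu_X = 2 * pa$nu_th, pa)
#' @export
solve_model_a <- function(nu_X, pA, flags = ablation_flags(), n_grid = 2000) {
  stopifnot(inherits(pA, "model_a_params"), length(nu_X) == 1L, nu_X >= 0)
  nrn <- pA$neuron
  nu_max <- nu_max_of(nrn)
  Ffun <- function(nu) {
    m <- model_a_moments(nu, nu_X, pA, flags)
    nu - phi_ricciardi(m, neuron = nrn)
  }
  grid <- seq(0, nu_max, length.out = n_grid)
  Fv <- Ffun(grid)
  roots <- numeric(0)
  if (Fv[1] == 0) roots <- c(roots, 0)
  sgn <- Fv[-1] * Fv[-n_grid]
  for (i in which(sgn < 0)) {
    r <- stats::uniroot(Ffun, c(grid[i], grid[i + 1]), tol = 1e-12 * nu_max)
    roots <- c(roots, r$root)
  }
  # exact zeros on interior grid points
  roots <- sort(unique(c(roots, grid[-1][Fv[-1] == 0])))
  if (length(roots) == 0) stop("no fixed point found; F(0) >= 0 should guarantee one")
  h <- 1e-6 * nu_max
  stab <- vapply(roots, function(r) {
    lo <- max(r - h, 0); hi <- min(r + h, nu_max)
    dF <- (Ffun(hi) - Ffun(lo)) / (hi - lo)
    if (abs(dF) < 1e-8) "unknown" else if (dF > 0) "stable" else "unstable"
  }, "")
  m <- model_a_moments(roots, nu_X, pA, flags)
  um <- ifelse(m$sigma > 0, (nrn$theta - m$mu) / m$sigma, Inf)
  fixed_point_frame(roots, roots, um, um, stab, seq_along(roots))
}

# Newton solve of the 2-D self-consistency from one seed; returns c(nu_E, nu_I)
# or NULL. `known` is a list of already-found roots used to abandon seeds that
# drift into an explored basin.
newton_b <- function(seed, nu_X, pB, flags, known = list(),
                     tol = 1e-10, max_iter = 50) {
  nu_max <- max(nu_max_of(pB$neuron_E), nu_max_of(pB$neuron_I))
  v <- pmin(pmax(seed, 0), nu_max)
  h <- 1e-7 * nu_max
  best <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    f <- v - phi_of_rates_b(v[1], v[2], nu_X, pB, flags)
    if (!all(is.finite(f))) return(NULL)
    if (max(abs(f)) < tol * nu_max) return(unname(v))
    # stagnation cutoff: residual not shrinking
    if (max(abs(f)) < 0.7 * best) {
      best <- max(abs(f))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 8L) return(NULL)
    }
    if (it > 3 && length(known)) {
      for (k in known) if (max(abs(v - k)) < 1e-3 * nu_max) return(NULL)
    }
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      vp <- v; vp[j] <- vp[j] + h
      fp <- vp - phi_of_rates_b(vp[1], vp[2], nu_X, pB, flags)
      Jm[, j] <- (fp - f) / h
    }
    dv <- tryCatch(solve(Jm, f), error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    # backtracking line search, projected into the admissible box
    accepted <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      vtry <- pmin(pmax(v - damp * dv, 0), nu_max)
      ftry <- vtry - phi_of_rates_b(vtry[1], vtry[2], nu_X, pB, flags)
      if (all(is.finite(ftry)) && max(abs(ftry)) < max(abs(f))) {
        v <- vtry
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      vtry <- pmin(pmax(v - dv, 0), nu_max)
      if (max(abs(vtry - v)) < 1e-13 * nu_max) return(NULL)
      v <- vtry
    }
  }
  f <- v - phi_of_rates_b(v[1], v[2], nu_X, pB, flags)
  if (max(abs(f)) < 1e2 * tol * nu_max) unname(v) else NULL
}

stability_b <- function(v, nu_X, pB, flags) {
  nu_max <- max(nu_max_of(pB$neuron_E), nu_max_of(pB$neuron_I))
  h <- 1e-6 * nu_max
  J <- matrix(0, 2, 2)
  f0 <- phi_of_rates_b(v[1], v[2], nu_X, pB, flags)
  for (j in 1:2) {
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- max(vm[j] - h, 0)
    fp <- phi_of_rates_b(vp[1], vp[2], nu_X, pB, flags)
    fm <- phi_of_rates_b(vm[1], vm[2], nu_X, pB, flags)
    J[, j] <- (fp - fm) / (vp[j] - vm[j])
  }
  tau <- c(pB$neuron_E$tau_m, pB$neuron_I$tau_m) / 1000
  A <- diag(1 / tau) %*% (J - diag(2))
  ev <- Re(eigen(A, only.values = TRUE)$values)
  if (any(abs(ev) * max(tau) < 1e-6)) "unknown"
  else if (all(ev < 0)) "stable" else "unstable"
}

#' All mean-field fixed points of model B
#'
#' Solves the coupled self-consistency `nu_A = phi_A(mu_A, sigma_A)` for
#' both populations. Newton iterations are seeded from (i) a coarse lattice
#' over the admissible rate box and (ii) the five first-order expansion
#' branches of [model_b_epsilon_solutions()]; converged roots are
#' de-duplicated and annotated with a stability label from the eigenvalues
#' of the Jacobian of the relaxation dynamics
#' `tau_A dnu_A/dt = -nu_A + phi_A` (labelled `"unknown"` when an
#' eigenvalue is within tolerance of zero; the 2-D relaxation dynamics is a
#' heuristic stability proxy).
#'
#' @param nu_X External drive (spikes/s), scalar.
#' @param pB A [model_b_params()].
#' @param flags An [ablation_flags()].
#' @param n_lattice Seeding lattice resolution per axis (default 25).
#' @param extra_seeds Optional matrix/list of additional `(nu_E, nu_I)` seeds.
#' @return A data frame of fixed points as in [solve_model_a()].
#' @export
solve_model_b <- function(nu_X, pB, flags = ablation_flags(), n_lattice = 25,
                          extra_seeds = NULL) {
  stopifnot(inherits(pB, "model_b_params"), length(nu_X) == 1L, nu_X >= 0)
  nu_max_E <- nu_max_of(pB$neuron_E)
  nu_max_I <- nu_max_of(pB$neuron_I)
  nu_max <- max(nu_max_E, nu_max_I)
  ax_E <- seq(0, nu_max_E, length.out = n_lattice)
  ax_I <- seq(0, nu_max_I, length.out = n_lattice)
  seeds <- as.matrix(expand.grid(nu_E = ax_E, nu_I = ax_I))
  # onset-scale roots sit at rates far below the linear lattice spacing;
  # log-spaced seeds near the origin catch them
  ax_log <- c(0, 10^seq(-3, log10(nu_max / 4), length.out = 7))
  seeds <- rbind(seeds, as.matrix(expand.grid(nu_E = ax_log, nu_I = ax_log)))
  eps_seeds <- tryCatch({
    sols <- model_b_epsilon_solutions(nu_X, pB)
    do.call(rbind, lapply(sols, function(s) {
      if (!is.finite(s$nu1_E) || !is.finite(s$nu1_I)) return(NULL)
      c(s$nu0_E + pB$epsilon * s$nu1_E, s$nu0_I + pB$epsilon * s$nu1_I)
    }))
  }, error = function(e) NULL)
  if (!is.null(eps_seeds)) {
    keep <- eps_seeds[, 1] >= -0.1 * nu_max & eps_seeds[, 1] <= 1.1 * nu_max &
            eps_seeds[, 2] >= -0.1 * nu_max & eps_seeds[, 2] <= 1.1 * nu_max
    seeds <- rbind(seeds, pmin(pmax(eps_seeds[keep, , drop = FALSE], 0), nu_max))
  }
  if (!is.null(extra_seeds)) seeds <- rbind(seeds, as.matrix(extra_seeds))
  # order seeds by residual so roots are found early and later seeds can be
  # abandoned as soon as they enter a known basin
  res <- apply(seeds, 1, function(v) {
    f <- v - phi_of_rates_b(v[1], v[2], nu_X, pB, flags)
    sum(abs(f))
  })
  seeds <- seeds[order(res), , drop = FALSE]
  roots <- list()
  merge_tol <- 1e-4 * nu_max
  for (i in seq_len(nrow(seeds))) {
    r <- newton_b(seeds[i, ], nu_X, pB, flags, known = roots)
    if (is.null(r)) next
    dup <- any(vapply(roots, function(k) max(abs(k - r)) < merge_tol, TRUE))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (length(roots) == 0) stop("no fixed point converged; increase n_lattice")
  ord <- order(vapply(roots, function(r) r[1] + r[2], 0))
  roots <- roots[ord]
  stab <- vapply(roots, stability_b, "", nu_X = nu_X, pB = pB, flags = flags)
  m <- lapply(roots, function(r) model_b_moments(r[1], r[2], nu_X, pB, flags))
  umE <- vapply(m, function(x)
    ifelse(x$E$sigma > 0, (pB$neuron_E$theta - x$E$mu) / x$E$sigma, Inf), 0)
  umI <- vapply(m, function(x)
    ifelse(x$I$sigma > 0, (pB$neuron_I$theta - x$I$mu) / x$I$sigma, Inf), 0)
  fixed_point_frame(vapply(roots, `[`, 0, 1), vapply(roots, `[`, 0, 2),
                    umE, umI, stab, seq_along(roots))
}

#' Network transfer curve with branch continuation
#'
#' Solves the mean-field fixed points on a monotone grid of external drives
#' and links solutions at consecutive drives into branches by
#' nearest-neighbour matching in `(nu_E, nu_I)`. Branch births and deaths
#' (saddle-node events at grid resolution) are visible as changes in the
#' per-drive solution count.
#'
#' @param params A [model_a_params()] or [model_b_params()].
#' @param nu_X_grid Monotone vector of external drives (spikes/s).
#' @param flags An [ablation_flags()].
#' @param ... Passed to the underlying solver.
#' @return A data frame with columns `nu_X`, `branch_id`, `nu_E`, `nu_I`,
#'   `u_max_E`, `u_max_I`, `stability`.
#' @export
transfer_curve <- function(params, nu_X_grid, flags = ablation_flags(), ...) {
  stopifnot(is.numeric(nu_X_grid), !is.unsorted(nu_X_grid) || !is.unsorted(rev(nu_X_grid)))
  solver <- if (inherits(params, "model_a_params")) solve_model_a
            else if (inherits(params, "model_b_params")) solve_model_b
            else stop("'params' must be model_a_params or model_b_params")
  out <- vector("list", length(nu_X_grid))
  prev <- NULL
  next_id <- 1L
  for (i in seq_along(nu_X_grid)) {
    fp <- solver(nu_X_grid[i], params, flags, ...)
    ids <- integer(nrow(fp))
    if (is.null(prev)) {
      ids <- seq_len(nrow(fp))
      next_id <- nrow(fp) + 1L
    } else {
      taken <- logical(nrow(prev))
      for (j in order(fp$nu_E + fp$nu_I)) {
        d <- sqrt((prev$nu_E - fp$nu_E[j])^2 + (prev$nu_I - fp$nu_I[j])^2)
        d[taken] <- Inf
        k <- which.min(d)
        if (length(k) && is.finite(d[k])) {
          ids[j] <- prev$branch_id[k]
          taken[k] <- TRUE
        } else {
          ids[j] <- next_id
          next_id <- next_id + 1L
        }
      }
      # births: more solutions than before
      for (j in which(ids == 0L)) {
        ids[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    fp$branch_id <- ids
    fp$nu_X <- nu_X_grid[i]
    out[[i]] <- fp
    prev <- fp
  }
  res <- do.call(rbind, out)
  res[, c("nu_X", "branch_id", "nu_E", "nu_I", "u_max_E", "u_max_I", "stability")]
}

#' Feedforward-only response at onset (model A)
#'
#' Explicit low-rate response when recurrent inputs are negligible:
#' \deqn{\tau\nu = \sqrt{\frac{K\tau}{\pi}}\,
#'   \frac{\nu_{th}-\nu_X}{\sqrt{g_X\nu_X}}\,
#'   \exp\left(-\frac{K\tau(\nu_{th}-\nu_X)^2}{g_X\nu_X}\right),}
#' identical to [phi_subthreshold()] evaluated at feedforward-only moments.
#' The rate rises super-exponentially as `nu_X` approaches `nu_th`.
#'
#' @param nu_X External drive (spikes/s); `0` returns rate 0.
#' @param pA A [model_a_params()].
#' @param warn_regime Warn when `nu_X >= nu_th` (outside the onset regime).
#' @return Firing rate(s) in spikes/s.
#' @export
feedforward_onset_rate <- function(nu_X, pA, warn_regime = TRUE) {
  stopifnot(inherits(pA, "model_a_params"), is.numeric(nu_X), all(nu_X >= 0))
  if (warn_regime && any(nu_X >= pA$nu_th))
    warning("feedforward_onset_rate called with nu_X >= nu_th: outside onset regime")
  tau_s <- pA$neuron$tau_m / 1000
  out <- numeric(length(nu_X))
  pos <- nu_X > 0
  x <- nu_X[pos]
  out[pos] <- sqrt(pA$K * tau_s / pi) * (pA$nu_th - x) / sqrt(pA$g_X * x) *
    exp(-pA$K * tau_s * (pA$nu_th - x)^2 / (pA$g_X * x)) / tau_s
  pmax(out, 0)
}

#' Onset feedback decomposition (model A)
#'
#' Linearized growth rate of the relaxation dynamics around an operating
#' point in the subthreshold regime,
#' \deqn{\lambda = -1 - \frac{du_{max}}{d\nu}\,
#'   \frac{2u_{max}^2-1}{\sqrt{\pi}}\,e^{-u_{max}^2}}
#' (in units of `1/tau`), together with the additive decomposition of
#' `du_max/dnu` into the mean-input pathway `K J tau (g*gamma - 1)/sigma`
#' (negative feedback on the rate when inhibition dominates) and the
#' noise pathway `-u_max (1 + g^2 gamma) J^2 tau K / (2 sigma^2)` (positive
#' feedback when `u_max > 0`). Multistability at onset requires the combined
#' derivative to be sufficiently large and negative.
#'
#' @param nu Network rate (spikes/s).
#' @param nu_X External drive (spikes/s).
#' @param pA A [model_a_params()].
#' @param flags An [ablation_flags()] applied to the moments.
#' @param warn_regime Warn when `u_max < 1`.
#' @return A list with `lambda`, `d_umax_mean_term`, `d_umax_noise_term`,
#'   `d_umax_total` and the operating point `u_max`.
#' @export
onset_feedback <- function(nu, nu_X, pA, flags = ablation_flags(),
                           warn_regime = TRUE) {
  stopifnot(inherits(pA, "model_a_params"), length(nu) == 1L, length(nu_X) == 1L)
  m <- model_a_moments(nu, nu_X, pA, flags)
  if (m$sigma <= 0) stop("sigma = 0 at this operating point")
  nrn <- pA$neuron
  tau_s <- nrn$tau_m / 1000
  u_max <- (nrn$theta - m$mu) / m$sigma
  if (warn_regime && u_max < 1)
    warning("onset_feedback called with u_max < 1: outside the subthreshold regime")
  mean_term <- if (flags$drop_recurrent_mean) 0 else
    pA$K * pA$J * tau_s * (pA$g * pA$gamma - 1) / m$sigma
  noise_term <- if (flags$drop_recurrent_noise) 0 else
    -u_max * (1 + pA$g^2 * pA$gamma) * pA$J^2 * tau_s * pA$K / (2 * m$sigma^2)
  du <- mean_term + noise_term
  lambda <- -1 - du * (2 * u_max^2 - 1) / sqrt(pi) * exp(-u_max^2) / tau_s
  list(lambda = lambda, d_umax_mean_term = mean_term,
       d_umax_noise_term = noise_term, d_umax_total = du, u_max = u_max)
}

#' Map of fixed-point multiplicity over inhibition strengths (model B)
#'
#' For each `(g_E, g_I)` cell, records the maximum number of coexisting
#' mean-field fixed points over a grid of external drives, computed both
#' with the full moment equations and with recurrent noise ablated. Regions
#' where the two counts differ identify noise-generated (or
#' noise-suppressed) multistability.
#'
#' @param g_E_grid,g_I_grid Vectors of efficacy ratios.
#' @param pB_template A [model_b_params()] providing all other parameters.
#' @param nu_X_grid External drives (spikes/s) scanned per cell.
#' @param n_lattice Seeding lattice resolution passed to [solve_model_b()].
#' @return A data frame with `g_E`, `g_I`, `n_with_noise`, `n_without_noise`.
#' @export
solution_count_map <- function(g_E_grid, g_I_grid, pB_template, nu_X_grid,
                               n_lattice = 9) {
  stopifnot(inherits(pB_template, "model_b_params"))
  grid <- expand.grid(g_E = g_E_grid, g_I = g_I_grid)
  count_for <- function(pB, flags) {
    max(vapply(nu_X_grid, function(nx)
      nrow(solve_model_b(nx, pB, flags, n_lattice = n_lattice)), 0L))
  }
  n_with <- integer(nrow(grid))
  n_without <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pB <- pB_template
    pB$g_E <- grid$g_E[i]
    pB$g_I <- grid$g_I[i]
    n_with[i] <- count_for(pB, ablation_flags())
    n_without[i] <- count_for(pB, ablation_flags(drop_recurrent_noise = TRUE))
  }
  cbind(grid, n_with_noise = n_with, n_without_noise = n_without)
}
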