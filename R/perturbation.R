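#' High-rate network response of model A (exact polynomial form)
#'
#' In the drift-dominated regime the network transfer function reduces to
#' \deqn{\nu_X = \nu_{th} + \nu\left[(\gamma g - 1) +
#'   \frac{\epsilon}{1-\tau_{rp}\nu}\right],}
#' quadratic in `nu` after clearing denominators. Returns all real roots in
#' `[0, 1/tau_rp]`; at most two exist.
#'
#' @param nu_X External drive (spikes/s).
#' @param pA A [model_a_params()].
#' @return Numeric vector of roots (spikes/s), possibly empty, sorted.
#' @export
model_a_highrate_roots <- function(nu_X, pA) {
  stopifnot(inherits(pA, "model_a_params"), length(nu_X) == 1L)
  r <- pA$neuron$tau_rp / 1000
  a <- pA$gamma * pA$g - 1
  y <- nu_X - pA$nu_th
  eps <- pA$epsilon
  nu_max <- nu_max_of(pA$neuron)
  # a*r*nu^2 - (a + y*r + eps)*nu + y = 0
  A <- a * r; B <- -(a + y * r + eps); C <- y
  if (abs(A) < 1e-300) {
    roots <- if (abs(B) > 0) -C / B else numeric(0)
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(numeric(0))
    q <- -0.5 * (B + sign(B + (B == 0)) * sqrt(disc))
    roots <- unique(c(q / A, if (q != 0) C / q else NA_real_))
    roots <- roots[is.finite(roots)]
  }
  # discard the spurious root introduced by clearing the (1 - tau_rp nu) pole
  ok <- roots >= 0 & roots <= nu_max & abs(1 - r * roots) > 1e-12
  resid <- abs(pA$nu_th + roots * (a + eps / (1 - r * roots)) - nu_X)
  sort(roots[ok & resid < 1e-6 * max(1, abs(nu_X))])
}

#' First-order expansion of the model A response in the coupling smallness
#'
#' Perturbative solution `nu = nu0 + epsilon*nu1 + ...` of the high-rate
#' polynomial relation around the strong-coupling (`epsilon = 0`) limit.
#' There are two zeroth-order branches: the balanced solution
#' `nu0 = (nu_X - nu_th)/(gamma*g - 1)` with
#' `nu1 = -nu0 / ((gamma*g - 1)(1 - tau_rp*nu0))`, and the saturated
#' solution `nu0 = 1/tau_rp` with
#' `nu1 = -nu0 / (tau_rp*(nu_X - nu_th) - (gamma*g - 1))`. In the
#' inhibition-dominated regime the two branches are mutually exclusive: the
#' saturated branch is admissible (correction pushing the rate below its
#' ceiling) precisely when the balanced rate would exceed the ceiling.
#'
#' @inheritParams model_a_highrate_roots
#' @return A list with components `balanced` and `saturated`, each a list
#'   `nu0`, `nu1`, `admissible`, plus `inhibition_dominated`.
#' @export
model_a_epsilon_terms <- function(nu_X, pA) {
  stopifnot(inherits(pA, "model_a_params"), length(nu_X) == 1L)
  r <- pA$neuron$tau_rp / 1000
  a <- pA$gamma * pA$g - 1
  nu_max <- nu_max_of(pA$neuron)
  bal_nu0 <- if (a != 0) (nu_X - pA$nu_th) / a else NA_real_
  bal_sing <- is.na(bal_nu0) || abs(1 - r * bal_nu0) < 1e-12
  bal_nu1 <- if (bal_sing) NA_real_ else -bal_nu0 / (a * (1 - r * bal_nu0))
  sat_nu0 <- nu_max
  sat_den <- r * (nu_X - pA$nu_th) - a
  sat_nu1 <- if (abs(sat_den) < 1e-300) NA_real_ else -sat_nu0 / sat_den
  bal_ok <- !bal_sing && is.finite(bal_nu0) && bal_nu0 >= 0 && bal_nu0 <= nu_max
  sat_ok <- is.finite(sat_nu1) && sat_nu1 <= 0
  list(balanced = list(nu0 = bal_nu0, nu1 = bal_nu1, admissible = bal_ok),
       saturated = list(nu0 = sat_nu0, nu1 = sat_nu1, admissible = sat_ok),
       inhibition_dominated = a > 0)
}

# effective per-population drives; the printed expansion omits the nu_th
# offsets, optionally reinstated
drives_b <- function(nu_X, pB, include_nu_th = FALSE) {
  dE <- pB$alpha_E * nu_X
  dI <- pB$alpha_I * nu_X
  if (include_nu_th) {
    dE <- dE - pB$nu_th_E
    dI <- dI - pB$nu_th_I
  }
  list(dE = dE, dI = dI)
}

#' The five expansion solution families of model B
#'
#' First-order terms of the coupling-smallness expansion of the high-rate
#' system for the two-population network. The families are:
#' `s1` (regular/balanced: both populations track the drive linearly),
#' `s2` (supersaturated: the excitatory population is silenced by
#' overwhelming inhibition), `s3` (both populations saturated),
#' `s4` (E balanced, I saturated) and `s5` (E saturated, I balanced).
#'
#' Admissibility requires both first-order rates in `[0, 1/tau_rp]` and,
#' where a population sits on a silent or saturated branch, consistency of
#' that branch (subthreshold mean drive for a silent population; the
#' first-order correction keeping a saturated population at or below its
#' ceiling — equivalent to a suprathreshold mean drive).
#'
#' @param nu_X External drive (spikes/s), scalar.
#' @param pB A [model_b_params()].
#' @param include_nu_th Reinstate the per-population threshold-drive
#'   offsets `nu_th_A` in the expansion (default `FALSE`, matching the
#'   leading-order simplification).
#' @return A named list of five `epsilon_solution` objects with fields
#'   `family`, `nu0_E`, `nu0_I`, `nu1_E`, `nu1_I`, `admissible`,
#'   `curvature_E`, `curvature_I`.
#' @export
model_b_epsilon_solutions <- function(nu_X, pB, include_nu_th = FALSE) {
  stopifnot(inherits(pB, "model_b_params"), length(nu_X) == 1L, nu_X >= 0)
  r <- pB$neuron_E$tau_rp / 1000
  nu_max <- nu_max_of(pB$neuron_E)
  gE <- pB$g_E; gI <- pB$g_I; gam <- pB$gamma; beta <- pB$beta
  d <- drives_b(nu_X, pB, include_nu_th)
  dE <- d$dE; dI <- d$dI

  fam <- function(family, nu0_E, nu0_I, nu1_E, nu1_I, consistent = TRUE) {
    first_E <- nu0_E + pB$epsilon * nu1_E
    first_I <- nu0_I + pB$epsilon * nu1_I
    adm <- consistent && all(is.finite(c(first_E, first_I))) &&
      first_E >= -1e-12 && first_E <= nu_max * (1 + 1e-12) &&
      first_I >= -1e-12 && first_I <= nu_max * (1 + 1e-12)
    structure(list(family = family, nu0_E = nu0_E, nu0_I = nu0_I,
                   nu1_E = nu1_E, nu1_I = nu1_I, admissible = isTRUE(adm)),
              class = "epsilon_solution")
  }

  make_all <- function(dE, dI) {
    occ <- function(nu0) 1 - r * nu0
    # s1 regular (balanced): undefined at g_E = g_I
    if (abs(gE - gI) > 1e-12) {
      nI0 <- (dE - dI) / (gam * (gE - gI))
      nE0 <- (gI * dE - gE * dI) / (gE - gI)
      P <- if (abs(occ(nE0)) > 1e-12) nE0 / occ(nE0) else Inf
      Q <- if (abs(occ(nI0)) > 1e-12) beta * nI0 / occ(nI0) else Inf
      s1 <- fam("s1_regular", nE0, nI0,
                (-gI * P + gE * Q) / (gE - gI),
                (Q - P) / (gam * (gE - gI)))
    } else {
      s1 <- fam("s1_regular", NA_real_, NA_real_, NA_real_, NA_real_,
                consistent = FALSE)
    }
    # s2 supersaturated: E silent; requires subthreshold E drive
    nI0 <- dI / (gam * gI)
    s2 <- fam("s2_supersaturated", 0, nI0, 0,
              if (abs(occ(nI0)) > 1e-12) -beta * nI0 / (gam * gI * occ(nI0)) else Inf,
              consistent = (dE - gam * gE * nI0) <= 1e-12 * max(1, abs(dE)))
    # s3 both saturated
    s3 <- fam("s3_both_saturated", nu_max, nu_max,
              -(1 / r) / (dE * r + 1 - gam * gE),
              -(beta / r) / (dI * r + 1 - gam * gI))
    # s4 E balanced, I saturated
    nE0 <- gam * gE / r - dE
    nI1 <- -(beta / r) / (dI * r + nE0 * r - gam * gI)
    s4 <- fam("s4_E_balanced_I_saturated", nE0, nu_max,
              gam * gE * nI1 +
                if (abs(occ(nE0)) > 1e-12) nE0 / occ(nE0) else Inf,
              nI1)
    # s5 E saturated, I balanced
    nI0 <- (1 / r + dI) / (gam * gI)
    nE1 <- -(1 / r) / (dE * r + 1 - gam * gE * r * nI0)
    s5 <- fam("s5_E_saturated_I_balanced", nu_max, nI0, nE1,
              (nE1 - if (abs(occ(nI0)) > 1e-12) beta * nI0 / occ(nI0) else Inf) /
                (gam * gI))
    list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5)
  }

  sols <- make_all(dE, dI)
  # curvature of the first-order correction: sign of d(nu1)/d(nu_X)
  h <- max(1e-6, 1e-6 * abs(nu_X))
  d2 <- drives_b(nu_X + h, pB, include_nu_th)
  sols_h <- make_all(d2$dE, d2$dI)
  lab <- function(now, nxt) {
    if (!is.finite(now) || !is.finite(nxt)) return("undefined")
    s <- (nxt - now) / h
    if (abs(s) < 1e-9) "linear" else if (s > 0) "supralinear" else "sublinear"
  }
  for (nm in names(sols)) {
    sols[[nm]]$curvature_E <- lab(sols[[nm]]$nu1_E, sols_h[[nm]]$nu1_E)
    sols[[nm]]$curvature_I <- lab(sols[[nm]]$nu1_I, sols_h[[nm]]$nu1_I)
  }
  sols
}

#' @export
print.epsilon_solution <- function(x, ...) {
  cat(sprintf("%s: nu0 = (%.4g, %.4g), nu1 = (%.4g, %.4g), %s\n",
              x$family, x$nu0_E, x$nu0_I, x$nu1_E, x$nu1_I,
              if (x$admissible) "admissible" else "not admissible"))
  invisible(x)
}

#' Supralinearity threshold for the regular (s1) branch
#'
#' The excitatory first-order correction of the regular branch near onset is
#' positive (supralinear response) iff
#' \deqn{\beta g_E(\alpha_E-\alpha_I) > \gamma g_I(\alpha_E g_I -
#'   g_E\alpha_I),}
#' with critical value `beta_star` at equality. (The inhibitory-ratio factor
#' `gamma` enters through the zeroth-order inhibitory rate of the regular
#' branch.) For `alpha_E = alpha_I` the threshold is undefined and the sign
#' of the right-hand side decides.
#'
#' @param pB A [model_b_params()].
#' @return A list with `supralinear` (logical, at the `beta` of `pB`),
#'   `beta_star` (critical value; `NA` when undefined) and `defined`.
#' @export
supralinearity_threshold <- function(pB) {
  stopifnot(inherits(pB, "model_b_params"))
  lhs_coef <- pB$g_E * (pB$alpha_E - pB$alpha_I)
  rhs <- pB$gamma * pB$g_I * (pB$alpha_E * pB$g_I - pB$g_E * pB$alpha_I)
  if (abs(pB$alpha_E - pB$alpha_I) < 1e-12) {
    return(list(supralinear = rhs < 0, beta_star = NA_real_, defined = FALSE))
  }
  list(supralinear = pB$beta * lhs_coef > rhs,
       beta_star = rhs / lhs_coef, defined = TRUE)
}

# closed-form admissibility of the five families in the nu_X -> 0+ limit,
# decided by signs of the zeroth-order slopes and of the limiting
# first-order denominators (first non-vanishing order at exact threshold
# ties). Returns a character vector subset of s1..s5.
scenario_at_zero <- function(pB) {
  gE <- pB$g_E; gI <- pB$g_I; gam <- pB$gamma
  aE <- pB$alpha_E; aI <- pB$alpha_I
  out <- character(0)
  dg <- gE - gI
  cross <- aE * gI - gE * aI
  if (abs(dg) > 1e-12) {
    slope_E <- cross / dg
    slope_I <- (aE - aI) / (gam * dg)
    if (slope_E > 0 && slope_I > 0) out <- c(out, "s1")
  }
  if (cross < 0) out <- c(out, "s2")
  s3_E <- gam * gE < 1 || (gam * gE == 1 && aE > 0)
  s3_I <- gam * gI < 1 || (gam * gI == 1 && aI > 0)
  if (s3_E && s3_I) out <- c(out, "s3")
  if (gam * gE < 1 && dg > 1e-12) out <- c(out, "s4")
  if (gam * gI > 1 && dg < -1e-12) out <- c(out, "s5")
  out
}

#' Admissibility scan of the expansion families at one drive
#'
#' Evaluates all five expansion families and reports which are admissible.
#' At `nu_X = 0` the decision uses leading-order sign analysis (rates vanish
#' there); at positive drives the first-order rates are range-checked
#' directly. The coexistence rules implied by the family structure are
#' asserted: `s3` and `s5` never co-occur, `s1` and `s2` together exclude
#' `s4`, and at most three families are admissible.
#'
#' @param pB A [model_b_params()].
#' @param nu_X External drive (spikes/s); `0` requests the onset-limit
#'   analysis.
#' @param include_nu_th Passed to [model_b_epsilon_solutions()] for finite
#'   drives.
#' @return An object of class `scenario_report`: a list with `params`,
#'   `nu_X`, `admissible_set` (character), `scenario_label` (canonical
#'   sorted string such as `"s1+s2+s3"`).
#' @export
admissibility_scan <- function(pB, nu_X = 0, include_nu_th = FALSE) {
  stopifnot(inherits(pB, "model_b_params"), length(nu_X) == 1L, nu_X >= 0)
  if (pB$epsilon > 0.2)
    warning("epsilon > 0.2: first-order expansion may be unreliable")
  adm <- if (nu_X == 0) {
    scenario_at_zero(pB)
  } else {
    sols <- model_b_epsilon_solutions(nu_X, pB, include_nu_th)
    sub("_.*", "", names(sols))[vapply(sols, `[[`, TRUE, "admissible")]
  }
  adm <- sort(unique(adm))
  if (all(c("s3", "s5") %in% adm))
    stop("internal consistency failure: s3 and s5 are mutually exclusive")
  if (all(c("s1", "s2") %in% adm) && "s4" %in% adm)
    stop("internal consistency failure: s1+s2 excludes s4")
  if (length(adm) > 3)
    stop("internal consistency failure: more than three admissible families")
  structure(list(params = pB, nu_X = nu_X, admissible_set = adm,
                 scenario_label = paste(adm, collapse = "+")),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario at nu_X = %g: {%s}\n", x$nu_X,
              paste(x$admissible_set, collapse = ", ")))
  invisible(x)
}

#' Enumerate admissibility scenarios over a sign-complete parameter lattice
#'
#' Scans a lattice of `(g_E, g_I, alpha_E, alpha_I, beta)` values covering
#' every sign pattern of the discriminating expressions (`g_I/g_E` vs
#' `alpha_I/alpha_E` vs 1, `gamma*g_E` and `gamma*g_I` vs 1) and collects
#' the distinct admissible sets at onset, each with one representative
#' parameter point. Degenerate points (equalities of the discriminants,
#' `g_E = g_I`) are skipped: they sit on scenario boundaries.
#'
#' @param g_E_grid,g_I_grid,alpha_I_grid,beta_grid Lattice axes
#'   (`alpha_E = 1` throughout; only the drive ratio matters at onset).
#' @param gamma Inhibitory in-degree ratio.
#' @param K,J Coupling scale used to instantiate parameter objects.
#' @return A data frame with one row per distinct scenario: columns
#'   `scenario`, `size`, `n_cells`, `g_E`, `g_I`, `alpha_E`, `alpha_I`,
#'   `beta` (representative point).
#' @export
scenario_enumeration <- function(g_E_grid = c(0.5, 1, 2, 3, 3.5, 5, 6, 8, 10, 12),
                                 g_I_grid = g_E_grid,
                                 alpha_I_grid = c(0.1, 0.2, 0.45, 0.8, 1.3, 2.2,
                                                  3.7, 6.1, 10),
                                 beta_grid = c(0.25, 1, 4),
                                 gamma = 0.25, K = 1000, J = 0.2) {
  cells <- expand.grid(g_E = g_E_grid, g_I = g_I_grid, alpha_I = alpha_I_grid,
                       beta = beta_grid)
  found <- list()
  counts <- integer(0)
  for (i in seq_len(nrow(cells))) {
    gE <- cells$g_E[i]; gI <- cells$g_I[i]; aI <- cells$alpha_I[i]
    if (abs(gE - gI) < 1e-9) next
    if (abs(gI - gE * aI) < 1e-9) next          # alpha_E*g_I == g_E*alpha_I tie
    if (abs(gamma * gE - 1) < 1e-9 || abs(gamma * gI - 1) < 1e-9) next
    pB <- model_b_params(J_EE = J, J_IE = J, g_E = gE, g_I = gI,
                         alpha_E = 1, alpha_I = aI, gamma = gamma,
                         K_EE = K, K_IE = round(K / cells$beta[i]))
    rep_ <- admissibility_scan(pB, nu_X = 0)
    lab <- rep_$scenario_label
    if (lab == "") lab <- "(none)"
    if (is.null(found[[lab]])) {
      found[[lab]] <- cells[i, ]
      counts[lab] <- 0L
    }
    counts[lab] <- counts[lab] + 1L
  }
  labs <- names(found)
  out <- data.frame(
    scenario = labs,
    size = vapply(labs, function(l)
      if (l == "(none)") 0L else length(strsplit(l, "+", fixed = TRUE)[[1]]),
      0L),
    n_cells = unname(counts[labs]),
    stringsAsFactors = FALSE)
  reps <- do.call(rbind, found)
  out <- cbind(out, g_E = reps$g_E, g_I = reps$g_I, alpha_E = 1,
               alpha_I = reps$alpha_I, beta = reps$beta)
  rownames(out) <- NULL
  out[order(out$size, out$scenario), ]
}

#' Uniqueness classification of the onset scenario
#'
#' Closed-form conditions under which a single expansion family is
#' admissible at onset: the regular branch alone
#' (`alpha_I/alpha_E < g_I/g_E < 1` and `gamma*g_E > 1`) or the
#' supersaturated branch alone (`g_I/g_E < alpha_I/alpha_E`,
#' `g_I/g_E < 1`, `gamma*g_E > 1`, `gamma*g_I < 1`). When neither condition
#' holds, the onset admissibility scan decides between `multiple` (more
#' than one family) and `undetermined` (a single family outside the two
#' closed-form regions).
#'
#' @param pB A [model_b_params()].
#' @return One of `"unique_s1"`, `"unique_s2"`, `"multiple"`,
#'   `"undetermined"`.
#' @export
uniqueness_conditions <- function(pB) {
  stopifnot(inherits(pB, "model_b_params"))
  ratio_g <- pB$g_I / pB$g_E
  ratio_a <- pB$alpha_I / pB$alpha_E
  if (ratio_a < ratio_g && ratio_g < 1 && pB$gamma * pB$g_E > 1)
    return("unique_s1")
  if (ratio_g < ratio_a && ratio_g < 1 && pB$gamma * pB$g_E > 1 &&
      pB$gamma * pB$g_I < 1)
    return("unique_s2")
  n <- length(admissibility_scan(pB, nu_X = 0)$admissible_set)
  if (n > 1) "multiple" else "undetermined"
}

#' External drive holding the operating point fixed (model A)
#'
#' Inverts the moment equations for the drive `nu_X` at which the network,
#' firing at rate `nu`, has operating point `u_max = omega`. At `omega = 0`
#' this is exactly the balanced relation
#' `nu_X = nu_th + (g*gamma - 1)*nu`; for `omega` of order one the
#' correction shrinks with coupling as `1/sqrt(K)` in rate units.
#'
#' @param nu Network rate (spikes/s), in `[0, 1/tau_rp)`.
#' @param omega Target operating point (dimensionless).
#' @param pA A [model_a_params()].
#' @return The drive `nu_X` (spikes/s).
#' @export
operating_point_input <- function(nu, omega, pA) {
  stopifnot(inherits(pA, "model_a_params"), length(nu) == 1L,
            length(omega) == 1L)
  nrn <- pA$neuron
  if (nu < 0 || nu >= nu_max_of(nrn)) stop("'nu' must lie in [0, 1/tau_rp)")
  tau_s <- nrn$tau_m / 1000
  a <- tau_s * pA$J * pA$K
  b <- tau_s * pA$J^2 * pA$K
  cmu <- (1 - pA$g * pA$gamma) * nu
  ds2 <- (1 + pA$g^2 * pA$gamma) * nu
  th <- nrn$theta
  if (omega == 0) return(th / a - cmu)
  # (th - a*cmu - a*x)^2 = omega^2 * b * (g_X * x + ds2)
  A2 <- a^2
  B2 <- -(2 * a * (th - a * cmu) + omega^2 * b * pA$g_X)
  C2 <- (th - a * cmu)^2 - omega^2 * b * ds2
  disc <- B2^2 - 4 * A2 * C2
  if (disc < 0) stop("no real drive attains this operating point")
  cand <- c((-B2 + sqrt(disc)) / (2 * A2), (-B2 - sqrt(disc)) / (2 * A2))
  ok <- cand >= 0 & sign(th - a * (cand + cmu)) == sign(omega)
  if (!any(ok)) stop("no admissible drive attains this operating point")
  # the branch continuously connected to omega = 0 has mu near threshold
  cand <- cand[ok]
  cand[which.min(abs(cand - (th / a - cmu)))]
}

#' Numerically exact solution of the high-rate system (model B)
#'
#' Newton solution of the drift-dominated polynomial system
#' \deqn{d_E + \nu_E - \gamma g_E \nu_I = \epsilon\nu_E/(1-\tau_{rp}\nu_E)}
#' \deqn{d_I + \nu_E - \gamma g_I \nu_I = \beta\epsilon\nu_I/(1-\tau_{rp}\nu_I)}
#' from a given seed, used to verify the convergence order of the expansion
#' families. For a saturated-family seed the corresponding rate coordinate
#' is solved in the variable `1 - tau_rp*nu` to preserve accuracy near the
#' ceiling.
#'
#' @param nu_X External drive (spikes/s).
#' @param pB A [model_b_params()].
#' @param seed Numeric `(nu_E, nu_I)` starting point (e.g. a first-order
#'   family prediction).
#' @param include_nu_th Reinstate threshold-drive offsets.
#' @return Numeric `(nu_E, nu_I)` or `NULL` if Newton fails.
#' @export
solve_highrate_b <- function(nu_X, pB, seed, include_nu_th = FALSE) {
  stopifnot(inherits(pB, "model_b_params"), length(seed) == 2L)
  r <- pB$neuron_E$tau_rp / 1000
  d <- drives_b(nu_X, pB, include_nu_th)
  gam <- pB$gamma; eps <- pB$epsilon; beta <- pB$beta
  G <- function(v) {
    c(d$dE + v[1] - gam * pB$g_E * v[2] - eps * v[1] / (1 - r * v[1]),
      d$dI + v[1] - gam * pB$g_I * v[2] - beta * eps * v[2] / (1 - r * v[2]))
  }
  v <- as.numeric(seed)
  scale <- max(abs(v), 1)
  for (it in 1:200) {
    f <- G(v)
    if (!all(is.finite(f))) return(NULL)
    if (max(abs(f)) < 1e-12 * max(1, max(abs(v)))) return(v)
    h <- 1e-8 * scale
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      vp <- v; vp[j] <- vp[j] + h
      Jm[, j] <- (G(vp) - f) / h
    }
    dv <- tryCatch(solve(Jm, f), error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    # keep iterates off the refractory pole
    vnew <- v - dv
    vnew <- pmin(vnew, 1 / r - 1e-9 / r)
    v <- vnew
  }
  if (max(abs(G(v))) < 1e-8 * max(1, max(abs(v)))) v else NULL
}
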