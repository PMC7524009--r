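pa_ref <- model_a_params(J = 0.2, g = 5, K = 1000)

test_that("model A moments match hand-computed values and limits", {
  # feedforward-only: mu = tau J K nu_X, sigma^2 = tau J^2 K g_X nu_X
  m <- model_a_moments(0, 5, pa_ref)
  expect_equal(m$mu, 0.02 * 0.2 * 1000 * 5)
  expect_equal(m$sigma^2, 0.02 * 0.04 * 1000 * 5)
  # reference one-population parameters, nu = nu_X = 5: direct substitution
  m2 <- model_a_moments(5, 5, pa_ref)
  expect_equal(m2$mu, 0.02 * 0.2 * 1000 * (5 + (1 - 5 * 0.25) * 5))
  expect_equal(m2$sigma^2, 0.02 * 0.04 * 1000 * (5 + (1 + 25 * 0.25) * 5))
  # g = 1/gamma: recurrent mean cancels
  pa_c <- model_a_params(J = 0.2, g = 4, gamma = 0.25, K = 1000)
  expect_equal(model_a_moments(10, 5, pa_c)$mu, model_a_moments(0, 5, pa_c)$mu)
  # ablations zero exactly the recurrent terms
  mm <- model_a_moments(5, 5, pa_ref, ablation_flags(drop_recurrent_mean = TRUE))
  expect_equal(mm$mu, m$mu)
  expect_equal(mm$sigma, m2$sigma)
  ms <- model_a_moments(5, 5, pa_ref, ablation_flags(drop_recurrent_noise = TRUE))
  expect_equal(ms$sigma, m$sigma)
  expect_error(model_a_moments(-1, 5, pa_ref), "non-negative")
})

test_that("model B moments reduce to model A under symmetry", {
  pb <- model_b_from_a(pa_ref)
  mB <- model_b_moments(4, 4, 5, pb)
  mA <- model_a_moments(4, 5, pa_ref)
  expect_equal(mB$E$mu, mA$mu)
  expect_equal(mB$I$mu, mA$mu)
  expect_equal(mB$E$sigma, mA$sigma)
  # zero rates: feedforward-only
  m0 <- model_b_moments(0, 0, 5, pb)
  expect_equal(m0$E$mu, 0.02 * 0.2 * 1000 * 5)
})

test_that("model A fixed points satisfy self-consistency and stability labels", {
  fp <- solve_model_a(2 * pa_ref$nu_th, pa_ref)
  expect_gte(nrow(fp), 1)
  for (i in seq_len(nrow(fp))) {
    m <- model_a_moments(fp$nu_E[i], 2 * pa_ref$nu_th, pa_ref)
    expect_lt(abs(fp$nu_E[i] - phi_ricciardi(m)), 1e-8 * 500)
  }
  # zero drive, no recurrence possible from silence: nu = 0 is a fixed point
  fp0 <- solve_model_a(0, pa_ref)
  expect_equal(min(fp0$nu_E), 0)
})

test_that("strong coupling converges to the balanced line", {
  dist_at <- function(K, nu_X) {
    pa <- model_a_params(J = 0.2, g = 5, K = K)
    bal <- (nu_X - pa$nu_th) / (pa$gamma * pa$g - 1)
    fp <- solve_model_a(nu_X, pa)
    min(abs(fp$nu_E - bal)) / bal
  }
  dist_K <- vapply(c(1e3, 1e4, 1e5), dist_at, 0, nu_X = 10)
  expect_true(all(diff(dist_K) < 0))
  # K = 1e5 within 2% of the balanced prediction well above onset
  expect_lt(dist_at(1e5, 40), 0.02)
})

test_that("onset multistability interval exists and is noise-generated", {
  pa <- model_a_params(J = 0.5, g = 5, K = 1000)
  grid <- seq(0.2, 0.9, by = 0.05) * pa$nu_th
  counts <- vapply(grid, function(nx) nrow(solve_model_a(nx, pa)), 0L)
  expect_gte(max(counts), 3)
  # ablating recurrent noise removes the multi-solution interval
  counts_nonoise <- vapply(grid, function(nx)
    nrow(solve_model_a(nx, pa, ablation_flags(drop_recurrent_noise = TRUE))), 0L)
  expect_equal(max(counts_nonoise), 1)
  # ablating the recurrent mean does not
  counts_nomean <- vapply(grid, function(nx)
    nrow(solve_model_a(nx, pa, ablation_flags(drop_recurrent_mean = TRUE))), 0L)
  expect_gte(max(counts_nomean), 3)
})

test_that("two-population solver agrees with the one-population solver", {
  pb <- model_b_from_a(pa_ref)
  for (f in c(0.8, 1.5, 2.5)) {
    fpA <- solve_model_a(f * pa_ref$nu_th, pa_ref)
    fpB <- solve_model_b(f * pa_ref$nu_th, pb, n_lattice = 9)
    expect_equal(nrow(fpA), nrow(fpB))
    expect_equal(sort(fpB$nu_E), sort(fpA$nu_E), tolerance = 1e-6)
    expect_equal(sort(fpB$nu_I), sort(fpA$nu_E), tolerance = 1e-6)
  }
})

test_that("coexisting fixed points match the brute-force grid oracle", {
  pb <- fixture_params("modelB_s1s2s3")
  fp <- solve_model_b(5, pb, n_lattice = 12)
  expect_equal(nrow(fp), 3)
  expect_equal(count_roots_grid_b(5, pb), 3)
  expect_setequal(fp$stability, c("stable", "unstable", "stable"))
  # root set invariant to doubling the seeding lattice (coexistence sets)
  for (nm in c("modelB_s1s2s3", "modelB_s1s3s4", "modelB_s1s2s5",
               "modelB_s2s3s4")) {
    p <- fixture_params(nm)
    a <- solve_model_b(0.04 * 500, p, n_lattice = 9)
    b <- solve_model_b(0.04 * 500, p, n_lattice = 18)
    expect_equal(nrow(a), nrow(b), label = nm)
    expect_equal(sort(a$nu_E), sort(b$nu_E), tolerance = 1e-6)
  }
})

test_that("supersaturation: excitatory rate non-monotone while inhibition grows", {
  pb <- with_beta(fixture_params("modelB_supersat"), 4)
  drv <- c(0.1, 1.15, 3, 6)
  tops <- t(vapply(drv, function(nx) {
    fp <- solve_model_b(nx, pb, n_lattice = 9)
    st <- fp[fp$stability == "stable", ]
    if (nrow(st) == 0) st <- fp
    unlist(st[which.max(st$nu_E + st$nu_I), c("nu_E", "nu_I")])
  }, c(nu_E = 0, nu_I = 0)))
  expect_gt(tops[2, "nu_E"], tops[1, "nu_E"])   # rises at onset
  expect_gt(tops[2, "nu_E"], tops[4, "nu_E"])   # then suppressed
  expect_true(all(diff(tops[, "nu_I"]) > 0))    # inhibition monotone
})

test_that("transfer_curve links branches consistently with the solvers", {
  pb <- fixture_params("modelB_s1s2s3")
  grid <- c(2, 5, 10, 20, 30)
  tc <- transfer_curve(pb, grid, n_lattice = 9)
  for (nx in grid) {
    expect_equal(sum(tc$nu_X == nx),
                 nrow(solve_model_b(nx, pb, n_lattice = 9)))
  }
  # single-solution parameter set: one branch spanning the grid
  pr <- fixture_params("sim_regular")
  tcr <- transfer_curve(pr, c(10, 14, 18), n_lattice = 9)
  expect_equal(unique(tcr$branch_id), 1L)
})

test_that("feedforward onset rate equals the subthreshold rate at zero recurrence", {
  pa <- model_a_params(J = 0.5, g = 5, K = 1000)
  for (f in c(0.3, 0.6, 0.8)) {
    nx <- f * pa$nu_th
    m <- model_a_moments(0, nx, pa)
    expect_equal(feedforward_onset_rate(nx, pa),
                 phi_subthreshold(m$mu, m$sigma), tolerance = 1e-12)
  }
  # steep exponential rise approaching nu_th: orders of magnitude per step
  r <- feedforward_onset_rate(c(0.3, 0.45, 0.6) * pa$nu_th, pa)
  expect_true(all(diff(log(r)) > 0))
  expect_true(all(diff(log(r)) > 10))
  expect_equal(feedforward_onset_rate(0, pa), 0)
  # direct substitution at nu_X = 0.8 nu_th (Kramers form)
  nx <- 0.8 * pa$nu_th
  tau_s <- 0.02
  u <- sqrt(1000 * tau_s) * (pa$nu_th - nx) / sqrt(nx)
  expect_equal(feedforward_onset_rate(nx, pa), u * exp(-u^2) / (tau_s * sqrt(pi)))
})

test_that("onset feedback decomposition has the predicted signs and derivative", {
  pa <- model_a_params(J = 0.5, g = 5, K = 1000)
  ofb <- onset_feedback(1, 0.6 * pa$nu_th, pa, warn_regime = FALSE)
  expect_gt(ofb$d_umax_mean_term, 0)    # inhibition-dominated: negative feedback
  expect_lt(ofb$d_umax_noise_term, 0)   # subthreshold noise: positive feedback
  # finite-difference check of the decomposition
  h <- 1e-6
  u_of <- function(nu) {
    m <- model_a_moments(nu, 0.6 * pa$nu_th, pa)
    (pa$neuron$theta - m$mu) / m$sigma
  }
  fd <- (u_of(1 + h) - u_of(1 - h)) / (2 * h)
  expect_equal(ofb$d_umax_total, fd, tolerance = 1e-6)
  expect_error(onset_feedback(0, 0, pa), "sigma")
})

test_that("solution count map shows noise effects in both directions", {
  pb <- fixture_params("modelB_countmap_weak")
  mp <- solution_count_map(c(6.5, 8), c(2, 8), pb,
                           seq(0.2, 1.3, length.out = 8) * pb$nu_th_E)
  gained <- any(mp$n_with_noise > mp$n_without_noise)
  lost <- any(mp$n_without_noise > mp$n_with_noise)
  expect_true(gained)
  expect_true(lost)
})
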