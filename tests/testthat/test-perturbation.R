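test_that("high-rate roots solve the polynomial relation exactly", {
  pa <- model_a_params(J = 0.2, g = 5, K = 1000)
  r <- pa$neuron$tau_rp / 1000
  for (nu_X in c(8, 15, 40, 120)) {
    roots <- model_a_highrate_roots(nu_X, pa)
    expect_lte(length(roots), 2)
    for (nu in roots) {
      lhs <- pa$nu_th + nu * ((pa$gamma * pa$g - 1) +
                                pa$epsilon / (1 - r * nu))
      expect_equal(lhs, nu_X, tolerance = 1e-10)
    }
  }
  # near-zero coupling smallness: root approaches the balanced line
  pa_big <- model_a_params(J = 0.2, g = 5, K = 1e7)
  nu_X <- 2 * pa_big$nu_th + 10
  bal <- (nu_X - pa_big$nu_th) / 0.25
  expect_equal(min(model_a_highrate_roots(nu_X, pa_big)), bal,
               tolerance = 1e-4)
  # sublinear saturation: root strictly below the balanced line
  for (nu_X in c(10, 20, 40)) {
    bal <- (nu_X - pa$nu_th) / 0.25
    expect_lt(min(model_a_highrate_roots(nu_X, pa)), bal)
  }
})

test_that("high-rate roots track the full transfer function in the drift regime", {
  pa <- model_a_params(J = 0.2, g = 5, K = 1000)
  for (nu_X in c(80, 120)) {
    fp <- solve_model_a(nu_X, pa)
    sol <- fp[which.max(fp$nu_E), ]
    expect_lt(sol$u_max_E, -1)
    roots <- model_a_highrate_roots(nu_X, pa)
    expect_lt(min(abs(roots - sol$nu_E)) / sol$nu_E, 0.05)
  }
})

test_that("model A expansion branches behave as derived", {
  pa <- model_a_params(J = 0.2, g = 5, K = 1000)
  # linear first-order correction at low occupancy
  et1 <- model_a_epsilon_terms(8, pa)
  et2 <- model_a_epsilon_terms(11, pa)   # double (nu_X - nu_th)
  expect_equal(et2$balanced$nu1 / et1$balanced$nu1, 2, tolerance = 0.05)
  # mutual exclusivity: saturated admissible iff balanced overshoots
  expect_true(et1$balanced$admissible)
  expect_false(et1$saturated$admissible)
  et_hi <- model_a_epsilon_terms(5 + 0.25 * 600, pa)  # balanced nu0 = 600 > 500
  expect_false(et_hi$balanced$admissible)
  expect_true(et_hi$saturated$admissible)
  expect_lte(et_hi$saturated$nu1, 0)
  # Richardson check: first-order prediction error shrinks as epsilon^2
  errs <- vapply(c(1, 2, 4), function(s) {
    p <- model_a_params(J = 0.2, g = 5, K = 1000 * s)
    nu_X <- 3 * p$nu_th + 20
    et <- model_a_epsilon_terms(nu_X, p)
    pred <- et$balanced$nu0 + p$epsilon * et$balanced$nu1
    exact <- min(model_a_highrate_roots(nu_X, p))
    abs(pred - exact)
  }, 0)
  expect_gt(errs[1] / errs[2], 3.3)  # halving epsilon ~quarters the error
  expect_gt(errs[2] / errs[3], 3.5)
})

ref_supra <- function(beta = 1)
  with_beta(model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = 8, g_I = 3.9,
                           alpha_E = 7, alpha_I = 1, K_EE = 1000,
                           K_IE = 1000), beta)

test_that("expansion families have the printed structure", {
  pb <- ref_supra()
  sols <- model_b_epsilon_solutions(2, pb)
  # regular-branch slopes by direct substitution:
  # nu0_E = (gI aE - gE aI)/(gE - gI) nu_X, nu0_I = (aE - aI)/(gam (gE-gI)) nu_X
  expect_equal(sols$s1$nu0_E / 2, (3.9 * 7 - 8 * 1) / (8 - 3.9),
               tolerance = 1e-12)
  expect_equal(sols$s1$nu0_I / 2, (7 - 1) / (0.25 * (8 - 3.9)),
               tolerance = 1e-12)
  # supersaturated: excitatory population silent, sublinear inhibitory
  expect_equal(sols$s2$nu0_E, 0)
  expect_equal(sols$s2$nu1_E, 0)
  expect_lte(sols$s2$nu1_I, 0)
  expect_equal(sols$s2$curvature_I, "sublinear")
  # saturated family starts at the ceiling
  expect_equal(sols$s3$nu0_E, 500)
  expect_equal(sols$s3$nu0_I, 500)
  # degenerate g_E = g_I: regular branch undefined
  pb_deg <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = 5, g_I = 5,
                           K_EE = 1000, K_IE = 1000)
  expect_false(model_b_epsilon_solutions(2, pb_deg)$s1$admissible)
})

test_that("supralinearity threshold is consistent with the first-order sign", {
  th <- supralinearity_threshold(ref_supra())
  expect_true(th$defined)
  # closed-form critical value (inhibitory-ratio factor included)
  expect_equal(th$beta_star,
               0.25 * 3.9 * (7 * 3.9 - 8 * 1) / (8 * (7 - 1)),
               tolerance = 1e-12)
  for (b in c(0.7, 1.3) * th$beta_star) {
    pb <- ref_supra(b)
    s1 <- model_b_epsilon_solutions(1, pb)$s1
    expect_equal(s1$nu1_E > 0, b > th$beta_star,
                 label = sprintf("sign flip at beta = %.3f", b))
    expect_equal(supralinearity_threshold(pb)$supralinear, b > th$beta_star)
  }
  # alpha_E = alpha_I: threshold undefined, RHS sign decides
  pb_eq <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = 8, g_I = 3.9,
                          alpha_E = 2, alpha_I = 2, K_EE = 1000, K_IE = 1000)
  expect_false(supralinearity_threshold(pb_eq)$defined)
})

test_that("uniqueness conditions classify the reference parameter sets", {
  expect_equal(uniqueness_conditions(fixture_params("sim_sublinear")),
               "unique_s1")
  expect_equal(uniqueness_conditions(fixture_params("modelB_supersat")),
               "unique_s2")
  # gamma g_E < 1 can never give unique_s1
  set.seed(2)
  for (i in 1:25) {
    g_E <- runif(1, 0.2, 3.9)  # gamma g_E < 1 at gamma = 0.25
    pb <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = g_E,
                         g_I = runif(1, 0.2, 12), alpha_E = runif(1, 0.1, 5),
                         alpha_I = runif(1, 0.1, 5), K_EE = 1000, K_IE = 1000)
    expect_true(uniqueness_conditions(pb) != "unique_s1")
  }
})

test_that("admissibility scan matches the reference coexistence sets", {
  for (nm in c(s1s2s3 = "modelB_s1s2s3", s1s3s4 = "modelB_s1s3s4",
               s1s2s5 = "modelB_s1s2s5", s2s3s4 = "modelB_s2s3s4")) {
    rep_ <- admissibility_scan(fixture_params(nm), nu_X = 0)
    expect_equal(length(rep_$admissible_set), 3, label = nm)
  }
  expect_setequal(admissibility_scan(fixture_params("modelB_s1s2s5"), 0)$admissible_set,
                  c("s1", "s2", "s5"))
  # very large drive: both populations saturate, only s3 admissible
  expect_equal(admissibility_scan(fixture_params("modelB_s1s2s3"), 4000)$admissible_set,
               "s3")
})

test_that("coexistence rules hold on a random parameter sample", {
  set.seed(7)
  n <- 4000
  for (i in seq_len(n)) {
    pb <- model_b_params(J_EE = 0.2, J_IE = 0.2,
                         g_E = runif(1, 0.3, 12), g_I = runif(1, 0.3, 12),
                         alpha_E = 10^runif(1, -1, 1),
                         alpha_I = 10^runif(1, -1, 1),
                         K_EE = 1000, K_IE = round(1000 / runif(1, 0.25, 4)))
    # internal assertions fire on any rule violation
    rep_ <- admissibility_scan(pb, nu_X = 0)
    expect_lte(length(rep_$admissible_set), 3)
    if (length(rep_$admissible_set) == 1 &&
        uniqueness_conditions(pb) %in% c("unique_s1", "unique_s2")) {
      expect_equal(paste0("unique_", rep_$admissible_set),
                   uniqueness_conditions(pb))
    }
  }
  expect_true(TRUE)  # reached without internal-consistency failures
})

test_that("scenario enumeration finds the printed triples and no pairs", {
  sc <- scenario_enumeration()
  triples <- sort(sc$scenario[sc$size == 3])
  expect_setequal(triples, c("s1+s2+s3", "s1+s2+s5", "s1+s3+s4", "s2+s3+s4"))
  expect_false(any(sc$size == 2))
  expect_true(all(c("s1", "s2", "s3") %in% sc$scenario[sc$size == 1]))
})

test_that("operating-point inversion reproduces the balanced relation", {
  pa <- model_a_params(J = 0.2, g = 5, K = 1000)
  for (nu in c(5, 30, 100)) {
    expect_equal(operating_point_input(nu, 0, pa),
                 pa$nu_th + (pa$g * pa$gamma - 1) * nu, tolerance = 1e-12)
  }
  # definitional inversion: solving at the returned drive recovers u_max = omega
  nu <- 30
  for (om in c(-1, 0.5, 1)) {
    nx <- operating_point_input(nu, om, pa)
    m <- model_a_moments(nu, nx, pa)
    expect_equal((pa$neuron$theta - m$mu) / m$sigma, om, tolerance = 1e-9)
  }
  # drive correction at omega = 1 shrinks like 1/sqrt(K)
  dev_K <- vapply(c(1e3, 1e4, 1e5), function(K) {
    p <- model_a_params(J = 0.2, g = 5, K = K)
    operating_point_input(30, 1, p) - operating_point_input(30, 0, p)
  }, 0)
  fit <- stats::lm(log(abs(dev_K)) ~ log(c(1e3, 1e4, 1e5)))
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("first-order model B solutions converge to exact roots at order ~2", {
  base <- fixture_params("modelB_s1s2s3")
  scales <- c(1, 2, 4, 8)
  errs <- vapply(scales, function(s) {
    p <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = base$g_E,
                        g_I = base$g_I, alpha_E = base$alpha_E,
                        alpha_I = base$alpha_I, K_EE = 1000 * s,
                        K_IE = 1000 * s)
    s1 <- model_b_epsilon_solutions(5, p)$s1
    pred <- c(s1$nu0_E + p$epsilon * s1$nu1_E, s1$nu0_I + p$epsilon * s1$nu1_I)
    ex <- solve_highrate_b(5, p, pred)
    max(abs(pred - ex))
  }, 0)
  slope <- -stats::coef(stats::lm(log(errs) ~ log(scales)))[2]
  expect_gt(unname(slope), 1.9)
  # successive observed orders increase toward 2
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(diff(orders) > 0))
})
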