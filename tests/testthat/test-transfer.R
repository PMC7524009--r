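test_that("erfcx is stable across the double range and matches the oracle", {
  x <- c(-26, -10, -3, -1, 0, 0.5, 1, 3, 6.9, 7, 10, 50, 1e4, 1e8)
  expect_equal(erfcx(x), erfcx_oracle(x), tolerance = 1e-13)
  expect_true(all(is.finite(erfcx(x))))
  # large-argument asymptote 1/(x sqrt(pi))
  expect_equal(erfcx(1e8) * 1e8 * sqrt(pi), 1, tolerance = 1e-10)
})

test_that("phi_ricciardi reproduces frozen quadrature values and limits", {
  # frozen from the independent adaptive-quadrature oracle (rel.tol 1e-12)
  expect_equal(phi_ricciardi(25, 5), 47.2174433041, tolerance = 1e-9)
  # deep subthreshold: astronomically small rate
  expect_lt(phi_ricciardi(-1000, 5), 1e-12)
  # refractory ceiling 1/tau_rp = 500 spk/s
  for (mu in c(0, 20, 50, 500)) {
    expect_lte(phi_ricciardi(mu, 5), 500)
    expect_gt(phi_ricciardi(mu, 5), 0)
  }
  # strictly increasing in mu at fixed sigma
  mus <- seq(-20, 60, by = 2.5)
  expect_true(all(diff(phi_ricciardi(mus, 4)) > 0))
})

test_that("phi_ricciardi matches adaptive and trapezoid oracles over a lattice", {
  mus <- c(-5, 5, 12, 18, 22, 30)
  sigs <- c(1.5, 6)
  for (mu in mus) for (s in sigs) {
    expect_equal(phi_ricciardi(mu, s), phi_oracle(mu, s), tolerance = 1e-9,
                 label = sprintf("phi(%g, %g) vs integrate oracle", mu, s))
  }
  expect_equal(phi_ricciardi(15, 4), phi_trapezoid(15, 4), tolerance = 5e-7)
})

test_that("sigma -> 0 connects continuously to the drift rate", {
  expect_equal(phi_drift(30), 1 / (0.002 + 0.02 * log(2)), tolerance = 1e-12)
  expect_equal(phi_ricciardi(30, 0), phi_drift(30))
  expect_equal(phi_drift(15), 0)            # subthreshold, no noise
  expect_equal(phi_drift(1e9), 500, tolerance = 1e-6)  # saturation
  # mu = 25 mV, sigma = 0.1 mV: within 1% of the deterministic rate
  expect_lt(abs(phi_ricciardi(25, 0.1) - phi_drift(25)) / phi_drift(25), 0.01)
})

test_that("subthreshold escape approximation is accurate in its regime", {
  # u_max >= 3 grid: relative error vs full quadrature < 10%
  for (s in c(2, 4)) {
    mu <- 20 - 3.2 * s  # u_max = 3.2
    expect_lt(abs(phi_subthreshold(mu, s) / phi_ricciardi(mu, s) - 1), 0.1)
  }
  # vanishes as sigma -> 0 below threshold; monotone in noise
  expect_equal(phi_subthreshold(10, 1e-4), 0, tolerance = 1e-30)
  expect_gt(phi_subthreshold(8, 4), phi_subthreshold(8, 2))
  expect_warning(phi_subthreshold(19.9, 5), "regime")
})

test_that("cv_isi matches nested-quadrature oracles and limiting behavior", {
  expect_equal(cv_isi(10, 5), cv_oracle(10, 5), tolerance = 1e-7)
  expect_equal(cv_isi(10, 5), cv_trapezoid(10, 5), tolerance = 1e-5)
  # drift-dominated firing is regular
  expect_lt(cv_isi(40, 0.5), 0.1)
  # deep-subthreshold Poisson limit
  expect_equal(cv_isi(0, 5), 1, tolerance = 0.05)
  expect_equal(cv_isi(-30, 10), 1, tolerance = 0.02)
  expect_error(cv_isi(10, 0), "sigma")
})

test_that("high-rate CV approximation decays linearly in the free fraction", {
  pa <- model_a_params(J = 0.2, g = 5, K = 1000)
  occ <- c(0.002, 0.001, 0.0005, 0.00025)
  nus <- (1 - occ) * 500
  cvs <- suppressWarnings(cv_suprathreshold_approx(nus, pa))
  ratio <- cvs[-1] / cvs[-length(cvs)]
  # CV ~ (1 - tau_rp nu): halving the free fraction halves the CV
  expect_equal(ratio, rep(0.5, 3), tolerance = 0.1)
  # agreement with the full CV once u_max < -2 (reference network parameters)
  nu <- 420
  nu_X <- 5 + nu * (0.25 + pa$epsilon / (1 - 0.002 * nu))  # high-rate relation
  m <- model_a_moments(nu, nu_X, pa)
  expect_lt((20 - m$mu) / m$sigma, -2)
  expect_lt(abs(suppressWarnings(cv_suprathreshold_approx(nu, pa)) /
                cv_isi(m) - 1), 0.2)
  # grows with K at fixed J and occupancy (read off the formula)
  pa2 <- model_a_params(J = 0.2, g = 5, K = 4000)
  expect_gt(suppressWarnings(cv_suprathreshold_approx(250, pa2)),
            suppressWarnings(cv_suprathreshold_approx(250, pa)))
})

test_that("input validation signals bad parameters", {
  expect_error(phi_ricciardi(Inf, 5), "finite")
  expect_error(phi_ricciardi(10, -1), "sigma")
  expect_error(neuron_params(theta = 5, v_reset = 10), "theta")
  expect_error(gaussian_input(10, -2), "sigma")
})
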