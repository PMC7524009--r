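# small networks keep these checks fast; accuracy at scale is exercised by
# the acceptance suite
pa_small <- model_a_params(J = 0.2, g = 5, K = 100)
cfg_fast <- spiking_net_config(seed = 5, t_transient = 0.3, t_measure = 1.5)

test_that("uniform wiring has exact in-degrees; builds are reproducible", {
  net <- build_network(pa_small, cfg_fast)
  expect_equal(net$NE, 11 * 100)
  expect_equal(net$NI, 11 * 25)
  expect_equal(var(net$core$in_degree), 0)
  expect_equal(net$core$in_degree[1], 100 + 25)
  net2 <- build_network(pa_small, cfg_fast)
  expect_identical(net$core$targets, net2$core$targets)
  expect_identical(net$core$delay_steps, net2$core$delay_steps)
  net3 <- build_network(pa_small, spiking_net_config(seed = 6))
  expect_false(identical(net$core$targets, net3$core$targets))
  # in-degree larger than the presynaptic pool is rejected
  expect_error(build_network(model_a_params(J = 0.2, g = 5, K = 100),
                             spiking_net_config(size_multiplier = 1)),
               "in-degree")
})

test_that("Erdos-Renyi wiring has binomial in-degrees around the nominal K", {
  cfg_er <- spiking_net_config(seed = 5, connectivity = "erdos_renyi")
  net <- build_network(pa_small, cfg_er)
  indeg <- net$core$in_degree[seq_len(net$NE)]
  expect_gt(var(indeg), 0)
  # mean within 3 SE of K_EE + K_EI
  K_tot <- 125
  se <- sqrt(K_tot) / sqrt(net$NE)  # loose upper bound on SE of the mean
  expect_lt(abs(mean(indeg) - K_tot), 3 * sqrt(125) )
  expect_lt(abs(mean(indeg) - K_tot) / K_tot, 0.05)
})

test_that("silent network stays silent; feedforward rate matches theory", {
  net <- build_network(pa_small, cfg_fast)
  s0 <- simulate_network(net, 0)
  expect_equal(s0$pop_rate_E, 0)
  expect_equal(s0$silent_fraction_E, 1)
  # recurrence off: Poisson-driven LIF ensemble vs Ricciardi prediction
  nuX <- 1.3 * pa_small$nu_th
  s <- simulate_network(net, nuX, recurrent = FALSE, t_measure = 2)
  m <- model_a_moments(0, nuX, pa_small)
  pred <- phi_ricciardi(m)
  se <- sqrt(pred / (net$NE * 2))
  expect_lt(abs(s$pop_rate_E - pred), 3 * se + 0.02 * pred)
  expect_lt(abs(s$cv_E - cv_isi(m)), 0.05)
})

test_that("halving the integration step changes rates by less than 2 percent", {
  nuX <- 1.3 * pa_small$nu_th
  r <- vapply(c(0.05, 0.025), function(dt) {
    cfg <- spiking_net_config(seed = 5, dt = dt, t_transient = 0.5,
                              t_measure = 3)
    simulate_network(build_network(pa_small, cfg), nuX)$pop_rate_E
  }, 0)
  expect_lt(abs(r[2] / r[1] - 1), 0.02)
})

test_that("ER connectivity widens the per-neuron rate distribution", {
  nuX <- 1.4 * pa_small$nu_th
  s_uni <- simulate_network(build_network(pa_small, cfg_fast), nuX,
                            t_measure = 2)
  cfg_er <- spiking_net_config(seed = 5, connectivity = "erdos_renyi",
                               t_transient = 0.3, t_measure = 2)
  s_er <- simulate_network(build_network(pa_small, cfg_er), nuX,
                           t_measure = 2)
  expect_gt(var(s_er$per_neuron_rates_E), 1.5 * var(s_uni$per_neuron_rates_E))
})

test_that("CV estimator recovers Poisson and periodic limits", {
  set.seed(31)
  # homogeneous Poisson trains at 20 Hz for 60 s
  tr <- do.call(rbind, lapply(1:40, function(id) {
    t <- cumsum(rexp(2000, 20))
    data.frame(neuron_id = id, time_s = t[t < 60])
  }))
  est <- estimate_cv(tr, min_spikes = 100)
  se <- 1 / sqrt(mean(est$per_neuron$n)) / sqrt(40)
  expect_lt(abs(est$mean_cv - 1), 3 * se + 0.01)
  # perfectly periodic train
  per <- data.frame(neuron_id = 1, time_s = seq(0, 10, by = 0.05))
  expect_equal(estimate_cv(per)$mean_cv, 0)
  # no qualifying neuron: undefined, not zero
  few <- data.frame(neuron_id = 1, time_s = c(0.1, 0.5))
  expect_true(is.na(estimate_cv(few, min_spikes = 3)$mean_cv))
  expect_error(estimate_cv(few, min_spikes = 2), "min_spikes")
})

test_that("replica external drive reproduces aggregate-mode rates", {
  cfg_rep <- spiking_net_config(seed = 5, external_mode = "replica",
                                t_transient = 0.3, t_measure = 1.5)
  net_a <- build_network(pa_small, cfg_fast)
  net_r <- build_network(pa_small, cfg_rep)
  nuX <- 1.3 * pa_small$nu_th
  ra <- simulate_network(net_a, nuX)$pop_rate_E
  rr <- simulate_network(net_r, nuX)$pop_rate_E
  expect_lt(abs(ra - rr) / ra, 0.15)
})

test_that("ramp protocol reports no hysteresis for a single-solution network", {
  pr <- fixture_params("sim_regular")
  # reduced scale for speed
  pr_small <- model_b_params(J_EE = 0.2, J_IE = 0.2, g_E = pr$g_E,
                             g_I = pr$g_I, alpha_E = 1, alpha_I = 1,
                             K_EE = 100, K_IE = 100)
  net <- build_network(pr_small, spiking_net_config(seed = 9,
                                                    t_transient = 0.4,
                                                    t_measure = 1.5))
  rp <- ramp_protocol(net, c(1, 1.3, 1.6) * pr_small$nu_th_E)
  expect_false(any(rp$hysteresis[rp$sweep == "down"]))
  expect_true(all(diff(rp$rate_E[rp$sweep == "up"]) > 0))
})
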