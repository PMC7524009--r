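#' Spiking-network simulation configuration
#'
#' Engineering knobs of the clock-driven simulator. Population sizes are
#' `N_E = size_multiplier * K_EE` and `N_I = size_multiplier * K_EI`
#' (inhibitory in-degree of E cells), so the default multiplier 11 at
#' `K = 400`, `gamma = 0.25` gives about 5,500 neurons. Synaptic delays are
#' drawn per synapse from uniform distributions (defaults `[0, 100]` ms for
#' excitatory and `[0, 1]` ms for inhibitory synapses, wide enough to
#' suppress synchronized oscillations) and rounded up to integration steps.
#'
#' @param size_multiplier Neurons per in-degree unit.
#' @param connectivity `"uniform"` (fixed in-degree) or `"erdos_renyi"`.
#' @param delay_range_E,delay_range_I Uniform delay bounds (ms).
#' @param dt Integration step (ms).
#' @param t_transient Discarded settling time per drive step (s).
#' @param t_measure Measured time per drive step (s).
#' @param seed Integer seed governing all randomness (wiring, delays,
#'   Poisson drive, initial conditions).
#' @param initial_condition `"reset"` (all at `V_r`) or `"uniform_random"`.
#' @param external_mode `"aggregate"` (one Poisson count of rate
#'   `K_AX * nu_AX` per neuron per step; statistically equivalent for rate
#'   and CV measurements) or `"replica"` (explicit pool of
#'   `size_multiplier * K_AX` shared Poisson units, for
#'   correlation-sensitive checks).
#' @param record_spikes Return the raw `(neuron_id, time_s)` spike table.
#' @param min_spikes Minimum spike count for a neuron to enter CV averages.
#' @return An object of class `spiking_net_config`.
#' @export
spiking_net_config <- function(size_multiplier = 11,
                               connectivity = c("uniform", "erdos_renyi"),
                               delay_range_E = c(0, 100),
                               delay_range_I = c(0, 1),
                               dt = 0.05, t_transient = 2, t_measure = 10,
                               seed = 1,
                               initial_condition = c("reset", "uniform_random"),
                               external_mode = c("aggregate", "replica"),
                               record_spikes = FALSE, min_spikes = 10) {
  connectivity <- match.arg(connectivity)
  initial_condition <- match.arg(initial_condition)
  external_mode <- match.arg(external_mode)
  stopifnot(dt > 0, t_measure > 0, t_transient >= 0,
            all(delay_range_E >= 0), all(delay_range_I >= 0),
            diff(delay_range_E) >= 0, diff(delay_range_I) >= 0)
  structure(list(size_multiplier = size_multiplier,
                 connectivity = connectivity,
                 delay_range_E = delay_range_E,
                 delay_range_I = delay_range_I, dt = dt,
                 t_transient = t_transient, t_measure = t_measure,
                 seed = as.integer(seed),
                 initial_condition = initial_condition,
                 external_mode = external_mode,
                 record_spikes = isTRUE(record_spikes),
                 min_spikes = min_spikes),
            class = "spiking_net_config")
}

#' Build a connectivity realization
#'
#' Instantiates the synaptic wiring for a spiking simulation: with
#' `"uniform"` connectivity every neuron receives exactly its nominal
#' in-degree from each presynaptic population (sampled without
#' replacement); with `"erdos_renyi"` every ordered pair is an independent
#' Bernoulli variable with probability in-degree/pool-size (no
#' self-connections). Per-synapse delays are drawn once at build time.
#' Builds are deterministic in `cfg$seed`.
#'
#' @param params A [model_b_params()] (or [model_a_params()], promoted
#'   symmetrically).
#' @param cfg A [spiking_net_config()].
#' @return An object of class `spiking_network`.
#' @export
build_network <- function(params, cfg = spiking_net_config()) {
  if (inherits(params, "model_a_params")) params <- model_b_from_a(params)
  stopifnot(inherits(params, "model_b_params"),
            inherits(cfg, "spiking_net_config"))
  pB <- params
  NE <- cfg$size_multiplier * pB$K_EE
  KEI <- round(pB$gamma * pB$K_EE)
  KII <- round(pB$gamma * pB$K_IE)
  NI <- cfg$size_multiplier * KEI
  if (max(pB$K_EE, pB$K_IE) > NE || max(KEI, KII) > NI)
    stop("in-degree exceeds presynaptic population size")
  core <- build_network_cpp(NE, NI, pB$K_EE, KEI, pB$K_IE, KII,
                            cfg$connectivity == "erdos_renyi",
                            cfg$delay_range_E[1], cfg$delay_range_E[2],
                            cfg$delay_range_I[1], cfg$delay_range_I[2],
                            cfg$dt, cfg$seed)
  xE <- list(); xI <- list()
  if (cfg$external_mode == "replica") {
    xE <- build_x_cpp(cfg$size_multiplier * pB$K_EE, NE, pB$K_EE,
                      cfg$seed + 101)
    xI <- build_x_cpp(cfg$size_multiplier * pB$K_IE, NI, pB$K_IE,
                      cfg$seed + 202)
    xI$targets <- xI$targets + NE
  }
  structure(list(core = core, xE = xE, xI = xI, params = pB, cfg = cfg,
                 NE = NE, NI = NI),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("Spiking network: %d E + %d I neurons, %s connectivity, %d synapses\n",
              x$NE, x$NI, x$cfg$connectivity, length(x$core$targets)))
  invisible(x)
}

run_phases <- function(net, nu_X_phase, t_phase, measure_phase,
                       seed_offset = 0, recurrent = TRUE) {
  pB <- net$params
  cfg <- net$cfg
  rec <- as.numeric(recurrent)
  JEE <- rec * pB$J_EE; JIE <- rec * pB$J_IE
  simulate_net_cpp(net$core, nu_X_phase, t_phase, measure_phase,
                   JEE = JEE, JEI = -pB$g_E * JEE,
                   JIE = JIE, JII = -pB$g_I * JIE,
                   # the drive parameter absorbs g_AX into nu_AX: external
                   # units fire at alpha_A*nu_X/g_AX with efficacy g_AX*J_AE,
                   # giving mean ~ alpha_A*nu_X and variance ~ g_AX*alpha_A*nu_X
                   JEX = pB$g_EX * pB$J_EE, JIX = pB$g_IX * pB$J_IE,
                   KEX = pB$K_EE, KIX = pB$K_IE,
                   alpha_E = pB$alpha_E / pB$g_EX,
                   alpha_I = pB$alpha_I / pB$g_IX,
                   theta = pB$neuron_E$theta, vr = pB$neuron_E$v_reset,
                   tau_E = pB$neuron_E$tau_m, tau_I = pB$neuron_I$tau_m,
                   trp = pB$neuron_E$tau_rp, dt_ms = cfg$dt,
                   seed = cfg$seed + seed_offset,
                   init_mode = if (cfg$initial_condition == "uniform_random") 1L else 0L,
                   record_spikes = cfg$record_spikes, pop_bin_ms = 1,
                   xE = net$xE, xI = net$xI)
}

oscillation_index_of <- function(bins, dt_bin = 1e-3) {
  if (length(bins) < 64 || sum(bins) == 0) return(NA_real_)
  x <- bins - mean(bins)
  p <- Mod(stats::fft(x))^2
  n <- length(p)
  # one-sided, drop DC and the slowest components (trend), up to Nyquist
  idx <- seq(4, floor(n / 2))
  if (length(idx) < 8) return(NA_real_)
  max(p[idx]) / stats::median(p[idx])
}

summarize_phase <- function(ph, NE, NI, min_spikes) {
  n <- length(ph$counts)
  rates <- ph$counts / ph$t
  eidx <- seq_len(NE)
  iidx <- seq(NE + 1, n)
  cv_of <- function(idx) {
    ok <- idx[ph$counts[idx] >= min_spikes & ph$isi_n[idx] >= 2]
    if (!length(ok)) return(list(mean = NA_real_, per = rep(NA_real_, length(idx))))
    m <- ph$isi_sum[ok] / ph$isi_n[ok]
    va <- pmax(ph$isi_sum2[ok] / ph$isi_n[ok] - m^2, 0) *
      ph$isi_n[ok] / pmax(ph$isi_n[ok] - 1, 1)
    per <- rep(NA_real_, length(idx))
    per[match(ok, idx)] <- sqrt(va) / m
    list(mean = mean(sqrt(va) / m), per = per)
  }
  cvE <- cv_of(eidx)
  cvI <- cv_of(iidx)
  structure(list(nu_X = ph$nu_X, t_measure = ph$t,
                 pop_rate_E = mean(rates[eidx]), pop_rate_I = mean(rates[iidx]),
                 per_neuron_rates_E = rates[eidx],
                 per_neuron_rates_I = rates[iidx],
                 cv_E = cvE$mean, cv_I = cvI$mean,
                 per_neuron_cv_E = cvE$per, per_neuron_cv_I = cvI$per,
                 silent_fraction_E = mean(ph$counts[eidx] == 0),
                 silent_fraction_I = mean(ph$counts[iidx] == 0),
                 oscillation_index = oscillation_index_of(ph$bin_E + ph$bin_I)),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("nu_X = %.3g: rate E = %.3g, I = %.3g spk/s; CV E = %.3g, I = %.3g; silent E = %.1f%%\n",
              x$nu_X, x$pop_rate_E, x$pop_rate_I, x$cv_E, x$cv_I,
              100 * x$silent_fraction_E))
  invisible(x)
}

#' Simulate the network at fixed external drive
#'
#' Runs a transient (discarded) followed by a measured window at constant
#' drive and summarizes rates, CVs, silent fractions and the oscillation
#' index (spectral peak over background of the 1-ms-binned population
#' rate).
#'
#' @param net A [build_network()] result.
#' @param nu_X External drive intensity (spikes/s).
#' @param t_measure,t_transient Override the config durations (s).
#' @param recurrent Set `FALSE` to zero all recurrent efficacies (external
#'   drive only), e.g. to validate against the feedforward transfer
#'   function.
#' @return A `sim_summary` (list) with population rates, per-neuron rates,
#'   mean ISI CVs, silent fractions, oscillation index; when the config has
#'   `record_spikes = TRUE` the spike table is attached as
#'   `attr(, "spikes")`.
#' @export
simulate_network <- function(net, nu_X, t_measure = NULL, t_transient = NULL,
                             recurrent = TRUE) {
  stopifnot(inherits(net, "spiking_network"), length(nu_X) == 1L, nu_X >= 0)
  cfg <- net$cfg
  tm <- if (is.null(t_measure)) cfg$t_measure else t_measure
  tt <- if (is.null(t_transient)) cfg$t_transient else t_transient
  res <- run_phases(net, c(nu_X, nu_X), c(tt, tm), c(FALSE, TRUE),
                    recurrent = recurrent)
  out <- summarize_phase(res$phases[[2]], net$NE, net$NI, cfg$min_spikes)
  if (!is.null(res$spikes)) attr(out, "spikes") <- res$spikes
  out
}

#' Ramp protocol: drive sweep with warm starts and hysteresis detection
#'
#' Steps the external drive up a monotone grid and (optionally) back down,
#' warm-starting each step from the final network state of the previous
#' one. Where the up- and down-sweep rates at the same drive differ by more
#' than a noise band the step is flagged as hysteretic: the signature of
#' coexisting stable states.
#'
#' @param net A [build_network()] result.
#' @param nu_X_grid Monotone increasing drive grid (spikes/s).
#' @param down Also sweep back down.
#' @param t_measure,t_transient Per-step durations (s); defaults from the
#'   config.
#' @param band Relative half-width of the hysteresis band (fraction of the
#'   larger rate), combined with an absolute floor of 3 standard errors.
#' @return A data frame with one row per drive and direction (`sweep` is
#'   `"up"`/`"down"`), rates and CVs per population, `oscillation_index`,
#'   and for down-sweep rows `hysteresis` (logical).
#' @export
ramp_protocol <- function(net, nu_X_grid, down = TRUE, t_measure = NULL,
                          t_transient = NULL, band = 0.1) {
  stopifnot(inherits(net, "spiking_network"), !is.unsorted(nu_X_grid))
  cfg <- net$cfg
  tm <- if (is.null(t_measure)) cfg$t_measure else t_measure
  tt <- if (is.null(t_transient)) cfg$t_transient else t_transient
  grid <- c(nu_X_grid, if (down) rev(nu_X_grid))
  dirs <- c(rep("up", length(nu_X_grid)),
            if (down) rep("down", length(nu_X_grid)))
  phases_nu <- rep(grid, each = 2)
  phases_t <- rep(c(tt, tm), length(grid))
  phases_meas <- rep(c(FALSE, TRUE), length(grid))
  res <- run_phases(net, phases_nu, phases_t, phases_meas)
  meas <- res$phases[seq(2, length(res$phases), by = 2)]
  summ <- lapply(meas, summarize_phase, NE = net$NE, NI = net$NI,
                 min_spikes = cfg$min_spikes)
  out <- data.frame(
    nu_X = grid, sweep = dirs,
    rate_E = vapply(summ, `[[`, 0, "pop_rate_E"),
    rate_I = vapply(summ, `[[`, 0, "pop_rate_I"),
    cv_E = vapply(summ, `[[`, 0, "cv_E"),
    cv_I = vapply(summ, `[[`, 0, "cv_I"),
    silent_fraction_E = vapply(summ, `[[`, 0, "silent_fraction_E"),
    oscillation_index = vapply(summ, `[[`, 0, "oscillation_index"),
    stringsAsFactors = FALSE)
  out$hysteresis <- NA
  if (down) {
    for (i in seq_along(nu_X_grid)) {
      up_i <- which(out$sweep == "up" & out$nu_X == nu_X_grid[i])[1]
      dn_i <- which(out$sweep == "down" & out$nu_X == nu_X_grid[i])[1]
      r_up <- out$rate_E[up_i] + out$rate_I[up_i]
      r_dn <- out$rate_E[dn_i] + out$rate_I[dn_i]
      # noise floor: ~3 SE of a Poisson-like count over the window
      se <- 3 * sqrt((r_up + r_dn + 1) / (net$NE * tm))
      thr <- max(band * max(r_up, r_dn), se, 0.5)
      out$hysteresis[dn_i] <- abs(r_up - r_dn) > thr
    }
  }
  out
}

#' ISI coefficient of variation from spike trains
#'
#' Per-neuron CV (SD/mean of inter-spike intervals) and the population mean
#' over neurons with at least `min_spikes` spikes.
#'
#' @param spikes A data frame or two-column matrix `(neuron_id, time_s)`.
#' @param min_spikes Minimum spikes per neuron (>= 3).
#' @return A list with `per_neuron` (data frame `neuron_id`, `n`, `cv`) and
#'   `mean_cv` (`NA` when no neuron qualifies).
#' @export
estimate_cv <- function(spikes, min_spikes = 10) {
  stopifnot(min_spikes >= 3)
  spikes <- as.data.frame(spikes)
  names(spikes)[1:2] <- c("neuron_id", "time_s")
  sp <- split(spikes$time_s, spikes$neuron_id)
  per <- lapply(sp, function(tt) {
    tt <- sort(tt)
    n <- length(tt)
    if (n < min_spikes) return(c(n = n, cv = NA_real_))
    isi <- diff(tt)
    c(n = n, cv = stats::sd(isi) / mean(isi))
  })
  tab <- data.frame(neuron_id = as.integer(names(per)),
                    n = vapply(per, `[[`, 0, "n"),
                    cv = vapply(per, `[[`, 0, "cv"))
  ok <- !is.na(tab$cv)
  list(per_neuron = tab,
       mean_cv = if (any(ok)) mean(tab$cv[ok]) else NA_real_)
}
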