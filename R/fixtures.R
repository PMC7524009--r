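#' Reference parameter fixtures
#'
#' Named parameter sets used across the package's documented examples and
#' test suite: a default neuron, one-population sets at several coupling
#' strengths, the two-population sets exhibiting each onset/saturation
#' scenario, supersaturation and noise-driven bistability examples, a grid
#' template for solution-count maps, and the rate-model comparison rows
#' (with their frozen noise values and SSN constants). All values are
#' plain numbers; network objects are constructed on demand via
#' [fixture_params()].
#'
#' @return A named list of fixture definitions (lists of plain parameters).
#' @export
reference_fixtures <- function() {
  list(
    neuron_default = list(theta = 20, v_reset = 10, tau_m = 20, tau_rp = 2,
                          gamma = 0.25),
    # one-population transfer function vs coupling (K varies)
    modelA_weak   = list(model = "A", J = 0.2, g = 5, g_X = 1, K = 1e3),
    modelA_mid    = list(model = "A", J = 0.2, g = 5, g_X = 1, K = 1e4),
    modelA_strong = list(model = "A", J = 0.2, g = 5, g_X = 1, K = 1e5),
    # one-population onset multistability
    modelA_onset  = list(model = "A", J = 0.5, g = 5, g_X = 1, K = 1e3),
    # two-population saturation families (sub/supralinear s1, sublinear s2)
    modelB_regular = list(model = "B", g_I = 3.9, g_E = 8, alpha_I = 1,
                          alpha_E = 7, J = 0.2, K = 1e3),
    modelB_supersat = list(model = "B", g_I = 3.9, g_E = 8, alpha_I = 10,
                           alpha_E = 7, J = 0.2, K = 1e3),
    # coexistence fixtures: three admissible families at low drive
    modelB_s1s2s3 = list(model = "B", g_I = 4, g_E = 3, alpha_I = 5,
                         alpha_E = 2, J = 0.2, K = 1e3),
    modelB_s1s3s4 = list(model = "B", g_I = 1, g_E = 2, alpha_I = 0.3,
                         alpha_E = 2, J = 0.2, K = 1e3),
    modelB_s1s2s5 = list(model = "B", g_I = 8, g_E = 6, alpha_I = 5,
                         alpha_E = 2, J = 0.2, K = 1e3),
    modelB_s2s3s4 = list(model = "B", g_I = 1, g_E = 2, alpha_I = 3,
                         alpha_E = 2, J = 0.2, K = 1e3),
    # solution-count map template (alpha and efficacies equal across pops);
    # the weak/strong coupling levels are a package choice
    modelB_countmap_weak = list(model = "B", g_I = 3, g_E = 3, alpha_I = 1,
                                alpha_E = 1, J = 0.5, K = 100),
    modelB_countmap_strong = list(model = "B", g_I = 3, g_E = 3, alpha_I = 1,
                                  alpha_E = 1, J = 0.5, K = 1000),
    # simulation / rate-model comparison rows (desk scale K = 400)
    sim_sublinear = list(model = "B", g_E = 8, g_I = 7, alpha_E = 4,
                         alpha_I = 2, J = 0.2, K = 400, sigma_rate = 25),
    sim_saturation_bistable = list(model = "B", g_E = 2.08, g_I = 1.67,
                                   alpha_E = 1, alpha_I = 1, J_EE = 0.2,
                                   J_IE = 0.2 * 2.4 / 2.5, K = 400,
                                   sigma_rate = 10),
    sim_regular = list(model = "B", g_E = 4.5, g_I = 2.9, alpha_E = 1,
                       alpha_I = 1, J = 0.2, K = 400, sigma_rate = 3),
    sim_mean_bistable = list(model = "B", g_E = 4.1, g_I = 2.46,
                             alpha_E = 1, alpha_I = 0.2, J = 0.2,
                             K_EE = 800, K_IE = 400, sigma_rate = 5),
    sim_noise_bistable = list(model = "B", g_E = 7, g_I = 6, alpha_E = 1,
                              alpha_I = 0.7, J = 0.5, K = 400,
                              sigma_rate = 7),
    ssn_default = list(k = 0.04, n = 2, W_EE = 1, W_IE = 1)
  )
}

#' Instantiate a parameter object from a fixture
#'
#' @param name A name from [reference_fixtures()].
#' @return A [model_a_params()] or [model_b_params()].
#' @examples
#' fixture_params("modelA_weak")$epsilon  # 0.05
#' @export
fixture_params <- function(name) {
  fx <- reference_fixtures()
  if (!name %in% names(fx)) stop("unknown fixture: ", name)
  f <- fx[[name]]
  if (is.null(f$model)) stop("fixture '", name, "' is not a parameter set")
  if (f$model == "A") {
    model_a_params(J = f$J, g = f$g, g_X = f$g_X, K = f$K)
  } else {
    J_EE <- if (!is.null(f$J_EE)) f$J_EE else f$J
    J_IE <- if (!is.null(f$J_IE)) f$J_IE else f$J
    K_EE <- if (!is.null(f$K_EE)) f$K_EE else f$K
    K_IE <- if (!is.null(f$K_IE)) f$K_IE else f$K
    model_b_params(J_EE = J_EE, J_IE = J_IE, g_E = f$g_E, g_I = f$g_I,
                   alpha_E = f$alpha_E, alpha_I = f$alpha_I,
                   K_EE = K_EE, K_IE = K_IE)
  }
}

#' Two-population parameters at a given relative coupling
#'
#' Helper implementing the relative-coupling convention for the
#' supersaturation examples: `K_EE = sqrt(beta) * K0`,
#' `K_IE = K0 / sqrt(beta)` (keeping the derived `beta` parameter equal to
#' the requested value), or the literal convention `K_EE = beta * K0`,
#' `K_IE = K0 / beta` (for which the derived `beta` is the square of the
#' label).
#'
#' @param base A [model_b_params()].
#' @param beta Requested coupling ratio.
#' @param K0 Base in-degree.
#' @param convention `"sqrt"` (default) or `"literal"`.
#' @return A [model_b_params()].
#' @export
with_beta <- function(base, beta, K0 = 1000,
                      convention = c("sqrt", "literal")) {
  stopifnot(inherits(base, "model_b_params"), beta > 0)
  convention <- match.arg(convention)
  s <- if (convention == "sqrt") sqrt(beta) else beta
  model_b_params(J_EE = base$J_EE, J_IE = base$J_IE, g_E = base$g_E,
                 g_I = base$g_I, g_EX = base$g_EX, g_IX = base$g_IX,
                 alpha_E = base$alpha_E, alpha_I = base$alpha_I,
                 gamma = base$gamma, K_EE = round(s * K0),
                 K_IE = round(K0 / s),
                 neuron_E = base$neuron_E, neuron_I = base$neuron_I)
}

#' Write the fixture tables to disk
#'
#' Serializes [reference_fixtures()] as one CSV of long-format key/value rows
#' plus a JSON copy, for use by external tooling and the command-line
#' interface.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir) {
  fx <- reference_fixtures()
  rows <- do.call(rbind, lapply(names(fx), function(nm) {
    f <- fx[[nm]]
    data.frame(fixture = nm, key = names(f),
               value = vapply(f, function(v) as.character(v[1]), ""),
               stringsAsFactors = FALSE)
  }))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "fixtures.csv")
  js <- file.path(dir, "fixtures.json")
  utils::write.csv(rows, csv, row.names = FALSE)
  jsonlite::write_json(fx, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
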