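# Ground-truth experiment generator: simulated multi-contrast reflectivity
# curves from known layer models, emulating a time-of-flight reflectometer
# (Q ~ 0.01-0.3 A^-1, dQ/Q = 3.5%, counting-statistics-like noise).

#' Define a synthetic experiment scenario
#'
#' @param name label.
#' @param truth ground-truth parameter object ([pqic_model_params()] or
#'   [pqiabc_model_params()]).
#' @param contrasts D2O volume fractions of the measured solvents.
#' @param q_range two-element Q range, A^-1, within (0, 1].
#' @param n_points points per curve (log-spaced), >= 10.
#' @param dq_over_q fractional resolution (FWHM).
#' @param noise_floor relative 1-sigma noise floor on the reflectivity.
#' @param background instrument background level added to the uncertainty,
#'   so the relative error grows as the reflectivity approaches it.
#' @param lipid_variant proximal bilayer isotopic form.
#' @param seed RNG seed recorded with the scenario.
#' @return object of class `experiment_scenario`.
#' @export
experiment_scenario <- function(name, truth,
                                contrasts = c(1.0, 0.8, 0.42, 0.0),
                                q_range = c(0.01, 0.3),
                                n_points = 100,
                                dq_over_q = 0.035,
                                noise_floor = 0.01,
                                background = 1e-7,
                                lipid_variant = "deuterated",
                                seed = 42) {
  stopifnot(inherits(truth, "pqic_model_params"))
  if (any(q_range <= 0) || any(q_range > 1) || q_range[1] >= q_range[2]) {
    stop("q_range must be increasing and within (0, 1]")
  }
  if (n_points < 10) stop("n_points must be >= 10")
  structure(
    list(name = name, truth = truth, contrasts = contrasts,
         q_range = q_range, n_points = n_points, dq_over_q = dq_over_q,
         noise_floor = noise_floor, background = background,
         lipid_variant = lipid_variant, seed = as.integer(seed)),
    class = "experiment_scenario"
  )
}

#' Simulate a multi-contrast reflectometry experiment
#'
#' For each contrast: builds the ground-truth stack, computes the smeared
#' model reflectivity on a log-spaced Q grid, assigns uncertainties
#' `dr = noise_floor * r + background` (relative noise with a floor that
#' inflates as the signal falls towards the instrument background) and adds
#' Gaussian noise of exactly that width. The `dr` column holds the true
#' sigma, so `(data - model) / dr` is standard normal by construction.
#'
#' @param scenario an [experiment_scenario()].
#' @param noiseless skip the stochastic perturbation (curves equal the
#'   smeared model exactly)?
#' @return list with one element per contrast, each a list of `curve`
#'   (a [reflectivity_curve()]), `solvent` and `lipid_variant`; the
#'   scenario is attached as an attribute.
#' @export
simulate_experiment <- function(scenario, noiseless = FALSE) {
  stopifnot(inherits(scenario, "experiment_scenario"))
  set.seed(scenario$seed)
  q <- exp(seq(log(scenario$q_range[1]), log(scenario$q_range[2]),
               length.out = scenario$n_points))
  out <- lapply(scenario$contrasts, function(f) {
    solv <- solvent(f)
    stack <- if (inherits(scenario$truth, "pqiabc_model_params")) {
      build_pqiabc_stack(scenario$truth, solv)
    } else {
      build_pqic_stack(scenario$truth, solv, scenario$lipid_variant)
    }
    r_true <- smeared_reflectivity(stack, q, scenario$dq_over_q)
    dr <- scenario$noise_floor * r_true + scenario$background
    r_obs <- if (noiseless) r_true else r_true + stats::rnorm(length(q)) * dr
    list(curve = reflectivity_curve(q, r_obs, dr = dr,
                                    dq_over_q = scenario$dq_over_q),
         solvent = solv, lipid_variant = scenario$lipid_variant)
  })
  attr(out, "scenario") <- scenario
  out
}

#' Built-in scenario catalogue
#'
#' The four stages of the supported-membrane assembly, each measured at the
#' four solvent contrasts (100%, 80%, 42% and 0% D2O): the bare oxide-coated
#' silicon substrate, a deuterated-DMPC bilayer, the bilayer with the ring
#' lipoprotein layer (truth: 50 A protein layer), and the full
#' trans-envelope assembly (truth: 230 A spanning layer, 280 A
#' intermembrane distance).
#'
#' @param noise_floor relative noise floor shared by all scenarios.
#' @param n_points points per curve.
#' @return named list of [experiment_scenario()] objects.
#' @export
builtin_scenarios <- function(noise_floor = 0.01, n_points = 100) {
  bare <- pqic_model_params(
    sio2_thickness = 12, sio2_hydration = 0.08,
    bilayer_coverage = 0, pqic_volume_fraction = 0,
    pqic_thickness = 0
  )
  bilayer <- pqic_model_params(
    sio2_thickness = 12, sio2_hydration = 0.08,
    apm = 60, head_hydration = 0.35, tail_hydration = 0.05,
    bilayer_coverage = 0.95,
    pqic_volume_fraction = 0, pqic_thickness = 0
  )
  bilayer_pqic <- pqic_model_params(
    sio2_thickness = 12, sio2_hydration = 0.08,
    apm = 60, head_hydration = 0.35, tail_hydration = 0.05,
    bilayer_coverage = 0.95,
    pqic_thickness = 50, pqic_volume_fraction = 0.25
  )
  pqiabc <- pqiabc_model_params(
    sio2_thickness = 12, sio2_hydration = 0.08,
    apm = 60, head_hydration = 0.35, tail_hydration = 0.05,
    bilayer_coverage = 0.95,
    pqic_thickness = 50, pqic_volume_fraction = 0.25,
    pqib_thickness = 230, pqib_volume_fraction = 0.20,
    distal_thickness = 45, distal_protein_fraction = 0.15,
    distal_lipid_fraction = 0.35, hdmpc_mixing_fraction = 0.10
  )
  list(
    bare_substrate = experiment_scenario("bare_substrate", bare,
                                         noise_floor = noise_floor,
                                         n_points = n_points, seed = 42),
    bilayer = experiment_scenario("bilayer", bilayer,
                                  noise_floor = noise_floor,
                                  n_points = n_points, seed = 43),
    bilayer_pqic = experiment_scenario("bilayer_pqic", bilayer_pqic,
                                       noise_floor = noise_floor,
                                       n_points = n_points, seed = 44),
    pqiabc = experiment_scenario("pqiabc", pqiabc,
                                 noise_floor = noise_floor,
                                 n_points = n_points, seed = 45)
  )
}

#' Write a simulated experiment to disk
#'
#' One ASCII reflectivity file per contrast plus a sidecar truth file
#' (JSON) recording the scenario's ground-truth parameters and seed.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; defaults to the scenario name.
#' @return invisibly, the written file paths.
#' @export
write_experiment <- function(sim, dir, prefix = NULL) {
  scenario <- attr(sim, "scenario")
  if (is.null(prefix)) prefix <- scenario$name
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sim, function(d) {
    path <- file.path(dir, sprintf("%s_d2o_%03.0f.dat", prefix,
                                   100 * d$solvent$f_d2o))
    write_reflectivity(d$curve, path)
    path
  }, character(1))
  truth <- scenario$truth
  truth$registry <- NULL
  truth$protein <- list(n_residues = sum(truth$protein$residue_counts))
  sidecar <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(
    list(name = scenario$name, seed = scenario$seed,
         contrasts = scenario$contrasts, truth = unclass(truth)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, sidecar))
}
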