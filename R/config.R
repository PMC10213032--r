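#' Growth-law parameter sets
#'
#' Constructors for the parameter blocks of the growth simulator. Defaults
#' are the values measured on *Podospora anserina* thalli growing on
#' standard (M2) medium: apical branch spacing follows a latency length
#' (apical dominance) of 180 µm followed by a base-2 exponential tail with
#' rate 10.4e-3 µm^-1, the branch point sitting 41 ± 11 µm behind the tip;
#' lateral branches respect a 480 µm dominance length and mix a burst
#' population (spatial decay 2.3e-3 µm^-1, inter-event rate 41e-3 min^-1)
#' with an isolated population (22% of events, local rate 6e-3 µm^-1 per
#' 90-min activity window); newly created branches sit on the side opposite
#' the local hyphal curvature with probability 0.82 (subapical) and 0.72
#' (lateral).
#'
#' Branching-angle magnitudes and the overall per-hypha lateral nucleation
#' intensity are calibration knobs, not measured values: they are chosen
#' once so that the reference simulation reproduces the apex-count doubling
#' frequency of the calibrated simulation (omega near 0.59 h^-1) and are
#' exposed here for sensitivity studies.
#'
#' @param L0 apical dominance length (µm).
#' @param alpha_rate base-2 exponential rate of the spacing tail (µm^-1).
#' @param L_api_mean,L_api_sd subapical offset distribution (µm); the
#'   normal is truncated at zero.
#' @param operating_angle_deg,exploratory_angle_deg branching angle of the
#'   operating (widest) and exploratory (smallest) daughter relative to the
#'   mother projection (degrees; calibration knobs).
#' @param angle_jitter_sd_deg Gaussian jitter applied to branching angles.
#' @param p_opposite_curvature probability that the new branch emerges on
#'   the side opposite the local curvature.
#' @return A parameter list with class `apical_params`.
#' @export
apical_params <- function(L0 = 180, alpha_rate = 10.4e-3,
                          L_api_mean = 41, L_api_sd = 11,
                          operating_angle_deg = 70,
                          exploratory_angle_deg = 20,
                          angle_jitter_sd_deg = 10,
                          p_opposite_curvature = 0.82) {
  stopifnot(L0 > 0, alpha_rate > 0, L_api_mean > 0, L_api_sd >= 0,
            p_opposite_curvature >= 0, p_opposite_curvature <= 1)
  structure(as.list(environment()), class = "apical_params")
}

#' @rdname apical_params
#' @param L_dominance lateral dominance length: minimum along-hypha distance
#'   between a lateral branch point and its apex (µm).
#' @param temporal_rate base-2 exponential rate of inter-event times within
#'   a burst train (min^-1).
#' @param gamma1 base-2 spatial decay of burst spacings (µm^-1).
#' @param uniform_fraction target fraction of isolated (uniformly placed)
#'   lateral events; burst trains continue with probability
#'   `1 - uniform_fraction` after each event.
#' @param p_isolated isolated-branch probability per µm of newly eligible
#'   hypha within one activity window (µm^-1 per window).
#' @param aging_window duration of the activity window (min).
#' @param lateral_angle_deg emergence angle of lateral branches
#'   (degrees; calibration knob).
#' @param activity dimensionless scale on the per-hypha nucleation
#'   intensity (calibration knob; see Details).
#' @details The burst/uniform spacing and timing laws are taken at their
#'   measured values; the overall nucleation intensity per hypha is
#'   `activity * p_isolated / aging_window` per µm of the newly eligible
#'   flank, with `activity` calibrated so laterals remain the minority
#'   contribution to apex production seen in the data.
#' @export
lateral_params <- function(L_dominance = 480, temporal_rate = 41e-3,
                           gamma1 = 2.3e-3, uniform_fraction = 0.22,
                           p_isolated = 6e-3, aging_window = 90,
                           lateral_angle_deg = 90,
                           angle_jitter_sd_deg = 10,
                           p_opposite_curvature = 0.72,
                           activity = 0.1) {
  stopifnot(L_dominance > 0, temporal_rate > 0, gamma1 > 0,
            uniform_fraction >= 0, uniform_fraction <= 1,
            p_isolated > 0, aging_window > 0, activity >= 0)
  structure(as.list(environment()), class = "lateral_params")
}

#' @rdname apical_params
#' @param theta0 angular half-range of one curvature step (radians).
#' @param a,b positive shape exponents of the turning-angle law
#'   \eqn{\propto (\theta_0 - \theta)^a (\theta + \theta_0)^b}; chirality
#'   is broken when `a != b`.
#' @param step_length arc length of one growth step between successive
#'   turning-angle draws (µm); curvature statistics are therefore
#'   independent of the integration time step.
#' @param axis_reversion per-step restoring weight pulling the heading
#'   back toward the hypha's growth axis. Zero gives a pure heading
#'   random walk; the small positive default makes hyphae locally wiggly
#'   but globally directed, as observed in radially growing thalli.
#' @export
curvature_params <- function(theta0 = 0.9, a = 2, b = 2, step_length = 20,
                             axis_reversion = 0.2) {
  stopifnot(theta0 > 0, a > 0, b > 0, step_length > 0,
            axis_reversion >= 0, axis_reversion <= 1)
  structure(as.list(environment()), class = "curvature_params")
}

#' @rdname apical_params
#' @param n_initial_hyphae number of germination hyphae leaving the spore.
#' @param v_asym asymptotic velocity of the leading apical hyphae
#'   (µm min^-1); sets the germination ramp of [elongation_velocity()].
#' @param ramp_length cumulative length each germination hypha must reach
#'   (µm) after `ramp_hours` of growth; fixes the ramp timescale.
#' @param ramp_hours see `ramp_length`.
#' @param v_tip mean effective tip advance speed (µm min^-1) used by the
#'   reference simulation; derived calibration
#'   \eqn{v_{tip} = \omega \ln 2 \langle \Delta L \rangle} tying the
#'   apex-count doubling frequency to the measured branch spacing.
#' @param use_ramp if `TRUE` the simulation uses the colony-time
#'   germination ramp (tips accelerating from rest to `v_asym`),
#'   emulating the early experimental phase; if `FALSE` (default) tips
#'   advance at the constant calibrated speed `v_tip`, matching the
#'   linear eigenvalue-length growth of the calibrated simulation.
#' @export
germination_params <- function(n_initial_hyphae = 2, v_asym = 4.5,
                               ramp_length = 500, ramp_hours = 7,
                               v_tip = 2.2, use_ramp = FALSE) {
  stopifnot(n_initial_hyphae >= 1, v_asym > 0, ramp_length > 0,
            ramp_hours > 0, v_tip > 0)
  structure(as.list(environment()), class = "germination_params")
}

#' Full simulator configuration
#'
#' Bundles all law parameters with the numerical settings of a run. Time is
#' measured in hours and space in micrometres throughout; minute-based
#' rates in the parameter blocks are converted internally.
#'
#' @param apical an [apical_params()] block.
#' @param lateral a [lateral_params()] block.
#' @param curvature named list of [curvature_params()] blocks for the
#'   `exploratory`, `operating` and `lateral` branch types (germination
#'   hyphae use the exploratory block).
#' @param germination a [germination_params()] block.
#' @param dt integration time step (h).
#' @param t_end duration of the run (h).
#' @param seed RNG seed of the run.
#' @param snapshot_cadence interval between recorded snapshots (h);
#'   default 0.3 h = 18 min, the cadence of the imaging series.
#' @param lateral_enabled switch for lateral branching.
#' @return A list of class `growth_config`.
#' @examples
#' cfg <- growth_config(t_end = 6, seed = 1)
#' @export
growth_config <- function(apical = apical_params(),
                          lateral = lateral_params(),
                          curvature = list(
                            exploratory = curvature_params(),
                            operating = curvature_params(),
                            lateral = curvature_params()
                          ),
                          germination = germination_params(),
                          dt = 0.1, t_end = 15, seed = 1L,
                          snapshot_cadence = 0.3,
                          lateral_enabled = TRUE) {
  stopifnot(dt > 0, t_end > dt, snapshot_cadence > 0)
  stopifnot(all(c("exploratory", "operating", "lateral") %in% names(curvature)))
  structure(
    list(apical = apical, lateral = lateral, curvature = curvature,
         germination = germination, dt = dt, t_end = t_end,
         seed = as.integer(seed), snapshot_cadence = snapshot_cadence,
         lateral_enabled = lateral_enabled),
    class = "growth_config"
  )
}

#' Reference and variant configurations
#'
#' `reference_config()` is the M2-calibrated default. The two variants
#' probe the roles of the branching types in the density phases:
#' `variant_dense_config()` boosts lateral branching and widens the
#' operating angle to 120 degrees, concentrating new material near the
#' colony centre (earlier density minimum); `variant_sparse_config()`
#' disables lateral branching and narrows the exploratory angle to
#' 10 degrees, concentrating growth on the outer crown (later minimum).
#'
#' @param t_end run duration (h).
#' @param seed RNG seed.
#' @return A [growth_config()].
#' @export
reference_config <- function(t_end = 15, seed = 1L) {
  growth_config(t_end = t_end, seed = seed)
}

#' @rdname reference_config
#' @export
variant_dense_config <- function(t_end = 15, seed = 1L) {
  growth_config(
    apical = apical_params(operating_angle_deg = 120),
    lateral = lateral_params(activity = 1),
    t_end = t_end, seed = seed
  )
}

#' @rdname reference_config
#' @export
variant_sparse_config <- function(t_end = 15, seed = 1L) {
  growth_config(
    apical = apical_params(exploratory_angle_deg = 10),
    lateral_enabled = FALSE,
    t_end = t_end, seed = seed
  )
}
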