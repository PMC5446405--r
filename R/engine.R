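# R front end of the event-driven engine.

#' Run event-driven discrete molecular dynamics
#'
#' Advances the system to `t_end` (simulation time units, ~48.9 fs each)
#' with an event loop: exact ballistic motion between events, breakpoint
#' crossings resolved by energy-conserving transmission/reflection, hard
#' walls for bonds, optional Anderson thermostat (Poisson ghost collisions
#' per mobile bead redrawing Maxwell-Boltzmann velocities), and periodic
#' boundaries via the minimum-image convention. Fixed (immobile) beads
#' never move. Deterministic given `seed`.
#'
#' @param system a `dmd_system` from [build_system()].
#' @param t_end simulation length, time units.
#' @param snapshot_interval time between recorded frames.
#' @param seed integer seed.
#' @param thermostat logical; `FALSE` gives microcanonical dynamics.
#' @param thermostat_rate ghost-collision rate per time unit per mobile
#'   bead.
#' @param horizon event-scheduling refresh horizon, time units.
#' @param max_events safety cap on the number of physical events.
#' @return A `dmd_trajectory`: recorded `times`, `frames` (list of Nx3
#'   coordinate matrices), per-frame kinetic/potential energies, final
#'   state, and event counts.
#' @examples
#' pep <- build_peptide_chain("AAAA", seed = 1)
#' sys <- build_system(pep, box = 60, seed = 1)
#' tr <- run_dmd(sys, t_end = 20, snapshot_interval = 5, seed = 1)
#' length(tr$times)
#' @export
run_dmd <- function(system, t_end, snapshot_interval = t_end / 20,
                    seed = NULL, thermostat = TRUE, thermostat_rate = 0.1,
                    horizon = 5, max_events = 5e8) {
  stopifnot(inherits(system, "dmd_system"), t_end > 0)
  b <- system$topology$beads
  inter <- system$interactions
  T_ <- nrow(inter$types)
  pot_bp <- lapply(inter$potentials, `[[`, "breakpoints")
  pot_lv <- lapply(inter$potentials, `[[`, "levels")
  bonds <- as.matrix(system$topology$bonds)
  if (nrow(bonds) == 0) bonds <- matrix(numeric(0), 0, 4)
  run <- .with_seed(seed, cpp_run_dmd(
    system$x, system$v, b$mass, b$mobile, b$mol, inter$type_index,
    b$exposed, system$box, T_, pot_bp, pot_lv, inter$core, bonds,
    t_end, snapshot_interval, kT(system$temperature),
    thermostat, thermostat_rate, horizon, max_events))
  if (isTRUE(run$starved)) {
    warning("event queue starved (no mobile dynamics); ",
            "trajectory completed ballistically")
  }
  structure(list(
    times = run$times, frames = run$frames,
    e_kin = run$e_kin, e_pot = run$e_pot,
    x_final = run$x_final, v_final = run$v_final,
    t_final = run$t_final, n_events = run$n_events,
    counts = run$counts, seed = seed, replica = NA_integer_,
    box = system$box, temperature = system$temperature,
    topology = system$topology, interactions = inter),
    class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat("DMD trajectory:", length(x$times), "frames to t =",
      format(x$t_final, digits = 5), "time units\n")
  cat("  events:", format(x$n_events, big.mark = ","),
      sprintf("(core %g, well %g, bond %g, thermostat %g)\n",
              x$counts$core, x$counts$well, x$counts$bond,
              x$counts$thermostat))
  cat("  energy (final frame): kin",
      format(utils::tail(x$e_kin, 1), digits = 5), "+ pot",
      format(utils::tail(x$e_pot, 1), digits = 5), "kcal/mol\n")
  invisible(x)
}

#' Instantaneous kinetic temperature along a trajectory
#'
#' @param trajectory a `dmd_trajectory`.
#' @return Kelvin per frame (mobile degrees of freedom only).
#' @export
kinetic_temperature <- function(trajectory) {
  n_dof <- 3 * sum(trajectory$topology$beads$mobile)
  2 * trajectory$e_kin / (n_dof * .kB_kcal)
}

#' Earliest breakpoint-crossing time for an isolated pair
#'
#' Solves the ballistic quadratic for the first time the minimum-image
#' separation of two beads crosses any breakpoint of a step potential;
#' `Inf` when the relative motion never reaches one (before the minimum
#' image changes). Exposed mainly for validation against brute-force
#' trajectory scanning.
#'
#' @param x1,v1,x2,v2 position/velocity 3-vectors.
#' @param box periodic box edge, Angstrom.
#' @param breakpoints increasing radii of the step potential.
#' @return Time to the first crossing, in time units.
#' @export
pair_event_time <- function(x1, v1, x2, v2, box, breakpoints) {
  cpp_pair_event_time(as.numeric(x1), as.numeric(v1),
                      as.numeric(x2), as.numeric(v2),
                      box, as.numeric(breakpoints))
}
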