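# The six simulation setups (and desk-scaled variants), replica
# management, and the equal-concentration box algebra.

.PROTOCOLS <- list(
  "monomer-1:1"   = list(n_pep = 1, n_prot = 1, fixed = FALSE,
                         fibril = FALSE, box = 74.3),
  "fixed-6:6"     = list(n_pep = 6, n_prot = 6, fixed = TRUE,
                         fibril = FALSE, box = 137.0),
  "free-2:2"      = list(n_pep = 2, n_prot = 2, fixed = FALSE,
                         fibril = FALSE, box = 95.0),
  "free-2:4"      = list(n_pep = 4, n_prot = 2, fixed = FALSE,
                         fibril = FALSE, box = NA),  # equal peptide conc.
  "crowded-48:6"  = list(n_pep = 6, n_prot = 48, fixed = TRUE,
                         fibril = FALSE, box = 240.0),
  "fibril-binding" = list(n_pep = 0, n_prot = 1, fixed = FALSE,
                          fibril = TRUE, box = 150.0))

.PROTEIN_SPECS <- list(
  "aLac-like" = list(net_charge = -7, mass = 14178),
  "Lys-like"  = list(net_charge = +7, mass = 14300))

#' Box edge preserving a molecule concentration
#'
#' Rescales a reference cubic box so `n_new` molecules have the same
#' number density as `n_ref` molecules in the reference box:
#' `edge_ref * (n_new / n_ref)^(1/3)`.
#'
#' @param n_ref,n_new molecule counts.
#' @param edge_ref reference box edge, Angstrom.
#' @return Box edge in Angstrom.
#' @examples
#' equal_concentration_edge(6, 137.0, 2) # 95.0
#' @export
equal_concentration_edge <- function(n_ref, edge_ref, n_new) {
  if (any(c(n_ref, edge_ref, n_new) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  edge_ref * (n_new / n_ref)^(1 / 3)
}

#' Construct a simulation protocol
#'
#' The named setups cover one peptide with one free protein (74.3 A box),
#' six peptides with six position-fixed proteins (137.0 A), two peptides
#' with two free proteins (95.0 A, same peptide concentration as the 6:6
#' system), four peptides with two free proteins, six peptides crowded by
#' 48 fixed proteins (240.0 A), and one protein binding the 20-chain
#' fibril (150 A). All run at 300 K; the full design is 20 replicas of
#' 50 ns each with the final 12.5 ns as the analysis window.
#'
#' `scale` multiplies simulation length and replica count; molecule counts
#' are scaled through the peptide count (protein count keeps the
#' protocol's protein:peptide ratio) and the box is rescaled with
#' [equal_concentration_edge()] so every species keeps its concentration.
#' `sim_ns` and `n_replicas` override the scaled values.
#'
#' @param name one of `"monomer-1:1"`, `"fixed-6:6"`, `"free-2:2"`,
#'   `"free-2:4"`, `"crowded-48:6"`, `"fibril-binding"`.
#' @param scale scaling factor in (0, 1].
#' @param protein_kind `"aLac-like"` (net -7e), `"Lys-like"` (net +7e) or
#'   `"mixture"` (50:50, rounded down for the aLac-like component).
#' @param sim_ns,n_replicas optional overrides.
#' @return A `dmd_protocol` list.
#' @examples
#' make_protocol("fixed-6:6")$box # 137.0
#' make_protocol("crowded-48:6", scale = 0.25)$n_proteins # 16
#' @export
make_protocol <- function(name, scale = 1.0,
                          protein_kind = c("aLac-like", "Lys-like",
                                           "mixture"),
                          sim_ns = NULL, n_replicas = NULL) {
  if (!name %in% names(.PROTOCOLS)) {
    stop("unknown protocol '", name, "'", call. = FALSE)
  }
  protein_kind <- match.arg(protein_kind)
  stopifnot(scale > 0, scale <= 1)
  p <- .PROTOCOLS[[name]]
  box <- p$box
  if (name == "free-2:4") {
    # same peptide concentration as free-2:2 (box not fixed by convention)
    box <- equal_concentration_edge(2, 95.0, 4)
  }
  n_pep <- p$n_pep
  n_prot <- p$n_prot
  if (scale < 1 && n_pep > 0) {
    ratio <- n_prot / n_pep
    n_pep_s <- max(1L, as.integer(round(n_pep * scale)))
    n_prot_s <- max(1L, as.integer(round(n_pep_s * ratio)))
    box <- equal_concentration_edge(n_pep, box, n_pep_s)
    n_pep <- n_pep_s
    n_prot <- n_prot_s
  }
  sim <- if (is.null(sim_ns)) 50 * scale else sim_ns
  reps <- if (is.null(n_replicas)) max(1L, as.integer(round(20 * scale)))
          else as.integer(n_replicas)
  structure(list(
    name = name, n_peptides = n_pep, n_proteins = n_prot,
    protein_kind = protein_kind, proteins_fixed = p$fixed,
    fibril = p$fibril, box = box, temperature = 300,
    n_replicas = reps, sim_ns = sim, window_frac = 12.5 / 50,
    scale = scale), class = "dmd_protocol")
}

#' @export
print.dmd_protocol <- function(x, ...) {
  cat("Protocol", x$name, sprintf("(scale %g):", x$scale), "\n")
  cat(sprintf("  %d peptide(s), %d %s protein(s)%s%s\n", x$n_peptides,
              x$n_proteins, x$protein_kind,
              if (x$proteins_fixed) " [fixed]" else "",
              if (x$fibril) " + fibril" else ""))
  cat(sprintf("  box %.1f A, %g K, %d replicas x %g ns\n", x$box,
              x$temperature, x$n_replicas, x$sim_ns))
  invisible(x)
}

#' Simulation time units per nanosecond
#'
#' @return Time units (of ~48.9 fs) in one nanosecond.
#' @export
ns_to_tu <- function() 1e6 / dmd_time_unit()

# assemble the molecule list of a protocol
.protocol_topologies <- function(protocol, n_beads = 42) {
  tops <- list()
  if (protocol$fibril) tops <- c(tops, list(build_fibril()))
  kinds <- if (protocol$protein_kind == "mixture") {
    n_a <- floor(protocol$n_proteins / 2)
    c(rep("aLac-like", n_a), rep("Lys-like", protocol$n_proteins - n_a))
  } else {
    rep(protocol$protein_kind, protocol$n_proteins)
  }
  for (k in kinds) {
    sp <- .PROTEIN_SPECS[[k]]
    g <- build_globular_protein(sp$net_charge, n_beads = n_beads,
                                mass = sp$mass)
    if (protocol$proteins_fixed) g <- freeze_molecules(g, kinds = "protein")
    tops <- c(tops, list(g))
  }
  fx <- iapp_fixture()
  for (i in seq_len(protocol$n_peptides)) {
    tops <- c(tops, list(build_peptide_chain(fx$sequence, fx$disulfide)))
  }
  tops
}

#' Run the replicas of a protocol
#'
#' One trajectory per replica; replica r uses seed `base_seed + r`, with
#' placements and initial velocities re-randomized per replica. Engine
#' errors in one replica are caught and reported without aborting the
#' rest.
#'
#' @param protocol a `dmd_protocol`.
#' @param base_seed integer.
#' @param snapshot_interval time units between frames (default: 50 frames
#'   per run).
#' @param thermostat_rate Anderson ghost-collision rate per time unit per
#'   bead; the protocol default (0.005) is chosen to preserve
#'   near-ballistic molecular transport at this coarse-grained scale.
#' @param n_beads_protein beads per protein globule.
#' @param ... passed on to [run_dmd()].
#' @return A `dmd_trajectory_set`: trajectories, the protocol, the base
#'   seed and any failed replicas.
#' @export
run_replicas <- function(protocol, base_seed = 1,
                         snapshot_interval = NULL,
                         thermostat_rate = 0.002,
                         n_beads_protein = 42, ...) {
  stopifnot(inherits(protocol, "dmd_protocol"))
  t_end <- protocol$sim_ns * ns_to_tu()
  if (is.null(snapshot_interval)) snapshot_interval <- t_end / 50
  trajs <- list()
  failed <- list()
  for (r in seq_len(protocol$n_replicas)) {
    seed_r <- base_seed + r
    res <- tryCatch(.with_seed(seed_r, {
      tops <- .protocol_topologies(protocol, n_beads = n_beads_protein)
      sys <- build_system(tops, box = protocol$box,
                          temperature = protocol$temperature)
      tr <- run_dmd(sys, t_end = t_end,
                    snapshot_interval = snapshot_interval,
                    thermostat = TRUE, thermostat_rate = thermostat_rate,
                    ...)
      tr$seed <- seed_r
      tr$replica <- r
      tr
    }), error = function(e) e)
    if (inherits(res, "error")) {
      warning("replica ", r, " failed: ", conditionMessage(res))
      failed[[length(failed) + 1]] <- list(replica = r,
                                           message = conditionMessage(res))
    } else {
      trajs[[length(trajs) + 1]] <- res
    }
  }
  structure(list(trajectories = trajs, protocol = protocol,
                 base_seed = base_seed, failed = failed),
            class = "dmd_trajectory_set")
}

#' @export
print.dmd_trajectory_set <- function(x, ...) {
  cat("Trajectory set:", length(x$trajectories), "replicas of protocol",
      x$protocol$name, sprintf("(base seed %d)\n", x$base_seed))
  if (length(x$failed) > 0) cat("  failed replicas:", length(x$failed), "\n")
  invisible(x)
}

#' Analysis window of a trajectory set
#'
#' Returns the time interval corresponding to the protocol's analysis
#' window (final quarter of the run by default, matching the 12.5-of-50 ns
#' design).
#'
#' @param tset a `dmd_trajectory_set`.
#' @return Numeric pair (t_start, t_end) in time units.
#' @export
analysis_window <- function(tset) {
  tmax <- max(tset$trajectories[[1]]$times)
  c((1 - tset$protocol$window_frac) * tmax, tmax)
}
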