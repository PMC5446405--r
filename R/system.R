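# System assembly: merge topologies, neutralize with counterions, place
# molecules without overlap in a periodic box, draw Maxwell-Boltzmann
# velocities, and build the interaction table.

.ION_PARAMS <- list(
  "Cl-" = list(mass = 35.45, charge = -1L, residue = "Cl"),
  "Na+" = list(mass = 22.99, charge = 1L, residue = "Na"))

.ion_topology <- function(species, count) {
  p <- .ION_PARAMS[[species]]
  beads <- .bead_frame(count)
  beads$mass <- p$mass
  beads$radius <- .ION_RADIUS
  beads$charge <- p$charge
  beads$hydrophobicity <- 0
  beads$residue <- p$residue
  beads$resindex <- 1L
  beads$chain <- seq_len(count)
  beads$mol <- seq_len(count)
  beads$kind <- "ion"
  beads$mobile <- TRUE
  beads$exposed <- TRUE
  .new_topology(beads, .empty_bonds(), matrix(0, count, 3))
}

#' Assemble the pair-interaction table
#'
#' Bead "types" are the unique (radius, charge, hydrophobicity) triples of
#' the topology. Each type pair gets one combined step potential: a hard
#' core at the sum of radii, an optional hydrophobic square well of depth
#' `eps_hp * h_i * h_j` over `hp_range` beyond the core, and the
#' discretized Debye-Hueckel screened Coulomb interaction (see
#' [discretize_screened_coulomb()]). Pairs in which either bead is flagged
#' non-exposed interact through the hard core alone.
#'
#' @param topology a `dmd_topology`.
#' @param temperature Kelvin.
#' @param ionic_strength mol/L, used for the Debye length unless
#'   `lambda_d` is given.
#' @param lambda_d Debye length override, Angstrom.
#' @param dielectric relative permittivity.
#' @param eps_hp hydrophobic well depth scale, kcal/mol (depth for a fully
#'   hydrophobic pair).
#' @param hp_range width of the hydrophobic well beyond the hard core,
#'   Angstrom.
#' @param es_steps number of shells discretizing the screened Coulomb tail.
#' @param contact_cutoff surface-to-surface contact distance used by the
#'   analysis layer, Angstrom.
#' @return An object of class `dmd_interactions`.
#' @export
interaction_table <- function(topology, temperature = 300,
                              ionic_strength = 0.1, lambda_d = NULL,
                              dielectric = 80, eps_hp = 1.2,
                              hp_range = 2.5, es_steps = 6,
                              contact_cutoff = 5.0) {
  if (is.null(lambda_d)) {
    lambda_d <- debye_length(dielectric, ionic_strength, temperature)
  }
  b <- topology$beads
  key <- paste(signif(b$radius, 8), b$charge, signif(b$hydrophobicity, 8))
  types <- !duplicated(key)
  tdef <- data.frame(radius = b$radius[types], charge = b$charge[types],
                     hydrophobicity = b$hydrophobicity[types])
  tindex <- match(key, key[types])
  T_ <- nrow(tdef)
  pots <- vector("list", T_ * T_)
  core <- matrix(0, T_, T_)
  for (a in seq_len(T_)) {
    for (d in seq_len(T_)) {
      ca <- tdef$radius[a] + tdef$radius[d]
      core[a, d] <- ca
      comps <- list()
      depth <- eps_hp * tdef$hydrophobicity[a] * tdef$hydrophobicity[d]
      if (depth > 0.01) {
        comps <- c(comps, list(step_potential(c(ca, ca + hp_range), -depth)))
      }
      qq <- tdef$charge[a] * tdef$charge[d]
      if (qq != 0) {
        comps <- c(comps, list(discretize_screened_coulomb(
          tdef$charge[a], tdef$charge[d], lambda_d, ca, es_steps,
          dielectric, temperature)))
      }
      pots[[(a - 1) * T_ + d]] <- .combine_potentials(ca, comps)
    }
  }
  structure(list(types = tdef, type_index = tindex, potentials = pots,
                 core = core, lambda_d = lambda_d,
                 bjerrum = bjerrum_length(dielectric, temperature),
                 eps_hp = eps_hp, hp_range = hp_range,
                 es_steps = es_steps, dielectric = dielectric,
                 temperature = temperature,
                 contact_cutoff = contact_cutoff),
            class = "dmd_interactions")
}

#' @export
print.dmd_interactions <- function(x, ...) {
  cat("Interaction table:", nrow(x$types), "bead types\n")
  cat(sprintf("  Debye length %.2f A, Bjerrum length %.2f A, T = %g K\n",
              x$lambda_d, x$bjerrum, x$temperature))
  cat(sprintf("  hydrophobic well scale %.2f kcal/mol over %.1f A; %d ES shells\n",
              x$eps_hp, x$hp_range, x$es_steps))
  invisible(x)
}

# potential for a bead pair (by bead index)
.pair_potential <- function(interactions, ti, tj) {
  T_ <- nrow(interactions$types)
  interactions$potentials[[(ti - 1) * T_ + tj]]
}

.wrap_delta <- function(d, box) d - box * round(d / box)

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a simulation system
#'
#' Merges the given topologies, adds counterions so the total charge is
#' zero, places every molecule at a random position and orientation without
#' hard-core overlaps (molecules of kind `"fibril"` stay at the box
#' center), draws Maxwell-Boltzmann velocities at the requested temperature
#' for mobile beads, and assembles the interaction table. Deterministic
#' given `seed`.
#'
#' @param topologies a `dmd_topology` or list of them.
#' @param box cubic box edge, Angstrom.
#' @param temperature Kelvin.
#' @param seed integer seed for placement and velocities.
#' @param ... further arguments passed to [interaction_table()].
#' @return An object of class `dmd_system`.
#' @examples
#' pep <- build_peptide_chain(iapp_fixture()$sequence, c(2, 7), seed = 1)
#' sys <- build_system(pep, box = 74.3, seed = 1)
#' sum(sys$topology$beads$charge) # 0 after counterions
#' @export
build_system <- function(topologies, box, temperature = 300, seed = NULL,
                         ...) {
  if (inherits(topologies, "dmd_topology")) topologies <- list(topologies)
  .with_seed(seed, {
    top <- merge_topologies(topologies)
    qtot <- sum(top$beads$charge)
    ci <- counterions_for(qtot)
    if (ci$count > 0) {
      top <- merge_topologies(list(top, .ion_topology(ci$species, ci$count)))
    }
    inter <- interaction_table(top, temperature = temperature, ...)

    rng <- 2 * max(top$beads$radius) + 3 * inter$lambda_d
    if (rng > box / 2) {
      warning(sprintf(
        "interaction range %.1f A exceeds half the box (%.1f A); ",
        rng, box / 2), "outermost shells are imaged approximately")
    }

    b <- top$beads
    x <- top$x
    mols <- unique(b$mol)
    placed <- matrix(numeric(0), 0, 3)
    placed_r <- numeric(0)
    for (m in mols) {
      sel <- which(b$mol == m)
      xm <- x[sel, , drop = FALSE]
      ctr <- colMeans(xm)
      xm <- sweep(xm, 2, ctr)
      if (b$kind[sel[1]] == "fibril") {
        xm_new <- sweep(xm, 2, rep(box / 2, 3), "+")
      } else {
        ok <- FALSE
        for (try in seq_len(2000)) {
          R <- .random_rotation()
          pos <- runif(3, 0, box)
          cand <- sweep(xm %*% t(R), 2, pos, "+")
          if (nrow(placed) == 0) { ok <- TRUE; break }
          # min-image surface separation against all placed beads
          clash <- FALSE
          for (k in seq_len(nrow(cand))) {
            d <- sweep(placed, 2, cand[k, ])
            d <- d - box * round(d / box)
            dist <- sqrt(rowSums(d^2))
            if (any(dist < placed_r + b$radius[sel[k]] + 0.5)) {
              clash <- TRUE; break
            }
          }
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place molecule ", m,
                      " without overlap (placement error)", call. = FALSE)
        xm_new <- cand
      }
      x[sel, ] <- xm_new
      placed <- rbind(placed, xm_new)
      placed_r <- c(placed_r, b$radius[sel])
    }

    v <- matrix(0, nrow(b), 3)
    mob <- which(b$mobile)
    if (length(mob) > 0) {
      sig <- sqrt(kT(temperature) / b$mass[mob])
      v[mob, ] <- rnorm(3 * length(mob)) * rep(sig, 3)
    }
    top$x <- x
    structure(list(topology = top, x = x, v = v, box = box,
                   temperature = temperature, interactions = inter,
                   seed = seed),
              class = "dmd_system")
  })
}

#' @export
print.dmd_system <- function(x, ...) {
  b <- x$topology$beads
  cat("DMD system:", nrow(b), "beads in a", x$box, "A box at",
      x$temperature, "K\n")
  kinds <- table(b$kind[!duplicated(b$mol)])
  cat("  molecules:", paste(sprintf("%d %s", kinds, names(kinds)),
                            collapse = ", "), "\n")
  cat("  mobile beads:", sum(b$mobile), "of", nrow(b), "\n")
  invisible(x)
}

#' Total energy of a configuration
#'
#' Kinetic energy plus the sum of step-potential levels at the current
#' minimum-image pair separations (inter-molecular pairs only; pairs with a
#' non-exposed member interact through the hard core alone and contribute
#' zero). A hard-core overlap is a corrupt state and raises an error.
#'
#' @param system a `dmd_system`.
#' @param x,v optional coordinate/velocity matrices overriding the system's.
#' @return list with `kinetic`, `potential` and `total` (kcal/mol).
#' @export
total_energy <- function(system, x = system$x, v = system$v) {
  b <- system$topology$beads
  inter <- system$interactions
  ek <- 0.5 * sum(b$mass * rowSums(v^2))
  ti <- inter$type_index
  n <- nrow(b)
  ep <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    j <- j[b$mol[j] != b$mol[i]]
    if (length(j) == 0) next
    d <- sweep(x[j, , drop = FALSE], 2, x[i, ])
    d <- d - system$box * round(d / system$box)
    r <- sqrt(rowSums(d^2))
    core <- inter$core[ti[i], ti[j]]
    if (any(r < core - 1e-9)) {
      stop("hard-core overlap: corrupt state", call. = FALSE)
    }
    ex <- b$exposed[i] & b$exposed[j]
    for (k in which(ex)) {
      p <- .pair_potential(inter, ti[i], ti[j[k]])
      e <- step_energy(p, r[k])
      if (is.finite(e)) ep <- ep + e
    }
  }
  list(kinetic = ek, potential = ep, total = ek + ep)
}
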