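# Coarse-grained topologies: one bead per residue for peptides, procedural
# sphere-packed globules for proteins, and the two-protofibril cross-beta
# fibril model. A topology carries beads (parameters + flags), a square-well
# bond list, and build coordinates.

.BACKBONE <- 3.8      # Calpha-Calpha distance, A
.BACKBONE_TOL <- 0.02 # fractional half-width of the backbone square well
.PSEUDO_MIN <- 5.4    # i,i+2 pseudo-bond window, A
.PSEUDO_MAX <- 7.3
.SS_MIN <- 4.0        # disulfide bond window, A
.SS_MAX <- 7.0
.ION_RADIUS <- 2.0

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.new_topology <- function(beads, bonds, x) {
  stopifnot(nrow(beads) == nrow(x))
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$rmin < bonds$rmax), all(bonds$i != bonds$j))
  }
  structure(list(beads = beads, bonds = bonds, x = x),
            class = "dmd_topology")
}

.bead_frame <- function(n) {
  data.frame(mass = numeric(n), radius = numeric(n), charge = integer(n),
             hydrophobicity = numeric(n), residue = character(n),
             resindex = integer(n), chain = integer(n), mol = integer(n),
             kind = character(n), mobile = logical(n), exposed = logical(n),
             stringsAsFactors = FALSE)
}

.empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0),
             rmin = numeric(0), rmax = numeric(0))
}

#' @export
print.dmd_topology <- function(x, ...) {
  b <- x$beads
  cat("Coarse-grained topology:", nrow(b), "beads,",
      nrow(x$bonds), "bonds\n")
  cat("  molecules:", length(unique(b$mol)),
      sprintf("(%s)", paste(sprintf("%d %s", table(b$kind[!duplicated(b$mol)]),
                                    names(table(b$kind[!duplicated(b$mol)]))),
                            collapse = ", ")), "\n")
  cat("  net charge:", sum(b$charge), "e;",
      sum(b$mobile), "mobile /", sum(!b$mobile), "fixed beads\n")
  invisible(x)
}

# random chain conformation: backbone 3.8 A, bend angle confined to the
# window implied by the i,i+2 pseudo-bond limits, random azimuth
.chain_coords <- function(n) {
  x <- matrix(0, n, 3)
  if (n == 1L) return(x)
  x[2, ] <- c(.BACKBONE, 0, 0)
  if (n == 2L) return(x)
  cos_lo <- .PSEUDO_MIN^2 / (2 * .BACKBONE^2) - 1
  cos_hi <- min(1, .PSEUDO_MAX^2 / (2 * .BACKBONE^2) - 1)
  u <- c(1, 0, 0)
  for (k in 3:n) {
    ca <- runif(1, cos_lo, cos_hi) # cos of angle between bond directions
    sa <- sqrt(1 - ca^2)
    phi <- runif(1, 0, 2 * pi)
    # orthonormal frame around u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    u <- ca * u + sa * (cos(phi) * e1 + sin(phi) * e2)
    u <- u / sqrt(sum(u^2))
    x[k, ] <- x[k - 1, ] + .BACKBONE * u
  }
  x
}

#' Build a one-bead-per-residue peptide chain
#'
#' Consecutive beads are joined by a tight square-well backbone bond
#' (3.8 A +/- 2%); next-nearest neighbours carry a 5.4-7.3 A pseudo-bond
#' that bounds the local bend angle; an optional disulfide bond links two
#' cysteines. A random self-consistent conformation is generated. All beads
#' are mobile and exposed.
#'
#' @param sequence 1-letter amino-acid string.
#' @param disulfide `NULL`, or an integer pair of residue positions to
#'   bridge (e.g. `c(2, 7)` for amylin).
#' @param params residue parameter table, see [residue_params()].
#' @param seed optional integer for a reproducible conformation.
#' @return A `dmd_topology` with one molecule of kind `"peptide"`.
#' @examples
#' top <- build_peptide_chain(iapp_fixture()$sequence, disulfide = c(2, 7),
#'                            seed = 1)
#' nrow(top$beads) # 37
#' @export
build_peptide_chain <- function(sequence, disulfide = NULL,
                                params = residue_params(), seed = NULL) {
  res <- .check_sequence(sequence)
  n <- length(res)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  .with_seed(seed, {
    beads <- .bead_frame(n)
    beads$mass <- params[res, "mass"]
    beads$radius <- params[res, "radius"]
    beads$charge <- params[res, "charge"]
    beads$hydrophobicity <- params[res, "hydrophobicity"]
    beads$residue <- res
    beads$resindex <- seq_len(n)
    beads$chain <- 1L
    beads$mol <- 1L
    beads$kind <- "peptide"
    beads$mobile <- TRUE
    beads$exposed <- TRUE

    bonds <- .empty_bonds()
    if (n >= 2) {
      i <- seq_len(n - 1)
      bonds <- rbind(bonds, data.frame(
        i = i, j = i + 1L,
        rmin = .BACKBONE * (1 - .BACKBONE_TOL),
        rmax = .BACKBONE * (1 + .BACKBONE_TOL)))
    }
    if (n >= 3) {
      i <- seq_len(n - 2)
      bonds <- rbind(bonds, data.frame(
        i = i, j = i + 2L, rmin = .PSEUDO_MIN, rmax = .PSEUDO_MAX))
    }
    has_ss <- !is.null(disulfide)
    if (has_ss) {
      stopifnot(length(disulfide) == 2L, all(disulfide >= 1),
                all(disulfide <= n), disulfide[1] != disulfide[2])
      bonds <- rbind(bonds, data.frame(
        i = min(disulfide), j = max(disulfide),
        rmin = .SS_MIN, rmax = .SS_MAX))
    }
    # rejection-sample a conformation satisfying the disulfide window
    for (try in seq_len(5000)) {
      x <- .chain_coords(n)
      if (!has_ss) break
      d <- sqrt(sum((x[disulfide[1], ] - x[disulfide[2], ])^2))
      if (d > .SS_MIN + 0.1 && d < .SS_MAX - 0.1) break
      if (try == 5000) stop("could not realize disulfide geometry")
    }
    .new_topology(beads, bonds, x)
  })
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# greedy farthest-point subset of points on a sphere
.spread_points <- function(pts, m) {
  n <- nrow(pts)
  if (m == 0L) return(integer(0))
  sel <- 1L
  d2min <- rowSums((pts - matrix(pts[1, ], n, 3, byrow = TRUE))^2)
  while (length(sel) < m) {
    nxt <- which.max(d2min)
    sel <- c(sel, nxt)
    d2 <- rowSums((pts - matrix(pts[nxt, ], n, 3, byrow = TRUE))^2)
    d2min <- pmin(d2min, d2)
  }
  sel
}

#' Build a procedural charged globular protein
#'
#' Beads are placed on a quasi-uniform (Fibonacci) sphere packing and
#' mutually bonded with tight square wells so the globule moves as a rigid
#' unit. Unit surface charges of the sign of `net_charge` are distributed
#' maximally apart; a stated fraction of the remaining surface beads is
#' flagged hydrophobic. If `radius` is not given it is derived from the
#' molecular mass using a protein mass density of 1.35 g/cm3.
#'
#' @param net_charge integer net charge in e (|net_charge| <= n_beads).
#' @param n_beads number of surface beads.
#' @param mass total molecular mass, Da.
#' @param radius overall globule radius, Angstrom (overrides the mass rule).
#' @param hydrophobic_fraction fraction of beads flagged as hydrophobic
#'   surface patches.
#' @param seed integer; the builder is deterministic given the seed.
#' @return A `dmd_topology` with one molecule of kind `"protein"`.
#' @examples
#' alac <- build_globular_protein(-7, n_beads = 42, mass = 14178, seed = 1)
#' sum(alac$beads$charge) # -7
#' @export
build_globular_protein <- function(net_charge, n_beads = 42, mass = 14300,
                                   radius = NULL,
                                   hydrophobic_fraction = 0.3, seed = NULL) {
  stopifnot(n_beads >= 1)
  net_charge <- as.integer(net_charge)
  if (abs(net_charge) > n_beads) {
    stop("|net_charge| cannot exceed n_beads", call. = FALSE)
  }
  if (is.null(radius)) radius <- protein_radius_from_mass(mass)
  .with_seed(seed, {
    # bead centers on a sphere such that bead surfaces roughly tile it
    spacing <- sqrt(4 * pi * radius^2 / n_beads)
    r_bead <- max(2.0, 0.5 * spacing)
    r_centers <- max(radius - r_bead, 1.0)
    x <- .fibonacci_sphere(n_beads) * r_centers
    beads <- .bead_frame(n_beads)
    beads$mass <- mass / n_beads
    beads$radius <- r_bead
    beads$charge <- 0L
    beads$hydrophobicity <- 0.1
    beads$residue <- "X"
    beads$resindex <- seq_len(n_beads)
    beads$chain <- 1L
    beads$mol <- 1L
    beads$kind <- "protein"
    beads$mobile <- TRUE
    beads$exposed <- TRUE
    if (net_charge != 0L) {
      sel <- .spread_points(x, abs(net_charge))
      beads$charge[sel] <- as.integer(sign(net_charge))
      beads$hydrophobicity[sel] <- 0.05
    }
    # soluble-globule calibration: patches weak enough that two isolated
    # proteins do not stick against their like-charge repulsion
    n_hp <- floor(hydrophobic_fraction * n_beads)
    cand <- which(beads$charge == 0L)
    if (n_hp > 0 && length(cand) > 0) {
      hp <- sample(cand, min(n_hp, length(cand)))
      beads$hydrophobicity[hp] <- 0.6
    }
    # rigid unit: bond every pair with a +/- 5% square well
    pr <- utils::combn(n_beads, 2)
    d <- sqrt(rowSums((x[pr[1, ], , drop = FALSE] -
                         x[pr[2, ], , drop = FALSE])^2))
    bonds <- data.frame(i = pr[1, ], j = pr[2, ],
                        rmin = d * 0.95, rmax = d * 1.05)
    .new_topology(beads, bonds, x)
  })
}

#' Globule radius from molecular mass
#'
#' Radius of a sphere of the given mass at a typical protein density of
#' 1.35 g/cm3.
#'
#' @param mass Da.
#' @param density g/cm3.
#' @return Radius in Angstrom.
#' @examples
#' protein_radius_from_mass(14300) # ~ 16 A (lysozyme-sized)
#' @export
protein_radius_from_mass <- function(mass, density = 1.35) {
  vol_cm3 <- mass * 1.66053906660e-24 / density
  vol_A3 <- vol_cm3 * 1e24
  (3 * vol_A3 / (4 * pi))^(1 / 3)
}

.FIBRIL_INWARD <- c(10L, 12L, 14L, 16L)
.FIBRIL_BURIED <- c(11L, 13L, 15L, 28:36)
.FIBRIL_MOBILE <- c(1:4, 9L, 11L, 15L, 17L, 18L, 20L, 21L, 37L)

#' Build the two-protofibril amylin fibril model
#'
#' Each protofibril is a stack of `n_per_protofibril` parallel in-register
#' chains (one bead per residue along the strand, inter-strand spacing
#' 4.8 A along the fibril axis); the second protofibril is the exact
#' two-fold rotation image of the first about the fibril axis. Residues
#' whose side chains point into the beta-sheet core (10, 12, 14, 16) or are
#' buried at the protofibril interface (11, 13, 15 and 28-36) are flagged
#' non-exposed. Only the unstructured N-terminus (residues 1-4) and the
#' solvent-exposed side-chain positions 9, 11, 15, 17, 18, 20, 21 and 37
#' are mobile; all other beads are fixed. Bond windows are set around the
#' as-built cross-beta geometry.
#'
#' @param n_per_protofibril chains per protofibril (>= 2).
#' @param layers 1 (single protofibril) or 2 (full fibril).
#' @param sequence peptide sequence (defaults to amylin).
#' @param spacing inter-strand spacing along the fibril axis, Angstrom.
#' @param interface_gap separation between the two protofibril layers,
#'   Angstrom.
#' @param params residue parameter table.
#' @return A `dmd_topology`: a single molecule of kind `"fibril"` with
#'   `layers * n_per_protofibril` chains.
#' @examples
#' fib <- build_fibril()
#' nrow(fib$beads) # 740 = 20 chains x 37 residues
#' @export
build_fibril <- function(n_per_protofibril = 10, layers = 2,
                         sequence = iapp_fixture()$sequence,
                         spacing = 4.8, interface_gap = 10,
                         params = residue_params()) {
  stopifnot(n_per_protofibril >= 2)
  if (!(layers %in% c(1L, 2L))) stop("layers must be 1 or 2", call. = FALSE)
  res <- .check_sequence(sequence)
  n <- length(res)
  n_chains <- as.integer(layers * n_per_protofibril)
  beads_list <- vector("list", n_chains)
  bonds_list <- vector("list", n_chains)
  x_list <- vector("list", n_chains)
  xc <- (n - 1) * .BACKBONE / 2  # rotation axis position
  zm <- interface_gap / 2
  yc <- (n_per_protofibril - 1) * spacing / 2
  chain_id <- 0L
  for (layer in seq_len(layers)) {
    for (c_i in seq_len(n_per_protofibril)) {
      chain_id <- chain_id + 1L
      b <- .bead_frame(n)
      b$mass <- params[res, "mass"]
      b$radius <- params[res, "radius"]
      b$charge <- params[res, "charge"]
      b$hydrophobicity <- params[res, "hydrophobicity"]
      b$residue <- res
      b$resindex <- seq_len(n)
      b$chain <- chain_id
      b$mol <- 1L
      b$kind <- "fibril"
      b$mobile <- b$resindex %in% .FIBRIL_MOBILE
      b$exposed <- !(b$resindex %in% c(.FIBRIL_INWARD, .FIBRIL_BURIED))
      x <- cbind((seq_len(n) - 1) * .BACKBONE,
                 rep((c_i - 1) * spacing, n),
                 rep(0, n))
      if (layer == 2L) {
        # two-fold rotation about the axis x = xc, z = zm (parallel to y)
        x <- cbind(2 * xc - x[, 1], x[, 2], 2 * zm - x[, 3])
      }
      off <- (chain_id - 1L) * n
      d12 <- .BACKBONE
      i1 <- seq_len(n - 1)
      bonds <- data.frame(i = off + i1, j = off + i1 + 1L,
                          rmin = d12 * (1 - .BACKBONE_TOL),
                          rmax = d12 * (1 + .BACKBONE_TOL))
      if (n >= 3) {
        i2 <- seq_len(n - 2)
        d13 <- 2 * .BACKBONE  # straight as built
        bonds <- rbind(bonds, data.frame(i = off + i2, j = off + i2 + 2L,
                                         rmin = d13 * 0.95,
                                         rmax = d13 * 1.05))
      }
      beads_list[[chain_id]] <- b
      bonds_list[[chain_id]] <- bonds
      x_list[[chain_id]] <- x
    }
  }
  beads <- do.call(rbind, beads_list)
  bonds <- do.call(rbind, bonds_list)
  x <- do.call(rbind, x_list)
  # center on the origin
  x <- sweep(x, 2, c(xc, yc, zm))
  .new_topology(beads, bonds, x)
}

#' Combine several topologies into one
#'
#' Bead indices, chain ids and molecule ids are offset so each input keeps
#' its identity. Coordinates are kept as built (placement happens in
#' [build_system()]).
#'
#' @param ... `dmd_topology` objects, or a single list of them.
#' @return A merged `dmd_topology`.
#' @export
merge_topologies <- function(...) {
  tops <- list(...)
  if (length(tops) == 1L && !inherits(tops[[1]], "dmd_topology")) {
    tops <- tops[[1]]
  }
  stopifnot(length(tops) >= 1L,
            all(vapply(tops, inherits, TRUE, "dmd_topology")))
  bead_off <- 0L; mol_off <- 0L; chain_off <- 0L
  beads_list <- list(); bonds_list <- list(); x_list <- list()
  for (t in tops) {
    b <- t$beads
    bo <- t$bonds
    b$mol <- b$mol + mol_off
    b$chain <- b$chain + chain_off
    if (nrow(bo) > 0) {
      bo$i <- bo$i + bead_off
      bo$j <- bo$j + bead_off
    }
    beads_list <- c(beads_list, list(b))
    bonds_list <- c(bonds_list, list(bo))
    x_list <- c(x_list, list(t$x))
    bead_off <- bead_off + nrow(b)
    mol_off <- mol_off + max(t$beads$mol)
    chain_off <- chain_off + max(t$beads$chain)
  }
  .new_topology(do.call(rbind, beads_list), do.call(rbind, bonds_list),
                do.call(rbind, x_list))
}

#' Freeze molecules of a topology
#'
#' Marks all beads of the given kinds (or molecule ids) immobile, as used
#' by protocols with fixed proteins.
#'
#' @param topology a `dmd_topology`.
#' @param kinds character vector of molecule kinds to freeze.
#' @param mols integer molecule ids to freeze.
#' @return The modified topology.
#' @export
freeze_molecules <- function(topology, kinds = NULL, mols = NULL) {
  sel <- rep(FALSE, nrow(topology$beads))
  if (!is.null(kinds)) sel <- sel | topology$beads$kind %in% kinds
  if (!is.null(mols)) sel <- sel | topology$beads$mol %in% mols
  topology$beads$mobile[sel] <- FALSE
  topology
}
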