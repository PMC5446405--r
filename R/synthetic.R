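# Seeded generators for every input the analysis stack needs: worm-like-
# chain contours with known persistence length, planted-cluster frames
# with known connected-component structure, and planted residue-contact
# patterns. Each generator emits its ground truth machine-readably.

#' Generate 2D worm-like-chain contours with known persistence length
#'
#' Chains of fixed step `ds` whose bend angle per step is independent
#' Gaussian with variance `ds / lambda`, which gives the exact 2D
#' tangent-correlation decay
#' \eqn{\langle\cos\theta(s)\rangle = e^{-s/(2\lambda)}}. An optional
#' Gaussian width profile (truncated at zero) is attached per point.
#' Deterministic given the seed.
#'
#' @param lambda persistence length (nm).
#' @param length contour length (nm).
#' @param ds arc-length step (nm); must satisfy `ds <= lambda / 10`.
#' @param n number of contours.
#' @param seed integer seed.
#' @param width_mean,width_sd optional width profile parameters (nm).
#' @return list of contours; each has `points` (matrix, nm), `ds`,
#'   optionally `width`, and the generating `lambda`.
#' @examples
#' cts <- generate_wlc_contours(100, 400, 5, n = 10, seed = 1)
#' length(cts) # 10
#' @export
generate_wlc_contours <- function(lambda, length, ds, n, seed = NULL,
                                  width_mean = NULL, width_sd = 0) {
  stopifnot(lambda > 0, length > 0, ds > 0, n >= 1)
  if (ds > lambda / 10) {
    stop("ds too coarse relative to lambda (need ds <= lambda/10)",
         call. = FALSE)
  }
  n_step <- max(2L, round(length / ds))
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      dth <- rnorm(n_step, 0, sqrt(ds / lambda))
      th <- runif(1, 0, 2 * pi) + cumsum(c(0, dth[-n_step]))
      pts <- rbind(c(0, 0),
                   cbind(cumsum(ds * cos(th)), cumsum(ds * sin(th))))
      out <- list(points = pts, ds = ds, lambda = lambda)
      if (!is.null(width_mean)) {
        out$width <- pmax(0, rnorm(nrow(pts), width_mean, width_sd))
      }
      out
    })
  })
}

#' Plant a frame with known cluster structure
#'
#' Places single-bead molecules so the realized contact graph at the given
#' cutoff is exactly a path within each requested block (hence the
#' connected components equal the requested partition) and no contact
#' exists between blocks. Blocks sit on a jittered grid. The ground truth
#' partition and edge list are returned alongside.
#'
#' @param partition list of integer vectors: the molecule ids of each
#'   cluster (every molecule in exactly one block).
#' @param kinds optional character vector of molecule kinds (per molecule
#'   id), e.g. `"peptide"` / `"protein"`; defaults to `"peptide"`.
#' @param box box edge (Angstrom); enlarged automatically if the blocks do
#'   not fit.
#' @param cutoff contact cutoff (Angstrom).
#' @param radius bead radius (Angstrom).
#' @param seed integer seed for the grid jitter.
#' @return A `dmd_planted_frame`: `frame`, `topology`, `box` and `truth`
#'   (membership and edges).
#' @examples
#' pf <- make_planted_frame(list(c(1, 2, 3), 4))
#' cs <- cluster_components(contact_graph(pf$frame, pf$topology, pf$box))
#' max(cs$membership) # 2 clusters
#' @export
make_planted_frame <- function(partition, kinds = NULL, box = NULL,
                               cutoff = 5.0, radius = 3.0, seed = NULL) {
  partition <- lapply(partition, as.integer)
  ids <- sort(unlist(partition))
  if (any(duplicated(ids)) || !identical(ids, seq_along(ids))) {
    stop("partition must cover molecule ids 1..M exactly once",
         call. = FALSE)
  }
  M <- length(ids)
  if (is.null(kinds)) kinds <- rep("peptide", M)
  stopifnot(length(kinds) == M)
  # consecutive members in contact, second neighbours safely apart
  d_touch <- 2 * radius + cutoff * 0.5
  if (2 * d_touch <= 2 * radius + cutoff) {
    stop("unrealizable geometry for this cutoff/radius", call. = FALSE)
  }
  longest <- max(vapply(partition, length, integer(1)))
  spacing <- longest * d_touch + 2 * (2 * radius + cutoff) + 10
  n_side <- ceiling(length(partition)^(1 / 3))
  need <- n_side * spacing
  if (is.null(box) || box < need) box <- need
  .with_seed(seed, {
    x <- matrix(0, M, 3)
    bi <- 0
    for (blk in partition) {
      gx <- bi %% n_side
      gy <- (bi %/% n_side) %% n_side
      gz <- bi %/% (n_side^2)
      origin <- (c(gx, gy, gz) + 0.5) * spacing + runif(3, -1, 1)
      for (k in seq_along(blk)) {
        x[blk[k], ] <- origin + c((k - 1) * d_touch, 0, 0)
      }
      bi <- bi + 1
    }
    beads <- .bead_frame(M)
    beads$mass <- 100
    beads$radius <- radius
    beads$charge <- 0L
    beads$hydrophobicity <- 0
    beads$residue <- "X"
    beads$resindex <- 1L
    beads$chain <- seq_len(M)
    beads$mol <- seq_len(M)
    beads$kind <- kinds
    beads$mobile <- TRUE
    beads$exposed <- TRUE
    topo <- .new_topology(beads, .empty_bonds(), x)
    membership <- integer(M)
    for (c_i in seq_along(partition)) membership[partition[[c_i]]] <- c_i
    edges <- do.call(rbind, lapply(partition, function(blk) {
      if (length(blk) < 2) return(matrix(integer(0), 0, 2))
      cbind(blk[-length(blk)], blk[-1])
    }))
    structure(list(frame = x, topology = topo, box = box,
                   truth = list(membership = membership,
                                edges = edges)),
              class = "dmd_planted_frame")
  })
}

#' Plant a frame with a known residue-contact pattern
#'
#' A single-bead "protein" sits at the origin; the residues of a peptide
#' chain are placed on a spherical arc around it so that exactly the
#' requested residues are within the contact cutoff. Used as ground truth
#' for per-residue binding profiles (coordinates are free-form; bonds are
#' not represented since the frame feeds analysis only).
#'
#' @param pattern logical vector: which residues contact the protein.
#' @param sequence peptide sequence (defaults to amylin; must match
#'   `length(pattern)`).
#' @param cutoff contact cutoff (Angstrom).
#' @param protein_radius radius of the protein bead.
#' @return A `dmd_planted_frame` with `truth$pattern`.
#' @export
make_planted_binding_frame <- function(pattern,
                                       sequence = iapp_fixture()$sequence,
                                       cutoff = 5.0, protein_radius = 10) {
  res <- .check_sequence(sequence)
  n <- length(res)
  stopifnot(length(pattern) == n)
  params <- residue_params()
  beads <- .bead_frame(n + 1L)
  beads$mass <- c(params[res, "mass"], 14300)
  beads$radius <- c(params[res, "radius"], protein_radius)
  beads$charge <- c(params[res, "charge"], 0L)
  beads$hydrophobicity <- c(params[res, "hydrophobicity"], 0.5)
  beads$residue <- c(res, "X")
  beads$resindex <- c(seq_len(n), 1L)
  beads$chain <- c(rep(1L, n), 2L)
  beads$mol <- c(rep(1L, n), 2L)
  beads$kind <- c(rep("peptide", n), "protein")
  beads$mobile <- TRUE
  beads$exposed <- TRUE
  # place residues on a golden-angle spiral around the protein bead
  dirs <- .fibonacci_sphere(n)
  r_in <- protein_radius + params[res, "radius"] + cutoff * 0.4
  r_out <- protein_radius + params[res, "radius"] + cutoff + 5
  rr <- ifelse(pattern, r_in, r_out)
  x <- rbind(dirs * rr, c(0, 0, 0))
  box <- 4 * max(rr)
  x <- x + box / 2
  topo <- .new_topology(beads, .empty_bonds(), x)
  structure(list(frame = x, topology = topo, box = box,
                 truth = list(pattern = pattern)),
            class = "dmd_planted_frame")
}

#' Wrap planted frames as a minimal trajectory
#'
#' Lets planted frames flow through the trajectory-based analysis
#' functions.
#'
#' @param frames list of coordinate matrices (or `dmd_planted_frame`
#'   objects sharing one topology).
#' @param topology the shared topology (taken from the first planted frame
#'   if omitted).
#' @param box box edge.
#' @param times frame times.
#' @return A `dmd_trajectory`.
#' @export
planted_trajectory <- function(frames, topology = NULL, box = NULL,
                               times = NULL) {
  if (inherits(frames, "dmd_planted_frame")) frames <- list(frames)
  if (inherits(frames[[1]], "dmd_planted_frame")) {
    if (is.null(topology)) topology <- frames[[1]]$topology
    if (is.null(box)) box <- frames[[1]]$box
    frames <- lapply(frames, `[[`, "frame")
  }
  if (is.null(times)) times <- seq_along(frames)
  structure(list(times = times, frames = frames,
                 e_kin = rep(NA_real_, length(frames)),
                 e_pot = rep(NA_real_, length(frames)),
                 t_final = max(times), n_events = 0,
                 counts = list(core = 0, well = 0, bond = 0,
                               thermostat = 0, stale = 0),
                 seed = NA_integer_, replica = NA_integer_,
                 box = box, temperature = NA_real_,
                 topology = topology, interactions = NULL),
            class = "dmd_trajectory")
}
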