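# Trajectory-derived aggregation statistics: contact graphs, cluster
# analysis, binding frequencies, per-residue binding profiles, oligomer
# histograms, proteins-per-cluster counts, and fibril binding-pose
# clustering.

# sequential minimum-image reconstruction: make every molecule whole
# (per chain, then chains placed relative to the first chain)
.molecule_whole <- function(x, beads, box) {
  out <- x
  for (m in unique(beads$mol)) {
    sel <- which(beads$mol == m)
    chains <- unique(beads$chain[sel])
    ref_com <- NULL
    for (cc in chains) {
      cs <- sel[beads$chain[sel] == cc]
      if (length(cs) > 1) {
        d <- diff(out[cs, , drop = FALSE])
        d <- d - box * round(d / box)
        out[cs[-1], ] <- matrix(out[cs[1], ], length(cs) - 1, 3,
                                byrow = TRUE) + apply(d, 2, cumsum)
      }
      com <- colMeans(out[cs, , drop = FALSE])
      if (is.null(ref_com)) {
        ref_com <- com
      } else {
        shift <- (com - ref_com) - box * round((com - ref_com) / box) -
          (com - ref_com)
        out[cs, ] <- sweep(out[cs, , drop = FALSE], 2, shift, "+")
      }
    }
  }
  out
}

#' Center of mass of a molecule, periodic-image safe
#'
#' @param frame Nx3 coordinate matrix.
#' @param topology the matching `dmd_topology`.
#' @param mol molecule id.
#' @param box box edge, Angstrom.
#' @return Mass-weighted center, 3-vector (unwrapped).
#' @export
molecule_com <- function(frame, topology, mol, box) {
  b <- topology$beads
  sel <- which(b$mol == mol)
  if (length(sel) == 0) stop("unknown molecule ", mol, call. = FALSE)
  xw <- .molecule_whole(frame, b, box)[sel, , drop = FALSE]
  colSums(xw * b$mass[sel]) / sum(b$mass[sel])
}

#' Radius of gyration of a molecule
#'
#' Mass-weighted RMS distance from the center of mass, with the molecule
#' reconstructed whole across periodic boundaries first.
#'
#' @inheritParams molecule_com
#' @return Angstrom.
#' @export
radius_of_gyration <- function(frame, topology, mol, box) {
  b <- topology$beads
  sel <- which(b$mol == mol)
  if (length(sel) == 0) stop("unknown molecule ", mol, call. = FALSE)
  xw <- .molecule_whole(frame, b, box)[sel, , drop = FALSE]
  m <- b$mass[sel]
  com <- colSums(xw * m) / sum(m)
  d2 <- rowSums(sweep(xw, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

# all contacting inter-molecular bead pairs at the surface-to-surface
# cutoff; returns a 2-column index matrix
.bead_contacts <- function(frame, beads, box, cutoff) {
  idx <- which(beads$kind != "ion")
  n <- length(idx)
  if (n < 2) return(matrix(integer(0), 0, 2))
  x <- frame[idx, , drop = FALSE]
  r <- beads$radius[idx]
  reach <- r + max(r) + cutoff
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (a in seq_len(n - 1)) {
    jj <- (a + 1):n
    jj <- jj[beads$mol[idx[jj]] != beads$mol[idx[a]]]
    if (length(jj) == 0) next
    d <- sweep(x[jj, , drop = FALSE], 2, x[a, ])
    d <- d - box * round(d / box)
    keep <- which(abs(d[, 1]) <= reach[a])
    if (length(keep) == 0) next
    jj <- jj[keep]; d <- d[keep, , drop = FALSE]
    dist <- sqrt(rowSums(d^2))
    hit <- which(dist <= r[a] + r[jj] + cutoff)
    if (length(hit) > 0) {
      pairs_i <- c(pairs_i, rep(idx[a], length(hit)))
      pairs_j <- c(pairs_j, idx[jj[hit]])
    }
  }
  cbind(pairs_i, pairs_j, deparse.level = 0)
}

#' Molecule-level contact graph of a frame
#'
#' Two beads are in contact when their minimum-image surface-to-surface
#' distance is at most `cutoff` (center distance within the sum of radii
#' plus `cutoff`); two molecules share an edge when at least one
#' inter-molecular bead contact exists. Counterions are excluded.
#'
#' @param frame Nx3 coordinate matrix.
#' @param topology matching `dmd_topology`.
#' @param box box edge, Angstrom.
#' @param cutoff surface-to-surface contact distance, Angstrom (5.0 is the
#'   conventional atomic-contact cutoff).
#' @return A `dmd_contact_graph`: molecule ids, kinds and an edge matrix.
#' @export
contact_graph <- function(frame, topology, box, cutoff = 5.0) {
  b <- topology$beads
  if (nrow(frame) != nrow(b)) stop("frame does not match topology")
  bc <- .bead_contacts(frame, b, box, cutoff)
  mols <- unique(b$mol[b$kind != "ion"])
  kinds <- b$kind[match(mols, b$mol)]
  if (nrow(bc) > 0) {
    me <- cbind(b$mol[bc[, 1]], b$mol[bc[, 2]])
    me <- t(apply(me, 1, sort))
    me <- unique(me)
  } else {
    me <- matrix(integer(0), 0, 2)
  }
  molecule_graph(mols, me, kinds)
}

#' Construct a molecule graph directly
#'
#' @param mols molecule ids (integer vector).
#' @param edges 2-column matrix of molecule-id pairs (undirected, no
#'   self-edges).
#' @param kinds optional molecule kinds aligned with `mols`.
#' @return A `dmd_contact_graph`.
#' @export
molecule_graph <- function(mols, edges, kinds = NULL) {
  mols <- as.integer(mols)
  if (is.null(kinds)) kinds <- rep("molecule", length(mols))
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    stopifnot(all(edges[, 1] != edges[, 2]),
              all(edges %in% mols))
  }
  structure(list(mols = mols, kinds = kinds, edges = edges),
            class = "dmd_contact_graph")
}

#' Connected components of a contact graph (cluster analysis)
#'
#' Two molecules form a cluster when they are in contact, and cluster
#' membership is transitive: molecules connected through intermediates
#' belong to one cluster. Implemented with union-find (path compression).
#'
#' @param graph a `dmd_contact_graph`.
#' @return A `dmd_cluster_set`: per-molecule cluster membership and
#'   per-cluster composition.
#' @export
cluster_components <- function(graph) {
  mols <- graph$mols
  n <- length(mols)
  parent <- seq_len(n)
  find <- function(a) {
    root <- a
    while (parent[root] != root) root <- parent[root]
    while (parent[a] != root) { nxt <- parent[a]; parent[a] <<- root; a <- nxt }
    root
  }
  if (nrow(graph$edges) > 0) {
    ei <- match(graph$edges[, 1], mols)
    ej <- match(graph$edges[, 2], mols)
    for (k in seq_along(ei)) {
      ra <- find(ei[k]); rb <- find(ej[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, unique(roots))
  comp <- data.frame(
    cluster = seq_along(unique(roots)),
    size = as.integer(table(membership)),
    n_peptides = as.integer(tapply(graph$kinds == "peptide", membership, sum)),
    n_proteins = as.integer(tapply(graph$kinds == "protein", membership, sum)))
  structure(list(mols = mols, kinds = graph$kinds,
                 membership = membership, composition = comp),
            class = "dmd_cluster_set")
}

#' @export
print.dmd_cluster_set <- function(x, ...) {
  cat("Cluster set:", length(unique(x$membership)), "clusters over",
      length(x$mols), "molecules\n")
  print(x$composition, row.names = FALSE)
  invisible(x)
}

# per-frame cluster membership for every trajectory in a set
.traj_list <- function(x) {
  if (inherits(x, "dmd_trajectory")) list(x)
  else if (inherits(x, "dmd_trajectory_set")) x$trajectories
  else if (is.list(x)) x
  else stop("expected a trajectory or trajectory set")
}

.frame_clusters <- function(traj, k, cutoff = 5.0) {
  g <- contact_graph(traj$frames[[k]], traj$topology, traj$box, cutoff)
  cluster_components(g)
}

#' Mean number of unbound peptides versus time
#'
#' A peptide is unbound when it is a singleton cluster (no contact with any
#' other molecule). Averaged over the replicas of a trajectory set.
#'
#' @param trajectories a `dmd_trajectory`, `dmd_trajectory_set`, or list of
#'   trajectories sharing a snapshot grid.
#' @param cutoff contact cutoff, Angstrom.
#' @return data.frame with `time` and `mean_unbound`.
#' @export
unbound_peptide_series <- function(trajectories, cutoff = 5.0) {
  tl <- .traj_list(trajectories)
  if (length(tl) == 0) stop("empty trajectory set", call. = FALSE)
  times <- tl[[1]]$times
  acc <- matrix(0, length(times), length(tl))
  for (r in seq_along(tl)) {
    tr <- tl[[r]]
    for (k in seq_along(times)) {
      cs <- .frame_clusters(tr, k, cutoff)
      sizes <- table(cs$membership)
      single <- as.integer(names(sizes))[sizes == 1]
      acc[k, r] <- sum(cs$kinds == "peptide" & cs$membership %in% single)
    }
  }
  data.frame(time = times, mean_unbound = rowMeans(acc))
}

#' Binding frequency of a molecule pair versus time
#'
#' Fraction of replicas in which the two molecules are bound at each time
#' point; `mode = "edge"` requires a direct contact, `mode = "cluster"`
#' membership in the same cluster.
#'
#' @param trajectories trajectory set.
#' @param pair integer pair of molecule ids.
#' @param mode `"edge"` or `"cluster"`.
#' @param cutoff contact cutoff, Angstrom.
#' @return data.frame with `time` and `frequency`.
#' @export
binding_frequency_series <- function(trajectories, pair,
                                     mode = c("edge", "cluster"),
                                     cutoff = 5.0) {
  mode <- match.arg(mode)
  tl <- .traj_list(trajectories)
  stopifnot(length(pair) == 2)
  mols <- unique(tl[[1]]$topology$beads$mol)
  if (!all(pair %in% mols)) stop("unknown molecule ids", call. = FALSE)
  times <- tl[[1]]$times
  acc <- matrix(0, length(times), length(tl))
  for (r in seq_along(tl)) {
    tr <- tl[[r]]
    for (k in seq_along(times)) {
      g <- contact_graph(tr$frames[[k]], tr$topology, tr$box, cutoff)
      if (mode == "edge") {
        e <- g$edges
        acc[k, r] <- as.numeric(nrow(e) > 0 &&
          any((e[, 1] == min(pair) & e[, 2] == max(pair)) |
              (e[, 1] == max(pair) & e[, 2] == min(pair))))
      } else {
        cs <- cluster_components(g)
        mm <- cs$membership[match(pair, cs$mols)]
        acc[k, r] <- as.numeric(mm[1] == mm[2])
      }
    }
  }
  data.frame(time = times, frequency = rowMeans(acc))
}

#' Per-residue binding probability with a partner molecule
#'
#' Restricted to frames in which the molecule and the partner form a bound
#' complex (`bound = "edge"`: direct contact, the natural choice for 1:1
#' systems; `bound = "cluster"`: shared cluster). The probability of a
#' residue index is the fraction of those frames in which at least one
#' exposed bead with that index (pooled over chains, so fibril profiles
#' aggregate the 20 chains) contacts an exposed bead of the partner.
#' Residues flagged non-exposed have probability exactly 0.
#'
#' @param trajectories trajectory set.
#' @param mol molecule whose residues are profiled.
#' @param partner partner molecule id.
#' @param bound `"edge"` or `"cluster"` bound-complex filter.
#' @param cutoff contact cutoff, Angstrom.
#' @return A `dmd_binding_profile`: data.frame `profile` (resindex,
#'   probability) plus the number of bound frames used. Zero bound frames
#'   give an empty profile with `n_frames = 0`.
#' @export
residue_binding_profile <- function(trajectories, mol, partner,
                                    bound = c("edge", "cluster"),
                                    cutoff = 5.0) {
  bound <- match.arg(bound)
  tl <- .traj_list(trajectories)
  b <- tl[[1]]$topology$beads
  if (!any(b$mol == mol) || !any(b$mol == partner)) {
    stop("unknown molecule ids", call. = FALSE)
  }
  resix <- sort(unique(b$resindex[b$mol == mol]))
  hits <- setNames(numeric(length(resix)), resix)
  n_bound <- 0L
  for (tr in tl) {
    for (k in seq_along(tr$times)) {
      fr <- tr$frames[[k]]
      g <- contact_graph(fr, tr$topology, tr$box, cutoff)
      is_bound <- if (bound == "edge") {
        e <- g$edges
        nrow(e) > 0 && any((e[, 1] == min(mol, partner) &
                              e[, 2] == max(mol, partner)) |
                             (e[, 1] == max(mol, partner) &
                                e[, 2] == min(mol, partner)))
      } else {
        cs <- cluster_components(g)
        mm <- cs$membership[match(c(mol, partner), cs$mols)]
        mm[1] == mm[2]
      }
      if (!is_bound) next
      n_bound <- n_bound + 1L
      bc <- .bead_contacts(fr, b, tr$box, cutoff)
      if (nrow(bc) == 0) next
      keep <- (b$mol[bc[, 1]] == mol & b$mol[bc[, 2]] == partner) |
        (b$mol[bc[, 2]] == mol & b$mol[bc[, 1]] == partner)
      keep <- keep & b$exposed[bc[, 1]] & b$exposed[bc[, 2]]
      bc <- bc[keep, , drop = FALSE]
      if (nrow(bc) == 0) next
      own <- ifelse(b$mol[bc[, 1]] == mol, bc[, 1], bc[, 2])
      ri <- unique(b$resindex[own])
      hits[as.character(ri)] <- hits[as.character(ri)] + 1
    }
  }
  prof <- data.frame(resindex = resix,
                     probability = if (n_bound > 0)
                       unname(hits) / n_bound else numeric(length(resix)))
  if (n_bound == 0) prof <- prof[0, ]
  structure(list(profile = prof, n_frames = n_bound, mol = mol,
                 partner = partner, bound = bound),
            class = "dmd_binding_profile")
}

#' @export
print.dmd_binding_profile <- function(x, ...) {
  cat("Residue binding profile: molecule", x$mol, "vs", x$partner,
      sprintf("(%d bound frames, filter '%s')\n", x$n_frames, x$bound))
  if (nrow(x$profile) > 0) {
    top <- x$profile[order(-x$profile$probability), ][1:min(5, nrow(x$profile)), ]
    cat("  top residues:",
        paste(sprintf("%d (%.2f)", top$resindex, top$probability),
              collapse = ", "), "\n")
  } else {
    cat("  (no bound frames)\n")
  }
  invisible(x)
}

#' Histogram of peptides bound per protein
#'
#' Over the frames of the analysis window and all replicas: for each
#' protein, count the peptides sharing its cluster; the histogram is
#' normalized to sum 1. `drop_empty` restricts the histogram to proteins
#' with at least one bound peptide (the bound-complex view).
#'
#' @param trajectories trajectory set.
#' @param window numeric pair of times (inclusive) delimiting the analysis
#'   window; default the final quarter of the run.
#' @param drop_empty exclude proteins with zero peptides.
#' @param cutoff contact cutoff, Angstrom.
#' @return data.frame with `n_peptides` and `probability`.
#' @export
peptides_per_protein_histogram <- function(trajectories, window = NULL,
                                           drop_empty = FALSE,
                                           cutoff = 5.0) {
  tl <- .traj_list(trajectories)
  times <- tl[[1]]$times
  if (is.null(window)) window <- c(0.75 * max(times), max(times))
  sel <- which(times >= window[1] & times <= window[2])
  if (length(sel) == 0) stop("empty analysis window", call. = FALSE)
  counts <- integer(0)
  for (tr in tl) {
    for (k in sel) {
      cs <- .frame_clusters(tr, k, cutoff)
      prot <- which(cs$kinds == "protein")
      for (p in prot) {
        cl <- cs$membership[p]
        counts <- c(counts,
                    sum(cs$kinds == "peptide" & cs$membership == cl))
      }
    }
  }
  if (drop_empty) counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(data.frame(n_peptides = integer(0), probability = numeric(0)))
  }
  tab <- table(factor(counts, levels = 0:max(counts)))
  data.frame(n_peptides = as.integer(names(tab)),
             probability = as.numeric(tab) / sum(tab))
}

#' Mean number of proteins per protein-containing cluster versus time
#'
#' The co-aggregation order parameter N_p: for every frame, the average
#' protein count over clusters holding at least one protein (1 = proteins
#' dispersed, n_proteins = fully co-aggregated), averaged over replicas.
#'
#' @param trajectories trajectory set.
#' @param cutoff contact cutoff, Angstrom.
#' @return data.frame with `time` and `n_p`.
#' @export
mean_proteins_per_cluster <- function(trajectories, cutoff = 5.0) {
  tl <- .traj_list(trajectories)
  times <- tl[[1]]$times
  acc <- matrix(NA_real_, length(times), length(tl))
  for (r in seq_along(tl)) {
    tr <- tl[[r]]
    for (k in seq_along(times)) {
      cs <- .frame_clusters(tr, k, cutoff)
      nprot <- cs$composition$n_proteins
      if (any(nprot > 0)) acc[k, r] <- mean(nprot[nprot > 0])
    }
  }
  data.frame(time = times, n_p = rowMeans(acc, na.rm = TRUE))
}

#' Ensemble of protein binding poses on the fibril surface
#'
#' Evenly strided selection of bound frames; each pose is the protein
#' center of mass relative to the fibril center, minimum-image wrapped.
#'
#' @param trajectories trajectory set from a fibril protocol.
#' @param protein protein molecule id (default: the first protein).
#' @param fibril fibril molecule id (default: the fibril).
#' @param stride keep every stride-th bound frame.
#' @param bound_only keep only frames where protein and fibril share a
#'   contact edge.
#' @param cutoff contact cutoff, Angstrom.
#' @return A `dmd_pose_ensemble`: pose matrix (n x 3), frame times, stride
#'   and box.
#' @export
pose_ensemble <- function(trajectories, protein = NULL, fibril = NULL,
                          stride = 1, bound_only = TRUE, cutoff = 5.0) {
  tl <- .traj_list(trajectories)
  b <- tl[[1]]$topology$beads
  if (is.null(protein)) protein <- b$mol[match("protein", b$kind)]
  if (is.null(fibril)) fibril <- b$mol[match("fibril", b$kind)]
  if (is.na(protein) || is.na(fibril)) {
    stop("need a protein and a fibril molecule", call. = FALSE)
  }
  poses <- matrix(numeric(0), 0, 3)
  times <- numeric(0)
  for (tr in tl) {
    for (k in seq_along(tr$times)) {
      fr <- tr$frames[[k]]
      if (bound_only) {
        g <- contact_graph(fr, tr$topology, tr$box, cutoff)
        e <- g$edges
        ok <- nrow(e) > 0 && any((e[, 1] == min(protein, fibril) &
                                    e[, 2] == max(protein, fibril)) |
                                   (e[, 1] == max(protein, fibril) &
                                      e[, 2] == min(protein, fibril)))
        if (!ok) next
      }
      rel <- molecule_com(fr, tl[[1]]$topology, protein, tr$box) -
        molecule_com(fr, tl[[1]]$topology, fibril, tr$box)
      rel <- rel - tr$box * round(rel / tr$box)
      poses <- rbind(poses, rel)
      times <- c(times, tr$times[k])
    }
  }
  if (nrow(poses) == 0) stop("no bound frames", call. = FALSE)
  keep <- seq(1, nrow(poses), by = stride)
  structure(list(poses = poses[keep, , drop = FALSE], times = times[keep],
                 stride = stride, box = tl[[1]]$box),
            class = "dmd_pose_ensemble")
}

#' Hierarchical clustering of binding poses
#'
#' Agglomerative clustering of the pairwise (minimum-image) center-of-mass
#' distances with mean linkage, joined until the smallest inter-cluster
#' distance exceeds `cutoff` (10 Angstrom = 1 nm by default). The centroid
#' of a cluster is the member with the smallest average distance to its
#' co-members; cluster sizes are normalized by the ensemble size.
#'
#' @param ensemble a `dmd_pose_ensemble`, or an n x 3 pose matrix.
#' @param cutoff joining cutoff, Angstrom.
#' @param box optional box edge for minimum-image distances when a bare
#'   matrix is given.
#' @return A `dmd_pose_clusters`: assignment vector, a `clusters`
#'   data.frame (cluster, size, normalized size, centroid index) ordered by
#'   decreasing size, and centroid coordinates.
#' @export
cluster_binding_poses <- function(ensemble, cutoff = 10, box = NULL) {
  if (inherits(ensemble, "dmd_pose_ensemble")) {
    poses <- ensemble$poses
    box <- ensemble$box
  } else {
    poses <- as.matrix(ensemble)
  }
  n <- nrow(poses)
  if (n == 0) stop("empty ensemble", call. = FALSE)
  if (n == 1) {
    assign <- 1L
    dmat <- matrix(0, 1, 1)
  } else {
    dd <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d <- sweep(poses[j, , drop = FALSE], 2, poses[i, ])
      if (!is.null(box)) d <- d - box * round(d / box)
      dv <- sqrt(rowSums(d^2))
      dd[i, j] <- dv; dd[j, i] <- dv
    }
    dmat <- dd
    hc <- stats::hclust(stats::as.dist(dd), method = "average")
    assign <- stats::cutree(hc, h = cutoff)
  }
  ids <- sort(unique(assign))
  cent_idx <- integer(length(ids))
  for (c_i in seq_along(ids)) {
    mem <- which(assign == ids[c_i])
    if (length(mem) == 1) {
      cent_idx[c_i] <- mem
    } else {
      avg <- rowMeans(dmat[mem, mem, drop = FALSE]) * length(mem) /
        (length(mem) - 1)
      cent_idx[c_i] <- mem[which.min(avg)]
    }
  }
  sizes <- as.integer(table(assign)[as.character(ids)])
  ord <- order(-sizes)
  clusters <- data.frame(cluster = seq_along(ids),
                         size = sizes[ord],
                         normalized_size = sizes[ord] / n,
                         centroid = cent_idx[ord])
  # relabel assignment by decreasing size
  relab <- match(assign, ids[ord])
  structure(list(assignment = relab, clusters = clusters,
                 centroids = poses[clusters$centroid, , drop = FALSE],
                 cutoff = cutoff, n = n),
            class = "dmd_pose_clusters")
}

#' @export
print.dmd_pose_clusters <- function(x, ...) {
  cat("Binding-pose clustering:", nrow(x$clusters), "clusters from",
      x$n, "poses (cutoff", x$cutoff, "A)\n")
  print(utils::head(x$clusters, 8), row.names = FALSE)
  invisible(x)
}
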