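# Independent oracles used across tests: breadth-first-search connected
# components, naive mean-linkage agglomeration, brute-force pair scans.

bfs_components <- function(mols, edges) {
  n <- length(mols)
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    ei <- match(edges[, 1], mols)
    ej <- match(edges[, 2], mols)
    for (k in seq_along(ei)) {
      adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
      adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# canonical form of a partition for comparisons
canon_partition <- function(membership) {
  match(membership, unique(membership))
}

# naive O(n^3) agglomerative clustering, mean linkage, joined while the
# closest cluster pair is within the cutoff
naive_mean_linkage <- function(dmat, cutoff) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    if (bestd > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (c_i in seq_along(clusters)) memb[clusters[[c_i]]] <- c_i
  memb
}

# brute-force O(N^2) molecule contact edges of a frame
brute_contact_edges <- function(frame, beads, box, cutoff = 5.0) {
  idx <- which(beads$kind != "ion")
  edges <- matrix(integer(0), 0, 2)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (beads$mol[i] == beads$mol[j]) next
      d <- frame[i, ] - frame[j, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= beads$radius[i] + beads$radius[j] + cutoff) {
        e <- sort(c(beads$mol[i], beads$mol[j]))
        edges <- rbind(edges, e)
      }
    }
  }
  unique(edges)
}

# small helper: an idealized two-bead system with a given pair potential,
# placed head-on; used for collision-rule checks
two_bead_system <- function(x1, x2, v1, v2, pot, box = 200, mass = c(10, 10),
                            mobile = c(TRUE, TRUE)) {
  beads <- data.frame(
    mass = mass, radius = pot$breakpoints[1] / 2, charge = 0L,
    hydrophobicity = 0, residue = "X", resindex = 1:2, chain = 1:2,
    mol = 1:2, kind = "peptide", mobile = mobile, exposed = TRUE,
    stringsAsFactors = FALSE)
  topo <- structure(list(beads = beads,
                         bonds = data.frame(i = integer(0), j = integer(0),
                                            rmin = numeric(0),
                                            rmax = numeric(0)),
                         x = rbind(x1, x2)), class = "dmd_topology")
  inter <- structure(list(
    types = data.frame(radius = pot$breakpoints[1] / 2, charge = 0L,
                       hydrophobicity = 0),
    type_index = c(1L, 1L),
    potentials = list(pot),
    core = matrix(pot$breakpoints[1], 1, 1),
    lambda_d = 10, bjerrum = 7, eps_hp = 0, hp_range = 0, es_steps = 0,
    dielectric = 80, temperature = 300, contact_cutoff = 5),
    class = "dmd_interactions")
  structure(list(topology = topo, x = rbind(x1, x2), v = rbind(v1, v2),
                 box = box, temperature = 300, interactions = inter,
                 seed = NULL), class = "dmd_system")
}
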