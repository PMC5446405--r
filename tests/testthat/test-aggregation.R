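# Contact graphs, cluster analysis, binding statistics, pose clustering
# and geometry helpers, validated against brute-force and planted truth.

test_that("distant molecules give an empty edge set", {
  pf <- make_planted_frame(list(1, 2, 3))
  g <- contact_graph(pf$frame, pf$topology, pf$box)
  expect_identical(nrow(g$edges), 0L)
})

test_that("contact edges are invariant under rigid translation", {
  pf <- make_planted_frame(list(c(1, 2), c(3, 4, 5), 6), seed = 1)
  g1 <- contact_graph(pf$frame, pf$topology, pf$box)
  shift <- matrix(c(13.2, -7.7, 41.9), nrow(pf$frame), 3, byrow = TRUE)
  g2 <- contact_graph(pf$frame + shift, pf$topology, pf$box)
  expect_identical(g1$edges, g2$edges)
})

test_that("contact edges are invariant under periodic re-wrapping", {
  pf <- make_planted_frame(list(c(1, 2), c(3, 4), 5), seed = 2)
  g1 <- contact_graph(pf$frame, pf$topology, pf$box)
  wrapped <- pf$frame - pf$box * floor(pf$frame / pf$box)
  g2 <- contact_graph(wrapped, pf$topology, pf$box)
  expect_identical(g1$edges, g2$edges)
})

test_that("contact graph equals the brute-force double loop", {
  set.seed(7)
  for (k in 1:25) {
    n_mol <- sample(4:8, 1)
    beads <- data.frame(
      mass = 100, radius = runif(n_mol * 2, 2, 4), charge = 0L,
      hydrophobicity = 0, residue = "X",
      resindex = rep(1:2, n_mol), chain = rep(seq_len(n_mol), each = 2),
      mol = rep(seq_len(n_mol), each = 2),
      kind = sample(c("peptide", "protein"), n_mol * 2, replace = TRUE),
      mobile = TRUE, exposed = TRUE, stringsAsFactors = FALSE)
    beads$kind <- rep(beads$kind[seq(1, n_mol * 2, 2)], each = 2)
    box <- 60
    frame <- matrix(runif(n_mol * 2 * 3, 0, box), ncol = 3)
    topo <- structure(list(beads = beads,
                           bonds = data.frame(i = integer(0), j = integer(0),
                                              rmin = numeric(0),
                                              rmax = numeric(0)),
                           x = frame), class = "dmd_topology")
    g <- contact_graph(frame, topo, box)
    oracle <- brute_contact_edges(frame, beads, box)
    got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
    want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("transitive contact defines a single cluster", {
  g <- molecule_graph(1:3, rbind(c(1, 2), c(2, 3)))
  cs <- cluster_components(g)
  expect_identical(max(cs$membership), 1L)
  g2 <- molecule_graph(1:4, matrix(integer(0), 0, 2))
  expect_identical(max(cluster_components(g2)$membership), 4L)
})

test_that("cluster partitions equal BFS components on random graphs", {
  set.seed(11)
  for (k in 1:250) {
    n <- sample(2:25, 1)
    m <- sample(0:min(30, n * (n - 1) / 2), 1)
    edges <- matrix(integer(0), 0, 2)
    if (m > 0) {
      e <- t(replicate(m, sample.int(n, 2)))
      edges <- e[e[, 1] != e[, 2], , drop = FALSE]
    }
    g <- molecule_graph(seq_len(n), edges)
    got <- canon_partition(cluster_components(g)$membership)
    want <- canon_partition(bfs_components(seq_len(n), edges))
    expect_identical(got, want)
  }
})

test_that("cluster partitions agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (k in 1:50) {
    n <- sample(3:20, 1)
    e <- t(replicate(sample(1:25, 1), sample.int(n, 2)))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    g <- molecule_graph(seq_len(n), e)
    got <- canon_partition(cluster_components(g)$membership)
    ig <- igraph::graph_from_edgelist(e, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    want <- canon_partition(igraph::components(ig)$membership)
    expect_identical(got, want)
  }
})

test_that("planted partitions are recovered exactly", {
  set.seed(17)
  for (k in 1:40) {
    n_mol <- sample(3:10, 1)
    memb <- sample.int(sample(1:4, 1), n_mol, replace = TRUE)
    part <- unname(split(seq_len(n_mol), memb))
    pf <- make_planted_frame(part, seed = k)
    cs <- cluster_components(contact_graph(pf$frame, pf$topology, pf$box))
    expect_identical(canon_partition(cs$membership),
                     canon_partition(pf$truth$membership))
  }
})

test_that("unbound peptide counting matches planted truth", {
  pf1 <- make_planted_frame(list(c(1, 2), 3, 4),
                            kinds = c("peptide", "protein", "peptide",
                                      "peptide"), seed = 1)
  tr <- planted_trajectory(list(pf1))
  s <- unbound_peptide_series(tr)
  expect_equal(s$mean_unbound, 2)  # molecules 3 and 4
  # everyone bound
  pf2 <- make_planted_frame(list(c(1, 2, 3, 4)),
                            kinds = c("peptide", "protein", "peptide",
                                      "peptide"), seed = 2)
  expect_equal(unbound_peptide_series(planted_trajectory(list(pf2)))$mean_unbound,
               0)
})

test_that("binding frequency recovers a planted on/off schedule", {
  kinds <- c("peptide", "protein")
  on <- make_planted_frame(list(c(1, 2)), kinds = kinds, seed = 1)
  off <- make_planted_frame(list(1, 2), kinds = kinds, seed = 2)
  sched <- list(on, off, on, off, on)
  # align boxes so frames are comparable
  tr <- planted_trajectory(lapply(sched, `[[`, "frame"),
                           topology = on$topology,
                           box = max(on$box, off$box))
  f <- binding_frequency_series(tr, pair = c(1, 2))
  expect_equal(f$frequency, c(1, 0, 1, 0, 1))
})

test_that("residue binding profiles match planted contact patterns", {
  set.seed(23)
  n <- 37
  pats <- replicate(40, runif(n) < 0.25, simplify = FALSE)
  frames <- lapply(pats, function(p) make_planted_binding_frame(p))
  tr <- planted_trajectory(lapply(frames, `[[`, "frame"),
                           topology = frames[[1]]$topology,
                           box = frames[[1]]$box)
  prof <- residue_binding_profile(tr, mol = 1, partner = 2)
  truth <- Reduce(`+`, pats) / length(pats)
  # frames with an all-FALSE pattern are unbound and excluded
  bound <- vapply(pats, any, logical(1))
  truth_bound <- Reduce(`+`, pats[bound]) / sum(bound)
  expect_identical(prof$n_frames, sum(bound))
  expect_equal(prof$profile$probability, truth_bound, tolerance = 1e-12)
})

test_that("single bound frame gives a 0/1 profile", {
  pat <- rep(FALSE, 37); pat[c(3, 11, 20)] <- TRUE
  pf <- make_planted_binding_frame(pat)
  tr <- planted_trajectory(pf)
  prof <- residue_binding_profile(tr, mol = 1, partner = 2)
  expect_true(all(prof$profile$probability %in% c(0, 1)))
  expect_equal(which(prof$profile$probability == 1), c(3, 11, 20))
})

test_that("buried residues have binding probability exactly zero", {
  pat <- rep(TRUE, 37)
  pf <- make_planted_binding_frame(pat)
  pf$topology$beads$exposed[10] <- FALSE
  tr <- planted_trajectory(list(pf$frame), topology = pf$topology,
                           box = pf$box)
  prof <- residue_binding_profile(tr, mol = 1, partner = 2)
  expect_equal(prof$profile$probability[10], 0)
  expect_true(all(prof$profile$probability[-10] == 1))
})

test_that("no bound frames give an empty-profile signal, not a crash", {
  pf <- make_planted_frame(list(1, 2), kinds = c("peptide", "protein"))
  tr <- planted_trajectory(pf)
  prof <- residue_binding_profile(tr, mol = 1, partner = 2)
  expect_identical(prof$n_frames, 0L)
  expect_identical(nrow(prof$profile), 0L)
})

test_that("peptides-per-protein histogram matches planted clusters", {
  # proteins 1..4 with 1, 1, 2, 3 peptides; peptides are ids 5..11
  part <- list(c(1, 5), c(2, 6), c(3, 7, 8), c(4, 9, 10, 11))
  kinds <- c(rep("protein", 4), rep("peptide", 7))
  pf <- make_planted_frame(part, kinds = kinds, seed = 3)
  tr <- planted_trajectory(pf)
  h <- peptides_per_protein_histogram(tr, window = c(0, 2))
  expect_equal(sum(h$probability), 1)
  expect_equal(h$probability[h$n_peptides == 1], 0.5)
  expect_equal(h$probability[h$n_peptides == 2], 0.25)
  expect_equal(h$probability[h$n_peptides == 3], 0.25)
})

test_that("all singletons put the histogram mass at zero", {
  pf <- make_planted_frame(list(1, 2, 3),
                           kinds = c("protein", "protein", "peptide"))
  h <- peptides_per_protein_histogram(planted_trajectory(pf),
                                      window = c(0, 2))
  expect_equal(h$probability[h$n_peptides == 0], 1)
})

test_that("N_p reproduces the dispersed and aggregated limits", {
  kinds <- c("protein", "protein", "peptide", "peptide")
  sep <- make_planted_frame(list(1, 2, 3, 4), kinds = kinds, seed = 1)
  expect_equal(mean_proteins_per_cluster(planted_trajectory(sep))$n_p, 1)
  agg <- make_planted_frame(list(c(1, 2, 3), 4), kinds = kinds, seed = 2)
  expect_equal(mean_proteins_per_cluster(planted_trajectory(agg))$n_p, 2)
  # mixed partition: clusters {P1,P2},{P3},{pep} -> mean (2 + 1)/2
  kinds3 <- c(rep("protein", 3), "peptide")
  mix <- make_planted_frame(list(c(1, 2), 3, 4), kinds = kinds3, seed = 3)
  expect_equal(mean_proteins_per_cluster(planted_trajectory(mix))$n_p, 1.5)
})

test_that("radius of gyration matches closed forms and direct sums", {
  pf <- make_planted_frame(list(1))
  topo <- pf$topology
  expect_equal(radius_of_gyration(pf$frame, topo, 1, pf$box), 0)
  # two equal masses at distance d -> d/2
  beads <- topo$beads[c(1, 1), ]
  beads$mol <- 1L; beads$chain <- c(1L, 1L); beads$resindex <- 1:2
  t2 <- structure(list(beads = beads,
                       bonds = data.frame(i = integer(0), j = integer(0),
                                          rmin = numeric(0),
                                          rmax = numeric(0)),
                       x = rbind(c(0, 0, 0), c(6, 0, 0))),
                  class = "dmd_topology")
  expect_equal(radius_of_gyration(t2$x, t2, 1, 100), 3)
  # random coordinates vs direct formula
  set.seed(5)
  x <- matrix(runif(30, 0, 10), 10, 3)
  b10 <- topo$beads[rep(1, 10), ]
  b10$mol <- 1L; b10$chain <- 1L; b10$resindex <- 1:10
  b10$mass <- runif(10, 50, 150)
  t10 <- structure(list(beads = b10,
                        bonds = data.frame(i = integer(0), j = integer(0),
                                           rmin = numeric(0),
                                           rmax = numeric(0)), x = x),
                   class = "dmd_topology")
  com <- colSums(x * b10$mass) / sum(b10$mass)
  oracle <- sqrt(sum(b10$mass * rowSums(sweep(x, 2, com)^2)) / sum(b10$mass))
  expect_equal(radius_of_gyration(x, t10, 1, 1000), oracle,
               tolerance = 1e-10)
})

test_that("molecule COM is invariant under periodic re-wrapping", {
  pep <- build_peptide_chain(iapp_fixture()$sequence, c(2, 7), seed = 4)
  box <- 40  # small box so the chain straddles boundaries after wrapping
  x <- pep$x + 35
  com1 <- molecule_com(x, pep, 1, box)
  wrapped <- x - box * floor(x / box)
  com2 <- molecule_com(wrapped, pep, 1, box)
  d <- (com1 - com2) - box * round((com1 - com2) / box)
  expect_equal(d, c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pose clustering handles the trivial geometries", {
  set.seed(31)
  tight <- matrix(rnorm(60, sd = 1), 20, 3)
  pc <- cluster_binding_poses(tight, cutoff = 10)
  expect_identical(nrow(pc$clusters), 1L)
  expect_equal(pc$clusters$normalized_size, 1)
  two <- rbind(matrix(rnorm(30, sd = 1), 10, 3),
               matrix(rnorm(30, mean = 50, sd = 1), 10, 3))
  pc2 <- cluster_binding_poses(two, cutoff = 10)
  expect_identical(nrow(pc2$clusters), 2L)
})

test_that("pose clustering equals naive mean-linkage agglomeration", {
  set.seed(37)
  for (k in 1:25) {
    n <- sample(8:40, 1)
    poses <- matrix(runif(n * 3, 0, 60), n, 3)
    pc <- cluster_binding_poses(poses, cutoff = 15)
    dmat <- as.matrix(stats::dist(poses))
    want <- canon_partition(naive_mean_linkage(dmat, 15))
    expect_identical(canon_partition(pc$assignment), want)
  }
})

test_that("pose cluster centroids minimize the mean within-cluster distance", {
  set.seed(41)
  poses <- matrix(runif(60, 0, 30), 20, 3)
  pc <- cluster_binding_poses(poses, cutoff = 20)
  dmat <- as.matrix(stats::dist(poses))
  for (r in seq_len(nrow(pc$clusters))) {
    mem <- which(pc$assignment == pc$clusters$cluster[r])
    if (length(mem) < 2) next
    avg <- rowMeans(dmat[mem, mem, drop = FALSE])
    expect_equal(pc$clusters$centroid[r], mem[which.min(avg)])
  }
})

test_that("pose ensembles stride evenly and respect the bound filter", {
  kinds <- c("protein", "peptide")
  frames <- list()
  topo <- NULL
  for (k in 1:10) {
    pf <- make_planted_frame(if (k %% 2 == 0) list(c(1, 2)) else list(1, 2),
                             kinds = kinds, seed = k)
    frames[[k]] <- pf$frame
    topo <- pf$topology
  }
  # rename the "peptide" molecule to fibril so the fibril machinery engages
  topo$beads$kind[topo$beads$mol == 2] <- "fibril"
  tr <- planted_trajectory(frames, topology = topo, box = 500)
  pe <- pose_ensemble(tr, stride = 1)
  expect_identical(nrow(pe$poses), 5L)  # the 5 bound frames
  pe2 <- pose_ensemble(tr, stride = 5)
  expect_identical(nrow(pe2$poses), 1L)
})
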