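# Event-driven engine: collision rules, conservation laws, determinism,
# fixed beads, thermostat, and event-time prediction against a
# brute-force scan.

test_that("equal-mass head-on hard-core collision swaps velocities", {
  pot <- step_potential(4)
  sys <- two_bead_system(c(50, 50, 50), c(60, 50, 50),
                         c(0.2, 0, 0), c(-0.1, 0, 0), pot)
  tr <- run_dmd(sys, t_end = 40, snapshot_interval = 40, thermostat = FALSE)
  expect_equal(tr$v_final[1, ], c(-0.1, 0, 0), tolerance = 1e-12)
  expect_equal(tr$v_final[2, ], c(0.2, 0, 0), tolerance = 1e-12)
})

test_that("capture into a well raises kinetic energy by the well depth", {
  eps <- 0.37
  pot <- step_potential(c(4, 8), -eps)
  sys <- two_bead_system(c(48, 50, 50), c(60, 50, 50),
                         c(0.05, 0, 0), c(0, 0, 0), pot)
  ek0 <- 0.5 * 10 * 0.05^2
  tr <- run_dmd(sys, t_end = 120, snapshot_interval = 2,
                thermostat = FALSE)
  d <- vapply(tr$frames, function(f) abs(f[1, 1] - f[2, 1]), numeric(1))
  expect_true(any(d < 8))  # the well was visited
  # inside the well the kinetic energy exceeds the initial one by eps
  inside <- which(d < 8 - 1e-6)
  expect_equal(tr$e_kin[inside], rep(ek0 + eps, length(inside)),
               tolerance = 1e-10)
  # total energy conserved at every frame
  expect_equal(tr$e_kin + tr$e_pot, rep(ek0, length(tr$e_kin)),
               tolerance = 1e-10)
})

test_that("insufficient radial energy reflects off a barrier", {
  # escape attempt with kinetic energy below the well depth
  eps <- 5
  pot <- step_potential(c(4, 8), -eps)
  # start inside the well moving outward slowly
  sys <- two_bead_system(c(50, 50, 50), c(56, 50, 50),
                         c(-0.05, 0, 0), c(0.05, 0, 0), pot)
  tr <- run_dmd(sys, t_end = 30, snapshot_interval = 30,
                thermostat = FALSE)
  # pair cannot leave the well: separation stays below the outer edge
  d <- abs(tr$x_final[1, 1] - tr$x_final[2, 1])
  expect_lt(d, 8)
  # speed magnitudes preserved after reflection
  expect_equal(sort(abs(tr$v_final[, 1])), c(0.05, 0.05),
               tolerance = 1e-12)
})

test_that("a single free bead moves ballistically and wraps", {
  pep <- build_peptide_chain("A", seed = 1)
  sys <- suppressWarnings(build_system(pep, box = 50, seed = 1))
  x0 <- sys$x[1, ]; v0 <- sys$v[1, ]
  tr <- run_dmd(sys, t_end = 500, snapshot_interval = 100,
                thermostat = FALSE)
  expect_equal(tr$x_final[1, ], x0 + v0 * 500, tolerance = 1e-9)
})

test_that("microcanonical dynamics conserve energy over many events", {
  pep1 <- build_peptide_chain(iapp_fixture()$sequence, c(2, 7), seed = 1)
  pep2 <- build_peptide_chain(iapp_fixture()$sequence, c(2, 7), seed = 2)
  sys <- build_system(list(pep1, pep2), box = 74.3, seed = 3)
  tr <- run_dmd(sys, t_end = 400, snapshot_interval = 20, seed = 4,
                thermostat = FALSE)
  expect_gt(tr$n_events, 1e4)
  E <- tr$e_kin + tr$e_pot
  expect_lt(max(abs(E - E[1])), 1e-6)
})

test_that("engine-reported energies match the R brute-force evaluation", {
  pep1 <- build_peptide_chain("KCNTATCA", seed = 1)
  pep2 <- build_peptide_chain("RLANFLVH", seed = 2)
  sys <- build_system(list(pep1, pep2), box = 74.3, seed = 3)
  tr <- run_dmd(sys, t_end = 50, snapshot_interval = 25, seed = 4)
  e <- total_energy(sys, tr$x_final, tr$v_final)
  k <- length(tr$times)
  expect_equal(tr$e_kin[k] + tr$e_pot[k], e$total, tolerance = 1e-9)
})

test_that("same seed gives bit-identical trajectories", {
  pep <- build_peptide_chain("KCNTATCATQ", seed = 1)
  sys <- suppressWarnings(build_system(pep, box = 60, seed = 2))
  tr1 <- run_dmd(sys, t_end = 200, snapshot_interval = 20, seed = 11)
  tr2 <- run_dmd(sys, t_end = 200, snapshot_interval = 20, seed = 11)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$v_final, tr2$v_final)
})

test_that("immobile beads never move", {
  prot <- freeze_molecules(build_globular_protein(-7, seed = 1),
                           kinds = "protein")
  pep <- build_peptide_chain("KCNTATCATQ", seed = 2)
  sys <- build_system(list(prot, pep), box = 95, seed = 3)
  fixed <- !sys$topology$beads$mobile
  x0 <- sys$x[fixed, ]
  tr <- run_dmd(sys, t_end = 300, snapshot_interval = 50, seed = 4)
  for (fr in tr$frames) {
    expect_equal(fr[fixed, ], x0, tolerance = 0, ignore_attr = TRUE)
  }
  expect_true(all(tr$v_final[fixed, ] == 0))
})

test_that("momentum of mobile pairs is conserved across collisions", {
  # two-bead well system, both mobile: total momentum before == after
  pot <- step_potential(c(4, 8), -1)
  sys <- two_bead_system(c(40, 50, 50), c(60, 51, 50),
                         c(0.08, 0.01, 0), c(-0.02, 0, 0.01), pot,
                         mass = c(7, 19))
  p0 <- 7 * c(0.08, 0.01, 0) + 19 * c(-0.02, 0, 0.01)
  tr <- run_dmd(sys, t_end = 300, snapshot_interval = 300,
                thermostat = FALSE)
  p1 <- 7 * tr$v_final[1, ] + 19 * tr$v_final[2, ]
  expect_equal(p1, p0, tolerance = 1e-9)
})

test_that("thermostatted runs hold the target temperature", {
  pep <- build_peptide_chain(paste(rep("A", 50), collapse = ""), seed = 1)
  sys <- build_system(pep, box = 80, seed = 1)
  tr <- run_dmd(sys, t_end = 4000, snapshot_interval = 5, seed = 2,
                thermostat = TRUE, thermostat_rate = 0.1)
  Tk <- kinetic_temperature(tr)
  expect_lt(abs(mean(Tk[-1]) - 300) / 300, 0.03)
})

test_that("thermostat redraws follow Maxwell-Boltzmann at T", {
  # distributional check on recorded frame-to-frame speeds of a nearly
  # ideal bead gas under frequent redraws
  pep <- build_peptide_chain("A", seed = 1)
  sys <- build_system(pep, box = 200, seed = 1)
  vs <- numeric(0)
  tr <- run_dmd(sys, t_end = 5000, snapshot_interval = 1, seed = 3,
                thermostat = TRUE, thermostat_rate = 2)
  # velocity components at frame times: normal with sd sqrt(kT/m)
  m <- sys$topology$beads$mass[1]
  sd_exp <- sqrt(kT(300) / m)
  # reconstruct component samples from kinetic energies
  ek <- tr$e_kin[-1]
  z <- 2 * ek / kT(300)   # ~ chi-square with 3 df per frame
  expect_equal(mean(z), 3, tolerance = 0.1)
  expect_equal(stats::var(z), 6, tolerance = 0.35)
})

test_that("event times match a brute-force trajectory scan", {
  set.seed(99)
  bp <- c(4, 6.5, 9)
  box <- 40
  n_checked <- 0
  for (k in 1:400) {
    x1 <- runif(3, 0, box); v1 <- rnorm(3, 0, 0.1)
    x2 <- x1 + runif(3, -12, 12); v2 <- rnorm(3, 0, 0.1)
    d0 <- x1 - x2; d0 <- d0 - box * round(d0 / box)
    r0 <- sqrt(sum(d0^2))
    if (r0 <= max(bp) + 0.2) next  # start outside every breakpoint
    dv <- v1 - v2
    # time of the first minimum-image change (predictions stop there)
    t_img <- suppressWarnings(min(ifelse(dv > 0, (box / 2 - d0) / dv,
                                         (-box / 2 - d0) / dv)[abs(dv) > 0]))
    t_pred <- pair_event_time(x1, v1, x2, v2, box, bp)
    # oracle: dense scan of the minimum-image distance
    tg <- seq(0, min(30, t_img), by = 1e-3)
    r <- sqrt((d0[1] + tg * dv[1])^2 + (d0[2] + tg * dv[2])^2 +
                (d0[3] + tg * dv[3])^2)
    hit <- which(r <= max(bp))[1]
    if (is.na(hit)) {
      if (is.finite(t_pred)) expect_gt(t_pred, max(tg))
      next
    }
    t_scan <- tg[hit]
    f <- function(t) {
      d <- d0 + dv * t
      sqrt(sum(d^2)) - max(bp)
    }
    lo <- max(0, t_scan - 1e-3)
    if (f(lo) > 0 && f(t_scan) <= 0) {
      t_ref <- stats::uniroot(f, c(lo, t_scan), tol = 1e-10)$root
      expect_equal(t_pred, t_ref, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)  # the comparison actually exercised crossings
})

test_that("all-static systems terminate cleanly with a warning", {
  prot <- freeze_molecules(build_globular_protein(0, n_beads = 5, seed = 1),
                           kinds = "protein")
  sys <- suppressWarnings(build_system(prot, box = 95, seed = 2))
  expect_warning(run_dmd(sys, t_end = 10, snapshot_interval = 5,
                         thermostat = FALSE), "starved|ballistic")
})
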