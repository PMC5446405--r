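# Step-wise pair potentials: the engine's only interaction representation.
# A potential is a set of strictly increasing radial breakpoints; the first
# breakpoint is an impenetrable hard core, each shell between consecutive
# breakpoints carries a constant energy, and the energy beyond the last
# breakpoint is exactly zero.

#' Construct a step-wise pair potential
#'
#' @param breakpoints strictly increasing radii (Angstrom); the first is the
#'   hard core.
#' @param levels finite energies (kcal/mol), one per shell between
#'   consecutive breakpoints (`length(breakpoints) - 1`); the region beyond
#'   the last breakpoint has energy 0 implicitly.
#' @return An object of class `step_potential`.
#' @examples
#' # square well: core 4 A, well of depth 0.5 kcal/mol out to 6 A
#' step_potential(c(4, 6), -0.5)
#' @export
step_potential <- function(breakpoints, levels = numeric(0)) {
  breakpoints <- as.numeric(breakpoints)
  levels <- as.numeric(levels)
  if (length(breakpoints) < 1L || any(breakpoints <= 0)) {
    stop("breakpoints must be positive", call. = FALSE)
  }
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (length(levels) != length(breakpoints) - 1L) {
    stop("need one level per shell between breakpoints", call. = FALSE)
  }
  if (any(!is.finite(levels))) stop("levels must be finite", call. = FALSE)
  structure(list(breakpoints = breakpoints, levels = levels),
            class = "step_potential")
}

#' @export
print.step_potential <- function(x, ...) {
  cat("Step-wise pair potential\n")
  cat("  hard core:", format(x$breakpoints[1], digits = 4), "A\n")
  n <- length(x$levels)
  if (n > 0) {
    for (k in seq_len(n)) {
      cat(sprintf("  (%.3f, %.3f] A : %+.4f kcal/mol\n",
                  x$breakpoints[k], x$breakpoints[k + 1], x$levels[k]))
    }
  }
  cat("  beyond", format(max(x$breakpoints), digits = 5), "A : 0\n")
  invisible(x)
}

#' Evaluate a step potential at given separations
#'
#' @param pot a [step_potential()].
#' @param r separations (Angstrom); values at or inside the hard core give
#'   `Inf`.
#' @return Energies in kcal/mol.
#' @export
step_energy <- function(pot, r) {
  bp <- pot$breakpoints
  lv <- c(Inf, pot$levels, 0)
  idx <- findInterval(r, bp, left.open = TRUE) + 1L
  lv[idx]
}

#' Discretize the Debye-Hueckel screened Coulomb interaction
#'
#' The continuous screened potential
#' \eqn{U(r) = q_1 q_2 \, l_B \, k_B T \, e^{-r/\lambda_D} / r}
#' is sampled at shell midpoints on `n_steps` equal shells spanning
#' `contact` to `contact + 3 * lambda_d`, beyond which the interaction is
#' truncated to zero. Opposite charges give attractive (negative) levels,
#' like charges repulsive ones; a zero charge gives identically zero levels.
#'
#' @param q1,q2 integer charges in units of e.
#' @param lambda_d Debye length, Angstrom.
#' @param contact inner edge of the screened interaction (typically the sum
#'   of the two bead radii), Angstrom.
#' @param n_steps number of shells (>= 1).
#' @param dielectric,temperature conditions for the Bjerrum length and
#'   \eqn{k_B T}.
#' @return A [step_potential()] whose first breakpoint is `contact`.
#' @export
discretize_screened_coulomb <- function(q1, q2, lambda_d, contact,
                                        n_steps = 6, dielectric = 80,
                                        temperature = 300) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (lambda_d <= 0 || contact <= 0) {
    stop("lambda_d and contact must be positive", call. = FALSE)
  }
  bp <- seq(contact, contact + 3 * lambda_d, length.out = n_steps + 1L)
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  lB <- bjerrum_length(dielectric, temperature)
  lv <- q1 * q2 * lB * kT(temperature) * exp(-mid / lambda_d) / mid
  step_potential(bp, lv)
}

# Sum several step-potential components that share a hard core into a
# single combined step potential. Components whose first breakpoint equals
# the core contribute their levels from the core outward.
.combine_potentials <- function(core, components) {
  bps <- core
  for (p in components) bps <- c(bps, p$breakpoints)
  bps <- sort(unique(bps[bps >= core - 1e-9]))
  # drop near-duplicate breakpoints
  keep <- c(TRUE, diff(bps) > 1e-9)
  bps <- bps[keep]
  if (length(bps) == 1L) return(step_potential(bps))
  mids <- (bps[-1] + bps[-length(bps)]) / 2
  lv <- rep(0, length(mids))
  for (p in components) {
    lv <- lv + vapply(mids, function(r) {
      e <- step_energy(p, r)
      if (!is.finite(e)) 0 else e
    }, numeric(1))
  }
  # trim trailing zero shells so the outermost level is exactly 0
  nz <- which(abs(lv) > 0)
  if (length(nz) == 0L) return(step_potential(bps[1]))
  last <- max(nz) + 1L
  step_potential(bps[seq_len(last)], lv[seq_len(max(nz))])
}
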