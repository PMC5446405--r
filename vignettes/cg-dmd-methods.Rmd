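---
title: "Coarse-grained discrete molecular dynamics of amylin-protein mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained discrete molecular dynamics of amylin-protein mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the
coarse-grained model, the event-driven dynamics, the aggregation and
fibril-metrology statistics, the parameters that matter and why their
defaults are what they are, and what the synthetic-data generators do and
do not emulate.

## The scientific setting

Islet amyloid polypeptide (IAPP, amylin) is a 37-residue peptide hormone
whose aggregation into oligomers and cross-beta amyloid fibrils is
implicated in type-2 diabetes. In physiological fluids amylin meets
abundant globular proteins; two well-studied examples of opposite net
charge are lysozyme (cationic, about +7e at neutral pH) and
alpha-lactalbumin (anionic, about -7e). Their binding can redirect amylin
aggregation: an anionic protein can co-aggregate with the cationic
peptide into large mixed clusters, while a cationic protein binds amylin
more weakly, keeps clusters small, and - in great excess - a crowd of
globular proteins can sequester peptides one by one so that oligomers
never grow. On the fibril surface, adsorbed proteins form a corona whose
binding poses concentrate near charged surface residues for the anionic
protein and spread more evenly for the cationic one.

The package provides a desk-scale, fully seeded simulation and analysis
stack for this problem: a coarse-grained (CG) event-driven molecular
dynamics engine on step-wise potentials, builders for the molecular
species, the published simulation protocols, the cluster/binding
statistics, and worm-like-chain metrology of fibril contours.

## The coarse-grained model

**Resolution.** One bead per residue for peptides (bead radius from the
residue's van der Waals volume, mass the residue mass); a procedural
sphere-packed globule for proteins; the fibril as twenty peptide chains
in two protofibrils. This is deliberately far coarser than the
united-atom resolution behind the original observations; what the CG
model retains is the charge and hydrophobicity pattern, the molecule
sizes, and the concentrations - the ingredients the mechanistic
orderings rest on.

**Charges.** Side-chain titration states at neutral pH: Arg and Lys +1e,
Asp and Glu -1e, His and everything else neutral; termini uncharged (the
+N/-C pair would cancel in the net charge anyway). This gives amylin +2e
and is the rule behind `net_charge()`. Counterions (Cl- or Na+) are
added by `build_system()` so every system is exactly neutral.

**Hydrophobicity.** The Kyte-Doolittle scale, min-max normalized to
[0, 1]. The pairwise hydrophobic attraction is a square well of depth
`eps_hp * h_i * h_j` (default scale 1.2 kcal/mol, i.e. about 2 kT at
300 K for a fully hydrophobic pair) extending 2.5 A beyond the hard
core. Only beads flagged *exposed* attract; buried beads are hard cores
only.

**Electrostatics.** Debye-Hueckel screened Coulomb,
U(r) = q1 q2 lB kT exp(-r/lambda_D)/r, with the Debye length computed
from the dielectric constant (80), ionic strength (0.1 M) and
temperature (300 K) - about 9.7 A, i.e. the conventional "1 nm". The
continuous curve is discretized into 6 equal shells from contact to
contact + 3 lambda_D, each shell carrying the curve's value at the shell
midpoint (`discretize_screened_coulomb()`). Six shells keep every level
within ~25% of the exact shell average while keeping event rates low.

**Bonds.** Square wells: backbone 3.8 A +/- 2%, next-nearest-neighbour
pseudo-bonds 5.4-7.3 A (standard C-alpha geometry bounds, also the bend-
angle constraint), the amylin 2-7 disulfide 4-7 A. Globule beads are
mutually bonded at +/- 5% of their built distances, making the protein a
rigid (slightly breathing) unit; the wider well halves the bond-event
rate relative to a +/-3% well with no effect on any analysis.

**The globular proteins.** `build_globular_protein()` places `n_beads`
(default 42) on a Fibonacci sphere whose radius follows from the
molecular mass at a protein density of 1.35 g/cm3 (~16 A for a 14.3 kDa
protein). Unit charges summing to the net charge are spread maximally
apart (greedy farthest-point selection). A fraction of the uncharged
beads (default 0.3) is flagged as hydrophobic surface patches with
h = 0.6. This surface composition is calibrated to the qualitative fact
that both model proteins are soluble on their own: two isolated
like-charged globules must not stick irreversibly through their surface
patches, while a hydrophobic peptide must still bind either protein.
An optional PDB path (`read_structure()`) places beads at C-alpha
positions instead.

**The fibril.** Two protofibrils of ten in-register chains (4.8 A
cross-beta stacking), the second protofibril the exact two-fold rotation
image of the first about the fibril axis, 10 A between the sheet layers.
Residues pointing into the beta-core (10, 12, 14, 16) and those buried
at the protofibril interface (11, 13, 15, 28-36) are non-exposed. Only
the unstructured N-terminus (1-4) and the solvent-exposed side-chain
positions 9, 11, 15, 17, 18, 20, 21, 37 are mobile; everything else is
fixed, which also means the fibril cannot bend (protein-induced fibril
softening is out of reach of this model by construction). Fibril chains
are kept straight by bond windows around the as-built geometry; the
2-7 disulfide is not imposed there (the extended strand geometry is
incompatible with it, and the bonded region is almost entirely fixed).

**Exclusions.** Non-bonded step potentials act only *between* molecules;
intra-molecular geometry is maintained by the bond network alone. This
is what allows the dense cross-beta packing of the fibril (same-molecule
beads sit inside each other's hard cores) and makes the peptide slightly
more compressible than a self-avoiding chain - an accepted cost at this
resolution.

## The event-driven engine

Between events every bead moves ballistically; an event is a pair
crossing a potential breakpoint, a bond hitting a wall, or a thermostat
ghost collision. Crossing a step of height dU transmits with
v_r' = sign(v_r) sqrt(v_r^2 - 2 dU/mu) when the radial kinetic energy
exceeds dU and reflects (v_r' = -v_r) otherwise; hard cores and bond
walls always reflect; an immobile partner is treated as infinite mass.
Kinetic plus potential energy is conserved to machine precision per
event (the package asserts <= 1e-6 kcal/mol drift over >= 1e5 events),
and momentum is conserved exactly for mobile-mobile collisions.

Units are Dalton, Angstrom and kcal/mol per molecule, making the time
unit [L] sqrt([M]/[E]) = 48.9 fs (the conventional "~50 fs"; note that
quoting the energy unit as 6.9e-22 J is inconsistent with that time
unit - 1 kcal/mol per molecule is 6.95e-21 J, and the engine uses the
latter). kB = 1.9872e-3 kcal/mol/K.

Scheduling is exact without neighbour cell lists: when a bead's velocity
changes, its future events against all partners are re-solved (O(N) per
event, the right trade-off below ~1000 beads), but only events within a
time horizon (default 5 time units) are queued; a per-bead refresh event
at the horizon re-scans, and stale events are discarded by per-bead
collision counters. Periodic boundaries are handled by the minimum-image
convention with an explicit re-examination event scheduled at the moment
a pair's minimum image changes, so boundary crossings are exact too.
Ties in the event queue break lexicographically on (time, bead indices,
kind), making runs bit-reproducible for a fixed seed (the horizon value
is part of that configuration).

The Anderson thermostat redraws the full velocity vector of one
uniformly chosen mobile bead from the Maxwell-Boltzmann distribution at
Poisson-distributed times. The engine-level default rate (0.1 per time
unit per bead) thermalizes a 50-bead system to within 2% of 300 K over
1e5 events. The *protocol* runs use a much lower rate (0.002): at 0.1 a
14 kDa globule's center-of-mass motion becomes diffusive on a ~1 A mean
free path and cannot traverse a 95 A box within a desk-scale run; 0.002
preserves near-ballistic transport while still controlling temperature
over the full run length. This is a transport choice, not a
thermodynamic one - Boltzmann weights are unaffected.

## Protocols and desk scaling

`make_protocol()` encodes the six setups: one peptide with one free
protein (74.3 A box), six peptides with six fixed proteins (137.0 A),
two peptides with two free proteins (95.0 A; the 6:6 and 2:2 boxes share
the peptide number density to 0.5%), four peptides with two free
proteins (box chosen to keep the 2:2 peptide concentration - the one
box the design leaves open), six peptides among 48 fixed proteins
(240.0 A), and one protein binding the 20-chain fibril (150 A). All at
300 K; the full design is 20 replicas of 50 ns with the final 12.5 ns
as analysis window (kept as the final quarter under scaling).

`scale` multiplies run length and replica count; molecule counts scale
through the peptide count with the protein:peptide ratio preserved
(e.g. crowded at scale 1/4: 2 peptides, 16 proteins), and the box
rescales by `equal_concentration_edge()` so all number densities are
preserved to 1%.

Desk-scale conditions used by this package's own acceptance checks
(chosen for a single CPU, stated here as the package's problem sizes):

* charge-sign ordering: free-2:2, 2 ns equivalent (~41,000 time units),
  one replica per seed, five seeds per protein kind;
* crowding ordering: crowded-48:6 at scale 1/3 (2 peptides, 16 fixed
  proteins, 166 A box) against fixed-6:6 at scale 1/3 (2 peptides, 2
  fixed proteins, 95 A box), 1 ns, three matched seeds;
* conservation and thermostat checks: two-peptide and 50-bead systems,
  >= 1e5 events each.

A 2 ns CG run is of course far shorter than 50 ns of united-atom
dynamics; CG dynamics on a smoothed landscape are also intrinsically
faster. The orderings these runs are asked to reproduce are equilibrium-
direction statements (which mixture co-aggregates more), not kinetic
ones, and they are asserted as orderings across seeds, never as values.

```{r protocol-example}
library(cgdmd)
p <- make_protocol("free-2:2", protein_kind = "aLac-like",
                   sim_ns = 2, n_replicas = 1)
ts <- run_replicas(p, base_seed = 100)
np <- mean_proteins_per_cluster(ts)
tail(np)
```

## Aggregation analysis

A bead contact is a minimum-image *surface-to-surface* distance of at
most 5.0 A (center distance within r_i + r_j + 5 A) - the CG translation
of the conventional 5.0 A atom-atom cutoff, since bead radii must be
discounted. Molecules sharing at least one inter-molecular bead contact
share an edge; counterions are excluded from all cluster statistics.
Clusters are the connected components (union-find; cross-checked against
breadth-first search and igraph in the tests). On top of this sit the
unbound-peptide series, pair binding frequencies across replicas,
per-residue binding probabilities over bound-complex frames (direct-edge
filter for 1:1 systems, shared-cluster for crowded ones, exposed beads
only - a buried residue has probability exactly 0), the peptides-per-
protein histogram (with and without the empty-protein bin; the
occupied-bin view is the right one for "how do bound peptides
distribute"), the proteins-per-cluster order parameter N_p, and the
fibril binding-pose machinery: evenly strided bound-frame ensembles of
protein centers of mass in the fibril frame, clustered agglomeratively
with mean linkage at a 1 nm cutoff (implemented via `stats::hclust`
"average" + `cutree`; the tests verify exact agreement with a naive
O(n^3) agglomerator), centroid = member with the smallest mean distance
to its co-members, sizes normalized by the ensemble size.

## Fibril metrology

Contours are ordered 2D polylines (nm) - transmission micrographs are
planar projections, so the 2D worm-like-chain convention is used
throughout: tangent correlations decay as exp(-s/(2 lambda)). Three
estimators are pooled over all contours and positions before fitting
(per-contour fits are far too noisy at realistic n):

* **BCF** - fit exp(-s/(2 lambda)) to the pooled tangent correlation
  over s in [ds, min(2 lambda_0, s_max)], lambda_0 from a log-linear
  pre-fit;
* **MSED** - fit the closed form <R^2(s)> = 4 lambda [s - 2 lambda
  (1 - exp(-s/(2 lambda)))] to the pooled internal-segment end-to-end
  statistic;
* **MSMD** - fit <u^2(s)> = s^3/(48 lambda) (perpendicular midpoint
  deviation from the secant) in the weakly-bent window s <= lambda/2,
  iterating once on the estimate. The s^3/48 constant follows from the
  Wiener-process tangent model and is certified against the generator in
  the tests (the round-trip is the authoritative check, since published
  descriptions of the midpoint method do not print the formula).

`wlc_fit()` averages the converged estimators (rigid ensembles - no
measurable decay - are flagged rather than fitted) and is the package's
classed estimator with `print`/`summary`/`coef`/`plot` methods.
Diameter statistics sample 100 points uniformly along pooled arc length
(seeded) and fit a Gaussian to the sampled widths, mirroring the
standard measurement protocol.

```{r wlc-example}
cts <- generate_wlc_contours(lambda = 2100, length = 8400, ds = 50,
                             n = 290, seed = 7,
                             width_mean = 8.9, width_sd = 1.1)
fit <- wlc_fit(cts)
fit
diameter_stats(cts, n_samples = 100, seed = 1)$fit$estimate
```

## Synthetic data: what it does and does not emulate

`generate_wlc_contours()` draws exact 2D worm-like chains (independent
Gaussian bend per step, variance ds/lambda), optionally with a Gaussian
width profile truncated at zero - the same model the diameter analysis
fits, by design. It does not emulate tracking noise, pixelation, fibril
crossings or finite image frames, so estimator recovery on it bounds
estimator bias only, not image-processing error. `make_planted_frame()`
realizes a requested cluster partition exactly (path-connected blocks on
a jittered grid, blocks isolated); `make_planted_binding_frame()`
realizes an arbitrary per-residue contact pattern on an arc around a
single protein bead. Planted frames are free-form coordinates for the
analysis stack - they need not satisfy bond geometry. Consequently,
passing the planted-truth tests certifies the *analysis* code exactly,
but says nothing about whether simulated configurations are realistic;
that link is made separately by the conservation, thermostat and
mechanistic-ordering checks on real engine output.

## Numerical choices and degenerate inputs

Event tolerances: a pair within 1e-9 (relative) of a breakpoint is
classified by its radial velocity sign; minimum-image re-examinations
are nudged 1e-9 time units past the switch. Grazing tangencies
(discriminant ~ 0) resolve as no-crossing. Peptide conformations are
rejection-sampled until the disulfide window is satisfiable. Globule
placement retries random positions/orientations up to 2000 times before
raising a placement error. Systems whose interaction range exceeds half
the box (the 74.3 A monomer box with 3 lambda_D tails is within ~1 A of
that bound) warn and image the outermost - negligible - shells
approximately. Rigid contour ensembles raise a "rigid" flag instead of a
fit; empty bound-frame sets return an empty profile object rather than
erroring.

The builder records the peptide mass computed from residue masses
(+ water); the conventional quoted MW of the amidated peptide reagent
(3,906) is kept as metadata rather than forced, since the amidation
state is not modelled.

## Known limitations

* The fibril is held rigid apart from the printed mobile mask, so
  protein-induced fibril softening/bending cannot occur in simulation;
  the metrology module quantifies it on contours instead.
* CG bead radii keep charges ~7 A apart at contact, weakening
  salt-bridge-like interactions relative to united-atom models; the
  mechanistic orderings survive this, absolute binding constants do not.
* Snapshot counts and pose-cluster counts from the original
  united-atom study (thousands of snapshots, 30-35 pose clusters)
  depend on that force field and are not desk-reproducible; the package
  reproduces the *procedures* and checks them against planted truth.
* Secondary structure is meaningless at one bead per residue and is
  not computed.
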