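# cgdmd

Coarse-grained, event-driven (discrete) molecular dynamics and analysis
for amyloid peptide aggregation in the presence of globular proteins,
plus worm-like-chain metrology of fibril contours.

## The problem

Islet amyloid polypeptide (IAPP, amylin) is a 37-residue, +2e peptide
whose oligomers and cross-beta fibrils are implicated in type-2
diabetes. In biological fluids it meets globular proteins of both signs
of charge — lysozyme-like (+7e) and alpha-lactalbumin-like (−7e) — and
their binding redirects its aggregation: the anionic protein
co-aggregates with the cationic peptide into large mixed clusters, the
cationic protein binds more weakly and leaves small oligomers, and a
large excess of either keeps peptides sequestered one per protein.
Adsorbed proteins also form a corona on the fibril surface whose
binding-pose distribution differs by protein charge. `cgdmd` is a
desk-scale, fully seeded simulation + analysis toolkit for exactly these
questions, for researchers who want a tested, reproducible CG surrogate
rather than a cluster-scale united-atom study.

## What is inside

* **Model builders** — one-bead-per-residue peptides (titration-state
  charges: Arg/Lys +1, Asp/Glu −1, His neutral; Kyte–Doolittle
  hydrophobicity normalized to [0, 1]), procedural charged globules,
  a 20-chain two-protofibril fibril model with the published
  mobile/buried residue masks, counterion accounting, and PDB input
  (C-alpha extraction).
* **DMD engine (C++)** — step-wise pair potentials (hard cores,
  hydrophobic square wells, Debye–Hückel screened Coulomb discretized
  into 6 shells out to 3 Debye lengths), exact event-driven dynamics
  with an Anderson thermostat and periodic boundaries; energy conserved
  to 1e−6 kcal/mol over 1e5+ events; bit-reproducible for a fixed seed.
  Units: Da, Å, kcal/mol; the derived time unit is 48.9 fs (~50 fs).
* **Protocols** — the six published setups (1:1, fixed 6:6, free 2:2,
  free 2:4, crowded 48:6, fibril binding) with the published box sizes
  (74.3 / 137.0 / 95.0 / 240.0 / 150 Å), equal-concentration box
  algebra, replica management, and desk scaling.
* **Aggregation analysis** — 5.0 Å-cutoff contact graphs, union-find
  cluster analysis, binding frequencies, per-residue binding
  probabilities, peptides-per-protein histograms, the proteins-per-
  cluster order parameter N_p, and hierarchical (mean-linkage, 1 nm
  cutoff) clustering of fibril binding poses with centroid poses and
  normalized cluster sizes.
* **Fibril metrology** — 2D worm-like-chain persistence length by three
  estimators (bond correlation function, mean-squared end-to-end
  distance, mean-squared midpoint displacement), their combination as a
  classed `wlc_fit` estimator, contour lengths, and Gaussian diameter
  statistics from 100 random arc-length samples.
* **Synthetic data** — seeded worm-like-chain contour generators with
  known persistence length and width model, and planted-cluster /
  planted-contact frames that carry machine-readable ground truth.

The core statistic for co-aggregation is the mean number of proteins per
protein-containing cluster,

N_p = ⟨ #proteins in cluster ⟩ over clusters with ≥ 1 protein,

which is 1 when proteins are dispersed and approaches the protein count
when they co-aggregate; the 2D worm-like chain enters through
⟨cos θ(s)⟩ = e^(−s/2λ), ⟨R²(s)⟩ = 4λ[s − 2λ(1 − e^(−s/2λ))] and
⟨u²(s)⟩ = s³/48λ.

## Worked example

```r
library(cgdmd)
fx <- iapp_fixture()
pep  <- build_peptide_chain(fx$sequence, disulfide = fx$disulfide, seed = 1)
prot <- build_globular_protein(-7, n_beads = 42, mass = 14178, seed = 1)
sys  <- build_system(list(prot, pep), box = 74.3, temperature = 300, seed = 1)
tr   <- run_dmd(sys, t_end = 2000, snapshot_interval = 100, seed = 2,
                thermostat_rate = 0.002)
tr
binding_frequency_series(tr, pair = c(1, 2)) |> tail(3)

cts <- generate_wlc_contours(lambda = 2100, length = 8400, ds = 50,
                             n = 290, seed = 7)
wlc_fit(cts)
```

which prints (the build warns that in the smallest published box the
outermost — negligible — screening shells graze the half-box bound):

```
DMD trajectory: 21 frames to t = 2000 time units
  events: 62,817 (core 45, well 2136, bond 60309, thermostat 327)
  energy (final frame): kin 77.656 + pot -0.73297 kcal/mol
   time frequency
19 1800         1
20 1900         1
21 2000         1
Worm-like-chain fit over 290 contours
  persistence length: 2312.8 nm (BCF 2211.8, MSED 2192.2, MSMD 2534.4)
  contour length: 8400.0 +/- 0.0 nm
```

Read: within 2000 time units (~0.1 ns equivalent) the +2e peptide binds
the −7e globule and stays bound (binding frequency 1 at the end of the
run), and the persistence-length estimators recover a 2100 nm generating
stiffness within 15% from 290 synthetic contours — the same ensemble
size as a typical fibril-image analysis.

A thin CLI (`inst/cli/cgdmd`) exposes `simulate`, `analyze`,
`fibril-stats` and `make-synthetic` subcommands over the same functions,
writing XYZ/CSV/JSON plus a reproducibility manifest.

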