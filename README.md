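# channelflow

Trajectory analysis of water and hydrogen-bond dynamics in the proton
channels of membrane proteins.

Proton pumps such as Cytochrome c Oxidase (CcO) move protons through
internal channels — in CcO the D-channel (named for D132) and the K-channel
(named for K362) — whose conductance depends on transient water wires and on
the protonation states of a handful of key residues.  Molecular-dynamics
simulations probe this, but the raw trajectories only become evidence after
a chain of geometric and statistical analyses.  `channelflow` implements
that chain as a tested R package, for computational biophysicists analysing
their own CHARMM/NAMD-style trajectories (PDB/PSF topologies, DCD
coordinates):

* **Channel hydration** — the channel volume in each frame is the convex
  polyhedron spanned by the centres of mass of user-declared corner
  residues; waters are counted inside it by their oxygen position.  A fixed
  enveloping cylinder (radius 9.5 Å, 15 × 2 Å height slices, ≤ 30 Å, axis
  from the channel-end Cα groups elongated by 10 %) resolves hydration along
  the channel axis and supports 2D occupancy projections.
* **Hydrogen bonds and lifetimes** — geometric criterion (donor–acceptor
  ≤ 3.5 Å, ≤ 35° off linear); per-residue bond counts against water; bond
  persistence via the strict time autocorrelation
  C(τ) = Σ h(t₀)·persist(t₀,τ) / Σ h(t₀)² over origins 120 ps apart, lags to
  100 ps, fitted with C(t) = A·e^(−t/τ₁) + B·e^(−t/τ₂), A + B = 1, and the
  lifetime reported as τ = A·τ₁ + B·τ₂.
* **Water-mediated connectivity** — per-frame graphs over key residues,
  channel waters and hydronium; connection probability of residue pairs via
  shortest-path search.
* **Conformation & electrostatics** — χ₁–χ₄ dihedrals, rule-atom distance
  distributions, up/down side-chain classification, and switched-Coulomb
  pair energies (10→12 Å switch, PSF charges).
* **Protonation-model bookkeeping** — the 40-model universe of binary codes
  (D132, E286, K362, E101) with hydronium positions a–f and `*` wildcards.
* **Synthetic systems** — a generator of toy channel trajectories with
  exact ground truth (per-slice water occupancy, Markov bond kinetics,
  stationary hydronium) so the whole pipeline is testable end to end.

The shipped D- and K-channel corner lists, key residues and K-channel width
pairs live in `inst/extdata/channels.yml`; donor/acceptor tables in
`inst/extdata/hbond_atoms.yml`.  Both are plain YAML and editable.

## Worked example

Generate a toy channel with 10 waters per slice and a probe residue whose
hydrogen bond to water switches with known rates (mean bonded dwell
1/k_off = 30 ps), then run the census and the lifetime machinery:

```r
library(channelflow)

spec <- synthetic_channel_spec(
  n_frames = 500, per_slice_waters = rep(10L, 15), n_bulk_waters = 50,
  probes = data.frame(label = "p1", k_on = 1/60, k_off = 1/30), seed = 7)
sys  <- generate_system(spec)

hyd  <- water_census(sys$traj, sys$channel)
hyd
#> cf_hydration (toy-channel): 500 frames, mean 150.00 waters in polyhedron,
#>   150 ever inside
head(height_profile(list(hyd)), 3)   # SE needs >1 replica, hence NA here
#>   slice height mean se
#> 1     1      1   10 NA
#> 2     2      3   10 NA
#> 3     3      5   10 NA

ser <- residue_water_hbond_stats(sys$traj, data.frame(chain = "P", resid = 1001))
all(ser$h == sys$truth$probe_h[, 1])   # detector reproduces the Markov truth
#> [1] TRUE

g  <- generate_hbond_series(1/60, 1/30, dt = 2, n_frames = 80000, seed = 7)
fit_lifetime(hbond_autocorrelation(g$h, dt = 2))
#> H-bond lifetime: tau = 30.35 ps (A=0.06 tau1=4.77, B=0.94 tau2=32.06)
```

The census recovers the generator's occupancy exactly (resampling mode is
exact by construction), and the fitted weighted lifetime lands within a few
percent of the true 30 ps dwell at the standard analysis length (160 ns at
2 ps saving).

The `analysis/` directory holds numbered drivers that run the same pipeline
as a narrative workflow — `01_simulate.R` (toy systems for models `0000` and
`1000c`, three replicas, written as PDB/PSF/DCD), `02_hydration.R`,
`03_hbonds.R`, `04_network.R`, `05_conformation_electro.R` — writing tidy
CSV tables under `results/`.  Real trajectories enter the same functions via
`read_structure()` / `read_trajectory()` and `default_channels()`.

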