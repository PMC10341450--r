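---
title: "Methods: channel hydration, hydrogen-bond kinetics and connectivity"
author: "channelflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel hydration, hydrogen-bond kinetics and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`channelflow` analyses molecular-dynamics trajectories of membrane proteins
with internal proton-uptake channels — the motivating system is Cytochrome c
Oxidase (CcO) with its D- and K-channels — and answers three families of
questions:

1. **How hydrated is a channel?**  A channel is declared by corner residues;
   its volume in a frame is the convex polyhedron spanned by their centres of
   mass, and water molecules (located by their oxygen) are counted inside it.
   An enveloping cylinder discretised into height slices resolves where along
   the channel the water sits.
2. **How stable are residue–water hydrogen bonds?**  Bonds are detected by
   the standard geometric criterion; their persistence is summarised by a
   strict autocorrelation function and a bi-exponential lifetime fit.
3. **Which residues are connected by water wires?**  Per-frame graphs over
   residues and waters, joined by detected hydrogen bonds, yield the
   probability that two residues are linked directly or through water.

Conformational descriptors (χ dihedrals, rule-atom distances, up/down
side-chain orientation), pairwise switched-Coulomb energies, and the
protonation-model bookkeeping used to index CcO simulations complete the
pipeline.  A synthetic trajectory generator with exact ground truth makes
every stage testable without external simulation data.

# The channel polyhedron

For every analysed frame the corner-residue centres of mass are computed and
their **convex hull** is taken as the channel volume; convexity is the unique
maximal-volume choice over those vertices and makes point membership
well defined (a point is inside iff it satisfies every facet half-space
inequality; boundary points count as inside — a deterministic convention with
measure-zero effect).  The hull is built by incremental insertion and is
validated in the test suite against a Monte-Carlo rejection-sampling
integration oracle and a per-facet brute-force membership oracle.

Water molecules are identified by residue name (`TIP3`, `HOH`, `WAT`, `SOL`
by default) and located **by their oxygen atom only**; a water whose
hydrogens straddle the boundary is counted by where its oxygen sits.  The
census records, per frame, the set of waters inside the polyhedron, and
accumulates the "ever-inside" set of waters that hit the channel at least
once in the analysis window.  Census tables default to the per-frame average
count; the ever-inside count is exported alongside since both readings of a
"number of waters in the channel" are useful.

# The enveloping cylinder

The polyhedron is enveloped by a cylinder of **radius 9.5 Å** built once per
trajectory and held fixed, anchored on the frame closest to the
time-averaged structure (the *median structure*: the frame minimising the
RMSD of a chosen selection from the per-atom time averages, computed without
superposition — trajectories are assumed pre-aligned; an optional Kabsch
pre-step exists but is off by default).  The axis runs from the Cα centre of
mass of the bottom residue group to that of the top group, is elongated by
**10 %** (5 % per end, covering channel entrance and exit symmetrically) and
is capped at **30 Å** (elongation applied before the cap; the cap shrinks
symmetrically about the midpoint).  The cylinder is partitioned into **15
half-open slices of 2 Å**, numbered 1–15 from the entrance (N-side); a point
axially outside `[0, height)` or radially beyond the wall is outside (the
wall itself counts as inside).  Slice thickness sits between the largest
intra-water distance (~1.5 Å H–H) and the hydrogen-bond O⋯O distance
(~2.8 Å), so a water cannot straddle more than two slices and neighbouring
slices remain distinguishable.

The original protocol names only "the lowermost and uppermost residues" as
axis anchors.  Because ties and near-ties are common in synthetic and real
geometries, the end groups are configurable; by default each is the single
corner residue with the extreme projection onto the dominant principal axis
of the corner points, oriented by an `axis_hint` (default +z, the
membrane normal in the usual setup).

Two invariants hold by construction and are asserted in the tests: per-frame
slice counts sum exactly to the inside-cylinder count, and the
inside-polyhedron water set nests inside the inside-cylinder set.

2D occupancy projections accumulate inside-cylinder water oxygens on a
0.5 Å grid (below the water excluded-volume radius, above coordinate noise)
in a channel-local frame; the two views differ by a 90° rotation about the
axis.

Periodic boundaries: analyses operate on whole molecules; when a box is
present, water oxygens are minimum-imaged toward the cylinder midpoint
before censusing.  The simulated boxes (~96 Å edges) are large against the
~30 Å channel, so this convention is sufficient.

# Hydrogen bonds

A hydrogen bond exists when the **donor–acceptor distance ≤ 3.5 Å** and the
D–H⋯A angle deviates from linearity by **at most 35°** (i.e. the angle at
the hydrogen is ≥ 145°).  Donor/acceptor atoms per residue type are not
derivable from coordinates alone, so an editable YAML table ships with the
package (water oxygen donates and accepts; Ser/Thr/Tyr hydroxyls both; Lys
NZ donates through three hydrogens when protonated; Asp/Glu carboxyl oxygens
accept, gaining a hydroxyl donor when protonated; Asn/Gln amides; His ring
nitrogens per tautomer; hydronium donates through three hydrogens).
Same-residue pairs are excluded.  Detection is validated against an
all-pairs brute force at every release of the criterion's boundaries.

## Lifetimes

For a residue, `h(t) = 1` in frames where at least one bond to *any* water
exists (partner identity and atoms may change).  With time origins spaced
**120 ps** apart (non-overlapping at the maximal lag), the autocorrelation at
lag τ (up to **100 ps**) is the fraction of bonded origins whose bond
persists through *every* saved frame of `[t0, t0+τ]`.  Persistence is strict
at the 2 ps frame resolution: a single unbonded frame breaks it; excursions
shorter than the saving interval are invisible, which biases run-length
statistics upward by O(k·dt) — the tests account for this explicitly.  The
denominator is the number of bonded origins, making C(τ) a survival
probability conditioned on being bonded at the origin; the ratio-of-sums
reading is used (per-origin ratios are ill-defined at unbonded origins), and
replica curves may be pooled with bonded-origin weights.

C(τ) is fitted with `C(t) = A·exp(−t/τ₁) + B·exp(−t/τ₂)`, `A + B = 1`,
`A, B ∈ [0, 1]`, `τᵢ > 0`, and the reported lifetime is the weighted sum
`τ = A·τ₁ + B·τ₂`.  The constraints are enforced by reparameterisation
(logistic for A, scaled logistic for the time constants) and the fit is
Levenberg–Marquardt with uniform weights over the lag grid and a 5-start
multistart.  The time constants are capped at five times the maximal lag:
without the cap a vanishing amplitude on an arbitrarily slow component
absorbs the statistical baseline of any noisy curve and inflates τ.  A fit
is flagged **not determined** when it fails to converge, when the slow
constant is pushed onto that cap (too-long lifetime for the observation
window — a flat curve lands here), or when a parameter's standard error
exceeds the parameter.  Per the replica convention, lifetimes are fitted per
replica and then averaged.

# Connectivity graphs

Per frame, a graph is built whose nodes are the channel's key residues, its
assigned waters (polyhedron scope by default; cylinder scope is
configurable) and the hydronium ion when present; an undirected, unweighted
edge joins two nodes with at least one detected hydrogen bond between them
(duplicates collapse).  Two residues are *connected* when any path exists —
direct, through waters, or through other residues (protein nodes may serve
as intermediates; they are nodes of the graph by construction).  The
shortest-path search runs Dijkstra on unit weights (equivalent to BFS, which
serves as the independent oracle in the tests).  The connection probability
of a pair is its connected-frame fraction, averaged over replicas with the
standard error of that mean.  The 1 % threshold used in network figures is a
display filter; full matrices are always written.

# Electrostatics

Pairwise residue–residue (and hydronium–residue) interaction energies use
direct-space Coulomb with the simulation's short-range scheme: the
C1-continuous cubic switching function from **10 Å** to a **12 Å** cutoff,
Coulomb constant 332.0636 kcal·Å/(mol·e²), charges from the PSF, no
dielectric screening, minimum image when a box is present.  This is a
deliberate methodological choice: the original interaction curves were
evaluated with full-system particle-mesh Ewald, whose per-pair decomposition
is not reproducible from pair charges alone.  Direct-space switched Coulomb
gives trend-comparable, not bit-identical, energies; the module documents
this and the tests pin the closed-form fixed points (332.0636 kcal/mol for
unit charges at 1 Å, zero beyond cutoff, continuity at both switch ends).
Residue groups default to whole residues; a side-chain-only flag exists
since the group convention is not fixed by the protocol.

# Conformational descriptors

χ₁–χ₄ side-chain dihedrals (where applicable) use the IUPAC sign convention
in (−180°, 180°], cross-checked against an independent torsion
implementation.  Inter-residue distances use fixed measurement atoms: the
polar side-chain oxygen for Tyr/Ser/Thr, NZ for Lys, both ND2 and OD1 for
Asn (two series), CE1 for His, the carboxyl carbons CG/CD for Asp/Glu.
Distance histograms default to 0.1 Å bins and dihedral distributions to 5°
bins (unstated in the protocol; chosen at the scale of coordinate noise).
The up/down classifier labels a frame "up" when the Cα→rule-atom vector has
a positive projection on the channel axis (oriented N-side → P-side, i.e.
toward the binuclear centre); zero projection is "down" — a hard,
parameter-free boundary (a configurable dead zone exists).  This is an
explicit operationalisation of a qualitative notion; distance-based
signatures should be reported alongside rather than asserted equivalent.

# Protonation models

Simulation variants are indexed by a 4-digit binary code for the protonation
of D132, E286, K362 and E101 (1 = protonated), optionally suffixed `a`–`f`
for a hydronium ion held at one of six heights in the K-channel (its oxygen
stationary; K362 and E101 unprotonated in those models, so the digit tail is
`00`).  The full universe has 16 + 4×6 = 40 codes; `*` wildcards expand
against it (`*b` → 4 models, `01*` → 10, `****` → 40).  The positions a–f
carry their distances to the Y288 Cα (23.4, 19.1, 15.5, 12.8, 10.4, 7.3 Å).

# The synthetic generator

The generator emulates exactly the features the pipeline measures, with
exact ground truth:

* **Geometry** — two rings of single-atom corner pseudo-residues (12 per
  ring, circumradius 9 Å) whose hull is a regular prism; the ring separation
  is chosen so the 10 %-elongated axis hits the 30 Å cap exactly and the
  cylinder covers 15 full slices.  Channel waters are placed within 6 Å of
  the axis (inside both hull and cylinder by construction) with a 1.4 Å
  excluded-volume radius between oxygens.
* **Occupancy** — each water is assigned a slice and stays in it:
  `resample` mode redraws positions i.i.d. every frame (censuses are exact
  by construction; used by tests), `diffuse` mode runs a reflected random
  walk (step σ 0.5 Å) inside the slice (realistic frame-to-frame
  correlation; used in demos).  Bulk waters live in a far annulus, outside
  everything.
* **Kinetics** — probe residues sit outside the channel wall with a
  dedicated partner water.  A two-state continuous-time Markov chain
  (formation rate k_on, breaking rate k_off; mean bonded dwell 1/k_off;
  stationary start) is simulated by alternating exponential sojourns and
  discretised at the frame interval; when "on", the partner water is placed
  in perfect bond geometry (collinear, 2.8 Å), when "off" at 6 Å.  The
  pipeline's detector reproduces the Markov indicator frame-for-frame.
  Defaults follow the production protocol: 2 ps saving interval; lifetime
  tests run 160 ns × 3 replicas (the post-equilibration window of a 200 ns
  run after discarding 40 ns).
* **Hydronium** — for models `a`–`f` a hydronium oxygen is held stationary
  on the axis; the real positions are defined by distances to the Y288 Cα,
  which the toy maps to fractional heights from the channel top
  (distance/30 × height) — a toy convention, stated as such.

What the generator does **not** emulate: force-field physics, realistic
water structure and orientation correlations, protein flexibility, channel
gating, or wrapped periodic coordinates.  Passing tests demonstrate the
correctness of the measurement machinery, not the biology of any particular
channel.

# Numerical choices and problem sizes

* Hull tolerances scale with geometry (1e-9 × diameter); membership
  tolerance 1e-9 Å absolute.
* Frame times start at 0, so a 200 ns run saved every 2 ps has 100,000
  frames and discarding t < 40 ns keeps exactly 80,000.
* Slice indices are 1-based in the R API (`NA` = outside).
* The test suite and the acceptance script use 20 random 17-corner hulls ×
  10⁶ Monte-Carlo samples, 50 random 500-water frames for detection, 160 ns
  × 3 replicas of Markov kinetics for lifetime recovery, and 300–500-frame
  toy trajectories for censuses — sizes at which every oracle is exact or
  its sampling error is far below the asserted tolerance.
* All randomness flows from a single seed per generated system; identical
  seeds give bit-identical topologies, trajectories and ground truth.

# Known limitations

* Per-pair PME electrostatics are out of scope (see above); energies are
  comparable in trend only.
* No gap-tolerant (intermittent) hydrogen-bond correlation variant; the
  strict-persistence definition is the only one implemented.
* No tunnel-finding (CAVER/HOLE-style) geometry: the polyhedron requires
  corner residues chosen by the analyst.
* The DCD writer/reader pair targets the CHARMM/NAMD 32-bit dialect only;
  XTC/TRR are unsupported.
* Whether hydrogens or solvent belong in the median-structure selection is
  genuinely unstated in the protocol; the selection is an explicit argument
  (defaulting to the channel's corner-residue atoms) rather than a guess.
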