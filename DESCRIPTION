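Package: channelflow
Title: Hydration and Hydrogen-Bond Network Analysis of Protein Proton Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of water and hydrogen-bond dynamics in the proton-uptake
    channels of membrane proteins from molecular-dynamics trajectories.
    Defines a channel as the convex polyhedron spanned by the centres of mass
    of user-declared corner residues, counts water molecules inside it frame
    by frame, envelops it with a sliced cylinder to resolve hydration along
    the channel axis, detects hydrogen bonds by the standard geometric
    criterion, estimates hydrogen-bond lifetimes from a strict-persistence
    time autocorrelation with a bi-exponential fit, and computes
    water-mediated connectivity between key residues via per-frame
    shortest-path graphs.  Side-chain conformational descriptors, pairwise
    switched-Coulomb interaction energies, protonation-state bookkeeping and
    a ground-truth synthetic trajectory generator complete the pipeline, so
    every stage is testable without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
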