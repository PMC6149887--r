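Package: higadock
Title: History-Guided Genetic Algorithm Search for Protein-Ligand Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a Lamarckian genetic algorithm for protein-ligand
    docking search that is guided by its own running history: an
    elite-parent-preserving crossover (CE), a mutation operator directed
    along the difference between the historic best and second-best
    solutions (ED), and a binary-space-partitioning archive that
    guarantees no genome cell is evaluated twice.  Provides plain GA and
    Lamarckian GA baselines over a shared budget protocol, a pluggable
    objective layer (AutoDock-style grid-map interpolation, a pairwise
    Lennard-Jones/Coulomb toy energy, analytic benchmark landscapes),
    readers and writers for ligand PDBQT and AutoDock grid-map text
    formats, post-run analytics (RMSD success rates, energy-ordered
    conformation clustering, convergence traces, distribution summaries),
    and deterministic fixture generators so every analysis runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
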