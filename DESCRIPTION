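Package: trajnet
Title: Trajectory Network and Domain-Detachment Analysis for Multi-Domain Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of multi-domain
    proteins, centred on the detachment of a regulatory domain from a
    catalytic subunit as seen in the PI3Kalpha E545K oncogenic mutant.
    Provides topology/trajectory ingestion (PDB, GRO, DCD, multi-model PDB),
    inter-domain geometric observables (RMSD, RMSF, centre-of-mass distances,
    hinge angle, solvent-accessible surface area), hydrogen-bond and
    salt-bridge occupancy tables, distance-fluctuation (plasticity) maps,
    correlation-weighted dynamical network analysis (Girvan-Newman
    communities, critical inter-community edges, optimal communication
    paths), stepwise detachment-event annotation, and a synthetic-trajectory
    generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, bio3d, igraph, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
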