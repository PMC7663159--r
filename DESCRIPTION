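Package: dyndist
Title: Dynamic-Distance Constrained Molecular Dynamics and Free-Energy
    Analysis of Metal-Mediated DNA Base Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the dynamic-distance collective variable (a
    reduced-mass-weighted root-mean-square over a set of non-overlapping
    atom-pair distances), a velocity-Verlet molecular dynamics engine with
    an exact holonomic constraint on that variable (SHAKE/RATTLE on a
    scalar collective variable), Nose-Hoover chain and Langevin
    thermostatting, simulated annealing, and blue-moon thermodynamic
    integration of the mean constraint force over stepped constraint
    windows.  A coarse-grained builder constructs parallel-stranded DNA
    duplex models bearing a dinuclear Hg(II)-mediated thymine:
    1,N6-ethenoadenine base pair, and a synthetic classical energy model
    with a bistable Hg coordination surface stands in for electronic
    structure engines.  Trajectory analyses cover Hg bonding-pattern
    classification (NO/NN coordination isomers), coordinate-bond and
    C1'-C1' distances, amino-group pyramidalization and turnstile
    dihedral tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
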