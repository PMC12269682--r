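Package: fwdyn
Title: Antibody Framework Mutational Scanning and Trajectory Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computational antibody framework engineering: saturated
    per-position mutational scanning with wild-type rank statistics, stability
    (ddG) based filtering of candidate double mutants against repertoire
    occurrence, geometric descriptors of antigen engagement and VH-VL domain
    packing from molecular dynamics ensembles, geometric classification of
    non-covalent interactions (hydrogen bonds, pi-pi stacking, CH/NH-ring)
    with differential residue interaction networks, and structural-alphabet
    mutual-information coupling analysis that calls antigen-binding-associated
    hub fragments from bound versus unbound ensembles. Includes seeded
    synthetic-data generators for every pipeline stage and a config-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    limma,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'contacts.R'
    'coupling.R'
    'fwdyn-package.R'
    'geomdyn.R'
    'mutscan.R'
    'pipeline.R'
    'structio.R'
    'synthdata.R'
    'utils.R'
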