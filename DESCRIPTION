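Package: lumpnet
Title: Minimal Biosynthetic Subnetworks and Balanced Lumped Reactions for
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing the biomass reaction of a genome-scale
    metabolic model into individual building blocks, finding the smallest
    balanced subnetworks of non-core reactions able to synthesize each
    building block from a user-defined core network (a mixed-integer linear
    program with binary reaction gating), enumerating alternative subnetworks
    with integer cuts, collapsing each subnetwork into a single elementally
    balanced lumped reaction via L1 net-flux minimization, ranking alternative
    lumps by carbon-mole yield, and assembling reduced core models whose
    growth approximates the parent model.  Models are read and written in
    BiGG-dialect JSON and SBML Level 3 (FBC).  Linear and mixed-integer
    programs are solved with the HiGHS solver through a bundled SciPy worker
    script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.9) with numpy and scipy (>= 1.9) on the
    PATH (used for LP/MILP solving via HiGHS)
Config/testthat/edition: 3
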