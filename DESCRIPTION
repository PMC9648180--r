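Package: cirdm
Title: Spin-Free Reduced Density Matrices from Configuration Interaction
    Wavefunctions
Version: 0.1.0
Authors@R:
    person("cirdm", "developers", email = "cirdm@example.org",
           role = c("aut", "cre"))
Description: String-based full configuration interaction (FCI) with bitwise
    Slater-Condon rules, Davidson iterative diagonalization, truncated CI(n),
    and Monte Carlo configuration interaction (MCCI) selected CI, together
    with efficient construction of spin-free one- and two-electron reduced
    density matrices (1-RDM, 2-RDM) from the resulting determinant
    expansions.  Includes FCIDUMP integral input/output with frozen-core
    folding, Loewdin spin projection of configuration state functions onto
    Slater determinant expansions, symmetry-adapted determinant-space
    counting by per-irrep string histograms, multireference-character and
    unnormalized error metrics, and a command-line interface with
    deterministic toy-fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
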