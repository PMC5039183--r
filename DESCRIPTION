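Package: hodgeflow
Title: Hodge Decomposition of Information Flow on Small-World Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates random threshold networks on Watts-Strogatz
    small-world graphs, estimates per-link information flow with the
    transfer entropy, and decomposes the resulting skew-symmetric edge
    flow into gradient, harmonic and curl components via the
    combinatorial Hodge decomposition. Includes the structural
    (rank-based) counterparts of the component ratios, closed-form
    predictions for the Watts-Strogatz ensemble, damage-spreading
    diagnostics of the dynamical phase, the small-world index omega,
    and an ensemble sweep over the rewiring probability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
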