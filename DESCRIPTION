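Package: beeknock
Title: Bees-Algorithm Search over ROOM-Scored Gene Knockouts for
    Growth-Coupled Metabolite Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico strain design by combinatorial gene-knockout search
    on constraint-based metabolic models. A Bees Algorithm explores binary
    knockout genotypes over the reaction list of a genome-scale model; each
    candidate is scored by regulatory on/off minimization (ROOM), a mixed
    integer linear program that predicts the mutant flux distribution
    minimizing the number of significant flux changes from a parsimonious
    wild-type reference. Includes SBML (Level 3 fbc) and COBRA JSON model
    readers, flux balance analysis with a production envelope evaluator for
    post-hoc validation of knockout lists, deterministic toy-network
    fixtures with brute-force oracles, and a performance-measurement
    protocol over repeated seeded runs. Linear programs are solved by a
    built-in bounded-variable two-phase simplex; the ROOM integer program
    by branch and bound on top of it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
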