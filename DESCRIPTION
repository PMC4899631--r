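Package: shmrep
Title: Somatic Hypermutation Analysis of B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic hypermutation (SHM) in immunoglobulin
    heavy-chain repertoires sequenced against a single germline V segment.
    Reads are aligned to the germline reference, filtered for productivity and
    germline identity, partitioned into clones by their CDR3 junction, and
    collapsed to per-clone consensus sequences so that shared mutational events
    are counted once. Mutations are classified by transition/transversion
    class, AID hotspot/coldspot 5-mer context (WRC/GYW, WA/TW vs SYC/GRS), and
    replacement/silent effect per variable-region subregion; background
    adjusted 5-mer mutabilities ("hedgehog" data) are estimated from clone
    consensuses. Germline-rooted clonal lineage trees with inferred
    intermediates are reconstructed by a minimum-mutation heuristic and
    exported as Newick. Companion utilities estimate plasma-cell half-lives
    from decay time courses by log-linear regression, compare decay slopes,
    and compute virus neutralization titres from optical-density tables. A
    fully parameterised synthetic-repertoire generator with ground-truth
    tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
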