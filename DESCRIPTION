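Package: mirbns
Title: miRNA Target-Site Discovery and Affinity Estimation from RNA Bind-n-Seq
Version: 0.1.0
Authors@R: person("RBNS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing RNA Bind-n-Seq (RBNS) experiments with
    miRNA-loaded Argonaute (RISC). Implements a formal grammar of miRNA
    target-site types (canonical seed matches, wobble, mismatch, bulge,
    deletion, centered and 3'-only sites), read quality filtering and
    adapter removal, de novo binding-site discovery by iterative 10-mer
    enrichment with masking, maximum-likelihood estimation of absolute
    dissociation constants across a RISC concentration series with
    self-consistent free-RISC concentrations, closed-form equilibrium
    binding isotherms (stoichiometric titration, direct binding,
    competition) with least-squares fitting, nearest-neighbor RNA duplex
    free energies with predicted dissociation constants, flanking
    dinucleotide context partitions, and site accessibility scoring from
    unpaired-probability profiles. Includes an equilibrium-selection
    simulator that reproduces the statistical structure of RBNS libraries
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
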