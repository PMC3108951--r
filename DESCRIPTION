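Package: mirddg
Title: Energy-Based MicroRNA Target Prediction with Relaxed Seed Requirements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores candidate microRNA target sites in 3'UTRs by the
    thermodynamics of stepwise duplex formation, without conservation or
    strict seed-match requirements. Sites are seeded by a perfect 4-nt
    Watson-Crick nucleus inside the miRNA seed region (positions 2-8),
    scored by hybridization energy (constrained cofolding of the miRNA
    with its local UTR context), disruption energy (RT log unpaired
    probability of the local target region, averaged over sliding
    windows), and their difference (the total energy of duplex
    formation). Includes the full seed-type taxonomy with G-U wobbles
    treated as mismatches, dinucleotide-shuffled control miRNAs, per-UTR
    energy feature summaries, a cross-validated linear model of
    miRNA-induced expression change, and ROC / rank-sum / enrichment
    evaluation utilities. A deterministic toy thermodynamics engine
    ships for testing; a ViennaRNA command-line adapter provides real
    folding energetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
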