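Package: crisprdesk
Title: Desk-Scale CRISPR-Cas9 Guide RNA Design with an Event-Driven Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Candidate guide RNA (gRNA) discovery and quality assessment for
    SpCas9 genome editing, runnable entirely on a workstation. Extracts all
    NGG protospacer-adjacent motif (PAM) sites from a gene or genome on both
    strands, scores genome-wide off-target risk with an inverted
    signature-slice-list (ISSL) Hamming-neighbour index over 2-bit encoded
    spacers, filters candidates with a consensus of rule-based on-target
    methods, and coordinates the stages through an event-driven engine of
    message queues and stateless batch workers that mirrors a serverless
    execution contract (byte-range chunked genome ingest, per-stage queues,
    resource limits, idempotent redelivery, scale-from-zero). Includes a
    synthetic-data module that generates random genomes with controlled GC
    content, planted off-target families at exact mismatch distances, and
    artificial genes containing a precise number of guides.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
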