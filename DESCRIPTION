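Package: methylgate
Title: Input-Template Gating for PCR-Based DNA Methylation Assays
Version: 0.1.0
Authors@R:
    person("Methylgate", "Developers", email = "maintainer@methylgate.dev",
           role = c("aut", "cre"))
Description: Tools to detect and prevent false-negative DNA methylation
    calls caused by insufficient PCR input template in bisulfite-PCR
    assays (MethyLight, MSP, DHPLC). Implements qPCR plate parsing and
    replicate aggregation, two-axis serial-dilution array bookkeeping,
    estimation of the methylated-template detection limit by the
    full-replicate rule, derivation of a minimum input-template (TAIT)
    policy (per-reaction nanograms, reference-gene Ct threshold, total
    DNA requirement), informative-sample gating and methylation calling,
    re-analysis workflows, cohort rate and group-difference statistics,
    and a stochastic single-molecule simulator of low-template qPCR for
    validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
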