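Package: famsearch
Title: Simulation-Based Evaluation of Familial DNA Database Search Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate likelihood-ratio based familial searching of
    forensic DNA databases, modelled on the two-threshold protocol used by the
    state of California. Simulates pairs of relatives (parent-offspring through
    second cousins) and unrelated individuals at the 13 core CODIS autosomal
    STR loci with background coancestry, together with patrilineally shared
    17-marker Y-STR haplotypes; computes autosomal kinship likelihood ratios,
    Y-haplotype likelihood ratios based on upper confidence-limit haplotype
    frequencies, and the combined database-scaled statistic; and estimates
    power, false-positive and distant-relative misidentification rates by
    Monte Carlo, including demographic weighting of false-positive involvement
    and Y-haplotype subsample-uniqueness analyses. Includes a synthetic
    population-panel generator so the full pipeline is testable without
    access to published reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
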