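Package: tetradose
Title: Allele Dosage Calling for Autotetraploid SNP Arrays with
    Multi-Population Mixture Models
Version: 0.1.0
Authors@R:
    person("tetradose", "developers", email = "tetradose@example.org",
           role = c("aut", "cre"))
Description: Automated allele-dosage calling (0-4) for biallelic SNP
    markers in autotetraploids from two-channel array fluorescence
    intensities.  For each marker a five-component normal mixture is
    fitted to arcsine-square-root transformed signal ratios by EM, with
    component means and variance shared across subpopulations while the
    mixing proportions follow per-population constraints: freely
    estimated, tetraploid Hardy-Weinberg equilibrium, fixed parental
    dosages, or F1 tetrasomic segregation ratios under random bivalent
    pairing.  Competing constraint combinations are compared by BIC, and
    called markers are quality-controlled by chi-squared matching of
    offspring dosage proportions against all parental-dosage
    combinations.  Includes a synthetic-data generator emulating a
    full-sib family with replicated parents plus an unstructured panel,
    and a batch driver with delimited-text input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    parallel
Config/testthat/edition: 3
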