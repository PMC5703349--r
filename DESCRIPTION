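Package: epimediate
Title: Two-Step Epigenetic Mendelian Randomization with DNA Methylation as
    Mediator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-step Mendelian randomization analyses that use
    DNA methylation as a putative mediator between a prenatal exposure and a
    later-life outcome. Step one instruments the exposure with a maternal
    genotype and scans the methylome for exposure-responsive CpG sites
    (covariate-adjusted linear regression, genomic-inflation diagnostics,
    false-discovery-rate control). Step two instruments methylation at the
    discovered sites with independent cis-mQTL variants (cis-window search
    and LD clumping) and estimates the causal effect of methylation on the
    outcome by the Wald ratio with delta-method standard errors, chaining the
    two steps into a mediated effect. A synthetic-cohort generator with
    recorded ground truth supports calibration and parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
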