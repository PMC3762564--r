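Package: rohmap
Title: Homozygosity Mapping of Recessive Loci in Inbred Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps autosomal-recessive disease loci in small, inbred
    case-control cohorts by combining per-marker allelic association with
    runs-of-homozygosity (ROH) detection, cross-case shared-segment
    intersection, haplotype-identity refinement, and recessive-model
    exclusion of loci carried homozygously by unaffected controls.
    Includes PLINK text PED/MAP and VCF genotype import, a sliding-window
    ROH caller, stop-loss (non-stop) variant consequence annotation on
    transcript models with isoelectric-point computation of the deduced
    protein, genotype-phenotype segregation tables, and a seeded
    synthetic-cohort generator with planted identical-by-descent loci for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
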