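Package: sdgdrive
Title: Population Genetics of CRISPR Sex-Distorter Gene Drives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic population-genetics models for an
    autosomal CRISPR homing gene drive coupled to an X-shredder sex distorter
    (SDGD), as used to design suppression drives against Anopheles gambiae.
    Implements the discrete-generation genotype-frequency recursions over the
    18 female and 12 male genotypes arising from three target-site alleles
    (wild type, drive, resistant) and damaged-X chromosome states; a finite
    cage-trial simulator with multinomial mating, egg laying, hatching and a
    larval bottleneck; and a continuous-time density-dependent population
    model for field-release predictions. Includes estimation of transmission,
    sex-distortion and fitness parameters from phenotypic assay tables, and
    synthetic-data generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
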