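Package: karyotrans
Title: Meiotic Segregation, Sex-Linked Haplotypes and Drift for an
    X-Autosome Reciprocal Translocation System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the chromosome-1/chromosome-6 reciprocal translocation
    polymorphism of the spiny frog Quasipaa boulengeri and the genetics used
    to show that the translocation arose on an X chromosome. Provides
    karyomorph classification (types I-V) from chromosome forms (M/T/m/St),
    meiotic gamete enumeration for translocation heterozygotes, exact cross
    distributions and per-sex karyomorph reachability closures under
    competing sex-linkage hypotheses, marker-dosage predictions for long-arm
    versus short-arm locus placement, a constructive simulator of sex-linked
    microsatellite haplotype cohorts (Y/Xn/Xr classes), neighbour-joining
    haplogroup inference with bootstrap and composition-based clade
    labelling, consistency scoring of hypotheses against observed cohorts,
    and forward-time Wright-Fisher drift of the chromosomal polymorphism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
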