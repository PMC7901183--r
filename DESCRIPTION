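Package: cfmix
Title: Deconvolution of Multi-Genome Cell-Free DNA Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting maternal plasma cell-free DNA that mixes
    several genetic sources, such as donor-derived hematopoietic DNA after a
    bone-marrow transplant, residual maternal DNA, and placental DNA from a
    donor-egg pregnancy. Provides sex-chromosome dosage arithmetic for
    component-fraction estimation, maximum-likelihood joint genotyping of
    two- and three-genome mixtures (pseudo-tetraploid and pseudo-hexaploid
    models), the match-ratio statistic (mrs) for pairwise relatedness with
    relationship classification, identity-by-state distances with classical
    multidimensional scaling, and a synthetic-data generator that emulates a
    targeted SNP capture panel and the pedigree structure of such a case.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
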