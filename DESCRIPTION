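Package: troykascan
Title: Structural Characterization of Troyka LTR Retrotransposons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo structural annotation of Troyka-superfamily LTR
    retrotransposons: single-linkage clustering of genomic repeat copies at
    75% coverage / 75% identity, 50% majority-rule consensus reconstruction
    with iterative flank elongation, joint LTR/TSD boundary calling, terminal
    pentamer signature classification (5'-CGCCA...TGGCG-3' versus canonical
    5'-TG...CA-3' termini), CCHC zinc-finger motif scanning, recent-activity
    screening, and pre-insertion (empty-site) reconstruction with orthologous
    locus validation in sibling genomes. Includes a synthetic-genome
    simulator that plants elements with known coordinates and target site
    duplications so every stage of the pipeline can be tested against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
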