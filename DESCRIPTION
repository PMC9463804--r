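Package: chimeraScreen
Title: Post-Processing, Classification and Quantification of Chimeric RNA
    Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising candidate chimeric RNAs (fusion
    transcripts) downstream of a fusion caller: a filtering cascade
    (confidence score, junction-class, normal-tissue blacklist,
    normal-sample subtraction, flank-homology screen), classification of
    each candidate by junction position (E/E, E/M, M/E, M/M), genomic
    relation (read-through, intra- and inter-chromosomal) and predicted
    reading frame, group-specific chimera set derivation,
    junction-spanning read counting by bit-parallel approximate string
    matching with k allowed errors, neuroendocrine-activity and
    chimeric-RNA product scores with HIGH/LOW stratification, and fusion
    ORF/protein isoform prediction. Includes a fully deterministic
    synthetic-data generator (genome, annotation, planted fusions of
    every category, decoys and junction-spanning reads) with complete
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
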