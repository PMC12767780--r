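Package: pepregnet
Title: Comparative Transcriptional Regulation of Neuropeptides and Their
    Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for comparing the transcriptional control of
    neuropeptide (NP) and neuropeptide-receptor (NPR) genes in Drosophila
    melanogaster. Provides cis-regulatory feature summaries (TFBS hotspot
    areas, cis-regulatory modules, ChIP peaks) with paired and unpaired
    class comparisons; tree-ensemble TF-to-target importance inference and
    motif-pruned regulons with rank-AUC per-cell activity scoring;
    exclusive-cell TF network construction and complexity comparison across
    tissues; age-stratified top-k importance ranking; 2^-ddCt qPCR relative
    quantification; Kolmogorov-Smirnov-gated test routing with bootstrap
    estimation statistics; and a seeded synthetic-data generator with
    planted ground truth so the whole pipeline is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    jsonlite,
    methods,
    nortest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
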