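Package: mtleo
Title: Mitochondrial Lifetime Energy Output and Comparative Lifespan Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative analyses relating mammalian maximum lifespan
    to mitochondrial metabolism and to the amino-acid composition of the
    mtDNA-encoded membrane proteins. Extracts four amino-acid variables
    (Ser, Thr and Cys contents and mean hydropathy of hydrophobic domains)
    from protein sequences via a windowed Kyte-Doolittle hydropathy profile,
    derives an alpha-parameterized per-mitochondrion metabolic rate from the
    allometric scaling of basal metabolic rate, selects alpha by minimizing
    the dispersion of lifetime energy output, fits weighted log-linear
    lifespan models with stratified per-clade variants, derives phylogenetic
    branching weights from trees, and generates fully synthetic study data
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
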