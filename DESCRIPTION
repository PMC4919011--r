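Package: epiwalsh
Title: Higher-Order Epistasis via Weighted Walsh-Hadamard Transforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies epistasis of all orders in combinatorially complete or
    partially observed binary genotype-phenotype data.  Mutant-cycle
    (reference-based), background-averaged (ensemble) and truncated-regression
    interaction coefficients are computed as weighted Walsh-Hadamard transforms
    of the phenotype landscape, with element-wise error propagation, partial
    background averaging for datasets complete only up to a given mutation
    order, least-squares estimation from incomplete data, and l1-based sparse
    recovery of epistatic spectra from subsampled landscapes.  Includes a
    synthetic-landscape simulator and the PDZ-ligand binding and Shaker
    potassium-channel gating case studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, glmnet
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
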