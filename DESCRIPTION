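Package: breedtrace
Title: PCA-Informative SNP Panels for Hierarchical Breed Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Selects small panels of PCA-informative SNP markers (PCAIMs) from
    diploid genotype data, removes linkage-disequilibrium redundancy by greedy
    column subset selection, organises breeds into a hierarchical decision tree
    by recursive clustering along significant principal components, assigns
    individuals to breeds by five-nearest-neighbour voting in principal-component
    space, and evaluates the whole procedure by complete leave-one-out
    cross-validation. Includes a Balding-Nichols multi-breed genotype simulator
    with tunable per-branch FST, missingness and redundant marker blocks, plus
    PLINK-style PED/MAP text input and output, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
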