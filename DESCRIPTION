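Package: ecostream
Title: Streaming Taxonomic Distinctness and Chunk-Invariant Permutation
    Tests for Community Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomic diversity and distinctness indices (Delta, Delta*,
    Delta+, Lambda+) computed in a streaming, block-wise fashion that never
    materializes the full species-by-species taxonomic distance matrix, so
    species pools of any size can be analysed on a desktop. Community
    dissimilarity tests (ANOSIM, one-way PERMANOVA, Mantel and partial
    Mantel, SIMPER) and BioEnv environmental subset search run through a
    chunked, reproducibly seeded permutation engine whose results are
    invariant to the number of workers and the chunk layout. Includes
    funnel-plot expectations for Delta+, a synthetic community data
    generator, strict CSV readers for the four standard input file kinds,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
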