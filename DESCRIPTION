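Package: rxncurate
Title: Curation and Benchmarking of Chemical Reaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning noisy chemical reaction records into
    machine-learning-ready benchmark datasets. Assigns reaction roles
    (reactant, product, solvent, agent) from atom-mapped reaction SMILES
    using heavy-atom map bookkeeping, resolves molecule names and
    canonicalizes SMILES via OpenBabel, applies a configurable cleaning
    ladder (component-count limits, yield sanitization, frequency
    filtering of rare spectators, deduplication, leakage-aware grouped
    splits), assembles forward-, retrosynthesis- and condition-prediction
    benchmarks with equivalent-SMILES augmentation and lossless
    tokenization, and evaluates condition predictions with order-invariant
    top-k exact-match combination accuracy and the average improvement
    over a frequency-informed baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
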