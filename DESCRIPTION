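Package: modalhmm
Title: Multi-Source Fusion of School-District Learning Modalities with a
    Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fuses conflicting, incomplete weekly reports of school-district
    learning modality (fully remote, hybrid, fully in-person) from multiple
    surveillance sources into a weekly consensus modality with a confidence
    score, using a categorical hidden Markov model with one emission matrix
    per source and explicit handling of missing observations. Provides
    Baum-Welch estimation over many independent district sequences, posterior
    and Viterbi decoding, majority-report resolution of hidden-state label
    switching, pairwise source-agreement statistics with paired one-sided
    t-tests, weekly modality-share trend tables (overall, by state, and by
    urban-rural class), and a synthetic multi-source panel generator with
    realistic per-source coverage for end-to-end parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
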