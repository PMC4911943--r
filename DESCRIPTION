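Package: taxalign
Title: Logic-Based Alignment of Taxonomic Concept Hierarchies with RCC-5
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aligns two taxonomic concept hierarchies ("name sec. author"
    classifications) that are articulated by expert Region Connection
    Calculus (RCC-5) statements. Encodes an alignment problem over candidate
    Euler regions, decides logical consistency under the nonemptiness,
    sibling-disjointness and coverage constraints, enumerates possible
    worlds, infers the Maximally Informative Relations (MIR) for every
    cross-taxonomy concept pair, diagnoses inconsistent inputs, renders
    merge taxonomies as DOT graphs, and computes name:meaning reliability
    statistics. Includes a brute-force occupancy oracle for verification,
    synthetic taxonomy-change generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
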