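Package: seedmix
Title: Trait-Based Seed Mix Design for Multifunctional Farmland
    Vegetative Strips
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evidence-informed design of seed mixes for farmland
    vegetative strips (field margins, watercourse buffers) that support
    several ecosystem services at once: water quality protection, pollinator
    support and crop-pest natural enemies. Candidate plant species are read
    from a trait table, gated on establishment criteria (perennial life
    history, native status, good regional distribution), scored against
    declarative ordinal rubrics that map functional traits (floral display
    size, leaf trichome density, leaf area, root system, leaf phenology,
    soil suitability, Grime CSR strategy, maximum height, associated
    floristic diversity) to rank points, ranked with deterministic
    tie-breaking, and assembled into seed mixes under growth-form
    composition, commercial availability and flowering-phenology coverage
    constraints. Includes a seeded synthetic trait-table generator with an
    independent scoring oracle for validation, packaged case-study fixtures,
    a YAML-configured end-to-end pipeline and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
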