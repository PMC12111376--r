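Package: hygrostab
Title: Moisture-Driven Shelf-Life Modelling for Hygroscopic Food Powders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for storage-stability studies of dry food powders such as
    instant coffee. Fits GAB moisture-sorption isotherms and Gordon-Taylor
    glass-transition curves, combines them into a modified state diagram with
    critical water activity and critical moisture at a storage temperature,
    fits first-order storage kinetics (moisture uptake, dissolution, pH decay)
    and solves times-to-threshold, computes an RGB-threshold freshness index
    from powder images, and runs the one-way and repeated-measures ANOVA with
    Tukey HSD compact letter displays customary in such studies. A seeded
    synthetic-study generator produces complete datasets with the statistical
    structure of a three-humidity storage experiment for validation and
    teaching.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
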