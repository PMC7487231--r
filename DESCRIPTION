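Package: trophicniche
Title: Trophic Niche Analysis from Fecal Contents, Stable Isotopes, and
    Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible workflow for quantifying trophic niches of
    sympatric consumers from two complementary data streams: fecal-content
    tables and blood stable-isotope values (delta13C, delta15N).  Computes
    prey-specific diet indices (FO, N, PN, V, PV, PSIRI), trophic-guild
    classification, Levins' niche breadth and Pianka's overlap, Bayesian
    stable-isotope mixing models with trophic discrimination factors,
    small-sample-corrected standard ellipse areas (SEAc) and their overlap
    in delta-space, and weighted consumer-resource bipartite networks built
    from both diet and mixing-model outputs, with weighted nestedness
    (WNODF), standardized Kullback-Leibler specialization (d'), and
    vaznull-style null-model significance tests.  Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
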