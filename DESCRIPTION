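Package: peristroma
Title: Peritumoral Stroma Delineation from Collagen Fiber Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of collagen organization and T-cell
    distribution around tumor-cell clusters in second-harmonic-generation
    (SHG) and immunofluorescence imagery. Delineates individual peritumoral
    stroma regions from the distance-resolved fraction of collagen fibers
    oriented parallel to the tumor borderline, quantifies T-cell density and
    distribution coefficients per region, summarises per-fiber collagen
    parameters (length, width, straightness, axial alignment, density), and
    analyses in-vitro T-cell track velocity and axial directionality on
    aligned collagen matrices. Includes seeded synthetic-data generators for
    tumor masks, fiber fields, T-cell masks and migration tracks so the whole
    pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    EBImage,
    jsonlite,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
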