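Package: fuzzimg
Title: Fuzzy-Logic Local Contrast Enhancement for Grayscale Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A twelve-step fuzzy-logic enhancement pipeline for 8-bit
    grayscale medical images (CT, MRI, X-ray). Pixel intensities are
    normalized, fuzzified into membership degrees, refined, and used to
    drive an adaptive nonlinear local-contrast transformation whose
    per-pixel exponent is derived from one of three local-contrast
    characteristics: histogram spread, fuzzy entropy, or fuzzy standard
    deviation. Each input image yields three complementary enhanced
    variants, tripling a training corpus. Includes seeded synthetic
    phantom and neighborhood-archetype generators, PNG/TIFF/NIfTI I/O,
    a command-line interface, and simple no-reference quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
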