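# fuzzimg

Fuzzy-logic local contrast enhancement for 8-bit grayscale medical
images (CT, MRI, X-ray), for researchers preparing low-contrast
imagery for reading or for training downstream models. One input
produces **three** complementary enhanced variants, so a corpus of 300
images becomes 900 — useful both as preprocessing and as dataset
augmentation.

## The method

The pipeline runs in twelve steps. Intensities are normalized to
`u = f/255`, fuzzified through a sigmoid membership function
`μ = 1 / (1 + exp(−a(u − b)))` with `a = 10`, `b = 0.5`, and refined by
`μ' = μ^γ` (`γ = 1.2`); inverting these exactly yields the shared
fuzzy-enhanced base image. On that base, sliding 3×3 windows yield
three local-contrast characteristics —

* **histogram spread** `(f_max − f_min)/h_max` (range over the modal
  bin count),
* **fuzzy entropy** `−(1/(n² ln n²)) Σ [μᵢ ln μᵢ + (1−μᵢ) ln(1−μᵢ)]`
  with `μᵢ` the in-window frequency of each intensity,
* **fuzzy standard deviation**
  `sqrt(Σ (fⱼ − f̄_W)² μⱼ / Σ μⱼ)` weighted by the refined membership —

each mapped to a per-pixel exponent field `α(x, y) ∈ [α_min, α_max]`
(defaults `[0.5, 2]`, sensitivities `s = 1.5 / 2 / 1.2`). The base's
local-contrast map `C = (max − min)/255` is then transformed through a
two-branch power law pivoted at its mean `Ĉ` (sending
`C_min → 0, Ĉ → ½, C_max → 1`), and each pixel is reconstructed from
its window mean with gain `C*/max(C, 1/255)`. See the methods
vignette (`vignettes/fuzzy-enhancement.Rmd`) for the full model,
parameter meanings, and design notes.

## Worked example

The reference 2×2 image `[[100, 150], [200, 50]]` traced through
normalization, fuzzification and refinement:

```r
library(fuzzimg)
worked_example_trace()
#>   row col original normalized membership refined
#> 1   1   1      100     0.3922    0.25380 0.19293
#> 2   1   2      150     0.5882    0.70731 0.65998
#> 3   2   1      200     0.7843    0.94496 0.93432
#> 4   2   2       50     0.1961    0.04569 0.02465
```

Pixel 100 normalizes to 0.392; its sigmoid membership 0.2535 says it
sits below the "bright" midpoint, and refinement lowers it to 0.193,
widening the gap to the brighter pixels. Enhancing a low-contrast blob
phantom raises its RMS contrast under all three variants:

```r
ph <- make_phantom(height = 32, width = 32, background = 110,
                   blobs = list(list(center = c(16, 16), radius = 6,
                                     offset = 25)),
                   noise = "gaussian", noise_sd = 4, seed = 8)
tri <- enhance_image(ph)
rbind(evaluate_quality(list(original = ph), "rms_contrast"),
      evaluate_quality(tri$variants, "rms_contrast"))
#>       image  score
#> 1  original 0.0351
#> 2 histogram 0.1440
#> 3   entropy 0.1407
#> 4       std 0.1360
```

The scores are the standard deviation of unit-scaled intensities: the
phantom's contrast roughly quadruples, with the three variants
differing in how they spend the enhancement (the histogram variant
stretches the global distribution hardest, the entropy variant focuses
on uncertain regions, the standard-deviation variant on dispersion).

## Command line

```sh
inst/scripts/fuzzimg enhance --out enhanced/ scans/*.png     # 3 outputs per input + manifest.json
inst/scripts/fuzzimg synth --out fixtures/ --kind phantom --count 5
inst/scripts/fuzzimg eval --metric rms_contrast enhanced/*.png
inst/scripts/fuzzimg trace                                   # the 2x2 trace above
```

`enhance` accepts PNG, TIFF and NIfTI volumes (sliced axially), takes
a YAML/JSON `--config` merged under explicit flags, and exits 0 on
success, 1 on partial failure, 2 on usage error.

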