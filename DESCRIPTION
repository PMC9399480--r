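Package: nilescreen
Title: Analysis of GFP-Normalised Nile Red Fat-Content Screens in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for semi-automated anti-obesity compound
    screening in Caenorhabditis elegans. Ingests dual-channel (Nile Red,
    GFP) 96-well plate-reader exports and plate layout maps, computes
    GFP-normalised Nile Red fat scores, performs Z'-factor assay quality
    control on control strains, calls compounds from duplicate wells,
    runs the primary/secondary screening cascade with annotation-based
    deselection, confirms hits with Welch t-tests after min/max and
    Grubbs outlier trimming, compares compound effects across mutant
    genetic backgrounds, quantifies fat from landmark-anchored regions
    of fluorescence micrographs, and simulates whole screens with known
    ground truth for operating-characteristic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
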