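Package: eddyforage
Title: Collocation of Ship-Borne Acoustic Backscatter with Mesoscale Eddies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantifying the effect of mesoscale
    oceanic eddies on forage fauna observed by 38 kHz ship-borne acoustics.
    Collocates georeferenced NASC (Nautical Area Scattering Coefficient)
    vertical profiles with an eddy-trajectory atlas, computes per-eddy
    inside-versus-outside anomalies of backscatter, sea-surface temperature
    and chlorophyll, classifies each eddy's effect (increase, decrease, null)
    with rank-sum tests, relates effects to eddy characteristics, and grids
    the results spatially. Includes a synthetic eddy-ocean generator with
    known ground-truth effects so every stage is testable without external
    altimetry, satellite or sonar products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
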