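Package: voxtab
Title: Voxel Cellular-Automaton Dissolution and Disintegration of Multilayer Tablets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models disintegration and dissolution of single-, bi- and
    triple-layer oral tablets. Builds voxelized virtual tablets from layer
    formulations (true density, porosity, oval punch geometry), evolves them
    with a synchronous three-dimensional cellular automaton (liquid ingress,
    species-specific dissolution, surface erosion, impermeable inert layers),
    and analyses release profiles with the Noyes-Whitney first-order model
    (specific surface as the sole fitted coefficient) and the f2 similarity
    factor. Includes generators for synthetic formulations and noisy release
    profiles so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
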