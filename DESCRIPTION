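Package: budstarch
Title: Winter Chilling, Dormancy Release and Ovary Starch Densitometry in
    Stone-Fruit Flower Buds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools linking winter temperature to flower-bud physiology in
    temperate fruit trees such as sweet cherry. Implements hourly
    chill-unit (Utah model) and growing-degree-hour accumulation,
    forcing-test dating of endodormancy release and the derived chilling
    requirement, colour-threshold segmentation and summed-optical-density
    quantification of iodine-stained starch in ovary sections, ovary
    growth measurement (cell layers, diameter), and the statistical layer
    tying them together (one-way ANOVA, Duncan's multiple-range letter
    groups, windowed Pearson correlations of starch against chill and
    heat). A seeded synthetic-data generator emulates contrasting cold
    and mild winters, weekly forcing tests and stained-section images
    with known ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    tidyr,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
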