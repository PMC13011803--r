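Package: domlink
Title: Microbe-Dissolved Organic Matter Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links microbial community dynamics to the molecular composition of
    dissolved organic matter (DOM). Annotates molecular formulae with van
    Krevelen chemistry metrics (H/C, O/C, modified aromaticity index, compound
    classes, biolability), computes intensity-weighted bulk DOM descriptors,
    and implements distance-based community ecology from first principles
    (Bray-Curtis, PCoA, PERMANOVA, vector fitting, Procrustes/PROTEST, dbRDA).
    Screens formula-by-time and species-by-formula Spearman correlations with
    dataset-wide percentile thresholds and tests compound-class enrichment with
    exact multinomial and binomial tests. Includes a consumer-resource
    microcosm simulator with planted consumption/production links for
    end-to-end validation of the screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
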