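Package: soilqi
Title: Soil Quality and Sustainable Yield Indices for Long-Term Fertilization Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes composite soil quality indices (direction-aware min-max
    indicator scoring with principal-component communality weights) and the
    sustainable yield index for multi-year field trials, together with the
    supporting inferential layer: one-way ANOVA with compact letter displays,
    assumption checks, Pearson correlation matrices with significance stars,
    random-forest permutation importance, and index-on-index regression.
    Includes a synthetic-trial generator emulating a randomized complete block
    fertilization experiment (five treatments, six blocks, ten years) and a
    reproducible pipeline that writes all intermediate tables as plain CSV
    with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    car,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
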