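Package: kinfeed
Title: Household Kinship Networks and Complementary Feeding Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs ego-network structural variables (degree, Burt
    effective size, constraint, efficiency, hierarchy, density) and
    compositional diversity variables (index of qualitative variation,
    age standard deviation, de jure/de facto diversity) from household
    kinship rosters in a DHS-recode-like dialect; codes the WHO infant
    and young child feeding indicators Minimum Dietary Diversity and
    Minimum Meal Frequency from feeding-recall records; and estimates
    per-round survey-weighted and pooled random-intercept logistic
    associations with SD-scaled average marginal effects. Includes a
    calibrated synthetic household generator so the full pipeline is
    testable without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    arrow,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
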