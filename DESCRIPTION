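Package: nutricomp
Title: Compositional Analysis of Macronutrient Niches in Wild Omnivore Diets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the protein, carbohydrate and lipid composition of
    wild-population diets from scat (fecal) records via digestibility
    correction factors and metabolizable-energy conversion, and analyses the
    resulting three-part compositions in Aitchison simplex geometry:
    log-ratio transforms, closed geometric means and variation matrices,
    compositional principal components, sigma and confidence regions on the
    simplex, isometric log-ratio linear models with multivariate ANOVA and
    influence diagnostics, equilateral and right-angled mixture-triangle
    plotting, and a logistic-normal synthetic-study generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
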