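#' Published brown-bear diet composition reference values
#'
#' Closed geometric mean macronutrient energy fractions (protein `P`,
#' carbohydrate `C`, lipid `L`) of brown-bear population diets estimated
#' from literature scat studies, by season and by anthropogenic-subsidy
#' class (`combined` pools both classes; season `annual` is the
#' across-season aggregate). These printed values serve two roles: worked
#' examples for the log-ratio machinery, and default group-by-season means
#' for the synthetic study generator, so simulated studies mimic the group
#' structure observed in the wild.
#'
#' @format A tibble with columns `group` (combined / natural /
#'   anthropogenic), `season` (spring / summer / autumn / annual) and
#'   numeric parts `P`, `C`, `L` summing to 1.
#' @export
bear_diet_reference <- tibble::tibble(
  group = rep(c("combined", "natural", "anthropogenic"), each = 4),
  season = rep(c("spring", "summer", "autumn", "annual"), times = 3),
  P = c(0.422, 0.371, 0.208, 0.314,
        0.493, 0.447, 0.293, 0.405,
        0.351, 0.290, 0.142, 0.242),
  C = c(0.212, 0.293, 0.474, 0.347,
        0.159, 0.229, 0.408, 0.281,
        0.275, 0.372, 0.532, 0.406),
  L = c(0.366, 0.336, 0.318, 0.339,
        0.348, 0.325, 0.300, 0.314,
        0.374, 0.338, 0.326, 0.352)
)

#' Annual log-ratio variation reference values
#'
#' Pairwise log-ratio variances among protein, carbohydrate and lipid in
#' annual brown-bear population diets (literature estimate): carbohydrate
#' log-ratios are the most variable, protein and lipid the most
#' codependent. Used to calibrate the default simulation covariance.
#'
#' @format A symmetric 3 x 3 matrix with zero diagonal.
#' @export
bear_variation_reference <- matrix(
  c(0,     0.700, 0.197,
    0.700, 0,     0.577,
    0.197, 0.577, 0),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("P", "C", "L"), c("P", "C", "L"))
)
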