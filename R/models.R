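#' Linear model for compositions in ilr coordinates
#'
#' Fits ordinary least squares to each isometric log-ratio coordinate of
#' the response compositions with a shared design matrix (a multivariate
#' `lm`), the standard way to regress a composition on covariates. Factor
#' predictors use treatment coding; for seasonal analyses set the reference
#' level (e.g. spring) before fitting. Fitted values and residuals are
#' available on the simplex via [generics::augment()].
#'
#' @param data Data frame holding the part columns and all model factors.
#'   Rows with `season == "winter"` are dropped before fitting when a
#'   `season` column is present (winter diets are retained descriptively
#'   but excluded from inference), with a message.
#' @param formula Right-hand-side formula of model terms, e.g. `~ season`
#'   or `~ subsidy`.
#' @inheritParams comp_ilr
#' @return An object of class `comp_lm` wrapping the multivariate `lm`,
#'   with elements `fit`, `data` (rows used), `formula`, `parts`, `basis`.
#' @export
comp_lm <- function(data, formula, parts = comp_parts(data),
                    basis = ilr_basis(parts)) {
  .check_basis(basis, length(parts))
  if (!inherits(formula, "formula")) abort("`formula` must be a formula.")
  if (length(formula) != 2) {
    abort("`formula` must be one-sided (the composition is the response).")
  }
  data <- as_tibble(data)
  if ("season" %in% names(data) && any(data$season == "winter")) {
    nw <- sum(data$season == "winter")
    message(sprintf("Dropping %d winter row(s) before fitting.", nw))
    data <- data[data$season != "winter", , drop = FALSE]
  }
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "compositional linear model")
  Y <- .ilr_mat(m, basis)
  colnames(Y) <- rownames(basis)
  mf <- stats::model.frame(formula, data = data)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) <= ncol(X) + ncol(Y) - 1) {
    abort("Too few observations for the number of model terms.")
  }
  fit <- stats::lm(Y ~ X - 1)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(stats::coef(fit)[, 1])]
    abort(paste0(
      "Rank-deficient design; aliased term(s): ", paste(aliased, collapse = ", ")
    ))
  }
  coefs <- stats::coef(fit)
  rownames(coefs) <- colnames(X)
  structure(
    list(
      fit = fit, coefficients = coefs, data = data, formula = formula,
      parts = parts, basis = basis,
      terms = attr(stats::terms(formula, data = data), "term.labels")
    ),
    class = "comp_lm"
  )
}

#' @export
print.comp_lm <- function(x, digits = 4, ...) {
  cat("Compositional linear model (ilr coordinates)\n")
  cat("Formula: composition", deparse(x$formula), "\n")
  cat("Parts:", paste(x$parts, collapse = ", "),
      " N =", nrow(x$data), "\n\nCoefficients (ilr space):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
tidy.comp_lm <- function(x, ...) {
  sm <- summary(x$fit)
  if (!is.list(sm) || inherits(sm, "summary.lm")) sm <- list(sm)
  out <- purrr::imap(sm, function(s, i) {
    cf <- stats::coef(s)
    tibble(
      coordinate = rownames(x$basis)[i],
      term = rownames(x$coefficients),
      estimate = cf[, 1], std_error = cf[, 2],
      statistic = cf[, 3], p_value = cf[, 4]
    )
  })
  dplyr::bind_rows(out)
}

#' @export
glance.comp_lm <- function(x, ...) {
  tibble(
    n = nrow(x$data),
    df_residual = x$fit$df.residual,
    n_coordinates = nrow(x$basis),
    sigma_pooled = sqrt(sum(stats::residuals(x$fit)^2) /
                          (x$fit$df.residual * nrow(x$basis)))
  )
}

#' @export
augment.comp_lm <- function(x, ...) {
  fitted <- .ilr_inv_mat(stats::fitted(x$fit), x$basis)
  colnames(fitted) <- paste0(".fitted_", x$parts)
  out <- dplyr::bind_cols(as_tibble(x$data), as_tibble(fitted))
  out$.cooksd <- comp_cooks_distance(x)$cooks_d
  out
}

#' Back-transformed group mean compositions from a fitted model
#'
#' Evaluates the fitted ilr surface at each combination of the model
#' factors and back-transforms to the simplex. For a single-factor model
#' these equal the per-group closed geometric means.
#'
#' @param object A [comp_lm()] fit.
#' @return A tibble of factor combinations with part columns.
#' @export
comp_lm_means <- function(object) {
  vars <- all.vars(object$formula)
  grid <- unique(as_tibble(object$data)[vars])
  X <- stats::model.matrix(object$formula, grid)
  comp <- .ilr_inv_mat(X %*% object$coefficients, object$basis)
  colnames(comp) <- object$parts
  dplyr::bind_cols(grid, as_tibble(comp))
}

#' Multivariate ANOVA for a model term
#'
#' Tests a term of a compositional linear model jointly across all ilr
#' coordinates by comparing the full fit against the fit without that term
#' (Wilks' lambda by default, Pillai trace optionally), using the standard
#' multivariate-regression F approximation. The statistic and p-value are
#' invariant to the choice of orthonormal ilr basis and to part ordering.
#'
#' @param object A [comp_lm()] fit.
#' @param term Model term to test; defaults to the last term in the
#'   formula.
#' @param statistic `"Wilks"` or `"Pillai"`.
#' @return A one-row tibble: `term`, `statistic`, `value`, `f_value`,
#'   `df1`, `df2`, `p_value`.
#' @export
comp_anova <- function(object, term = NULL,
                       statistic = c("Wilks", "Pillai")) {
  statistic <- match.arg(statistic)
  if (!inherits(object, "comp_lm")) abort("`object` must be a comp_lm fit.")
  terms_all <- object$terms
  if (length(terms_all) == 0) abort("The model has no testable terms.")
  term <- term %||% terms_all[length(terms_all)]
  if (!term %in% terms_all) {
    abort(paste0("Term `", term, "` is not in the model (terms: ",
                 paste(terms_all, collapse = ", "), ")."))
  }
  reduced_rhs <- setdiff(terms_all, term)
  reduced_formula <- stats::reformulate(if (length(reduced_rhs)) reduced_rhs else "1")
  reduced <- comp_lm(object$data, reduced_formula, object$parts, object$basis)
  an <- stats::anova(reduced$fit, object$fit, test = statistic)
  row <- an[2, ]
  tibble(
    term = term,
    statistic = statistic,
    value = row[[statistic]],
    f_value = row[["approx F"]],
    df1 = row[["num Df"]],
    df2 = row[["den Df"]],
    p_value = row[["Pr(>F)"]]
  )
}

#' Univariate logit linear models per macronutrient
#'
#' The conventional cross-check to the compositional model: for each part,
#' an ordinary least-squares fit of the logit-transformed decimal
#' proportion on an ordered factor (polynomial contrasts), reporting the
#' linear-trend contrast. Proportions must lie strictly inside (0, 1).
#'
#' @param data Data frame with part columns and the ordered-factor column.
#' @param factor Name of the ordering factor column (e.g. `"season"`);
#'   its level order is taken as given (`spring < summer < autumn` for
#'   seasons).
#' @inheritParams comp_close
#' @param levels Optional explicit level order for the factor.
#' @return A tibble with one row per part: `part`, `linear_estimate`,
#'   `std_error`, `statistic`, `p_value`, plus a list-column `fit` of the
#'   underlying `lm` objects.
#' @export
logit_lm <- function(data, factor = "season", parts = comp_parts(data),
                     levels = NULL) {
  if (!factor %in% names(data)) {
    abort(paste0("Factor column `", factor, "` not found."))
  }
  m <- .closure_mat(part_matrix(data, parts))
  if (any(m <= 0 | m >= 1)) {
    abort("Proportions must lie strictly in (0, 1); see comp_replace_zeros().")
  }
  f <- data[[factor]]
  levels <- levels %||% (if (is.factor(f)) base::levels(f) else sort(unique(f)))
  of <- factor(f, levels = levels, ordered = TRUE)
  rows <- purrr::map(seq_along(parts), function(i) {
    y <- stats::qlogis(m[, i])
    fit <- stats::lm(y ~ of)
    cf <- stats::coef(summary(fit))
    lin <- grep("\\.L$", rownames(cf))
    tibble(
      part = parts[i],
      linear_estimate = cf[lin, 1],
      std_error = cf[lin, 2],
      statistic = cf[lin, 3],
      p_value = cf[lin, 4],
      fit = list(fit)
    )
  })
  dplyr::bind_rows(rows)
}

#' Cook's distance for a compositional linear model
#'
#' Influence of each observation on the fit, computed in stacked ilr
#' coordinate space: with hat value `h_i` from the shared design matrix,
#' squared ilr residual norm `||e_i||^2`, pooled residual variance `s^2`
#' and `p = (number of model columns) x (D - 1)` stacked parameters,
#' `D_i = ||e_i||^2 h_i / (p s^2 (1 - h_i)^2)`. A common screening
#' threshold is `4 / N`; the threshold is left to the user, as influence
#' was assessed visually in practice.
#'
#' @param object A [comp_lm()] fit.
#' @return A tibble with `row`, `population_id` (if present in the model
#'   data), `cooks_d`.
#' @export
comp_cooks_distance <- function(object) {
  if (!inherits(object, "comp_lm")) abort("`object` must be a comp_lm fit.")
  e <- stats::residuals(object$fit)
  h <- stats::lm.influence(object$fit, do.coef = FALSE)$hat
  q <- ncol(e)
  k <- object$fit$rank
  p <- k * q
  s2 <- sum(e^2) / (q * object$fit$df.residual)
  d <- rowSums(e^2) * h / (p * s2 * (1 - h)^2)
  out <- tibble(row = seq_along(d), cooks_d = unname(d))
  if ("population_id" %in% names(object$data)) {
    out$population_id <- object$data$population_id
    out <- out[c("row", "population_id", "cooks_d")]
  }
  out
}

#' Refit a compositional model without selected rows
#'
#' Sensitivity analysis helper: drops the given rows (e.g. the most
#' influential observation flagged by [comp_cooks_distance()], or a named
#' population) and refits the same model.
#'
#' @param object A [comp_lm()] fit.
#' @param rows Integer row indices into the model data to drop.
#' @param population Alternatively, `population_id` values to drop.
#' @return A new `comp_lm` fit.
#' @export
comp_lm_drop <- function(object, rows = NULL, population = NULL) {
  data <- object$data
  drop <- rep(FALSE, nrow(data))
  if (!is.null(rows)) drop[rows] <- TRUE
  if (!is.null(population)) {
    if (!"population_id" %in% names(data)) {
      abort("Model data has no `population_id` column.")
    }
    drop <- drop | data$population_id %in% population
  }
  if (!any(drop)) abort("No rows selected to drop.")
  comp_lm(data[!drop, , drop = FALSE], object$formula, object$parts, object$basis)
}

#' Macronutrient intake target
#'
#' The self-selected optimal diet of captive brown bears: 17% of
#' metabolizable energy from protein, with a +/- 4 percentage-point band,
#' the remainder from carbohydrate and lipid in any mixture.
#'
#' @param protein_fraction Target protein energy fraction (default 0.17).
#' @param band_halfwidth Half-width of the tolerance band (default 0.04).
#' @return A list of class `intake_target`.
#' @export
intake_target <- function(protein_fraction = 0.17, band_halfwidth = 0.04) {
  if (protein_fraction - band_halfwidth <= 0 ||
      protein_fraction + band_halfwidth >= 1) {
    abort("The target band must lie strictly inside (0, 1).")
  }
  structure(
    list(protein_fraction = protein_fraction, band_halfwidth = band_halfwidth),
    class = "intake_target"
  )
}

#' Compare diet compositions to the protein intake target
#'
#' Classifies each composition as `below`, `within` or `above` the protein
#' band of an [intake_target()] (band bounds inclusive) and reports the
#' signed gap between the protein fraction and the target.
#'
#' @inheritParams comp_close
#' @param target An [intake_target()].
#' @param protein Name of the protein part column (default the first part).
#' @return `data` with added columns `target_class` (factor
#'   below/within/above) and `protein_gap`.
#' @export
compare_to_target <- function(data, target = intake_target(),
                              parts = comp_parts(data), protein = parts[1]) {
  m <- .closure_mat(part_matrix(data, parts))
  p <- m[, protein]
  lo <- target$protein_fraction - target$band_halfwidth
  hi <- target$protein_fraction + target$band_halfwidth
  cls <- ifelse(p < lo, "below", ifelse(p > hi, "above", "within"))
  out <- as_tibble(data)
  out$target_class <- factor(cls, levels = c("below", "within", "above"))
  out$protein_gap <- unname(p - target$protein_fraction)
  out
}
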