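#' Metabolizable-energy conversion factors (kJ/g)
#'
#' Protein and available carbohydrate contribute 17 kJ of metabolizable
#' energy per gram; lipid contributes 37 kJ/g.
#'
#' @export
energy_kj_per_g <- c(P = 17, C = 17, L = 37)

.norm_item <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Convert fecal volume shares to digestible-dry-matter shares
#'
#' Applies fecal correction factors (CF): each food item's percent fecal
#' volume is multiplied by its CF, the products are summed within a
#' population-season, and each product is expressed as a fraction of that
#' sum. CFs compensate for differential digestibility, so highly digestible
#' foods (large CF) gain share relative to their fecal-volume signal.
#' Item-specific CFs override category-level CFs when both are present.
#'
#' @param records Data frame of fecal records with columns `population_id`,
#'   `season`, `food_item`, `pct_vol` (percent of fecal volume, 0-100).
#' @param cf_table Data frame with columns `food_item` and `cf`
#'   (positive multiplier). Food-item matching is exact after case and
#'   whitespace normalization.
#' @return A tibble with columns `population_id`, `season`, `food_item`,
#'   `ddm` where `ddm` sums to 1 within each population-season.
#' @examples
#' recs <- data.frame(population_id = 1, season = "spring",
#'                    food_item = c("A", "B"), pct_vol = c(60, 40))
#' cfs <- data.frame(food_item = c("A", "B"), cf = c(0.5, 2))
#' apply_correction_factors(recs, cfs)
#' @export
apply_correction_factors <- function(records, cf_table) {
  req <- c("population_id", "season", "food_item", "pct_vol")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(c("food_item", "cf") %in% names(cf_table))) {
    abort("`cf_table` must have columns `food_item` and `cf`.")
  }
  if (any(cf_table$cf <= 0)) abort("Correction factors must be positive.")
  if (any(records$pct_vol < 0)) abort("`pct_vol` must be non-negative.")
  key <- .norm_item(cf_table$food_item)
  if (anyDuplicated(key)) abort("`cf_table` contains duplicate food items.")
  idx <- match(.norm_item(records$food_item), key)
  if (anyNA(idx)) {
    bad <- unique(records$food_item[is.na(idx)])
    abort(paste0(
      "No correction factor for food item(s): ", paste(bad, collapse = ", ")
    ))
  }
  out <- as_tibble(records)
  out$.w <- out$pct_vol * cf_table$cf[idx]
  out <- dplyr::group_by(out, .data$population_id, .data$season)
  tot <- dplyr::summarise(out, .tot = sum(.data$.w), .groups = "drop")
  if (any(tot$.tot <= 0)) {
    abort("A population-season has zero total volume; cannot form a %DDM profile.")
  }
  out <- dplyr::mutate(out, ddm = .data$.w / sum(.data$.w))
  out <- dplyr::ungroup(out)
  out[c("population_id", "season", "food_item", "ddm")]
}

#' Macronutrient energy composition of foods
#'
#' Converts per-food macronutrient masses (grams of protein, available
#' carbohydrate and lipid per unit digestible dry matter) to fractions of
#' metabolizable energy using [energy_kj_per_g], and closes them to 1.
#'
#' @param food_table Data frame with columns `food_item`, `protein_g`,
#'   `carbohydrate_g`, `lipid_g`.
#' @param energy Named energy conversion vector (kJ/g); default
#'   [energy_kj_per_g].
#' @return A tibble with columns `food_item`, `P`, `C`, `L` (energy
#'   fractions summing to 1) and `energy_density` (kJ per unit dry matter).
#' @export
food_energy_composition <- function(food_table, energy = energy_kj_per_g) {
  req <- c("food_item", "protein_g", "carbohydrate_g", "lipid_g")
  missing <- setdiff(req, names(food_table))
  if (length(missing) > 0) {
    abort(paste0("`food_table` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  g <- as.matrix(food_table[c("protein_g", "carbohydrate_g", "lipid_g")])
  if (any(g < 0)) abort("Macronutrient masses must be non-negative.")
  kj <- sweep(g, 2, energy[c("P", "C", "L")], "*")
  dens <- rowSums(kj)
  if (any(dens <= 0)) {
    bad <- food_table$food_item[dens <= 0]
    abort(paste0("Food(s) with zero total energy: ", paste(bad, collapse = ", ")))
  }
  frac <- kj / dens
  tibble(
    food_item = food_table$food_item,
    P = frac[, 1], C = frac[, 2], L = frac[, 3],
    energy_density = dens
  )
}

#' Macronutrient composition of a diet from its %DDM profile
#'
#' Weights each food's macronutrient energy fractions by its share of
#' digestible dry matter and sums, yielding the diet's protein /
#' carbohydrate / lipid energy composition. Mode `"as-stated"` (default)
#' averages the foods' energy-fraction compositions directly with the ddm
#' weights; mode `"energy-weighted"` additionally weights each food by its
#' energy density (kJ per unit dry matter) before normalizing, i.e. it
#' tracks energy bookkeeping exactly. The two agree whenever all foods have
#' equal energy density.
#'
#' @param ddm_profile Data frame with columns `food_item` and `ddm`
#'   (fractions summing to 1), optionally grouped by `population_id` /
#'   `season` columns (all rows must then belong to one group).
#' @param food_comp Output of [food_energy_composition()] (columns
#'   `food_item`, `P`, `C`, `L`, `energy_density`).
#' @param mode `"as-stated"` or `"energy-weighted"`.
#' @return A one-row tibble with columns `P`, `C`, `L` summing to 1.
#' @export
diet_composition <- function(ddm_profile, food_comp,
                             mode = c("as-stated", "energy-weighted")) {
  mode <- match.arg(mode)
  if (!all(c("food_item", "ddm") %in% names(ddm_profile))) {
    abort("`ddm_profile` must have columns `food_item` and `ddm`.")
  }
  idx <- match(.norm_item(ddm_profile$food_item), .norm_item(food_comp$food_item))
  if (anyNA(idx)) {
    bad <- unique(ddm_profile$food_item[is.na(idx)])
    abort(paste0("Food item(s) missing from food table: ", paste(bad, collapse = ", ")))
  }
  w <- ddm_profile$ddm
  if (mode == "energy-weighted") {
    w <- w * food_comp$energy_density[idx]
  }
  w <- w / sum(w)
  e <- as.matrix(food_comp[idx, c("P", "C", "L")])
  out <- colSums(e * w)
  out <- unname(out / sum(out))
  tibble(P = out[1], C = out[2], L = out[3])
}

#' Estimate seasonal diet compositions for a scat study
#'
#' End-to-end per population-season pipeline: fecal volume records are
#' corrected to %DDM shares with [apply_correction_factors()], the food
#' table is converted to energy fractions with [food_energy_composition()],
#' and each population-season profile is collapsed to a three-part
#' macronutrient composition with [diet_composition()].
#'
#' @inheritParams apply_correction_factors
#' @inheritParams food_energy_composition
#' @inheritParams diet_composition
#' @return A tibble with one row per population-season: `population_id`,
#'   `season`, part columns `P`, `C`, `L`, and a list-column `ddm_profile`
#'   holding each group's food-level %DDM tibble.
#' @export
estimate_diets <- function(records, cf_table, food_table,
                           mode = c("as-stated", "energy-weighted")) {
  mode <- match.arg(mode)
  ddm <- apply_correction_factors(records, cf_table)
  fc <- food_energy_composition(food_table)
  nested <- tidyr::nest(
    dplyr::group_by(ddm, .data$population_id, .data$season),
    ddm_profile = c("food_item", "ddm")
  )
  nested <- dplyr::ungroup(nested)
  comps <- purrr::map(nested$ddm_profile, diet_composition, food_comp = fc, mode = mode)
  dplyr::bind_cols(
    nested[c("population_id", "season")],
    dplyr::bind_rows(comps),
    nested["ddm_profile"]
  )
}

#' Aggregate seasonal diet estimates to an annual diet
#'
#' Each seasonal diet is treated as representative of its period: the
#' annual %DDM profile is the unweighted arithmetic mean of the seasonal
#' profiles over the union of foods (a food absent in a season contributes
#' zero there), re-closed; the annual macronutrient composition is then
#' recomputed from that pooled profile. Averaging at the profile level
#' (rather than averaging the seasonal macronutrient compositions) is the
#' default; `level = "composition"` exposes the alternative for sensitivity
#' checks.
#'
#' @param seasonal Output of [estimate_diets()] for one or more populations
#'   (columns `population_id`, `season`, `P`, `C`, `L`, `ddm_profile`).
#' @param food_table Food macronutrient table, needed to recompute the
#'   annual composition when `level = "ddm"`.
#' @param mode Weighting mode passed to [diet_composition()].
#' @param level `"ddm"` (default) averages %DDM profiles then recomputes
#'   the composition; `"composition"` averages the seasonal compositions
#'   arithmetically and re-closes.
#' @return A tibble with one row per population: `population_id`, `P`,
#'   `C`, `L`, `n_seasons`, and (for `level = "ddm"`) the pooled
#'   `ddm_profile` list-column.
#' @export
aggregate_annual <- function(seasonal, food_table = NULL,
                             mode = c("as-stated", "energy-weighted"),
                             level = c("ddm", "composition")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (nrow(seasonal) == 0) abort("`seasonal` has no rows.")
  if (level == "composition") {
    out <- dplyr::summarise(
      dplyr::group_by(seasonal, .data$population_id),
      P = mean(.data$P), C = mean(.data$C), L = mean(.data$L),
      n_seasons = dplyr::n(), .groups = "drop"
    )
    return(comp_close(out, c("P", "C", "L")))
  }
  if (is.null(food_table)) {
    abort("`food_table` is required when aggregating at the %DDM level.")
  }
  if (!"ddm_profile" %in% names(seasonal)) {
    abort("`seasonal` must carry the `ddm_profile` list-column (see estimate_diets()).")
  }
  fc <- food_energy_composition(food_table)
  pops <- split(seasonal, seasonal$population_id)
  rows <- purrr::map(pops, function(sx) {
    ns <- nrow(sx)
    prof <- dplyr::bind_rows(sx$ddm_profile)
    # mean over seasons with absent foods counting as zero:
    # sum of ddm over seasons / number of seasons
    prof <- dplyr::summarise(
      dplyr::group_by(prof, .data$food_item),
      ddm = sum(.data$ddm) / ns, .groups = "drop"
    )
    prof$ddm <- prof$ddm / sum(prof$ddm)
    comp <- diet_composition(prof, fc, mode = mode)
    tibble(
      population_id = sx$population_id[1],
      P = comp$P, C = comp$C, L = comp$L,
      n_seasons = ns,
      ddm_profile = list(prof)
    )
  })
  dplyr::bind_rows(rows)
}

#' Canonical season synonym map
#'
#' Named character vector mapping free-text season labels (lower case) to
#' the four canonical tokens `spring`, `summer`, `autumn`, `winter`.
#'
#' @export
season_synonyms <- function() {
  c(
    spring = "spring", summer = "summer", autumn = "autumn", winter = "winter",
    fall = "autumn", "pre-denning" = "autumn", hyperphagia = "autumn",
    "early season" = "spring", "late season" = "autumn",
    "den emergence" = "spring", "post-denning" = "spring"
  )
}

#' Classify free-text season labels
#'
#' Maps study-specific season labels to the canonical tokens via a synonym
#' map; labels not in the map fall back to a month-midpoint rule when a
#' month range is supplied (Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter). Unmappable labels are an error, never a guess.
#'
#' @param label Character vector of season labels.
#' @param month_range Optional integer vector of length 2 (first and last
#'   month, 1-12) applied to labels absent from the synonym map; a range
#'   wrapping past December (e.g. `c(11, 2)`) is handled.
#' @param synonyms Named map as from [season_synonyms()].
#' @return Character vector of canonical season tokens.
#' @examples
#' classify_season("fall")
#' classify_season("hyperphagia", month_range = c(9, 10))
#' @export
classify_season <- function(label, month_range = NULL,
                            synonyms = season_synonyms()) {
  if (length(label) == 0 || any(!nzchar(trimws(label)))) {
    abort("`label` must be non-empty.")
  }
  key <- .norm_item(label)
  out <- unname(synonyms[key])
  if (anyNA(out)) {
    if (!is.null(month_range)) {
      if (length(month_range) != 2 || any(month_range < 1 | month_range > 12)) {
        abort("`month_range` must be two months in 1..12.")
      }
      a <- month_range[1]; b <- month_range[2]
      mid <- if (b >= a) (a + b) / 2 else (a + b + 12) / 2
      tok <- cut(mid %% 12, breaks = c(-0.5, 2.5, 5.5, 8.5, 11.5),
                 labels = c("winter", "spring", "summer", "autumn"))
      out[is.na(out)] <- as.character(tok)
    } else {
      bad <- unique(label[is.na(out)])
      abort(paste0(
        "Cannot classify season label(s): ", paste(bad, collapse = ", "),
        ". Accepted synonyms: ", paste(names(synonyms), collapse = ", "),
        "; or supply `month_range`."
      ))
    }
  }
  out
}
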