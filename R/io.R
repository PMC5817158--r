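.check_headers <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  extra <- setdiff(names(df), required)
  if (length(missing) > 0) {
    abort(paste0(
      "Invalid ", what, " file `", path, "`: missing header(s) ",
      paste(missing, collapse = ", "),
      if (length(extra) > 0) paste0(" (found instead: ", paste(extra, collapse = ", "), ")")
      else ""
    ))
  }
  invisible(df)
}

#' Read and validate fecal (scat) volume records
#'
#' CSV with headers `population_id`, `season`, `food_item`, `pct_vol`.
#' Duplicate (population, season, food) rows are an error. Within each
#' population-season the `pct_vol` values should sum to 100; totals
#' deviating by more than `tolerance` (default 2) are renormalized to 100
#' with a warning, smaller deviations are accepted as rounding.
#'
#' @param path CSV file path.
#' @param tolerance Allowed deviation of a season's total from 100 before
#'   renormalization kicks in.
#' @return A validated tibble of records.
#' @export
read_fecal_records <- function(path, tolerance = 2) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_headers(df, c("population_id", "season", "food_item", "pct_vol"),
                 "fecal record", path)
  if (!is.numeric(df$pct_vol)) abort("`pct_vol` must be numeric.")
  if (any(df$pct_vol < 0)) abort("`pct_vol` must be non-negative.")
  key <- paste(df$population_id, df$season, .norm_item(df$food_item), sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (population_id, season, food_item) rows in fecal records.")
  }
  df <- dplyr::group_by(df, .data$population_id, .data$season)
  df <- dplyr::mutate(df, .tot = sum(.data$pct_vol))
  df <- dplyr::ungroup(df)
  off <- abs(df$.tot - 100) > tolerance
  if (any(off)) {
    bad <- unique(df[off, c("population_id", "season", ".tot")])
    warn(paste0(
      "Renormalizing ", nrow(bad),
      " population-season(s) whose %Vol totals deviate from 100 by more than ",
      tolerance, "."
    ))
    df$pct_vol[off] <- df$pct_vol[off] / df$.tot[off] * 100
  }
  df$.tot <- NULL
  df
}

#' Read and validate a correction-factor table
#'
#' CSV with headers `food_item`, `cf`; every CF must be positive and food
#' items unique (after case/whitespace normalization).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_cf_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_headers(df, c("food_item", "cf"), "correction factor", path)
  if (!is.numeric(df$cf) || any(df$cf <= 0)) {
    abort("Correction factors must be positive numbers.")
  }
  if (anyDuplicated(.norm_item(df$food_item))) {
    abort("Duplicate food items in correction-factor table.")
  }
  df
}

#' Read and validate a food macronutrient table
#'
#' CSV with headers `food_item`, `protein_g`, `carbohydrate_g`, `lipid_g`
#' (grams per unit digestible dry matter); masses must be non-negative and
#' not all zero for a food.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_food_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_headers(df, c("food_item", "protein_g", "carbohydrate_g", "lipid_g"),
                 "food macronutrient", path)
  g <- as.matrix(df[c("protein_g", "carbohydrate_g", "lipid_g")])
  if (any(g < 0)) abort("Macronutrient masses must be non-negative.")
  if (any(rowSums(g) == 0)) abort("Each food needs at least one non-zero macronutrient.")
  if (anyDuplicated(.norm_item(df$food_item))) {
    abort("Duplicate food items in food table.")
  }
  df
}

#' Read a full scat study (records + CFs + food table)
#'
#' Convenience loader running the three validators and cross-checking that
#' every recorded food item resolves in both the correction-factor and
#' food tables.
#'
#' @param records_path,cf_path,food_path CSV file paths.
#' @return A list with `records`, `cf_table`, `food_table`.
#' @export
read_diet_study <- function(records_path, cf_path, food_path) {
  records <- read_fecal_records(records_path)
  cf_table <- read_cf_table(cf_path)
  food_table <- read_food_table(food_path)
  items <- unique(.norm_item(records$food_item))
  miss_cf <- setdiff(items, .norm_item(cf_table$food_item))
  miss_food <- setdiff(items, .norm_item(food_table$food_item))
  if (length(miss_cf) > 0) {
    abort(paste0("Food item(s) without a correction factor: ",
                 paste(miss_cf, collapse = ", ")))
  }
  if (length(miss_food) > 0) {
    abort(paste0("Food item(s) without macronutrient data: ",
                 paste(miss_food, collapse = ", ")))
  }
  list(records = records, cf_table = cf_table, food_table = food_table)
}

#' Write a table of compositions (or any tibble) to CSV
#'
#' Numeric columns are written with six decimal places so composition
#' tables round-trip losslessly at working precision.
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(data, path, digits = 6) {
  out <- as_tibble(data)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = digits, format = "f"))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Serializes the output of [simulate_study()] as the three standard input
#' CSVs plus a ground-truth table, ready to be read back with
#' [read_diet_study()].
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_composition_csv(study$records, file.path(dir, "fecal_records.csv"))
  write_composition_csv(study$cf_table, file.path(dir, "correction_factors.csv"))
  write_composition_csv(study$food_table, file.path(dir, "food_macronutrients.csv"))
  write_composition_csv(study$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
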