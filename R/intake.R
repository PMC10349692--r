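#' Read and validate a food-group intake table
#'
#' Reads a delimited file of participant-level daily intakes for the 18
#' indexed food groups plus alcohol, margarine, total energy and gender.
#' The delimiter is explicit (no sniffing). Validation failures name the
#' offending column and, where applicable, the offending rows.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default `","`. Use `"\t"` for TSV.
#' @return A validated tibble with one row per participant: `participant_id`,
#'   the 18 group columns (servings/day), `alcohol` (servings/day),
#'   `margarine` (portions/day), `energy` (kcal/day) and `gender`
#'   (`"male"`/`"female"`).
#' @seealso [aggregate_intake()] to build the group table from item-level
#'   records, [apply_energy_exclusions()] for the plausibility filter.
#' @export
load_intake <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("intake file not found: ", path))
  }
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  out <- validate_intake(tbl)
  inform(paste0("load_intake: read ", nrow(out), " participants from ", path))
  out
}

#' Validate an in-memory intake table
#'
#' Checks the column contract of the food-group intake table: all 18 groups
#' plus alcohol, margarine, energy and gender present; intakes finite and
#' non-negative; energy strictly positive; gender restricted to
#' male/female. Returns the table with intake columns coerced to double.
#'
#' @param intake A data frame of per-participant intakes.
#' @return The validated tibble (invisibly identical content).
#' @export
validate_intake <- function(intake) {
  intake <- tibble::as_tibble(intake)
  required <- intake_required_cols()
  missing <- setdiff(required, names(intake))
  if (length(missing) > 0) {
    abort(paste0("intake table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(intake$participant_id)) {
    abort("intake table has duplicated participant_id values")
  }
  num_cols <- c(intake_group_cols(), "alcohol", "margarine", "energy")
  for (col in num_cols) {
    v <- as.double(intake[[col]])
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(paste0("column `", col, "` has non-finite values at row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    if (col == "energy") {
      bad <- which(v <= 0)
      if (length(bad) > 0) {
        abort(paste0("column `energy` must be > 0; violated at row(s): ",
                     paste(head(bad, 5), collapse = ", ")))
      }
    } else {
      bad <- which(v < 0)
      if (length(bad) > 0) {
        abort(paste0("column `", col, "` has negative intakes at row(s): ",
                     paste(head(bad, 5), collapse = ", ")))
      }
    }
    intake[[col]] <- v
  }
  if (!all(intake$gender %in% c("male", "female"))) {
    bad <- unique(setdiff(intake$gender, c("male", "female")))
    abort(paste0("column `gender` must be 'male' or 'female'; found: ",
                 paste(bad, collapse = ", ")))
  }
  intake
}

#' Aggregate item-level intakes to the 18 index food groups
#'
#' Collapses long-format item records (one row per participant x food item)
#' onto the group level via a user-supplied mapping with per-item weights
#' (servings per reported unit). Items mapping to `alcohol` or `margarine`
#' are aggregated onto those covariate columns; groups with no mapped items
#' are filled with zero.
#'
#' @param items A data frame with columns `participant_id`, `item`, `amount`.
#' @param mapping A data frame with columns `item`, `group`, `weight`. Every
#'   `group` must be one of the 18 index groups, `"alcohol"` or
#'   `"margarine"`.
#' @return A wide tibble: `participant_id` plus one column per group in the
#'   mapping target set (group value = sum of weight x amount).
#' @examples
#' items <- tibble::tibble(
#'   participant_id = 1, item = c("lettuce", "carrot", "soup_veg"),
#'   amount = c(1, 2, 2)
#' )
#' map <- tibble::tibble(
#'   item = c("lettuce", "carrot", "soup_veg"),
#'   group = "vegetables", weight = c(1, 1, 0.5)
#' )
#' aggregate_intake(items, map) # vegetables = 4
#' @export
aggregate_intake <- function(items, mapping) {
  for (col in c("participant_id", "item", "amount")) {
    if (!col %in% names(items)) {
      abort(paste0("item table is missing column `", col, "`"))
    }
  }
  for (col in c("item", "group", "weight")) {
    if (!col %in% names(mapping)) {
      abort(paste0("mapping is missing column `", col, "`"))
    }
  }
  allowed <- c(intake_group_cols(), "alcohol", "margarine")
  bad <- setdiff(unique(mapping$group), allowed)
  if (length(bad) > 0) {
    abort(paste0("mapping targets unknown group(s): ",
                 paste(bad, collapse = ", ")))
  }
  unmapped <- setdiff(unique(items$item), mapping$item)
  if (length(unmapped) > 0) {
    warn(paste0("dropping ", length(unmapped),
                " item(s) absent from the mapping: ",
                paste(head(unmapped, 5), collapse = ", ")))
  }
  items |>
    dplyr::inner_join(mapping, by = "item", relationship = "many-to-many") |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(value = sum(.data$weight * .data$amount),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value",
                       values_fill = 0)
}

#' Gender-specific energy-intake plausibility windows
#'
#' @return Named list with `male` and `female` elements, each `c(min, max)`
#'   in kcal/day. Defaults: men 800-4200, women 500-3500.
#' @export
energy_bounds <- function() {
  list(male = c(800, 4200), female = c(500, 3500))
}

#' Exclude participants with implausible energy intakes
#'
#' Removes participants whose reported total energy intake falls strictly
#' below or strictly above the gender-specific plausibility window
#' (men: < 800 or > 4200 kcal/day; women: < 500 or > 3500 kcal/day).
#' Boundary values are retained — the comparators are strict. The filter is
#' idempotent and partitions the input exactly into kept and excluded rows.
#'
#' @param intake A validated intake table (see [validate_intake()]).
#' @param bounds Plausibility windows, default [energy_bounds()].
#' @return A list with `kept` (the filtered intake tibble) and `excluded`
#'   (tibble: `participant_id`, `gender`, `energy`, `reason` of
#'   `"energy_below_min"` / `"energy_above_max"`).
#' @export
apply_energy_exclusions <- function(intake, bounds = energy_bounds()) {
  if (!all(c("energy", "gender") %in% names(intake))) {
    abort("intake table must have `energy` and `gender` columns")
  }
  if (!all(intake$gender %in% names(bounds))) {
    bad <- unique(setdiff(intake$gender, names(bounds)))
    abort(paste0("unknown gender value(s): ", paste(bad, collapse = ", ")))
  }
  lo <- vapply(bounds, `[`, numeric(1), 1L)[intake$gender]
  hi <- vapply(bounds, `[`, numeric(1), 2L)[intake$gender]
  reason <- dplyr::case_when(
    intake$energy < lo ~ "energy_below_min",
    intake$energy > hi ~ "energy_above_max",
    .default = NA_character_
  )
  excluded <- intake |>
    dplyr::select("participant_id", "gender", "energy") |>
    dplyr::mutate(reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  kept <- intake[is.na(reason), , drop = FALSE]
  if (nrow(excluded) > 0) {
    inform(paste0("apply_energy_exclusions: removed ", nrow(excluded),
                  " of ", nrow(intake), " participants"))
  }
  list(kept = kept, excluded = excluded)
}
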