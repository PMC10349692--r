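#' The 18 indexed food groups and their classification
#'
#' The plant-based diet indices are built from 18 food groups: 7 healthy
#' plant-based groups (whole grains, fruits, vegetables, nuts, legumes,
#' vegetable oils, tea & coffee), 5 unhealthy plant-based groups (fruit
#' juices, refined grains, potatoes, sugar-sweetened beverages, sweets) and
#' 6 animal-based groups (animal fat, dairy, fish, meat, eggs, miscellaneous
#' animal-based foods). Alcohol and margarine are recorded alongside the
#' intake table but are never part of any index; they enter the analysis as
#' covariates only.
#'
#' @return A tibble with columns `group` (snake_case column name used
#'   throughout the package) and `category` (one of `"healthy_plant"`,
#'   `"unhealthy_plant"`, `"animal"`).
#' @examples
#' food_groups()
#' @export
food_groups <- function() {
  tibble::tibble(
    group = c(
      "whole_grains", "fruits", "vegetables", "nuts", "legumes",
      "vegetable_oils", "tea_coffee",
      "fruit_juices", "refined_grains", "potatoes",
      "sugar_sweetened_beverages", "sweets",
      "animal_fat", "dairy", "fish", "meat", "eggs", "misc_animal"
    ),
    category = rep(
      c("healthy_plant", "unhealthy_plant", "animal"),
      times = c(7L, 5L, 6L)
    )
  )
}

#' Scoring direction of each food group under a diet-index scheme
#'
#' Each index sums 18 quintile scores. A group scored `"positive"`
#' contributes its quintile score (1-5); a group scored `"reversed"`
#' contributes 6 minus its score. Animal-based groups are reversed in all
#' three schemes. The overall index (PDI) scores all plant groups
#' positively; the healthful index (hPDI) reverses the unhealthy plant
#' groups; the unhealthful index (uPDI) scores unhealthy plant groups
#' positively and reverses the healthy ones.
#'
#' @param scheme One of `"PDI"`, `"hPDI"`, `"uPDI"`.
#' @param groups Group classification table; defaults to [food_groups()].
#'   Supplying a modified table allows sensitivity analyses with alternative
#'   group memberships.
#' @return A tibble with columns `group`, `category` and `direction`
#'   (`"positive"` or `"reversed"`).
#' @examples
#' scheme_directions("hPDI")
#' @export
scheme_directions <- function(scheme = c("PDI", "hPDI", "uPDI"),
                              groups = food_groups()) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("group", "category") %in% names(groups)))
  dir <- switch(scheme,
    PDI = c(healthy_plant = "positive", unhealthy_plant = "positive",
            animal = "reversed"),
    hPDI = c(healthy_plant = "positive", unhealthy_plant = "reversed",
             animal = "reversed"),
    uPDI = c(healthy_plant = "reversed", unhealthy_plant = "positive",
             animal = "reversed")
  )
  dplyr::mutate(groups, direction = unname(dir[.data$category]))
}

# Column sets shared across modules
intake_group_cols <- function() food_groups()$group
intake_extra_cols <- function() c("alcohol", "margarine", "energy", "gender")
intake_required_cols <- function() {
  c("participant_id", intake_group_cols(), intake_extra_cols())
}
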