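#' Assemble the per-participant analysis data frame
#'
#' Runs the data-preparation stages on a cohort: energy-implausibility
#' exclusions on the intake table, diet-index scoring (quintiles, three
#' indices, energy adjustment, tertiles), cognitive composites (baseline,
#' follow-up, change) standardized against the post-exclusion analysis
#' cohort's baseline, complete-case filter on baseline global cognition,
#' and a join with covariates, arm labels and the raw animal-food intakes
#' used by the stratified analyses.
#'
#' @param cohort A `synthetic_cohort`, or any list with elements `intake`,
#'   `covariates`, `battery_baseline` and optionally `battery_followup`
#'   and `arm`.
#' @param stroop_interference Passed to [score_cognition()].
#' @param tertiles_on Passed to [score_diet()].
#' @return A tibble with one row per analysis participant, carrying stage
#'   counts in the `"stage_counts"` attribute and the exclusion log in
#'   `"exclusions"`.
#' @export
build_analysis_data <- function(cohort,
                                stroop_interference = c("ratio", "difference"),
                                tertiles_on = c("adjusted", "raw")) {
  stroop_interference <- match.arg(stroop_interference)
  tertiles_on <- match.arg(tertiles_on)
  intake <- validate_intake(cohort$intake)
  n_loaded <- nrow(intake)

  excl <- apply_energy_exclusions(intake)
  intake <- excl$kept
  n_energy <- nrow(intake)

  keep_ids <- intake$participant_id
  battery_b <- cohort$battery_baseline |>
    dplyr::filter(.data$participant_id %in% keep_ids)
  battery_f <- cohort$battery_followup
  if (!is.null(battery_f)) {
    battery_f <- dplyr::filter(battery_f,
                               .data$participant_id %in% keep_ids)
  }

  # complete-case on baseline cognition: participants with no usable
  # baseline global composite never enter the analysis cohort, and the
  # standardization parameters are estimated after this exclusion
  probe <- suppressMessages(derive_composites(battery_b,
                                              stroop_interference = stroop_interference))
  usable <- probe$participant_id[!is.na(probe$z_global)]
  battery_b <- dplyr::filter(battery_b, .data$participant_id %in% usable)
  if (!is.null(battery_f)) {
    battery_f <- dplyr::filter(battery_f, .data$participant_id %in% usable)
  }
  intake <- dplyr::filter(intake, .data$participant_id %in% usable)
  n_cognition <- nrow(intake)

  scores <- suppressMessages(score_diet(intake, tertiles_on = tertiles_on))
  cognition <- suppressMessages(
    score_cognition(battery_b, battery_f,
                    stroop_interference = stroop_interference)
  )

  out <- intake |>
    dplyr::select("participant_id", "energy",
                  dplyr::all_of(intake_group_cols())) |>
    dplyr::left_join(cohort$covariates, by = "participant_id") |>
    dplyr::left_join(
      dplyr::select(scores, "participant_id", dplyr::matches("_(raw|adj|tertile)$")),
      by = "participant_id"
    ) |>
    dplyr::left_join(cognition, by = "participant_id")
  if (!is.null(cohort$arm)) {
    out <- dplyr::left_join(out, cohort$arm, by = "participant_id")
  }
  attr(out, "stage_counts") <- c(loaded = n_loaded,
                                 after_energy_exclusion = n_energy,
                                 after_baseline_cognition_filter = n_cognition)
  attr(out, "exclusions") <- excl$excluded
  attr(out, "norms") <- attr(cognition, "norms")
  out
}

default_pipeline_config <- function() {
  list(
    simulation = NULL,
    input = NULL,
    analysis = list(
      designs = c("cross"),
      stratify_by = character(0),
      stroop_interference = "ratio",
      tertiles_on = "adjusted"
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$simulation) && is.null(cfg$input)) {
    abort("config must provide either a `simulation` block or `input` paths")
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain participant data (simulate a
#' synthetic cohort, or load CSV inputs), apply exclusions, score the diet
#' indices and cognitive composites, fit the requested association models,
#' and write all stage outputs plus a run manifest to a directory. Reruns
#' with the same configuration and seed produce identical outputs.
#'
#' The configuration is a named list or a YAML file with blocks:
#' \describe{
#'   \item{simulation}{arguments for [sim_config()] (synthetic run), or}
#'   \item{input}{paths `intake`, `covariates`, `battery_baseline` and
#'     optionally `battery_followup`, `arm` pointing at CSV tables;}
#'   \item{analysis}{`designs` (subset of `"cross"`, `"long"`),
#'     `stratify_by` (subset of fish/meat/eggs/dairy),
#'     `stroop_interference` (`"ratio"`/`"difference"`), `tertiles_on`
#'     (`"adjusted"`/`"raw"`).}
#' }
#'
#' @param config Configuration list or path to a YAML file.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly. Outputs written: the cohort
#'   tables, `analysis_data.csv`, `exclusions.csv`,
#'   `results_cross_sectional.csv` / `results_longitudinal.csv` /
#'   `results_stratified.csv` (as requested) and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  manifest <- list(config = cfg[setdiff(names(cfg), "input")],
                   package_version = as.character(utils::packageVersion("pdicog")))

  result <- tryCatch({
    if (!is.null(cfg$simulation)) {
      cohort <- simulate_cohort(do.call(sim_config, cfg$simulation))
      manifest$seed <- cfg$simulation$seed
      write_cohort(cohort, file.path(out_dir, "cohort"))
    } else {
      paths <- cfg$input
      manifest$input_hashes <- vapply(unlist(paths), function(p)
        unname(tools::md5sum(p)), character(1))
      cohort <- list(
        intake = load_intake(paths$intake),
        covariates = readr::read_csv(paths$covariates,
                                     show_col_types = FALSE),
        battery_baseline = readr::read_csv(paths$battery_baseline,
                                           show_col_types = FALSE),
        battery_followup = if (!is.null(paths$battery_followup)) {
          readr::read_csv(paths$battery_followup, show_col_types = FALSE)
        },
        arm = if (!is.null(paths$arm)) {
          readr::read_csv(paths$arm, show_col_types = FALSE)
        }
      )
    }

    stage <- "prepare"
    ana <- cfg$analysis
    data <- suppressMessages(build_analysis_data(
      cohort,
      stroop_interference = ana$stroop_interference,
      tertiles_on = ana$tertiles_on
    ))
    manifest$stage_counts <- as.list(attr(data, "stage_counts"))
    readr::write_csv(attr(data, "exclusions"),
                     file.path(out_dir, "exclusions.csv"))
    readr::write_csv(data, file.path(out_dir, "analysis_data.csv"))

    if ("long" %in% ana$designs &&
        !"z_global_chg" %in% names(data)) {
      abort("longitudinal design requested but no follow-up battery is available")
    }

    results <- list()
    if ("cross" %in% ana$designs) {
      stage <- "cross_sectional"
      res <- format_results(run_cross_sectional(data))
      readr::write_csv(res, file.path(out_dir, "results_cross_sectional.csv"))
      manifest$n_results_cross <- nrow(res)
      results$cross <- res
    }
    if ("long" %in% ana$designs) {
      stage <- "longitudinal"
      res <- format_results(run_longitudinal(data))
      readr::write_csv(res, file.path(out_dir, "results_longitudinal.csv"))
      manifest$n_results_long <- nrow(res)
      results$long <- res
    }
    if (length(ana$stratify_by) > 0) {
      stage <- "stratified"
      res <- purrr::map(ana$stratify_by, function(by) {
        stratified_analysis(data, by = by)
      }) |> purrr::list_rbind() |> format_results()
      readr::write_csv(res, file.path(out_dir, "results_stratified.csv"))
      results$stratified <- res
    }
    results
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
    abort(paste0("pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
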