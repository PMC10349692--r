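#' The cognitive test battery schema
#'
#' Twelve component measures across four domains, plus the MMSE which is
#' carried as a descriptive field only and never modelled as an outcome.
#' Direction conventions are fixed here: for the timed tests (Trail Making
#' Test, Stroop Colour-Word cards) a larger value means worse performance
#' and their Z-scores are sign-reversed inside the composites.
#'
#' @return A tibble with columns `test` (column name) and `direction`
#'   (`"higher_better"` or `"higher_worse"`).
#' @export
cognitive_tests <- function() {
  tibble::tribble(
    ~test,                 ~direction,
    "ravlt_immediate",     "higher_better",
    "ravlt_delayed",       "higher_better",
    "ravlt_recognition",   "higher_better",
    "digit_span_forward",  "higher_better",
    "digit_span_backward", "higher_better",
    "tmt_a_seconds",       "higher_worse",
    "tmt_b_seconds",       "higher_worse",
    "stroop1_seconds",     "higher_worse",
    "stroop2_seconds",     "higher_worse",
    "stroop3_seconds",     "higher_worse",
    "sdmt",                "higher_better",
    "letter_fluency",      "higher_better"
  )
}

#' Validate a cognitive battery table
#'
#' @param battery Data frame with `participant_id` and the 12 test columns
#'   of [cognitive_tests()]; an `mmse` column (0-30) is optional. `NA`s are
#'   allowed and handled downstream by complete-case composite rules.
#' @return The battery as a tibble.
#' @export
validate_battery <- function(battery) {
  battery <- tibble::as_tibble(battery)
  missing <- setdiff(c("participant_id", cognitive_tests()$test),
                     names(battery))
  if (length(missing) > 0) {
    abort(paste0("battery is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(battery$participant_id)) {
    abort("battery has duplicated participant_id values")
  }
  timed <- grep("_seconds$", cognitive_tests()$test, value = TRUE)
  for (col in timed) {
    v <- battery[[col]]
    if (any(v <= 0, na.rm = TRUE)) {
      abort(paste0("timing column `", col, "` must be > 0"))
    }
  }
  if ("mmse" %in% names(battery) &&
      any(battery$mmse < 0 | battery$mmse > 30, na.rm = TRUE)) {
    abort("`mmse` must lie in [0, 30]")
  }
  battery
}

# Measures entering the composites: the raw tests used directly plus three
# quantities derived per participant on the raw scale before any
# standardization (Stroop basic speed, Stroop interference, TMT B/A ratio).
composite_measures <- function() {
  c("ravlt_immediate", "ravlt_delayed", "ravlt_recognition",
    "digit_span_forward", "digit_span_backward",
    "stroop_basic", "tmt_a_seconds", "sdmt",
    "stroop_interference", "tmt_ba_ratio", "letter_fluency")
}

# Add derived raw-scale measures to a battery. Stroop interference is the
# incongruent-card slowing relative to the two basic cards: ratio form
# III / mean(I, II) by default, difference form III - mean(I, II) optional.
add_derived_measures <- function(battery,
                                 stroop_interference = c("ratio", "difference")) {
  stroop_interference <- match.arg(stroop_interference)
  battery |>
    dplyr::mutate(
      stroop_basic = (.data$stroop1_seconds + .data$stroop2_seconds) / 2,
      stroop_interference = if (stroop_interference == "ratio") {
        .data$stroop3_seconds / .data$stroop_basic
      } else {
        .data$stroop3_seconds - .data$stroop_basic
      },
      tmt_ba_ratio = .data$tmt_b_seconds / .data$tmt_a_seconds
    )
}

#' Baseline standardization parameters for the battery
#'
#' Estimates the cohort mean and standard deviation (n-1 denominator) of
#' every composite-relevant measure — the raw tests and the derived
#' Stroop/TMT quantities — from a baseline battery. These parameters
#' standardize both baseline and follow-up scores, so 2-year change is
#' measured on the baseline scale.
#'
#' @param battery_baseline A validated baseline battery.
#' @inheritParams derive_composites
#' @return A tibble with columns `measure`, `mean`, `sd`.
#' @export
baseline_norms <- function(battery_baseline,
                           stroop_interference = c("ratio", "difference")) {
  stroop_interference <- match.arg(stroop_interference)
  aug <- add_derived_measures(validate_battery(battery_baseline),
                              stroop_interference)
  norms <- tibble::tibble(
    measure = composite_measures(),
    mean = unname(vapply(composite_measures(),
                         function(m) mean(aug[[m]], na.rm = TRUE),
                         numeric(1))),
    sd = unname(vapply(composite_measures(),
                       function(m) sd(aug[[m]], na.rm = TRUE),
                       numeric(1)))
  )
  zero <- norms$measure[!is.na(norms$sd) & norms$sd == 0]
  if (length(zero) > 0) {
    abort(paste0("zero baseline standard deviation for measure(s): ",
                 paste(zero, collapse = ", ")))
  }
  norms
}

#' Standardize scores against baseline parameters
#'
#' `Z = (raw - baseline mean) / baseline sd`. Follow-up scores are
#' standardized with the same baseline parameters.
#'
#' @param x Numeric vector of raw scores.
#' @param baseline_mean,baseline_sd Baseline cohort parameters; `baseline_sd`
#'   must be > 0.
#' @param test Optional measure name used in error messages.
#' @return Numeric vector of Z-scores.
#' @export
zscore_to_baseline <- function(x, baseline_mean, baseline_sd, test = NULL) {
  if (!is.finite(baseline_sd) || baseline_sd <= 0) {
    abort(paste0("baseline sd must be > 0",
                 if (!is.null(test)) paste0(" for test `", test, "`")))
  }
  (x - baseline_mean) / baseline_sd
}

#' Build the five composite cognitive Z-scores
#'
#' Standardizes each measure against the baseline cohort parameters,
#' reverses the sign of the timed measures (TMT, Stroop) so that higher
#' always means better, and averages into four domain composites plus
#' global cognition:
#' \itemize{
#'   \item episodic memory = mean of the three RAVLT Z-scores;
#'   \item attention & working memory = mean of Digit Span forward/backward;
#'   \item information processing speed = mean of -Z(Stroop I-II mean time),
#'     -Z(TMT-A) and +Z(SDMT);
#'   \item executive functioning = mean of -Z(Stroop interference),
#'     -Z(TMT B/A ratio) and +Z(Letter Fluency);
#'   \item global cognition = mean of the four domain composites.
#' }
#' Derived quantities (Stroop I-II mean, Stroop interference, TMT B/A) are
#' computed on the raw scale per participant and then standardized. A
#' participant missing any component of a composite gets `NA` for that
#' composite (complete-case per composite).
#'
#' @param battery A validated battery at one timepoint.
#' @param norms Baseline parameters from [baseline_norms()]. When `NULL`
#'   (default) they are estimated from `battery` itself, which is only
#'   appropriate when `battery` is the baseline.
#' @param stroop_interference `"ratio"` (Stroop III / mean(I, II), default)
#'   or `"difference"` (III - mean(I, II)).
#' @return A tibble: `participant_id`, `z_episodic_memory`,
#'   `z_attention_wm`, `z_processing_speed`, `z_executive`, `z_global`,
#'   plus `mmse` carried through if present (descriptive only).
#' @export
derive_composites <- function(battery, norms = NULL,
                              stroop_interference = c("ratio", "difference")) {
  stroop_interference <- match.arg(stroop_interference)
  battery <- validate_battery(battery)
  if (is.null(norms)) {
    norms <- baseline_norms(battery, stroop_interference)
  }
  aug <- add_derived_measures(battery, stroop_interference)
  z <- purrr::map(setNames(nm = composite_measures()), function(m) {
    nr <- norms[norms$measure == m, ]
    if (nrow(nr) != 1) abort(paste0("norms table lacks measure `", m, "`"))
    zscore_to_baseline(aug[[m]], nr$mean, nr$sd, test = m)
  }) |> tibble::as_tibble()

  out <- tibble::tibble(
    participant_id = battery$participant_id,
    z_episodic_memory = (z$ravlt_immediate + z$ravlt_delayed +
                           z$ravlt_recognition) / 3,
    z_attention_wm = (z$digit_span_forward + z$digit_span_backward) / 2,
    z_processing_speed = (-z$stroop_basic - z$tmt_a_seconds + z$sdmt) / 3,
    z_executive = (-z$stroop_interference - z$tmt_ba_ratio +
                     z$letter_fluency) / 3
  )
  out$z_global <- (out$z_episodic_memory + out$z_attention_wm +
                     out$z_processing_speed + out$z_executive) / 4
  n_na <- sum(is.na(out$z_global))
  if (n_na > 0) {
    inform(paste0("derive_composites: ", n_na,
                  " participant(s) missing at least one component"))
  }
  if ("mmse" %in% names(battery)) out$mmse <- battery$mmse
  out
}

#' Two-year change in composite scores
#'
#' `change = follow-up - baseline` per composite, both standardized with
#' baseline parameters. Participants without a follow-up row are excluded
#' (logged); duplicated ids are an error.
#'
#' @param baseline,followup Composite tables from [derive_composites()].
#' @return A tibble: `participant_id` and `<composite>_chg` columns.
#' @export
change_scores <- function(baseline, followup) {
  if (anyDuplicated(baseline$participant_id) ||
      anyDuplicated(followup$participant_id)) {
    abort("duplicate participant_id values in composite tables")
  }
  zcols <- grep("^z_", names(baseline), value = TRUE)
  matched <- intersect(baseline$participant_id, followup$participant_id)
  dropped <- setdiff(baseline$participant_id, matched)
  if (length(dropped) > 0) {
    inform(paste0("change_scores: ", length(dropped),
                  " participant(s) without follow-up excluded"))
  }
  b <- baseline[match(matched, baseline$participant_id), ]
  f <- followup[match(matched, followup$participant_id), ]
  out <- tibble::tibble(participant_id = matched)
  for (col in zcols) {
    out[[paste0(col, "_chg")]] <- f[[col]] - b[[col]]
  }
  out
}

#' Score a cohort's cognition end-to-end
#'
#' Convenience wrapper: estimates baseline norms, derives baseline (and,
#' when provided, follow-up) composites and 2-year change scores, and
#' returns one wide tibble per participant.
#'
#' @param battery_baseline Baseline battery (all analysis participants).
#' @param battery_followup Optional follow-up battery.
#' @inheritParams derive_composites
#' @return A tibble with baseline composites (`z_*`), follow-up composites
#'   (`z_*_fu`) and change scores (`z_*_chg`) when follow-up data are
#'   given. The baseline norms table is attached as attribute `"norms"`.
#' @export
score_cognition <- function(battery_baseline, battery_followup = NULL,
                            stroop_interference = c("ratio", "difference")) {
  stroop_interference <- match.arg(stroop_interference)
  norms <- baseline_norms(battery_baseline, stroop_interference)
  base <- derive_composites(battery_baseline, norms, stroop_interference)
  out <- base
  if (!is.null(battery_followup) && nrow(battery_followup) > 0) {
    fu <- derive_composites(battery_followup, norms, stroop_interference)
    zcols <- grep("^z_", names(base), value = TRUE)
    fu_ren <- fu |>
      dplyr::select("participant_id", dplyr::all_of(zcols)) |>
      dplyr::rename_with(~ paste0(.x, "_fu"), dplyr::all_of(zcols))
    chg <- change_scores(base[c("participant_id", zcols)],
                         fu[c("participant_id", zcols)])
    out <- out |>
      dplyr::left_join(fu_ren, by = "participant_id") |>
      dplyr::left_join(chg, by = "participant_id")
  }
  attr(out, "norms") <- norms
  out
}
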