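# Covariate sets for the three model tiers. Reference levels for the
# dummy-coded categorical covariates: gender = male, education = low,
# smoking = never, alcohol = light.
tier_covariates <- function(model) {
  switch(model,
    crude = character(0),
    model1 = c("age", "gender", "education"),
    model2 = c("age", "gender", "education", "bmi", "physical_activity",
               "smoking", "alcohol_category", "margarine"),
    abort(paste0("unknown model tier: ", model))
  )
}

index_prefix <- function(index) {
  pre <- c(PDI = "pdi", hPDI = "hpdi", uPDI = "updi")[index]
  if (is.na(pre)) abort(paste0("unknown index: ", index))
  unname(pre)
}

# Coerce categorical covariates to factors with the documented reference
# levels so regression contrasts are against the stated references.
set_covariate_factors <- function(data) {
  lv <- list(gender = c("male", "female"),
             education = c("low", "middle", "high"),
             smoking = c("never", "current", "former"),
             alcohol_category = c("light", "moderate", "excessive"))
  for (col in names(lv)) {
    if (col %in% names(data)) {
      bad <- setdiff(unique(stats::na.omit(as.character(data[[col]]))),
                     lv[[col]])
      if (length(bad) > 0) {
        abort(paste0("`", col, "` has level(s) outside ",
                     paste(lv[[col]], collapse = "/"), ": ",
                     paste(bad, collapse = ", ")))
      }
      data[[col]] <- factor(data[[col]], levels = lv[[col]])
    }
  }
  data
}

#' Fit one diet-cognition linear model
#'
#' Ordinary least squares of a cognition outcome (baseline composite or
#' 2-year change) on a plant-based diet index exposure, in one of three
#' covariate tiers: `crude` (exposure only), `model1` (plus age, gender,
#' education) and `model2` (model 1 plus BMI, physical activity, smoking,
#' alcohol category and margarine intake). The exposure is either the
#' energy-adjusted index divided by 10 (`continuous`, so the coefficient is
#' per 10 index points) or the tertile category with T1 as reference
#' (`tertile`, emitting T2-vs-T1 and T3-vs-T1 contrasts). 95% confidence
#' intervals use the t distribution with residual degrees of freedom.
#'
#' @param data Analysis data frame (see [build_analysis_data()]) holding
#'   the outcome, the index columns (`<index>_adj`, `<index>_tertile`) and
#'   the covariates.
#' @param outcome Name of the outcome column (e.g. `"z_global"` or
#'   `"z_global_chg"`).
#' @param index `"PDI"`, `"hPDI"` or `"uPDI"`.
#' @param exposure_form `"continuous"` or `"tertile"`.
#' @param model `"crude"`, `"model1"` or `"model2"`.
#' @param baseline Optional name of a baseline-composite column added as a
#'   covariate in every tier (used by the longitudinal change models).
#' @param stratum Optional stratum label recorded in the result.
#' @return An object of class `pdi_fit`; use [tidy()] for the effect rows
#'   and [glance()] for the model summary.
#' @export
fit_model <- function(data, outcome, index = "PDI",
                      exposure_form = c("continuous", "tertile"),
                      model = c("crude", "model1", "model2"),
                      baseline = NULL, stratum = NA_character_) {
  exposure_form <- match.arg(exposure_form)
  model <- match.arg(model)
  pre <- index_prefix(index)

  exp_col <- if (exposure_form == "continuous") {
    paste0(pre, "_per10")
  } else {
    paste0(pre, "_tertile")
  }
  covs <- c(tier_covariates(model), baseline)
  need <- c(outcome, paste0(pre, if (exposure_form == "continuous")
    "_adj" else "_tertile"), covs)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("analysis data is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }

  df <- set_covariate_factors(tibble::as_tibble(data))
  if (exposure_form == "continuous") {
    df[[exp_col]] <- df[[paste0(pre, "_adj")]] / 10
  } else {
    df[[exp_col]] <- factor(df[[exp_col]], levels = c("T1", "T2", "T3"))
  }
  use <- c(outcome, exp_col, covs)
  df <- df[complete.cases(df[use]), use, drop = FALSE]

  fml <- stats::reformulate(c(exp_col, covs), response = outcome)
  mm <- model.matrix(fml, df)
  p <- ncol(mm)
  if (nrow(df) < p + 10) {
    abort(paste0("insufficient complete cases (", nrow(df),
                 ") for ", p, " parameters"))
  }
  qr_rank <- qr(mm)$rank
  if (qr_rank < p) {
    fit0 <- lm(fml, data = df)
    aliased <- names(coef(fit0))[is.na(coef(fit0))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  fit <- lm(fml, data = df)
  structure(list(
    fit = fit, index = index, outcome = outcome,
    exposure_form = exposure_form, exposure_col = exp_col, model = model,
    baseline = baseline, stratum = stratum, n_used = nrow(df)
  ), class = "pdi_fit")
}

#' @export
print.pdi_fit <- function(x, ...) {
  cat("<pdi_fit> ", x$index, " -> ", x$outcome, " (", x$model, ", ",
      x$exposure_form, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy the exposure estimates of a fitted diet-cognition model
#'
#' Returns one row per exposure contrast in the standard result layout:
#' effect estimate, 95% CI bounds, p-value, sample size, model tier and
#' exposure form (`continuous_per10`, `tertile_T2_vs_T1`,
#' `tertile_T3_vs_T1`).
#'
#' @param x A `pdi_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `index`, `outcome`, `exposure_form`,
#'   `model`, `beta`, `ci_low`, `ci_high`, `p`, `n_used`, `stratum`,
#'   `p_interaction`.
#' @method tidy pdi_fit
#' @export
tidy.pdi_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = 0.95)
  terms <- if (x$exposure_form == "continuous") {
    setNames(x$exposure_col, "continuous_per10")
  } else {
    setNames(paste0(x$exposure_col, c("T2", "T3")),
             c("tertile_T2_vs_T1", "tertile_T3_vs_T1"))
  }
  tibble::tibble(
    index = x$index,
    outcome = x$outcome,
    exposure_form = names(terms),
    model = x$model,
    beta = unname(sm[terms, "Estimate"]),
    ci_low = unname(ci[terms, 1]),
    ci_high = unname(ci[terms, 2]),
    p = unname(sm[terms, "Pr(>|t|)"]),
    n_used = x$n_used,
    stratum = x$stratum,
    p_interaction = NA_real_
  )
}

#' Model-level summary of a fitted diet-cognition model
#'
#' @param x A `pdi_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `n_used`.
#' @method glance pdi_fit
#' @export
glance.pdi_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df.residual = x$fit$df.residual,
    n_used = x$n_used
  )
}

composite_outcomes <- function(change = FALSE) {
  base <- c("z_global", "z_episodic_memory", "z_attention_wm",
            "z_processing_speed", "z_executive")
  if (change) paste0(base, "_chg") else base
}

run_design <- function(data, outcomes, baseline_map,
                       indices = c("PDI", "hPDI", "uPDI"),
                       models = c("crude", "model1", "model2")) {
  grid <- tidyr::expand_grid(index = indices, outcome = outcomes,
                             model = models,
                             exposure_form = c("tertile", "continuous"))
  purrr::pmap(grid, function(index, outcome, model, exposure_form) {
    tidy(fit_model(data, outcome = outcome, index = index,
                   exposure_form = exposure_form, model = model,
                   baseline = baseline_map[[outcome]]))
  }) |> purrr::list_rbind()
}

#' Cross-sectional analysis: baseline cognition on diet adherence
#'
#' Fits the full grid of cross-sectional models on the total study
#' population: 3 indices x 5 composite outcomes x 3 exposure contrasts
#' (T2 vs T1, T3 vs T1, continuous per 10 points) x 3 model tiers,
#' returning a tidy table of 135 result rows.
#'
#' @param data Analysis data frame from [build_analysis_data()].
#' @param indices,models Subsets of the default grids, if desired.
#' @return A tibble of association results (see [tidy.pdi_fit()]).
#' @export
run_cross_sectional <- function(data, indices = c("PDI", "hPDI", "uPDI"),
                                models = c("crude", "model1", "model2")) {
  run_design(data, composite_outcomes(change = FALSE),
             baseline_map = list(), indices = indices, models = models)
}

#' Longitudinal analysis: 2-year cognitive change on diet adherence
#'
#' Same grid as [run_cross_sectional()] but on the 2-year change composites,
#' restricted to the placebo arm (to keep the trial intervention out of the
#' change estimates) and with the corresponding baseline composite added as
#' a covariate in every tier.
#'
#' @inheritParams run_cross_sectional
#' @return A tibble of association results on the change outcomes.
#' @export
run_longitudinal <- function(data, indices = c("PDI", "hPDI", "uPDI"),
                             models = c("crude", "model1", "model2")) {
  if (!"arm" %in% names(data)) {
    abort("longitudinal analysis requires an `arm` column")
  }
  outcomes <- composite_outcomes(change = TRUE)
  missing <- setdiff(outcomes, names(data))
  if (length(missing) > 0) {
    abort(paste0("longitudinal analysis requires follow-up change columns; ",
                 "missing: ", paste(missing, collapse = ", ")))
  }
  placebo <- data[data$arm == "placebo", , drop = FALSE]
  if (nrow(placebo) == 0) abort("no placebo-arm participants in the data")
  baseline_map <- setNames(as.list(composite_outcomes(FALSE)), outcomes)
  run_design(placebo, outcomes, baseline_map = baseline_map,
             indices = indices, models = models)
}

#' Effect-modification analysis by animal-food consumption
#'
#' Splits the cohort at the cohort median intake of an animal food group
#' (fish, meat, eggs or dairy; low: below the median, high: at or above
#' it), fits the fully adjusted model in each stratum, and tests effect
#' modification with a single exposure-by-stratum product term added to the
#' pooled fully adjusted model (one-df Wald test).
#'
#' @param data Analysis data frame from [build_analysis_data()]; must
#'   contain the stratifier intake column.
#' @param by Stratifier: `"fish"`, `"meat"`, `"eggs"` or `"dairy"`.
#' @param outcome Outcome column; defaults to global cognition at baseline.
#' @param index Diet index for the exposure.
#' @param exposure_form `"continuous"` (default) or `"tertile"`; the
#'   interaction test always uses the continuous exposure unless
#'   `"tertile"` is selected, in which case the product term spans both
#'   tertile contrasts and a two-df test is reported.
#' @param design `"cross"` or `"long"`; the longitudinal design restricts
#'   to the placebo arm and adjusts for the baseline composite.
#' @param min_stratum_n Smallest admissible stratum size.
#' @return A two-row tibble (low/high stratum results) with the stratifier
#'   median in `split_at` and the interaction p-value replicated in
#'   `p_interaction`.
#' @export
stratified_analysis <- function(data, by = c("fish", "meat", "eggs", "dairy"),
                                outcome = "z_global", index = "PDI",
                                exposure_form = c("continuous", "tertile"),
                                design = c("cross", "long"),
                                min_stratum_n = 30) {
  by <- match.arg(by)
  exposure_form <- match.arg(exposure_form)
  design <- match.arg(design)
  if (!by %in% names(data)) {
    abort(paste0("stratifier column `", by, "` not found in data"))
  }
  baseline <- NULL
  if (design == "long") {
    if (!"arm" %in% names(data)) abort("longitudinal design requires `arm`")
    data <- data[data$arm == "placebo", , drop = FALSE]
    if (!grepl("_chg$", outcome)) outcome <- paste0(outcome, "_chg")
    baseline <- sub("_chg$", "", outcome)
  }
  split_at <- median(data[[by]])
  high <- data[[by]] >= split_at
  if (min(sum(high), sum(!high)) < min_stratum_n) {
    abort(paste0("degenerate stratum for `", by, "`: sizes ",
                 sum(!high), "/", sum(high)))
  }

  res <- purrr::map2(list(!high, high), c("low", "high"), function(sel, lab) {
    tidy(fit_model(data[sel, , drop = FALSE], outcome = outcome,
                   index = index, exposure_form = exposure_form,
                   model = "model2", baseline = baseline,
                   stratum = paste0(by, "_", lab)))
  }) |> purrr::list_rbind()

  # pooled fully adjusted model with exposure x high-stratum product term
  pre <- index_prefix(index)
  df <- set_covariate_factors(tibble::as_tibble(data))
  df$.high <- high
  if (exposure_form == "continuous") {
    df$.exposure <- df[[paste0(pre, "_adj")]] / 10
  } else {
    df$.exposure <- factor(df[[paste0(pre, "_tertile")]],
                           levels = c("T1", "T2", "T3"))
  }
  covs <- c(tier_covariates("model2"), baseline)
  fml <- stats::reformulate(c(".exposure * .high", covs), response = outcome)
  use <- c(outcome, ".exposure", ".high", covs)
  dfc <- df[complete.cases(df[use]), , drop = FALSE]
  pooled <- lm(fml, data = dfc)
  sm <- summary(pooled)$coefficients
  int_terms <- grep("^\\.exposure.*:\\.highTRUE$", rownames(sm), value = TRUE)
  p_int <- if (length(int_terms) == 1) {
    sm[int_terms, "Pr(>|t|)"]
  } else {
    # joint F test across the product terms (tertile exposure)
    red <- lm(stats::reformulate(c(".exposure", ".high", covs),
                                 response = outcome), data = dfc)
    stats::anova(red, pooled)[2, "Pr(>F)"]
  }
  res$p_interaction <- p_int
  res$split_at <- split_at
  res
}

#' Render association results in the conventional table format
#'
#' Formats each result row as `"beta [ci_low, ci_high] p"`, the cell format
#' conventionally used to report these models.
#'
#' @param results A result tibble from the analysis runners.
#' @param digits Decimal places for the estimate and CI (default 2).
#' @return The tibble with a `formatted` column added.
#' @export
format_results <- function(results, digits = 2) {
  fmt_p <- function(p) {
    ifelse(p < 0.01, "< 0.01", sprintf("%.2f", p))
  }
  results |>
    dplyr::mutate(formatted = sprintf(
      paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f] %s"),
      .data$beta, .data$ci_low, .data$ci_high, fmt_p(.data$p)
    ))
}
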