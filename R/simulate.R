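# Default gamma intake distributions (servings/day) per food group: mean and
# shape chosen to give right-skewed intakes on scales plausible for an
# older Dutch cohort; zero-inflation concentrates on episodically consumed
# groups (fish, legumes, nuts, juices, soft drinks). These are stated
# modelling assumptions, not estimates from any cohort.
default_intake_params <- function() {
  tibble::tribble(
    ~group,                      ~mean, ~shape,
    "whole_grains",               2.5,   2.0,
    "fruits",                     1.8,   2.0,
    "vegetables",                 2.2,   3.0,
    "nuts",                       0.40,  1.2,
    "legumes",                    0.25,  1.2,
    "vegetable_oils",             0.80,  1.5,
    "tea_coffee",                 4.5,   4.0,
    "fruit_juices",               0.50,  1.2,
    "refined_grains",             1.8,   2.0,
    "potatoes",                   0.90,  2.5,
    "sugar_sweetened_beverages",  0.40,  1.2,
    "sweets",                     1.5,   1.8,
    "animal_fat",                 0.50,  1.5,
    "dairy",                      3.0,   3.0,
    "fish",                       0.16,  1.3,
    "meat",                       1.2,   2.5,
    "eggs",                       0.35,  1.5,
    "misc_animal",                0.30,  1.2
  )
}

default_zero_inflation <- function() {
  zi <- setNames(rep(0, 18), intake_group_cols())
  zi[c("nuts", "legumes", "fish", "fruit_juices",
       "sugar_sweetened_beverages", "eggs", "misc_animal")] <-
    c(0.25, 0.35, 0.15, 0.20, 0.30, 0.10, 0.20)
  zi
}

# Cognitive test scales used by the generator: published-plausible means and
# SDs on each test's natural scale. The timed measures are generated through
# their latent "higher = better" form and sign-flipped onto seconds.
default_test_scales <- function() {
  tibble::tribble(
    ~measure,               ~mean, ~sd,   ~reversed,
    "ravlt_immediate",      42,    9,     FALSE,
    "ravlt_delayed",        8.5,   2.7,   FALSE,
    "ravlt_recognition",    27,    2.5,   FALSE,
    "digit_span_forward",   8.5,   2.0,   FALSE,
    "digit_span_backward",  6.0,   2.0,   FALSE,
    "sdmt",                 45,    10,    FALSE,
    "letter_fluency",       38,    11,    FALSE,
    "tmt_a_seconds",        45,    12,    TRUE,
    "tmt_ba_ratio",         2.4,   0.55,  TRUE,
    "stroop_basic",         47,    8,     TRUE,
    "stroop_interference",  1.9,   0.35,  TRUE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Effects are
#' expressed on the scale used by the downstream analysis: Z-score units of
#' the composite outcome per 10 points of energy-adjusted index. Invalid
#' fields are rejected with the field named.
#'
#' @param n_participants Cohort size (>= 25 recommended so every quintile
#'   holds several participants; a warning is issued below that).
#' @param seed Integer RNG seed; the generator is bit-reproducible given
#'   the seed.
#' @param effect_pdi_cross Cross-sectional effect of the energy-adjusted
#'   overall index (PDI) on latent cognition, in Z per 10 index points.
#' @param effect_hpdi_change Effect of the energy-adjusted healthful index
#'   (hPDI) on 2-year cognitive change, in Z per 10 index points.
#' @param fish_modification Additional cross-sectional per-10-point PDI
#'   effect among participants at or above the cohort median fish intake.
#' @param noise_sd_cognition SD of the test-specific noise around the
#'   shared latent ability, on the latent Z scale. The latent ability SD is
#'   set so each test's total baseline variance is 1 on that scale, so the
#'   default 0.5 corresponds to a per-test reliability of 0.75.
#' @param zero_inflation Named vector mapping food groups to the
#'   probability of zero intake; defaults concentrate on fish, legumes,
#'   nuts and similar episodically eaten groups.
#' @param missing_followup_fraction Fraction of participants (all arms)
#'   missing the 2-year battery, missing completely at random.
#' @param arm_fraction_placebo Probability of assignment to the placebo
#'   arm; assignment is independent of everything else (randomized trial).
#' @param age_mean,age_sd Target mean/SD of age in years; ages are drawn as
#'   65 + gamma so the cohort is 65+ while matching both moments.
#' @param prop_male Expected fraction of men.
#' @param effect_age Linear age gradient of latent cognition (Z per year,
#'   centred at the cohort mean age).
#' @param decline_mean,decline_sd Mean and between-person SD of the 2-year
#'   latent decline (Z units; negative mean = decline).
#' @param intake_params Gamma mean/shape per food group
#'   (see `pdicog:::default_intake_params`).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 658,
                       seed = 1L,
                       effect_pdi_cross = 0,
                       effect_hpdi_change = 0,
                       fish_modification = 0,
                       noise_sd_cognition = 0.5,
                       zero_inflation = default_zero_inflation(),
                       missing_followup_fraction = 0.05,
                       arm_fraction_placebo = 0.5,
                       age_mean = 72.1,
                       age_sd = 5.4,
                       prop_male = 0.59,
                       effect_age = -0.02,
                       decline_mean = -0.12,
                       decline_sd = 0.25,
                       intake_params = default_intake_params()) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    effect_pdi_cross = effect_pdi_cross,
    effect_hpdi_change = effect_hpdi_change,
    fish_modification = fish_modification,
    noise_sd_cognition = noise_sd_cognition,
    zero_inflation = zero_inflation,
    missing_followup_fraction = missing_followup_fraction,
    arm_fraction_placebo = arm_fraction_placebo,
    age_mean = age_mean, age_sd = age_sd, prop_male = prop_male,
    effect_age = effect_age,
    decline_mean = decline_mean, decline_sd = decline_sd,
    intake_params = tibble::as_tibble(intake_params)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_num <- function(field, len = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != len || any(!is.finite(v))) {
      abort(paste0("`", field, "` must be a finite numeric of length ", len))
    }
  }
  chk_num("n_participants")
  if (cfg$n_participants < 5) {
    abort("`n_participants` must be at least 5 (quintile scoring)")
  }
  if (cfg$n_participants < 25) {
    warn(paste0("`n_participants` = ", cfg$n_participants,
                " gives fewer than 5 participants per quintile on average"))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort("`seed` must be a single integer")
  }
  for (f in c("effect_pdi_cross", "effect_hpdi_change", "fish_modification",
              "effect_age", "decline_mean")) {
    chk_num(f)
  }
  for (f in c("noise_sd_cognition", "age_sd", "decline_sd")) {
    chk_num(f)
    if (cfg[[f]] < 0) abort(paste0("`", f, "` must be non-negative"))
  }
  for (f in c("missing_followup_fraction", "arm_fraction_placebo",
              "prop_male")) {
    chk_num(f)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("`", f, "` must lie in [0, 1]"))
    }
  }
  chk_num("age_mean")
  if (cfg$age_mean <= 65) abort("`age_mean` must exceed 65")
  zi <- cfg$zero_inflation
  if (is.null(names(zi)) || !all(names(zi) %in% intake_group_cols())) {
    abort("`zero_inflation` must be named by food group")
  }
  if (any(zi < 0 | zi > 1)) abort("`zero_inflation` must lie in [0, 1]")
  full_zi <- setNames(rep(0, 18), intake_group_cols())
  full_zi[names(zi)] <- zi
  cfg$zero_inflation <- full_zi
  ip <- cfg$intake_params
  if (!all(c("group", "mean", "shape") %in% names(ip)) ||
      !setequal(ip$group, intake_group_cols())) {
    abort("`intake_params` must cover exactly the 18 food groups")
  }
  if (any(ip$mean <= 0) || any(ip$shape <= 0)) {
    abort("`intake_params` means and shapes must be > 0")
  }
  structure(cfg, class = "sim_config")
}

# Zero-inflated gamma draw on the group's natural scale
rzigamma <- function(n, mean, shape, p_zero) {
  x <- rgamma(n, shape = shape, scale = mean / shape)
  if (p_zero > 0) x[runif(n) < p_zero] <- 0
  x
}

# Generate one battery from latent cognition c (Z scale). Each composite
# measure gets its own noise; the raw Stroop cards and TMT part B are
# reconstructed from the generated derived quantities so the downstream
# derivations (Stroop I-II mean, interference ratio, TMT B/A) recover the
# latent structure exactly.
generate_battery <- function(ids, latent, noise_sd, include_mmse = TRUE) {
  n <- length(latent)
  scales <- default_test_scales()
  vals <- purrr::map(setNames(nm = scales$measure), function(m) {
    sc <- scales[scales$measure == m, ]
    z <- latent + rnorm(n, 0, noise_sd)
    if (sc$reversed) sc$mean - sc$sd * z else sc$mean + sc$sd * z
  })
  # floors keep counts non-negative and times positive; hit only in far tails
  for (m in c("ravlt_immediate", "ravlt_delayed", "ravlt_recognition",
              "digit_span_forward", "digit_span_backward", "sdmt",
              "letter_fluency")) {
    vals[[m]] <- pmax(vals[[m]], 0)
  }
  vals$tmt_a_seconds <- pmax(vals$tmt_a_seconds, 6)
  vals$tmt_ba_ratio <- pmax(vals$tmt_ba_ratio, 1.05)
  vals$stroop_basic <- pmax(vals$stroop_basic, 12)
  vals$stroop_interference <- pmax(vals$stroop_interference, 1.05)

  # split the basic-card mean into word (I, faster) and colour (II) cards,
  # and rebuild part B / card III from the generated ratios
  gap <- pmin(pmax(rnorm(n, 0.09, 0.03), 0), 0.3)
  battery <- tibble::tibble(
    participant_id = ids,
    ravlt_immediate = vals$ravlt_immediate,
    ravlt_delayed = vals$ravlt_delayed,
    ravlt_recognition = vals$ravlt_recognition,
    digit_span_forward = vals$digit_span_forward,
    digit_span_backward = vals$digit_span_backward,
    tmt_a_seconds = vals$tmt_a_seconds,
    tmt_b_seconds = vals$tmt_a_seconds * vals$tmt_ba_ratio,
    stroop1_seconds = vals$stroop_basic * (1 - gap),
    stroop2_seconds = vals$stroop_basic * (1 + gap),
    stroop3_seconds = vals$stroop_basic * vals$stroop_interference,
    sdmt = vals$sdmt,
    letter_fluency = vals$letter_fluency
  )
  if (include_mmse) {
    battery$mmse <- pmin(pmax(round(28.8 + 0.7 * latent + rnorm(n, 0, 0.8)),
                              0), 30)
  }
  battery
}

#' Simulate a synthetic older-adult cohort
#'
#' Generates participant-level data with the statistical structure the
#' diet-cognition analysis assumes: right-skewed, partly zero-inflated
#' food-group intakes; total energy positively correlated with summed
#' intake; covariates for a community-dwelling 65+ cohort; and a cognitive
#' battery at baseline and 2-year follow-up driven by a shared latent
#' ability plus configurable linear diet effects. Effects are injected on
#' the energy-adjusted index scale (per 10 points), so the downstream
#' regression estimand equals the configured value; the latent-ability
#' variance is calibrated so each test has unit total variance at baseline,
#' making baseline Z-standardization recover the latent scale.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_cohort` with elements `intake`,
#'   `covariates`, `battery_baseline`, `battery_followup` (rows only for
#'   participants with follow-up), `arm` (tibble: `participant_id`, `arm`)
#'   and `true_params` (the generating effect sizes and calibration).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 100, seed = 1))
#' nrow(cohort$intake)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  withr::with_seed(as.integer(config$seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- as.integer(cfg$n_participants)
  ids <- sprintf("P%04d", seq_len(n))
  gender <- ifelse(runif(n) < cfg$prop_male, "male", "female")

  # intakes: zero-inflated gamma per group, drawn in fixed group order
  ip <- cfg$intake_params[match(intake_group_cols(), cfg$intake_params$group), ]
  intake <- tibble::tibble(participant_id = ids)
  for (i in seq_len(nrow(ip))) {
    g <- ip$group[i]
    intake[[g]] <- rzigamma(n, ip$mean[i], ip$shape[i], cfg$zero_inflation[[g]])
  }
  intake$alcohol <- rzigamma(n, 1.0, 0.8, 0.25)
  intake$margarine <- rzigamma(n, 18, 1.2, 0.10)
  total <- rowSums(intake[intake_group_cols()])
  intake$energy <- pmax(600 + 300 * (gender == "male") + 55 * total +
                          rnorm(n, 0, 200), 400)
  intake$gender <- gender

  # covariates: age as 65 + gamma matching the target mean/SD above 65
  age_shape <- ((cfg$age_mean - 65) / cfg$age_sd)^2
  age_scale <- cfg$age_sd^2 / (cfg$age_mean - 65)
  covariates <- tibble::tibble(
    participant_id = ids,
    age = 65 + rgamma(n, shape = age_shape, scale = age_scale),
    gender = gender,
    education = sample(c("low", "middle", "high"), n, replace = TRUE,
                       prob = c(0.43, 0.24, 0.33)),
    bmi = pmax(rnorm(n, 27.2, 3.9), 16),
    physical_activity = rgamma(n, shape = 2.2, scale = 27),
    smoking = sample(c("never", "current", "former"), n, replace = TRUE,
                     prob = c(0.30, 0.11, 0.59)),
    alcohol_category = cut(intake$alcohol, breaks = c(-Inf, 1, 3, Inf),
                           labels = c("light", "moderate", "excessive")) |>
      as.character(),
    margarine = intake$margarine
  )

  arm <- tibble::tibble(
    participant_id = ids,
    arm = ifelse(runif(n) < cfg$arm_fraction_placebo,
                 "placebo", "intervention")
  )

  # exposures as the downstream analysis defines them: energy-adjusted
  # index per 10 points, centred
  scored <- suppressMessages(score_diet(intake))
  x_pdi <- (scored$pdi_adj - mean(scored$pdi_adj)) / 10
  x_hpdi <- (scored$hpdi_adj - mean(scored$hpdi_adj)) / 10
  fish_high <- intake$fish >= median(intake$fish)

  # deterministic part of latent baseline cognition; the residual ability
  # SD is set so total latent variance is 1 - noise_sd^2, hence each
  # generated test has unit variance at baseline
  det1 <- cfg$effect_pdi_cross * x_pdi +
    cfg$fish_modification * x_pdi * fish_high +
    cfg$effect_age * (covariates$age - mean(covariates$age))
  det1 <- det1 - mean(det1)
  ability_var <- 1 - cfg$noise_sd_cognition^2 -
    stats::var(det1) * (n - 1) / n
  if (ability_var < 0.02) {
    warn("simulate_cohort: configured effects and noise leave almost no latent ability variance; flooring at 0.02")
    ability_var <- 0.02
  }
  latent1 <- det1 + rnorm(n, 0, sqrt(ability_var))

  battery_baseline <- generate_battery(ids, latent1, cfg$noise_sd_cognition)

  decline <- cfg$decline_mean + cfg$effect_hpdi_change * x_hpdi +
    rnorm(n, 0, cfg$decline_sd)
  latent2 <- latent1 + decline
  has_fu <- runif(n) >= cfg$missing_followup_fraction
  battery_followup <- generate_battery(ids, latent2,
                                       cfg$noise_sd_cognition)[has_fu, ]

  structure(list(
    intake = intake,
    covariates = covariates,
    battery_baseline = battery_baseline,
    battery_followup = battery_followup,
    arm = arm,
    true_params = list(
      effect_pdi_cross = cfg$effect_pdi_cross,
      effect_hpdi_change = cfg$effect_hpdi_change,
      fish_modification = cfg$fish_modification,
      effect_age = cfg$effect_age,
      decline_mean = cfg$decline_mean,
      noise_sd_cognition = cfg$noise_sd_cognition,
      ability_sd = sqrt(ability_var),
      fish_median = median(intake$fish)
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  participants:", nrow(x$intake), "\n")
  cat("  with follow-up battery:", nrow(x$battery_followup), "\n")
  cat("  placebo arm:", sum(x$arm$arm == "placebo"), "\n")
  tp <- x$true_params
  cat(sprintf("  true effects: PDI cross %.3f, hPDI change %.3f, fish mod %.3f\n",
              tp$effect_pdi_cross, tp$effect_hpdi_change,
              tp$fish_modification))
  invisible(x)
}

#' Write the cohort tables as CSV
#'
#' Writes `intake.csv`, `covariates.csv`, `battery_baseline.csv`,
#' `battery_followup.csv` and `arm.csv` to a directory, with columns as
#' documented in the respective table constructors.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("intake", "covariates", "battery_baseline",
              "battery_followup", "arm")
  for (tb in tables) {
    readr::write_csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  invisible(dir)
}
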