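# Minimal analysis frame with a fully controlled outcome
toy_analysis_data <- function(n = 120, seed = 51) {
  set.seed(seed)
  tibble::tibble(
    participant_id = seq_len(n),
    pdi_adj = rnorm(n, 54, 6),
    pdi_tertile = NA,
    age = runif(n, 65, 85),
    gender = sample(c("male", "female"), n, TRUE),
    education = sample(c("low", "middle", "high"), n, TRUE),
    bmi = rnorm(n, 27, 4),
    physical_activity = rgamma(n, 2, scale = 25),
    smoking = sample(c("never", "current", "former"), n, TRUE),
    alcohol_category = sample(c("light", "moderate", "excessive"), n, TRUE),
    margarine = rgamma(n, 1.5, scale = 10)
  ) |>
    dplyr::mutate(pdi_tertile = assign_tertiles(.data$pdi_adj))
}

test_that("a noiseless linear outcome is recovered exactly", {
  d <- toy_analysis_data()
  d$z_global <- 0.05 * (d$pdi_adj / 10)
  fit <- fit_model(d, "z_global", "PDI", "continuous", "crude")
  td <- suppressWarnings(tidy(fit))  # summary.lm warns on a perfect fit
  expect_equal(td$beta, 0.05, tolerance = 1e-10)
  expect_lt(td$ci_high - td$ci_low, 1e-8)
  expect_equal(td$n_used, 120)
})

test_that("estimates and intervals equal the normal-equations computation", {
  d <- toy_analysis_data(n = 80, seed = 52)
  d$z_global <- 0.1 * (d$pdi_adj / 10) - 0.02 * d$age + rnorm(80, 0, 0.7)
  fit <- fit_model(d, "z_global", "PDI", "continuous", "model1")
  td <- tidy(fit)

  X <- cbind(1, d$pdi_adj / 10, d$age,
             d$gender == "female",
             d$education == "middle", d$education == "high")
  o <- oracle_ols(X, d$z_global)
  expect_equal(td$beta, o$beta[2], tolerance = 1e-8)
  tq <- qt(0.975, o$df)
  expect_equal(td$ci_low, o$beta[2] - tq * o$se[2], tolerance = 1e-8)
  expect_equal(td$ci_high, o$beta[2] + tq * o$se[2], tolerance = 1e-8)
  expect_equal(td$p, 2 * pt(-abs(o$beta[2] / o$se[2]), o$df),
               tolerance = 1e-8)
  expect_equal(glance(fit)$df.residual, o$df)
})

test_that("tertile exposures emit T2 and T3 contrasts against T1", {
  d <- toy_analysis_data()
  d$z_global <- as.integer(d$pdi_tertile) * 0.3
  td <- suppressWarnings(tidy(fit_model(d, "z_global", "PDI", "tertile",
                                        "crude")))
  expect_equal(td$exposure_form, c("tertile_T2_vs_T1", "tertile_T3_vs_T1"))
  expect_equal(td$beta, c(0.3, 0.6), tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- toy_analysis_data()
  d$z_global <- rnorm(120)
  d$bmi <- d$age  # collinear
  expect_error(fit_model(d, "z_global", "PDI", "continuous", "model2"),
               "collinear")
  small <- toy_analysis_data()[1:12, ]
  small$z_global <- rnorm(12)
  expect_error(fit_model(small, "z_global", "PDI", "continuous", "model2"),
               "insufficient")
  expect_error(fit_model(d, "z_global", "XDI"), "index")
  expect_error(fit_model(dplyr::select(d, -"pdi_adj"), "z_global", "PDI"),
               "missing")
  bad <- toy_analysis_data()
  bad$z_global <- rnorm(120)
  bad$smoking[1] <- "vaping"
  expect_error(fit_model(bad, "z_global", "PDI", "continuous", "model2"),
               "smoking")
})

test_that("the cross-sectional grid covers 3 x 5 x 3 x 3 result rows", {
  cohort <- simulate_cohort(sim_config(n_participants = 200, seed = 53,
                                       effect_pdi_cross = 0.1))
  data <- quiet_analysis_data(cohort)
  res <- run_cross_sectional(data)
  expect_equal(nrow(res), 135)
  expect_equal(
    nrow(dplyr::distinct(res, .data$index, .data$outcome, .data$model,
                         .data$exposure_form)), 135)
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$n_used <= 200))
  # deterministic given the cohort
  expect_identical(res, run_cross_sectional(data))
})

test_that("longitudinal models use the placebo arm and baseline adjustment", {
  cohort <- simulate_cohort(sim_config(n_participants = 250, seed = 54,
                                       effect_hpdi_change = 0.1))
  data <- quiet_analysis_data(cohort)
  res <- run_longitudinal(data)
  expect_equal(nrow(res), 135)
  n_placebo <- sum(data$arm == "placebo")
  expect_true(all(res$n_used <= n_placebo))
  expect_true(all(grepl("_chg$", res$outcome)))

  no_fu <- data[setdiff(names(data), grep("_(fu|chg)$", names(data),
                                          value = TRUE))]
  expect_error(run_longitudinal(no_fu), "follow-up")
  all_int <- dplyr::mutate(data, arm = "intervention")
  expect_error(run_longitudinal(all_int), "placebo")
  expect_error(run_longitudinal(dplyr::select(data, -"arm")), "arm")
})

test_that("the baseline covariate changes the longitudinal fit", {
  cohort <- simulate_cohort(sim_config(n_participants = 250, seed = 55))
  data <- quiet_analysis_data(cohort)
  placebo <- data[data$arm == "placebo", ]
  with_bl <- fit_model(placebo, "z_global_chg", "PDI", "continuous",
                       "crude", baseline = "z_global")
  without_bl <- fit_model(placebo, "z_global_chg", "PDI", "continuous",
                          "crude")
  expect_true("z_global" %in% names(coef(with_bl$fit)))
  expect_false("z_global" %in% names(coef(without_bl$fit)))
})

test_that("median-split strata follow the at-or-above-median convention", {
  cohort <- simulate_cohort(sim_config(n_participants = 400, seed = 56,
                                       fish_modification = 0.2))
  data <- quiet_analysis_data(cohort)
  st <- stratified_analysis(data, "fish")
  m <- median(data$fish)
  expect_equal(unique(st$split_at), m)
  expect_equal(st$n_used[st$stratum == "fish_high"], sum(data$fish >= m))
  expect_equal(st$n_used[st$stratum == "fish_low"], sum(data$fish < m))
  expect_equal(length(unique(st$p_interaction)), 1)
  expect_true(st$p_interaction[1] > 0 & st$p_interaction[1] <= 1)

  # the documented convention on a tiny vector: exact median goes high
  x <- c(1, 2, 3, 4)
  expect_equal(sum(x >= median(x)), 2)
  expect_error(stratified_analysis(data, "fish", min_stratum_n = 300),
               "degenerate")
  expect_error(stratified_analysis(dplyr::select(data, -"fish"), "fish"),
               "fish")
})

test_that("tertile and continuous estimates agree in sign for linear effects", {
  agree <- vapply(1:5, function(i) {
    cohort <- simulate_cohort(sim_config(n_participants = 500,
                                         seed = 5600 + i,
                                         effect_pdi_cross = 0.3))
    data <- quiet_analysis_data(cohort)
    t3 <- tidy(fit_model(data, "z_global", "PDI", "tertile", "model2"))
    cont <- tidy(fit_model(data, "z_global", "PDI", "continuous", "model2"))
    sign(t3$beta[t3$exposure_form == "tertile_T3_vs_T1"]) ==
      sign(cont$beta)
  }, logical(1))
  expect_true(all(agree))
})

test_that("results render in the conventional cell format", {
  res <- tibble::tibble(beta = c(0.041, -0.136), ci_low = c(-0.052, -0.24),
                        ci_high = c(0.134, -0.04), p = c(0.40, 0.008))
  fmt <- format_results(res)$formatted
  expect_equal(fmt[1], "0.04 [-0.05, 0.13] 0.40")
  expect_equal(fmt[2], "-0.14 [-0.24, -0.04] < 0.01")
})
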