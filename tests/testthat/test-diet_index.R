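test_that("quintile scores assign one fifth per score on tie-free input", {
  expect_equal(quintile_rank(c(10, 20, 30, 40, 50)), 1:5)

  set.seed(21)
  x <- runif(25)
  s <- quintile_rank(x)
  expect_equal(as.integer(table(s)), rep(5L, 5))
  expect_equal(s, oracle_quintile(x))

  # scores are monotone in intake
  expect_true(all(diff(s[order(x)]) >= 0))
})

test_that("ties share a score determined by their common CDF value", {
  set.seed(22)
  x <- rgamma(100, 1.5)
  x[sample(100, 40)] <- 0
  s <- quintile_rank(x)
  expect_equal(length(unique(s[x == 0])), 1L)
  expect_equal(min(s[x > 0]), max(s[x == 0]) + 1L)
  expect_equal(s, oracle_quintile(x))
})

test_that("quintile scoring matches the brute-force oracle on random vectors", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    x <- rgamma(n, shape = runif(1, 0.5, 3))
    x[runif(n) < runif(1, 0, 0.6)] <- 0
    if (length(unique(x)) == 1) next
    expect_equal(quintile_rank(x), oracle_quintile(x))
  }
})

test_that("degenerate and undersized intake vectors are handled explicitly", {
  expect_warning(s <- quintile_rank(rep(2, 10)), "degenerate")
  expect_equal(s, rep(1L, 10))
  expect_error(quintile_rank(c(1, 2, 3)), "at least 5")
  expect_error(quintile_rank(c(1, 2, 3, 4, NA)), "finite")
  expect_error(quintile_rank(c(1, 2, 3, 4, -1)), "non-negative")
})

test_that("index summation applies scheme directions and bounds", {
  groups <- food_groups()$group
  mid <- tibble::as_tibble(setNames(as.list(rep(3L, 18)), groups))
  for (sch in c("PDI", "hPDI", "uPDI")) {
    expect_equal(score_index(mid, sch), 54L)
  }

  plant <- food_groups()$group[food_groups()$category != "animal"]
  animal <- setdiff(groups, plant)
  best <- mid
  best[plant] <- 5L
  best[animal] <- 1L
  expect_equal(score_index(best, "PDI"), 12L * 5L + 6L * (6L - 1L))

  expect_error(score_index(mid[-1], "PDI"), "whole_grains")
  expect_error(score_index(dplyr::mutate(mid, fish = 7L), "PDI"), "1..5")
})

test_that("index algebra identities hold on random cohorts", {
  set.seed(31)
  groups <- food_groups()
  healthy <- groups$group[groups$category == "healthy_plant"]
  unhealthy <- groups$group[groups$category == "unhealthy_plant"]
  animal <- groups$group[groups$category == "animal"]
  for (i in 1:25) {
    intake <- random_intake(50, p_zero = runif(1, 0, 0.4))
    scores <- purrr::map(setNames(nm = groups$group), function(g) {
      suppressWarnings(quintile_rank(intake[[g]]))
    }) |> tibble::as_tibble()
    pdi <- score_index(scores, "PDI")
    hpdi <- score_index(scores, "hPDI")
    updi <- score_index(scores, "uPDI")
    expect_true(all(pdi >= 18 & pdi <= 90))
    expect_true(all(hpdi >= 18 & hpdi <= 90))
    expect_true(all(updi >= 18 & updi <= 90))
    animal_rev <- rowSums(6L - as.matrix(scores[animal]))
    expect_equal(hpdi + updi - 2 * animal_rev, rep(72, 50))
    expect_equal(pdi - updi, 2 * rowSums(as.matrix(scores[healthy])) - 42)
    expect_equal(pdi - hpdi, 2 * rowSums(as.matrix(scores[unhealthy])) - 30)
  }
})

test_that("tie-free cohorts with n divisible by 5 have mean index exactly 54", {
  set.seed(32)
  intake <- random_intake(100)
  scored <- score_diet(intake)
  expect_identical(mean(scored$pdi_raw), 54)
  expect_identical(mean(scored$hpdi_raw), 54)
  expect_identical(mean(scored$updi_raw), 54)
  # per-group score distribution exactly uniform
  expect_equal(as.integer(table(scored$score_fish)), rep(20L, 5))
})

test_that("residual-method energy adjustment behaves as specified", {
  set.seed(33)
  n <- 200
  energy <- runif(n, 1500, 3000)

  # index built orthogonal to energy: adjustment is a no-op
  noise <- rnorm(n)
  noise <- unname(residuals(lm(noise ~ energy)))
  idx <- 54 + noise
  expect_equal(energy_adjust(idx, energy), idx, tolerance = 1e-12)

  # index perfectly explained by energy: adjusted collapses to the mean
  idx2 <- 0.01 * energy
  adj2 <- energy_adjust(idx2, energy)
  expect_equal(adj2, rep(mean(idx2), n), tolerance = 1e-10)

  # random cohort: mean preserved, energy component annihilated, and the
  # result equals the normal-equations computation
  idx3 <- rnorm(n, 54, 6) + 0.004 * energy
  adj3 <- energy_adjust(idx3, energy)
  expect_equal(mean(adj3), mean(idx3), tolerance = 1e-10)
  expect_lt(abs(cor(adj3, energy)), 1e-8)
  o <- oracle_ols(cbind(1, energy), idx3)
  expect_equal(adj3, idx3 - o$beta[2] * (energy - mean(energy)),
               tolerance = 1e-10)

  expect_warning(same <- energy_adjust(idx3, rep(2000, n)), "constant")
  expect_equal(same, idx3)
  expect_error(energy_adjust(idx3, energy[-1]), "length")
  expect_error(energy_adjust(idx3, c(energy[-1], 0)), "> 0")
})

test_that("tertile assignment is cohort-specific with T1 lowest", {
  t <- assign_tertiles(1:9)
  expect_equal(as.character(t), rep(c("T1", "T2", "T3"), each = 3))

  expect_warning(td <- assign_tertiles(rep(4, 6)), "degenerate")
  expect_equal(as.character(td), rep("T1", 6))
  expect_error(assign_tertiles(c(1, 2)), "at least 3")

  set.seed(34)
  x <- rnorm(658)
  t2 <- assign_tertiles(x)
  sizes <- as.integer(table(t2))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(as.character(t2), oracle_tertile_chunks(x))
})

test_that("score_diet returns the documented per-participant layout", {
  set.seed(35)
  intake <- random_intake(60, p_zero = 0.2)
  scored <- suppressWarnings(score_diet(intake))
  expect_equal(nrow(scored), 60)
  expect_true(all(paste0("score_", food_groups()$group) %in% names(scored)))
  expect_true(all(c("pdi_raw", "hpdi_raw", "updi_raw", "pdi_adj",
                    "hpdi_adj", "updi_adj", "pdi_tertile", "hpdi_tertile",
                    "updi_tertile") %in% names(scored)))
  expect_true(all(levels(scored$pdi_tertile) == c("T1", "T2", "T3")))
  # energy adjustment preserved each index mean
  expect_equal(mean(scored$pdi_adj), mean(scored$pdi_raw), tolerance = 1e-10)
  # tertiles computed on the adjusted index
  expect_equal(as.character(scored$pdi_tertile),
               oracle_tertile_chunks(scored$pdi_adj))
})
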