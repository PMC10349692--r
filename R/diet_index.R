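# Rank-based k-quantile scores from the empirical CDF, shared by the
# quintile (k = 5) and tertile (k = 3) assignments. With F(x) the empirical
# CDF, a value receives score s iff F(x) in ((s-1)/k, s/k]; ties share one
# score because they share F(x). Integer arithmetic avoids float edge cases:
# score = ceiling(k * r / n) with r the ties-max rank (= n * F(x)).
quantile_scores <- function(x, k) {
  n <- length(x)
  r <- rank(x, ties.method = "max")
  as.integer((k * r + n - 1L) %/% n)
}

#' Cohort-specific quintile scores for one food group
#'
#' Ranks a cohort's intake of a food group into cohort-specific quintiles
#' and assigns each participant an integer score 1-5 (1 = lowest fifth of
#' the intake distribution). Equal intakes always receive equal scores:
#' tied values share the score implied by their common empirical-CDF value,
#' so with heavy ties (e.g. many zero consumers) some lower scores may go
#' unused. With no ties and `n` divisible by 5 the scores are exactly
#' uniform with n/5 participants per score.
#'
#' @param x Numeric vector of intakes (servings/day) across the cohort;
#'   must be finite, non-negative and of length >= 5.
#' @return Integer vector of scores in 1..5, same length as `x`.
#' @examples
#' quintile_rank(c(10, 20, 30, 40, 50))
#' @export
quintile_rank <- function(x) {
  if (length(x) < 5) {
    abort("quintile_rank requires at least 5 observations")
  }
  if (!all(is.finite(x)) || any(x < 0)) {
    abort("quintile_rank requires finite, non-negative intakes")
  }
  if (length(unique(x)) == 1L) {
    warn("quintile_rank: all intakes equal (degenerate group); scoring all 1")
    return(rep(1L, length(x)))
  }
  quantile_scores(x, 5L)
}

#' Sum 18 quintile scores into a plant-based diet index
#'
#' Applies a scoring scheme to a table of per-group quintile scores and
#' returns the raw index: positively scored groups contribute their
#' quintile score, reversed groups contribute 6 minus it. With 18 groups
#' each contributing 1-5 points the raw index is bounded in \[18, 90\].
#'
#' @param scores A data frame with `participant_id` and one integer score
#'   column (1-5) per food group, as produced by [quintile_rank()].
#' @param scheme `"PDI"`, `"hPDI"` or `"uPDI"`, or a directions table from
#'   [scheme_directions()].
#' @return Integer vector of raw index values, one per row of `scores`.
#' @export
score_index <- function(scores, scheme = "PDI") {
  if (is.character(scheme)) scheme <- scheme_directions(scheme)
  missing <- setdiff(scheme$group, names(scores))
  if (length(missing) > 0) {
    abort(paste0("scores table is missing group(s): ",
                 paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(scores[scheme$group])
  if (any(!mat %in% 1:5)) {
    abort("per-group quintile scores must be integers in 1..5")
  }
  rev_idx <- scheme$direction == "reversed"
  mat[, rev_idx] <- 6L - mat[, rev_idx]
  as.integer(rowSums(mat))
}

#' Energy-adjust a diet index by the residual method
#'
#' Regresses the index on total energy intake (simple least squares) and
#' replaces it with the residual plus the predicted index at the cohort-mean
#' energy. The adjusted index therefore keeps the cohort mean of the raw
#' index while having zero sample correlation with energy (up to numerical
#' tolerance).
#'
#' @param index Numeric vector of raw index values.
#' @param energy Numeric vector of energy intakes (kcal/day, > 0), same
#'   length.
#' @return Numeric vector of energy-adjusted index values.
#' @export
energy_adjust <- function(index, energy) {
  if (length(index) != length(energy)) {
    abort("`index` and `energy` must have the same length")
  }
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    abort("`energy` must be finite and > 0")
  }
  if (stats::var(energy) == 0) {
    warn("energy_adjust: constant energy vector; returning index unchanged")
    return(as.double(index))
  }
  fit <- lm(index ~ energy)
  # residual + fitted value at mean energy; with an intercept the latter is
  # exactly mean(index)
  unname(stats::residuals(fit) + mean(index))
}

#' Assign cohort-specific tertile categories
#'
#' Splits a (typically energy-adjusted) index into cohort-specific tertiles
#' T1 < T2 < T3, with T1 the lowest-adherence third used as the reference
#' category in regression. Ties share one label via their common
#' empirical-CDF value; with tie-free values the category sizes differ by
#' at most one.
#'
#' @param x Numeric vector, length >= 3.
#' @return Factor with levels `T1`, `T2`, `T3`.
#' @export
assign_tertiles <- function(x) {
  if (length(x) < 3) {
    abort("assign_tertiles requires at least 3 observations")
  }
  if (!all(is.finite(x))) {
    abort("assign_tertiles requires finite values")
  }
  if (length(unique(x)) == 1L) {
    warn("assign_tertiles: all values equal (degenerate); assigning all T1")
    return(factor(rep("T1", length(x)), levels = c("T1", "T2", "T3")))
  }
  factor(paste0("T", quantile_scores(x, 3L)), levels = c("T1", "T2", "T3"))
}

#' Score the three plant-based diet indices for a cohort
#'
#' End-to-end diet scoring: cohort-specific quintile scores for each of the
#' 18 food groups, the three raw indices (PDI, hPDI, uPDI), residual-method
#' energy adjustment of each, and tertile categories. Tertiles are computed
#' on the energy-adjusted index (the analysed exposure) by default;
#' `tertiles_on = "raw"` gives the unadjusted alternative.
#'
#' @param intake A validated intake table (see [validate_intake()]).
#' @param energy_adjust Logical; apply residual-method energy adjustment
#'   (default `TRUE`). When `FALSE` the `_adj` columns equal the raw index.
#' @param tertiles_on `"adjusted"` (default) or `"raw"`.
#' @return A tibble with `participant_id`, one `score_<group>` column per
#'   food group, `pdi_raw`, `hpdi_raw`, `updi_raw`, `pdi_adj`, `hpdi_adj`,
#'   `updi_adj` and `pdi_tertile`, `hpdi_tertile`, `updi_tertile`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 50, seed = 1))
#' scores <- score_diet(cohort$intake)
#' dplyr::glimpse(scores[, c("participant_id", "pdi_raw", "pdi_adj")])
#' @export
score_diet <- function(intake, energy_adjust = TRUE,
                       tertiles_on = c("adjusted", "raw")) {
  tertiles_on <- match.arg(tertiles_on)
  intake <- validate_intake(intake)
  groups <- intake_group_cols()

  scores <- purrr::map(setNames(groups, paste0("score_", groups)),
                       function(g) quintile_rank(intake[[g]])) |>
    tibble::as_tibble() |>
    dplyr::mutate(participant_id = intake$participant_id, .before = 1)

  score_tbl <- scores |>
    dplyr::rename_with(~ sub("^score_", "", .x), dplyr::starts_with("score_"))

  out <- scores
  for (sch in c("PDI", "hPDI", "uPDI")) {
    pre <- c(PDI = "pdi", hPDI = "hpdi", uPDI = "updi")[[sch]]
    raw <- score_index(score_tbl, sch)
    adj <- if (energy_adjust) {
      energy_adjust(raw, intake$energy)
    } else {
      as.double(raw)
    }
    out[[paste0(pre, "_raw")]] <- raw
    out[[paste0(pre, "_adj")]] <- adj
    out[[paste0(pre, "_tertile")]] <-
      assign_tertiles(if (tertiles_on == "adjusted") adj else raw)
  }
  out
}
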