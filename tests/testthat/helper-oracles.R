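# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately avoid the package's own code paths.

# Empirical-CDF quintile oracle: value with CDF value F gets score s iff
# F lies in ((s-1)/5, s/5]; ties share the score of their common F.
oracle_quintile <- function(x) {
  vapply(x, function(xi) {
    F <- mean(x <= xi)
    which(F > (0:4) / 5 - 1e-12 & F <= (1:5) / 5 + 1e-12)[1]
  }, integer(1))
}

# Sort-and-chunk oracle for tertiles of tie-free values
oracle_tertile_chunks <- function(x) {
  n <- length(x)
  sizes <- diff(floor(n * (0:3) / 3))
  rep(c("T1", "T2", "T3"), times = sizes)[rank(x)]
}

# Closed-form OLS via the normal equations
oracle_ols <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(beta = drop(beta), se = se, df = df)
}

# Random group-level intake table with configurable zero inflation,
# independent of the generator under test
random_intake <- function(n, p_zero = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- pdicog::food_groups()$group
  tbl <- tibble::tibble(participant_id = sprintf("R%04d", seq_len(n)))
  for (g in groups) {
    x <- rgamma(n, shape = runif(1, 1, 3), scale = runif(1, 0.2, 2))
    if (p_zero > 0) x[runif(n) < p_zero] <- 0
    tbl[[g]] <- x
  }
  tbl$alcohol <- rgamma(n, 1, 1)
  tbl$margarine <- rgamma(n, 1.5, 0.1)
  tbl$energy <- runif(n, 1200, 3200)
  tbl$gender <- sample(c("male", "female"), n, replace = TRUE)
  tbl
}

# Hand-built 5-participant battery fixture used by the cell-by-cell
# composite oracle
fixture_battery <- function() {
  tibble::tibble(
    participant_id = paste0("F", 1:5),
    ravlt_immediate = c(35, 48, 42, 55, 29),
    ravlt_delayed = c(6, 10, 8, 12, 4),
    ravlt_recognition = c(26, 29, 27, 30, 22),
    digit_span_forward = c(7, 10, 8, 11, 6),
    digit_span_backward = c(4, 7, 6, 8, 3),
    tmt_a_seconds = c(62, 38, 45, 30, 80),
    tmt_b_seconds = c(150, 80, 102, 60, 210),
    stroop1_seconds = c(50, 42, 45, 38, 58),
    stroop2_seconds = c(58, 47, 52, 42, 70),
    stroop3_seconds = c(120, 82, 95, 70, 155),
    sdmt = c(35, 52, 44, 58, 28),
    letter_fluency = c(28, 44, 36, 50, 21),
    mmse = c(28, 30, 29, 30, 26)
  )
}

# Spreadsheet-style recomputation of the five composites for any battery,
# written as explicit per-cell arithmetic
oracle_composites <- function(b) {
  z <- function(v) (v - mean(v)) / sd(v)
  stroop12 <- (b$stroop1_seconds + b$stroop2_seconds) / 2
  interf <- b$stroop3_seconds / stroop12
  ba <- b$tmt_b_seconds / b$tmt_a_seconds
  epi <- (z(b$ravlt_immediate) + z(b$ravlt_delayed) +
            z(b$ravlt_recognition)) / 3
  att <- (z(b$digit_span_forward) + z(b$digit_span_backward)) / 2
  spd <- (-z(stroop12) - z(b$tmt_a_seconds) + z(b$sdmt)) / 3
  exe <- (-z(interf) - z(ba) + z(b$letter_fluency)) / 3
  tibble::tibble(
    participant_id = b$participant_id,
    z_episodic_memory = epi, z_attention_wm = att,
    z_processing_speed = spd, z_executive = exe,
    z_global = (epi + att + spd + exe) / 4
  )
}

# Toy intake rows spanning the gender-specific energy windows
fixture_energy_rows <- function() {
  base <- random_intake(6, seed = 404)
  base$gender <- rep(c("male", "female"), each = 3)
  base$energy <- c(700, 900, 4300, 450, 600, 3500)
  base
}

# One simulated cohort reduced to the analysis frame
quiet_analysis_data <- function(cohort) {
  suppressMessages(pdicog::build_analysis_data(cohort))
}
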