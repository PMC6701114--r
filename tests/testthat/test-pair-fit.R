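test_that("coefficients, RSS, F and p match the normal-equations oracle on the printed fixture", {
  fx <- fixture_pair10()
  fit <- fit_pair(fx$y, fx$x, fx$cohorts, reference = "A")

  X_full <- oracle_design(fx$x, fx$cohorts, "A")
  X_red <- oracle_design(fx$x, fx$cohorts, "A", interaction = FALSE)
  full <- oracle_ols(fx$y, X_full)
  red <- oracle_ols(fx$y, X_red)
  k <- 2
  df_full <- length(fx$y) - 2 * k
  f_exp <- ((red$rss - full$rss) / k) / (full$rss / df_full)

  expect_equal(fit$beta, full$beta, tolerance = 1e-10)
  expect_equal(fit$rss_full, full$rss, tolerance = 1e-12)
  expect_equal(fit$rss_reduced, red$rss, tolerance = 1e-12)
  expect_equal(fit$df_full, df_full)
  expect_equal(fit$df_reduced, length(fx$y) - k)
  expect_equal(fit$F, f_exp, tolerance = 1e-10)
  expect_equal(fit$p, oracle_f_tail(f_exp, k, df_full), tolerance = 1e-8)
})

test_that("degenerate and under-sampled pairs raise classed errors", {
  x <- c(1, 2, 3, 4, 5, 6)
  ch <- rep(c("A", "B"), each = 3)

  # constant response
  expect_error(fit_pair(rep(0.2, 6), x, ch, "A"),
               class = "omescreen_degenerate_error")
  # readout constant within every cohort -> singular full design
  expect_error(
    fit_pair(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), rep(c(1, 2), each = 3),
             rep(c("A", "B"), each = 3), "A"),
    class = "omescreen_degenerate_error"
  )
  # a cohort with fewer than 2 samples
  expect_error(fit_pair(runif(5), rnorm(5), c("A", "A", "A", "A", "B"), "A"),
               class = "omescreen_insufficient_error")
  # too few samples for the 2K-parameter model
  expect_error(fit_pair(runif(4), rnorm(4), rep(c("A", "B"), 2), "A"),
               class = "omescreen_insufficient_error")
  # unknown reference
  expect_error(fit_pair(runif(6), rnorm(6), ch, "Z"),
               class = "omescreen_contract_error")
})

test_that("when the cohort-only model already fits exactly, F = 0 and p = 1", {
  # response depends only on cohort membership, zero noise
  ch <- rep(c("A", "B"), each = 6)
  y <- ifelse(ch == "A", 0.2, 0.5)
  fit <- fit_pair(y, c(1:6, 1:6) / 6, ch, "A")
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  expect_equal(fit$max_influence, 0)
})

test_that("interaction p-values match the covariance-matrix oracle on a 3-cohort fixture", {
  set.seed(101)
  ch <- rep(c("HC", "CD", "UC"), each = 8)
  x <- rlnorm(24)
  y <- 0.1 + ifelse(ch == "CD", 0.2, ifelse(ch == "UC", -0.1, 0.05)) * x +
    rnorm(24, sd = 0.05)
  fit <- fit_pair(y, x, ch, reference = "HC")

  X <- oracle_design(x, ch, "HC")
  p_oracle <- oracle_coef_p(y, X)
  expect_equal(
    fit$interaction_p,
    c(CD = unname(p_oracle[["cohortCD:x"]]), UC = unname(p_oracle[["cohortUC:x"]])),
    tolerance = 1e-10
  )

  # accessor contract
  expect_equal(interaction_pvalues(fit, "CD"), fit$interaction_p[["CD"]])
  expect_error(interaction_pvalues(fit, "HC"),
               class = "omescreen_contract_error")
})

test_that("identical per-cohort slopes give an interaction p near 1; a planted strong interaction gives p < 0.001", {
  # same slope, same symmetric perturbation in both cohorts: the interaction
  # estimate is exactly zero
  x <- rep(c(1, 2, 3, 4, 5, 6), 2)
  e <- rep(c(0.02, -0.02, 0.02, -0.02, 0.02, -0.02), 2)
  y <- 0.1 + 0.05 * x + e
  ch <- rep(c("A", "B"), each = 6)
  fit0 <- fit_pair(y, x, ch, "A")
  expect_gt(fit0$interaction_p[["B"]], 0.5)

  # slopes +2 vs -2, low noise, n = 40
  set.seed(7)
  x2 <- rnorm(40)
  ch2 <- rep(c("A", "B"), each = 20)
  y2 <- ifelse(ch2 == "A", 2, -2) * x2 + rnorm(40, sd = 0.3)
  fit1 <- fit_pair(y2, x2, ch2, "A")
  expect_lt(fit1$interaction_p[["B"]], 0.001)
})

test_that("closed-form DFFITS equals brute-force leave-one-out refits on every observation", {
  fx <- fixture_pair12()
  fit <- fit_pair(fx$y, fx$x, fx$cohorts, reference = "A")
  X <- oracle_design(fx$x, fx$cohorts, "A")
  expected <- oracle_dffits(fx$y, X)

  expect_equal(fit$dffits, expected, tolerance = 1e-10)
  expect_equal(fit$max_influence, max(abs(expected)), tolerance = 1e-10)

  # and on a noisier 3-cohort dataset
  set.seed(33)
  ch <- rep(c("A", "B", "C"), each = 7)
  x <- rlnorm(21)
  y <- runif(21)
  fit3 <- fit_pair(y, x, ch, "A")
  expect_equal(fit3$dffits, oracle_dffits(y, oracle_design(x, ch, "A")),
               tolerance = 1e-10)
})

test_that("exchangeable observations have equal |DFFITS| and a planted extreme point attains the max", {
  # two duplicated observations are exchangeable
  y <- c(0.1, 0.2, 0.2, 0.35, 0.4, 0.15, 0.22, 0.3, 0.41, 0.5)
  x <- c(1, 2, 2, 3.5, 4, 1.2, 2.1, 3, 4.1, 5)
  ch <- rep(c("A", "B"), each = 5)
  fit <- fit_pair(y, x, ch, "A")
  expect_equal(abs(fit$dffits[2]), abs(fit$dffits[3]), tolerance = 1e-12)

  # one point 10x the rest in both coordinates drives the fit
  y2 <- c(0.031, 0.025, 0.04, 0.028, 0.035, 0.033, 0.021, 0.039, 0.026, 0.3)
  x2 <- c(1.1, 0.8, 1.3, 0.9, 1.2, 1.0, 0.7, 1.25, 0.85, 10)
  ch2 <- c(rep(c("A", "B"), 4), "A", "B")
  fit2 <- fit_pair(y2, x2, ch2, "A")
  oracle <- oracle_dffits(y2, oracle_design(x2, ch2, "A"))
  expect_equal(which.max(abs(fit2$dffits)), which.max(abs(oracle)))
  expect_equal(which.max(abs(fit2$dffits)), 10L)
  expect_equal(fit2$max_influence, abs(fit2$dffits[10]))
})

test_that("diagnostics are skipped with a warning when the deletion fit is undefined", {
  # n = 2K + 1 leaves df_full = 1
  y <- c(0.1, 0.3, 0.2, 0.5, 0.6)
  x <- c(1, 2, 3, 1.5, 2.5)
  ch <- c("A", "A", "A", "B", "B")
  expect_warning(
    fit <- fit_pair(y, x, ch, "A"),
    class = "omescreen_diagnostics_skipped"
  )
  expect_null(fit$dffits)
  expect_true(is.na(fit$max_influence))
})

test_that("per-cohort lines follow the treatment-coding identity and glyph endpoints hit the unit square", {
  fx <- fixture_pair10()
  fit <- fit_pair(fx$y, fx$x, fx$cohorts, reference = "A")
  lines <- cohort_lines(fit)

  # reference cohort line is (beta0, beta_x); other cohorts add their offsets
  expect_equal(lines$intercept[lines$cohort == "A"],
               unname(fit$beta[["(Intercept)"]]))
  expect_equal(lines$slope[lines$cohort == "A"], unname(fit$beta[["x"]]))
  expect_equal(lines$slope[lines$cohort == "B"],
               unname(fit$beta[["x"]] + fit$beta[["cohortB:x"]]))

  # segments span only their own cohort's readout range
  expect_equal(lines$x_min, c(1.2, 1.9))
  expect_equal(lines$x_max, c(5.5, 5.9))

  # hand-computed affine map: u = (x - min) / range over pooled endpoints
  gx <- range(c(lines$x_min, lines$x_max))
  gy <- range(c(lines$y0, lines$y1))
  expect_equal(lines$gx0, (lines$x_min - gx[1]) / diff(gx))
  expect_equal(lines$gy1, (lines$y1 - gy[1]) / diff(gy))
  expect_equal(range(c(lines$gx0, lines$gx1)), c(0, 1))
  expect_equal(range(c(lines$gy0, lines$gy1)), c(0, 1))
})

test_that("a planted flat non-reference cohort yields a near-zero slope equal to beta_x + beta_Bx", {
  set.seed(5)
  x <- rep(seq(0.5, 5, length.out = 10), 2)
  ch <- rep(c("A", "B"), each = 10)
  y <- ifelse(ch == "A", 0.1 + 0.15 * x, 0.4) + rnorm(20, sd = 0.01)
  fit <- fit_pair(y, x, ch, "A")
  lines <- cohort_lines(fit)
  slope_b <- lines$slope[lines$cohort == "B"]
  expect_equal(slope_b, unname(fit$beta[["x"]] + fit$beta[["cohortB:x"]]))
  expect_lt(abs(slope_b), 0.02)
})

test_that("nesting holds and per-cohort slopes are recovered within 4 standard errors", {
  set.seed(2026)
  hits <- 0
  for (r in 1:500) {
    x <- rlnorm(40)
    ch <- rep(c("A", "B"), each = 20)
    slopes <- c(A = 0.3, B = -0.2)
    y <- 0.2 + slopes[ch] * x + rnorm(40, sd = 0.1)
    fit <- fit_pair(y, x, ch, "A")
    expect_gte(fit$rss_reduced, fit$rss_full - 1e-12)

    est <- tidy(fit)
    b_x <- est$estimate[est$term == "x"]
    se_x <- est$std.error[est$term == "x"]
    b_bx <- est$estimate[est$term == "cohortB:x"]
    se_bx <- est$std.error[est$term == "cohortB:x"]
    ok_a <- abs(b_x - slopes[["A"]]) < 4 * se_x
    # slope difference for cohort B is its interaction coefficient
    ok_b <- abs(b_bx - (slopes[["B"]] - slopes[["A"]])) < 4 * se_bx
    hits <- hits + as.integer(ok_a && ok_b)
  }
  expect_gte(hits / 500, 0.95)
})

test_that("tidy and glance expose the fit in broom shape", {
  fx <- fixture_pair10()
  fit <- fit_pair(fx$y, fx$x, fx$cohorts, reference = "A", microbe = "mb_1",
                  immune = "IL.6")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$microbe, "mb_1")
  expect_equal(gl$immune, "IL.6")
  expect_equal(gl$p, fit$p)
  expect_equal(gl$df_num, 2)
})
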