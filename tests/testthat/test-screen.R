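test_that("one fit is attempted per pair, in manifest order, deterministically", {
  set.seed(12)
  vals <- cbind(
    mb_b = runif(12, 0, 0.5), mb_a = runif(12, 0, 0.5),
    ir_2 = rlnorm(12), ir_1 = rlnorm(12)
  )
  tbl <- make_merged(vals, c("microbe", "microbe", "immune", "immune"))
  cfg <- run_config("A", "raw_p", 0.5)

  s <- screen_pairs(tbl, cfg)
  expect_equal(nrow(s), 4)
  # microbes outer, immune inner, both in manifest (column) order
  expect_equal(s$microbe, c("mb_b", "mb_b", "mb_a", "mb_a"))
  expect_equal(s$immune, c("ir_2", "ir_1", "ir_2", "ir_1"))

  # single pair
  tbl1 <- make_merged(vals[, c(1, 3)], c("microbe", "immune"))
  expect_equal(nrow(screen_pairs(tbl1, cfg)), 1)

  # an ome with zero features is a configuration error
  tbl0 <- make_merged(vals[, 1:2], c("microbe", "microbe"))
  expect_error(screen_pairs(tbl0, cfg), class = "omescreen_config_error")

  # byte-identical repeat runs
  s2 <- screen_pairs(tbl, cfg)
  expect_identical(
    document_json(run_screen(tbl, cfg, quiet = TRUE)$document),
    document_json(run_screen(tbl, cfg, quiet = TRUE)$document)
  )
  expect_equal(s$p, s2$p)
})

test_that("degenerate pairs are recorded with a reason, not errors", {
  set.seed(3)
  vals <- cbind(
    mb_ok = runif(10, 0, 0.4),
    mb_const = rep(0, 10),
    ir_1 = rlnorm(10)
  )
  tbl <- make_merged(vals, c("microbe", "microbe", "immune"))
  s <- screen_pairs(tbl, run_config("A", "raw_p", 0.5))
  expect_equal(nrow(s), 2)
  expect_false(s$degenerate[s$microbe == "mb_ok"])
  expect_true(s$degenerate[s$microbe == "mb_const"])
  expect_match(s$reason[s$microbe == "mb_const"], "constant response")
  expect_true(is.na(s$p[s$microbe == "mb_const"]))
})

test_that("Benjamini-Hochberg adjustment reproduces hand-computed step-up values", {
  # m = 1 identity
  expect_equal(bh_adjust(0.03), 0.03)
  # hand evaluation: sorted (0.002, 0.01, 0.03, 0.04) -> q = (0.008, 0.02,
  # 0.04, 0.04) after monotone step-up, mapped back to input order
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  # all-equal input is a fixed point
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  # contract
  expect_error(bh_adjust(c(0.1, 1.2)), class = "omescreen_contract_error")
  expect_error(bh_adjust(c(-0.1, 0.5)), class = "omescreen_contract_error")
})

test_that("BH output dominates the input and is permutation-invariant", {
  set.seed(99)
  for (r in 1:20) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("top-table thresholding is strict, sorted, keyed, and column-configurable", {
  s <- fake_screen(c(0.05, 0.01, 0.2, 0.049))
  cfg_raw <- run_config("A", "raw_p", 0.05)
  tt <- build_top_table(s, cfg_raw)
  # strict inequality: 0.05 itself is excluded
  expect_equal(nrow(tt), 2)
  expect_equal(tt$p, c(0.01, 0.049))
  expect_equal(tt$key, 1:2)

  # ties in p break lexicographically by (microbe, immune)
  s_tie <- fake_screen(c(0.01, 0.01), microbe = c("mb_z", "mb_a"))
  tt_tie <- build_top_table(s_tie, cfg_raw)
  expect_equal(tt_tie$microbe, c("mb_a", "mb_z"))

  # pAdj >= p and the fdr_p rows are a subset of the raw_p rows
  s2 <- fake_screen(c(0.001, 0.02, 0.04, 0.3, 0.8))
  tt_raw <- build_top_table(s2, run_config("A", "raw_p", 0.05))
  tt_fdr <- build_top_table(s2, run_config("A", "fdr_p", 0.05))
  expect_true(all(tt_raw$pAdj >= tt_raw$p))
  expect_true(all(
    paste(tt_fdr$microbe, tt_fdr$immune) %in%
      paste(tt_raw$microbe, tt_raw$immune)
  ))

  # metric columns follow the configuration
  tt_min <- build_top_table(s2, run_config("A", "raw_p", 0.05,
                                           metric_columns = c("F", "pAdj")))
  expect_false("max_influence" %in% names(tt_min))
  expect_false("interaction_p" %in% names(tt_min))
  expect_true(all(c("F", "pAdj") %in% names(tt_min)))
  tt_inf <- build_top_table(s2, run_config("A", "raw_p", 0.05,
                                           metric_columns = "max_influence"))
  expect_true("max_influence" %in% names(tt_inf))

  # empty result is an empty table, not an error
  tt0 <- build_top_table(fake_screen(c(0.4, 0.9)), cfg_raw)
  expect_s3_class(tt0, "top_table")
  expect_equal(nrow(tt0), 0)
})

test_that("BH m counts only non-degenerate fits", {
  s <- fake_screen(c(0.01, 0.02, 0.03, 0.04))
  s$degenerate[3:4] <- TRUE
  s$p[3:4] <- NA_real_
  tt <- build_top_table(s, run_config("A", "fdr_p", 1))
  expect_equal(attr(tt, "m_tests"), 2)
  expect_equal(tt$pAdj, p.adjust(c(0.01, 0.02), "BH"))
})

test_that("network summary counts degrees, preserves the edge-row bijection, and handles hubs", {
  # empty
  tt0 <- build_top_table(fake_screen(c(0.9)), run_config("A", "raw_p", 0.05))
  net0 <- network_summary(tt0)
  expect_equal(nrow(net0$nodes), 0)
  expect_equal(nrow(net0$edges), 0)

  # seven microbes sharing one immune analyte: a hub of degree 7
  s <- fake_screen(seq(0.001, 0.007, by = 0.001),
                   microbe = sprintf("mb_%d", 1:7),
                   immune = rep("IL.1alpha", 7))
  tt <- build_top_table(s, run_config("A", "raw_p", 0.05))
  net <- network_summary(tt)
  hub <- net$nodes[net$nodes$analyte == "IL.1alpha", ]
  expect_equal(hub$degree, 7)
  expect_equal(hub$ome, "immune")
  expect_equal(nrow(net$edges), nrow(tt))
  expect_equal(sort(net$edges$key), tt$key)

  # handshake identity on a simulated run
  sim <- generate_dataset(synthetic_spec(
    cohorts = c(A = 10, B = 10), n_microbes = 8, n_immune = 3,
    planted = list(planted_pair(1, 1, slopes = c(A = 0.4), noise_sd = 0.02),
                   planted_pair(2, 2, slopes = c(B = 0.4), noise_sd = 0.02)),
    seed = 21
  ))
  res <- run_screen(sim$table, run_config("A", "raw_p", 0.3), quiet = TRUE)
  net2 <- network_summary(res$top_table)
  expect_equal(sum(net2$nodes$degree), 2 * nrow(net2$edges))
  expect_s3_class(as_igraph(net2), "igraph")
})
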