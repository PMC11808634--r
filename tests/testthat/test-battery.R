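test_that("the Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(sprintf("%.4f", bonferroni_alpha(0.05, 6)), "0.0083")
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(1.5, 6))
})

test_that("the one-sample t matches hand arithmetic", {
  centred <- t_test_vs_constant(c(4, 5, 6), 5, "smaller")
  expect_equal(centred$t_statistic, 0)
  expect_equal(centred$p_one_tailed, 0.5)

  got <- t_test_vs_constant(c(1, 2, 3), 4, "smaller")
  expect_equal(got$t_statistic, (2 - 4) / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(got$t_statistic, -3.4641, tolerance = 1e-4)
  expect_equal(got$df, 2)

  p_s <- t_test_vs_constant(c(1, 2, 3), 4, "smaller")$p_one_tailed
  p_l <- t_test_vs_constant(c(1, 2, 3), 4, "larger")$p_one_tailed
  expect_equal(p_s + p_l, 1, tolerance = 1e-12)
  expect_error(t_test_vs_constant(c(5, 5, 5), 4), "zero standard deviation")
})

test_that("the two-sample t matches hand arithmetic for pooled and Welch forms", {
  got <- t_test_two_sample(c(1, 2, 3), c(4, 5, 6), "smaller", "pooled")
  expect_equal(got$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$t_statistic, -3.6742, tolerance = 1e-4)
  expect_equal(got$df, 4)

  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3), "smaller")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_one_tailed, 0.5)

  w <- t_test_two_sample(c(1, 2, 3), c(4, 5, 6), "smaller", "welch")
  expect_equal(w$t_statistic, got$t_statistic, tolerance = 1e-12)
  expect_lte(w$df, got$df)
})

test_that("the pooled statistic equals the scalar formula on random inputs", {
  withr::with_seed(12, {
    for (i in 1:20) {
      a <- rnorm(sample(3:12, 1), 10, 2)
      b <- rnorm(sample(3:12, 1), 11, 3)
      na <- length(a); nb <- length(b)
      sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
      t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
      got <- t_test_two_sample(a, b, "smaller", "pooled")
      expect_equal(got$t_statistic, t_hand, tolerance = 1e-12)
      # and agreement with the stock Welch implementation as a cross-check
      ref <- stats::t.test(a, b, alternative = "less")
      wgot <- t_test_two_sample(a, b, "smaller", "welch")
      expect_equal(wgot$p_one_tailed, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("one-tailed p-values are uniform under the null", {
  withr::with_seed(13, {
    p <- vapply(seq_len(10000), function(i) {
      t_test_vs_constant(rnorm(10), 0, "smaller")$p_one_tailed
    }, numeric(1))
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  })
})

test_that("the battery emits six measurements by three comparison blocks", {
  colony <- simulate_colony(small_colony_config(seed = 71))
  adj <- apply_sex_adjustment(colony$records)
  out <- run_size_battery(adj)
  expect_equal(nrow(out), 18L)
  expect_equal(unique(table(out$comparison)), 6L)
  expect_setequal(unique(out$comparison),
                  c("vs_smaller_parent_mean", "vs_larger_parent_mean", "vs_mid_parental"))
  expect_equal(unique(out$alpha_adjusted), 0.05 / 6)
  expect_equal(out$significant, out$p_one_tailed < 0.05 / 6)

  both <- run_size_battery(adj, mode = "both")
  expect_equal(nrow(both), 30L)
})

test_that("raising alpha never turns a significant result non-significant", {
  colony <- simulate_colony(small_colony_config(seed = 72))
  adj <- apply_sex_adjustment(colony$records)
  lo <- run_size_battery(adj, alpha = 0.01)
  hi <- run_size_battery(adj, alpha = 0.10)
  expect_true(all(!lo$significant | hi$significant))
})

test_that("the hybridity test is quiet when hybrids sit on the parity line", {
  # fixed parents, hybrids = additive expectation + symmetric noise
  withr::with_seed(14, {
    parents <- make_phenotypes(
      rep(c(0, 1), each = 20),
      weight = c(rnorm(20, 16, 2.5), rnorm(20, 13, 2.5))
    )
    mi <- mean(parents$weight[parents$group == "indian"])
    mc <- mean(parents$weight[parents$group == "chinese"])
    n_sig <- vapply(seq_len(100), function(i) {
      A <- sample(seq(0.125, 0.875, by = 0.125), 60, replace = TRUE)
      hybrids <- make_phenotypes(A, weight = expected_value(A, mi, mc) + rnorm(60, 0, 2.5))
      x <- rbind(parents, hybrids)
      tst <- midparent_test(x, "weight", "smaller")
      tst$p_one_tailed < bonferroni_alpha(0.05, 6)
    }, logical(1))
    expect_gte(sum(!n_sig), 95)
  })
})

test_that("strong planted dysgenesis is flagged against the smaller parent everywhere", {
  cfg <- sim_config(seed = 81)
  cfg$dominance <- -5 * cfg$env_sd / cfg$loci
  colony <- suppressMessages(simulate_colony(cfg))
  adj <- apply_sex_adjustment(colony$records)
  out <- run_size_battery(adj)
  smaller <- out[out$comparison == "vs_smaller_parent_mean", ]
  expect_equal(nrow(smaller), 6L)
  expect_true(all(smaller$significant))
  expect_true(all(smaller$t_statistic < 0))
})

test_that("the male-effective standard error is used on internally adjusted data", {
  colony <- simulate_colony(small_colony_config(seed = 82))
  adj <- apply_sex_adjustment(colony$records)
  raw <- colony$records
  t_adj <- midparent_test(adj, "femur", "smaller")
  t_raw <- midparent_test(raw, "femur", "smaller")
  # male-only variance components rest on far fewer animals
  expect_lt(t_adj$df, t_raw$df)
  # externally supplied offsets leave nothing estimated: full-n SE branch
  off <- sex_offsets(colony$records)
  ext <- apply_sex_adjustment(colony$records, offsets = off)
  expect_false(isTRUE(attr(ext, "offsets_estimated")))
})

test_that("groups with fewer than two values are skipped with a warning", {
  x <- make_phenotypes(c(0, 0.5, 1), weight = c(16, 14, 13))
  attr(x, "sex_adjusted") <- TRUE
  w <- capture_warnings(out <- run_size_battery(x))
  expect_true(length(w) > 0 && all(grepl("n < 2", w)))
  expect_equal(nrow(out), 0L)
})
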