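test_that("genotype endpoints and the deterministic even split are exact", {
  cfg <- sim_config(seed = 1)
  g0 <- simulate_genotypes(0, cfg)
  expect_true(all(g0 == 0L))
  g1 <- simulate_genotypes(1, cfg)
  expect_true(all(g1 == 2L))
  g <- simulate_genotypes(0.5, cfg)
  expect_equal(sum(g), 100L)        # exactly 2 * L * A Chinese alleles
  expect_true(all(g == 1L))         # split as evenly as possible: all heterozygous
  g625 <- simulate_genotypes(0.625, cfg)
  expect_equal(sum(g625), 125L)
  expect_equal(sum(g625 == 1L), 75L)
})

test_that("realized ancestry at many loci concentrates near 2LA Chinese alleles", {
  cfg <- sim_config(loci = 10000L, realized_ancestry = TRUE, seed = 5)
  withr::with_seed(99, {
    n_chi <- sum(simulate_genotypes(0.8, cfg))
  })
  sigma <- sqrt(2 * 10000 * 0.8 * 0.2)
  expect_lt(abs(n_chi - 16000), 3 * sigma)
})

test_that("the noiseless degenerate trait equals the lineage mean plus dimorphism", {
  cfg <- sim_config(phenotypic_sd = 0, seed = 2)
  g <- simulate_genotypes(0, cfg)
  f <- simulate_trait(g, cfg, "F", "crown_rump")
  m <- simulate_trait(g, cfg, "M", "crown_rump")
  expect_equal(f, 583.00, tolerance = 1e-9)
  expect_equal(m, 583.00 + 35, tolerance = 1e-9)
  gc_ <- simulate_genotypes(1, cfg)
  expect_equal(simulate_trait(gc_, cfg, "F", "weight"), 12.78, tolerance = 1e-9)
})

test_that("the default colony reproduces the study composition", {
  colony <- simulate_colony(sim_config(seed = 10))
  x <- colony$records
  expect_equal(nrow(x), 134L)
  expect_equal(sum(x$group == "indian"), 19L)
  expect_equal(sum(x$group == "chinese"), 13L)
  expect_equal(sum(x$group == "hybrid"), 102L)
  expect_equal(sum(x$sex == "F"), 92L)
  expect_equal(sum(x$sex == "M"), 42L)
  for (m in c("weight", "crown_rump", "humerus", "radius", "femur", "tibia")) {
    expect_true(all(x[[m]] > 0))
  }
})

test_that("colonies are reproducible given the seed and change with it", {
  a <- simulate_colony(sim_config(seed = 11))$records
  b <- simulate_colony(sim_config(seed = 11))$records
  d <- simulate_colony(sim_config(seed = 12))$records
  expect_identical(a, b)
  expect_false(identical(a$weight, d$weight))
})

test_that("a single-bin configuration yields a single group", {
  cfg <- sim_config(bin_counts = tibble::tibble(ancestry = 0, n_female = 5L,
                                                n_male = 3L), seed = 4)
  x <- simulate_colony(cfg)$records
  expect_true(all(x$group == "indian"))
  expect_equal(nrow(x), 8L)
})

test_that("simulated means match the additive closed form at A = 0.5", {
  cfg <- sim_config(bin_counts = tibble::tibble(ancestry = 0.5,
                                                n_female = 10000L, n_male = 0L),
                    seed = 13)
  x <- simulate_colony(cfg)$records
  mid <- (16.02 + 12.78) / 2
  se <- 2.6 / sqrt(10000)
  expect_lt(abs(mean(x$weight) - mid), 3 * se)
})

test_that("dominance produces the closed-form heterotic excess", {
  cfg <- sim_config(bin_counts = tibble::tibble(ancestry = 0.5,
                                                n_female = 5000L, n_male = 0L),
                    realized_ancestry = TRUE, seed = 14)
  d_val <- 0.05  # mm per heterospecific femur locus
  cfg$dominance[] <- d_val
  x <- simulate_colony(cfg)$records
  truth <- sim_truth(cfg)
  shift <- heterotic_shift(truth, 0.5)[["femur"]]
  expect_equal(shift, 2 * 0.25 * 100 * d_val, tolerance = 1e-12)
  mid <- (196.14 + 209.96) / 2
  excess <- mean(x$femur) - mid
  # per-animal variance: phenotypic + dominance-count dispersion
  p_het <- 2 * 0.5 * 0.5
  v <- 8.1^2 + d_val^2 * 100 * p_het * (1 - p_het)
  expect_lt(abs(excess - shift), 3 * sqrt(v / 5000))
})

test_that("regression on ancestry recovers the lineage mean difference", {
  bins <- tibble::tibble(ancestry = seq(0, 1, 0.125),
                         n_female = c(60L, 60L, 60L, 60L, 60L, 60L, 60L, 40L, 40L),
                         n_male = 0L)
  x <- simulate_colony(sim_config(bin_counts = bins, seed = 15))$records
  fit <- summary(stats::lm(humerus ~ ancestry, data = x))$coefficients
  expect_lt(abs(fit["ancestry", "Estimate"] - (180.61 - 165.91)),
            2 * fit["ancestry", "Std. Error"])
})

test_that("sim_truth echoes the exact population quantities", {
  cfg <- sim_config(seed = 1)
  truth <- sim_truth(cfg)
  expect_equal(truth$means$mu_indian[truth$means$measurement == "weight"], 16.02)
  expect_equal(truth$means$mu_chinese[truth$means$measurement == "tibia"], 192.09)
  expect_equal(unname(heterotic_shift(truth, 0.3)), rep(0, 6))
  expect_equal(truth$loci, 100L)
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(bin_counts = tibble::tibble(ancestry = 1.5,
                                                      n_female = 1L, n_male = 1L)),
               "\\[0, 1\\]")
  expect_error(sim_config(mean_indian = c(weight = 16)), "named")
  expect_error(sim_config(phenotypic_sd = -1), ">= 0")
  expect_error(simulate_colony(sim_config(bin_counts = tibble::tibble(
    ancestry = 0.5, n_female = 0L, n_male = 0L))), "empty")
})

test_that("a small power analysis returns well-formed rates", {
  pw <- power_analysis(small_colony_config(seed = 16), effect_grid = c(0, 10),
                       reps = 4)
  expect_equal(nrow(pw), 2L)
  expect_equal(pw$direction, c("smaller", "larger"))
  expect_true(all(pw$rejection_rate >= 0 & pw$rejection_rate <= 1))
  expect_true(all(pw$detect_all_rate <= pw$rejection_rate + 1e-12))
})
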