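# Seeded simulator of admixed-colony phenotype datasets.
#
# Each trait is controlled by L loci (two alleles per locus). An allele
# inherited from the Indian lineage contributes an effect drawn around the
# Indian per-allele mean, a Chinese-derived allele around the Chinese
# mean, so a full-bred's expected trait value is 2L times its lineage's
# mean allelic effect. With dominance d != 0, every locus carrying one
# allele of each ancestry adds d (d > 0: heterosis; d < 0: dysgenesis),
# giving an expected excess over the additive expectation of
# 2A(1-A) * L * d when per-locus ancestries are drawn independently with
# probability A. Sexual dimorphism is a per-lineage male-female offset,
# interpolated between the lineages by the individual's realized Chinese
# allele fraction; environmental noise is Gaussian.
#
# Because a sum of independent Gaussian allelic effects is itself
# Gaussian, simulate_colony() collapses the 2L per-allele draws per
# animal and trait into a single draw with the exact same distribution
# (mean nC*aC + nI*aI, variance 2L * allele_effect_sd^2). The per-locus
# sampler simulate_genotypes() is exposed for inspection and testing.

# Defaults: lineage means follow the published group means for a captive
# Chinese x Indian rhesus colony; phenotypic SDs are calibrated so that
# group CVs land near the reported values (~16-21% for weight, ~3-5% for
# lengths); dimorphism offsets are plausible adult rhesus male-female
# differences, slightly larger in the Indian lineage.
SIM_MEAN_INDIAN <- c(weight = 16.02, crown_rump = 583.00, humerus = 165.91,
                     radius = 160.65, femur = 196.14, tibia = 177.17)
SIM_MEAN_CHINESE <- c(weight = 12.78, crown_rump = 575.13, humerus = 180.61,
                      radius = 176.49, femur = 209.96, tibia = 192.09)
SIM_PHEN_SD <- c(weight = 2.6, crown_rump = 20, humerus = 7,
                 radius = 7.9, femur = 8.1, tibia = 8.7)
SIM_DIMORPH_INDIAN <- c(weight = 3.0, crown_rump = 35, humerus = 10,
                        radius = 9, femur = 12, tibia = 10)
SIM_DIMORPH_CHINESE <- c(weight = 2.2, crown_rump = 28, humerus = 8,
                         radius = 8, femur = 10, tibia = 9)

# colony composition: ancestry bin (eighths) x (females, males)
default_bin_counts <- function() {
  tibble::tibble(
    ancestry = seq(0, 1, by = 0.125),
    n_female = c(11L, 29L, 15L, 12L, 5L, 3L, 7L, 1L, 9L),
    n_male   = c(8L, 15L, 8L, 3L, 2L, 2L, 0L, 0L, 4L)
  )
}

named_measurement_vector <- function(value, what) {
  if (length(value) == 1L && is.null(names(value))) {
    value <- stats::setNames(rep(value, length(RAW_MEASUREMENTS)), RAW_MEASUREMENTS)
  }
  if (!all(RAW_MEASUREMENTS %in% names(value))) {
    stop(what, " must be named with all raw measurement codes", call. = FALSE)
  }
  value[RAW_MEASUREMENTS]
}

#' Simulator configuration
#'
#' Builds a validated configuration for [simulate_colony()]. Trait-scale
#' arguments (`mean_indian`, `mean_chinese`, `phenotypic_sd`) are
#' converted to per-allele quantities internally: the mean allelic effect
#' of a lineage is its mean divided by `2 * loci`, and the total variance
#' is split equally between the genetic component (spread of allelic
#' effects) and environmental noise, so `env_sd = phenotypic_sd / sqrt(2)`
#' and `allele_effect_sd = phenotypic_sd / sqrt(2) / sqrt(2 * loci)`.
#'
#' @param bin_counts Tibble with columns `ancestry`, `n_female`, `n_male`
#'   giving the colony composition per ancestry bin; the default is the
#'   134-animal composition (19 Indian, 13 Chinese, 102 hybrids across
#'   eighths bins; 92 females, 42 males).
#' @param loci Number of loci L per trait (default 100; the additive
#'   expectation is invariant to L).
#' @param mean_indian,mean_chinese Named per-measurement lineage means
#'   (female baseline, trait units).
#' @param phenotypic_sd Named per-measurement total phenotypic SD within
#'   a lineage.
#' @param dominance Named per-measurement per-heterospecific-locus
#'   deviation d (0 = purely additive, > 0 heterosis, < 0 dysgenesis).
#' @param dimorphism_indian,dimorphism_chinese Named per-measurement
#'   male-female offsets per lineage.
#' @param realized_ancestry If `TRUE`, each allele is Chinese with
#'   probability A independently (realized ancestry varies around the
#'   pedigree value); if `FALSE` (default), the Chinese allele count is
#'   the deterministic `round(2 * loci * A)`, spread as evenly as
#'   possible across loci.
#' @param seed Integer seed; all colony draws are reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(bin_counts = default_bin_counts(),
                       loci = 100L,
                       mean_indian = SIM_MEAN_INDIAN,
                       mean_chinese = SIM_MEAN_CHINESE,
                       phenotypic_sd = SIM_PHEN_SD,
                       dominance = 0,
                       dimorphism_indian = SIM_DIMORPH_INDIAN,
                       dimorphism_chinese = SIM_DIMORPH_CHINESE,
                       realized_ancestry = FALSE,
                       seed = 1L) {
  stopifnot(is.data.frame(bin_counts),
            all(c("ancestry", "n_female", "n_male") %in% names(bin_counts)))
  if (any(bin_counts$ancestry < 0 | bin_counts$ancestry > 1)) {
    stop("bin ancestries must lie in [0, 1]", call. = FALSE)
  }
  if (any(bin_counts$n_female < 0 | bin_counts$n_male < 0)) {
    stop("bin counts must be non-negative", call. = FALSE)
  }
  loci <- as.integer(loci)
  stopifnot(loci >= 1L)
  mean_indian <- named_measurement_vector(mean_indian, "mean_indian")
  mean_chinese <- named_measurement_vector(mean_chinese, "mean_chinese")
  phenotypic_sd <- named_measurement_vector(phenotypic_sd, "phenotypic_sd")
  dominance <- named_measurement_vector(dominance, "dominance")
  dimorphism_indian <- named_measurement_vector(dimorphism_indian, "dimorphism_indian")
  dimorphism_chinese <- named_measurement_vector(dimorphism_chinese, "dimorphism_chinese")
  if (any(phenotypic_sd < 0)) stop("phenotypic_sd must be >= 0", call. = FALSE)

  structure(list(
    bin_counts = tibble::as_tibble(bin_counts),
    loci = loci,
    allele_effect_indian = mean_indian / (2 * loci),
    allele_effect_chinese = mean_chinese / (2 * loci),
    allele_effect_sd = phenotypic_sd / sqrt(2) / sqrt(2 * loci),
    env_sd = phenotypic_sd / sqrt(2),
    dominance = dominance,
    dimorphism_indian = dimorphism_indian,
    dimorphism_chinese = dimorphism_chinese,
    realized_ancestry = isTRUE(realized_ancestry),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Ground truth of a simulator configuration
#'
#' The exact population quantities implied by a configuration: per
#' measurement, the true (female-baseline) parental means
#' `mu = 2 * loci * allele_effect`, the dominance coefficient, and the
#' dimorphism offsets. Under `dominance = 0` and deterministic ancestry,
#' `E[trait | A] = (1 - A) * mu_indian + A * mu_chinese` exactly (plus
#' the dimorphism offset for males).
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_truth` with elements `means` (tibble),
#'   `loci` and `config`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  means <- tibble::tibble(
    measurement = RAW_MEASUREMENTS,
    mu_indian = unname(2 * config$loci * config$allele_effect_indian),
    mu_chinese = unname(2 * config$loci * config$allele_effect_chinese),
    dominance = unname(config$dominance),
    dimorphism_indian = unname(config$dimorphism_indian),
    dimorphism_chinese = unname(config$dimorphism_chinese)
  )
  structure(list(means = means, loci = config$loci, config = config),
            class = "sim_truth")
}

#' Expected heterotic shift at ancestry A
#'
#' Expected excess of the trait over its additive expectation under
#' independently drawn per-locus ancestries: `2 * A * (1 - A) * loci * d`
#' per measurement.
#'
#' @param truth A `sim_truth`.
#' @param A Ancestry fraction.
#' @return Named numeric vector per measurement.
#' @export
heterotic_shift <- function(truth, A) {
  stopifnot(inherits(truth, "sim_truth"))
  stats::setNames(2 * A * (1 - A) * truth$loci * truth$means$dominance,
                  truth$means$measurement)
}

#' Simulate per-locus genotype ancestries
#'
#' Returns the number of Chinese-derived alleles (0, 1 or 2) at each of
#' the L loci for one individual of pedigree ancestry A. With
#' `realized_ancestry`, each of the 2L alleles is Chinese independently
#' with probability A; otherwise the total Chinese allele count is fixed
#' at `round(2 * L * A)` and spread as evenly as possible across loci.
#'
#' @param A Chinese-ancestry fraction in \[0, 1\].
#' @param config A `sim_config`.
#' @return Integer vector of length `config$loci`.
#' @export
simulate_genotypes <- function(A, config) {
  stopifnot(inherits(config, "sim_config"), length(A) == 1L, A >= 0, A <= 1)
  L <- config$loci
  if (config$realized_ancestry) {
    as.integer(stats::rbinom(L, 2L, A))
  } else {
    k <- round(2 * L * A)
    g <- rep(k %/% L, L)
    r <- k %% L
    if (r > 0L) g[seq_len(r)] <- g[seq_len(r)] + 1L
    as.integer(g)
  }
}

#' Simulate one trait value from a genotype
#'
#' Sums per-allele effects (drawn around the lineage mean for each
#' allele's ancestry with SD `allele_effect_sd`), adds the dominance
#' deviation for each heterospecific locus, the sex offset (interpolated
#' between the lineage dimorphism offsets by the realized Chinese allele
#' fraction; females are the baseline), and Gaussian environmental noise.
#' Non-positive outcomes have their noise resampled (with a message).
#'
#' @param genotypes Integer vector from [simulate_genotypes()].
#' @param config A `sim_config`.
#' @param sex `"F"` or `"M"`.
#' @param measurement A raw measurement code.
#' @return A single positive trait value.
#' @export
simulate_trait <- function(genotypes, config, sex, measurement) {
  stopifnot(inherits(config, "sim_config"), sex %in% c("F", "M"),
            measurement %in% RAW_MEASUREMENTS)
  L <- config$loci
  stopifnot(length(genotypes) == L)
  n_chi <- sum(genotypes)
  n_ind <- 2L * L - n_chi
  n_het <- sum(genotypes == 1L)
  a_frac <- n_chi / (2 * L)

  genetic <- sum(stats::rnorm(n_chi, config$allele_effect_chinese[[measurement]],
                              config$allele_effect_sd[[measurement]])) +
    sum(stats::rnorm(n_ind, config$allele_effect_indian[[measurement]],
                     config$allele_effect_sd[[measurement]]))
  dom <- config$dominance[[measurement]] * n_het
  dim_off <- if (identical(sex, "M")) {
    (1 - a_frac) * config$dimorphism_indian[[measurement]] +
      a_frac * config$dimorphism_chinese[[measurement]]
  } else {
    0
  }
  base <- genetic + dom + dim_off
  value <- base + stats::rnorm(1L, 0, config$env_sd[[measurement]])
  tries <- 0L
  while (value <= 0 && tries < 1000L) {
    value <- base + stats::rnorm(1L, 0, config$env_sd[[measurement]])
    tries <- tries + 1L
  }
  if (tries > 0L) message("resampled environmental noise ", tries,
                          " time(s) to keep ", measurement, " positive")
  if (value <= 0) stop("could not generate a positive ", measurement,
                       " value; check config scales", call. = FALSE)
  value
}

# Vectorised genotype summary for a vector of ancestries: returns a list
# with per-animal Chinese allele counts and heterospecific locus counts.
# Distributionally identical to calling simulate_genotypes() per animal.
genotype_summary <- function(A, config) {
  L <- config$loci
  n <- length(A)
  if (config$realized_ancestry) {
    p_het <- 2 * A * (1 - A)
    n_het <- stats::rbinom(n, L, p_het)
    p2 <- ifelse(A %in% c(0, 1), as.numeric(A == 1),
                 A^2 / (A^2 + (1 - A)^2))
    n_hom_chi <- stats::rbinom(n, L - n_het, p2)
    list(n_chi = n_het + 2L * n_hom_chi, n_het = n_het)
  } else {
    k <- round(2 * L * A)
    base <- k %/% L
    r <- k %% L
    n_het <- ifelse(base == 0, r, ifelse(base == 1, L - r, 0))
    # base == 1 covers k in [L, 2L): r loci hold 2 Chinese alleles
    list(n_chi = as.integer(k), n_het = as.integer(n_het))
  }
}

#' Simulate a full admixed colony
#'
#' Generates one phenotype record per configured animal (all six raw
#' measurements), deterministic given `config$seed`, together with the
#' generating truth. Per-allele effect sums are drawn in collapsed
#' (exactly equivalent) Gaussian form; see [simulate_trait()] for the
#' explicit per-allele model.
#'
#' @param config A `sim_config`.
#' @return A list with `records` (phenotype tibble in the package's
#'   standard layout, plus a `realized_chinese_fraction` column) and
#'   `truth` (a [sim_truth()]).
#' @export
simulate_colony <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  bins <- config$bin_counts
  A <- rep(bins$ancestry, times = bins$n_female + bins$n_male)
  sex <- unlist(Map(function(f, m) c(rep("F", f), rep("M", m)),
                    bins$n_female, bins$n_male), use.names = FALSE)
  n <- length(A)
  if (n == 0L) stop("empty colony configuration", call. = FALSE)
  L <- config$loci

  records <- withr::with_seed(config$seed, {
    gs <- genotype_summary(A, config)
    a_frac <- gs$n_chi / (2 * L)
    male <- sex == "M"
    out <- tibble::tibble(
      id = sprintf("sim%03d", seq_len(n)),
      sex = sex, ancestry = A, group = ancestry_group(A),
      realized_chinese_fraction = a_frac
    )
    for (m in RAW_MEASUREMENTS) {
      base <- gs$n_chi * config$allele_effect_chinese[[m]] +
        (2L * L - gs$n_chi) * config$allele_effect_indian[[m]] +
        stats::rnorm(n, 0, sqrt(2 * L) * config$allele_effect_sd[[m]]) +
        config$dominance[[m]] * gs$n_het +
        ifelse(male,
               (1 - a_frac) * config$dimorphism_indian[[m]] +
                 a_frac * config$dimorphism_chinese[[m]],
               0)
      value <- base + stats::rnorm(n, 0, config$env_sd[[m]])
      resampled <- 0L
      while (any(value <= 0) && resampled < 1000L) {
        bad <- value <= 0
        value[bad] <- base[bad] + stats::rnorm(sum(bad), 0, config$env_sd[[m]])
        resampled <- resampled + 1L
      }
      if (resampled > 0L) message("resampled noise for ", m, " (", resampled,
                                  " round(s)) to keep values positive")
      if (any(value <= 0)) stop("could not keep ", m, " positive", call. = FALSE)
      out[[m]] <- value
    }
    out
  })
  list(records = records, truth = sim_truth(config))
}

#' Power and type-I-error study of the hybridity test
#'
#' For each planted dominance strength, repeatedly simulates a colony,
#' sex-adjusts it (default scheme), runs the battery's mid-parental
#' (hybridity) block at the Bonferroni-adjusted level, and records how
#' often the planted direction is flagged. Grid values are expressed as
#' `loci * d` in units of each measurement's environmental SD, so one
#' value plants a comparably sized effect in every measurement; the
#' direction tested follows the sign of the planted effect (`smaller`
#' at zero, the a-priori dysgenesis tail).
#'
#' @param config Base `sim_config` (its dominance entries are replaced by
#'   the grid values).
#' @param effect_grid Numeric vector of planted effects (`loci * d` per
#'   `env_sd`); include 0 for the empirical type-I error.
#' @param alpha Familywise one-tailed level before Bonferroni correction.
#' @param reps Replicates per grid value.
#' @param adjustment Sex-adjustment scheme applied before testing.
#' @return A tibble with one row per grid value: `effect`, `direction`,
#'   `reps`, `rejection_rate` (per-test, pooled over measurements) and
#'   `detect_all_rate` (replicates in which every measurement was
#'   flagged).
#' @export
power_analysis <- function(config = sim_config(), effect_grid = c(0, 5, 10),
                           alpha = 0.05, reps = 200,
                           adjustment = c("paper", "per-bin", "none")) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  adjustment <- match.arg(adjustment)
  alpha_adj <- bonferroni_alpha(alpha, length(RAW_MEASUREMENTS))
  seeds <- withr::with_seed(config$seed, {
    matrix(sample.int(.Machine$integer.max - 1L, reps * length(effect_grid)),
           nrow = reps)
  })
  rows <- lapply(seq_along(effect_grid), function(j) {
    g <- effect_grid[[j]]
    dir <- if (g > 0) "larger" else "smaller"
    cfg <- config
    cfg$dominance <- g * cfg$env_sd / cfg$loci
    hits <- matrix(NA, nrow = reps, ncol = length(RAW_MEASUREMENTS))
    for (i in seq_len(reps)) {
      cfg$seed <- seeds[i, j]
      colony <- suppressMessages(simulate_colony(cfg))
      adj <- apply_sex_adjustment(colony$records, scheme = adjustment)
      for (k in seq_along(RAW_MEASUREMENTS)) {
        tst <- midparent_test(adj, RAW_MEASUREMENTS[[k]], direction = dir)
        hits[i, k] <- tst$p_one_tailed < alpha_adj
      }
    }
    tibble::tibble(effect = g, direction = dir, reps = reps,
                   rejection_rate = mean(hits),
                   detect_all_rate = mean(apply(hits, 1L, all)))
  })
  dplyr::bind_rows(rows)
}
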