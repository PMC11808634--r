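# One-tailed t-test battery comparing hybrids to parental references.
#
# Three comparison blocks per measurement:
#   * vs_smaller_parent_mean - one-sample t of hybrid values against the
#     smaller full-bred mean (tail: hybrids smaller);
#   * vs_larger_parent_mean  - the same against the larger full-bred mean;
#   * vs_mid_parental        - the hybridity test: per-individual deviations
#     from the ancestry-weighted additive expectation, tested against zero.
# A two-sample mode compares the hybrid sample directly with each full-bred
# sample. Directions are fixed a priori (the dysgenesis hypothesis,
# "hybrids smaller"), not read off the observed signs. The Bonferroni
# threshold alpha/m is applied within each block, m = number of
# measurements tested (the raw six by default; composites are linear
# combinations of tested traits and are excluded).
#
# The hybridity test deserves care. The expectation subtracted from each
# hybrid is built from *estimated* parental means, so the deviations share
# the parental-mean sampling error; a naive one-sample t that treats them
# as independent is badly anticonservative. The standard error here
# therefore carries three components:
#   SE^2 = Var(hybrid mean) + (1-Abar)^2 Var(indian mean)
#                           + Abar^2    Var(chinese mean),
# with Satterthwaite degrees of freedom. When the data were sex-adjusted
# with offsets estimated from the same records, each group's adjusted mean
# equals its male sample mean exactly, so the variance components are
# estimated from the male subsamples (male counts, not total counts).

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Familywise level in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 6) # 0.0083 at 4 decimals
bonferroni_alpha <- function(alpha, m) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(m), m >= 1)
  alpha / m
}

one_tailed_p <- function(t_stat, df, direction) {
  switch(direction,
    smaller = stats::pt(t_stat, df, lower.tail = TRUE),
    larger = stats::pt(t_stat, df, lower.tail = FALSE),
    stop("direction must be 'smaller' or 'larger'", call. = FALSE)
  )
}

#' One-sample one-tailed t-test against a constant
#'
#' `t = (mean - reference) / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom and a one-tailed p-value in the stated direction.
#'
#' @param sample Numeric vector, n >= 2, no missing values.
#' @param reference The constant to compare against.
#' @param direction `"smaller"`: alternative mean < reference; `"larger"`:
#'   the reverse.
#' @return A one-row tibble: `t_statistic`, `df`, `p_one_tailed`,
#'   `direction`, `n`.
#' @export
t_test_vs_constant <- function(sample, reference,
                               direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(sample), length(sample) >= 2L, !anyNA(sample))
  s <- stats::sd(sample)
  if (s == 0) stop("zero standard deviation; t statistic undefined", call. = FALSE)
  n <- length(sample)
  t_stat <- (mean(sample) - reference) / (s / sqrt(n))
  df <- n - 1
  tibble::tibble(t_statistic = t_stat, df = df,
                 p_one_tailed = one_tailed_p(t_stat, df, direction),
                 direction = direction, n = n)
}

#' Two-sample one-tailed t-test
#'
#' Standard independent two-sample t, either with pooled variance
#' (`df = n_a + n_b - 2`) or the Welch form with Satterthwaite degrees of
#' freedom, one-tailed on sample a relative to sample b.
#'
#' @param sample_a,sample_b Numeric vectors, each n >= 2, no missing
#'   values.
#' @param direction `"smaller"`: alternative mean(a) < mean(b);
#'   `"larger"`: the reverse.
#' @param variance_rule `"pooled"` or `"welch"`.
#' @return A one-row tibble: `t_statistic`, `df`, `p_one_tailed`,
#'   `direction`, `n_a`, `n_b`.
#' @export
t_test_two_sample <- function(sample_a, sample_b,
                              direction = c("smaller", "larger"),
                              variance_rule = c("pooled", "welch")) {
  direction <- match.arg(direction)
  variance_rule <- match.arg(variance_rule)
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L,
            !anyNA(sample_a), !anyNA(sample_b))
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    stop("both standard deviations are zero; t statistic undefined", call. = FALSE)
  }
  diff <- mean(sample_a) - mean(sample_b)
  if (identical(variance_rule, "pooled")) {
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(va / n_a + vb / n_b)
    df <- (va / n_a + vb / n_b)^2 /
      ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  }
  t_stat <- diff / se
  tibble::tibble(t_statistic = t_stat, df = df,
                 p_one_tailed = one_tailed_p(t_stat, df, direction),
                 direction = direction, n_a = n_a, n_b = n_b)
}

#' Hybridity test: mean deviation from the additive expectation
#'
#' Tests whether the mean per-individual deviation of hybrids from their
#' ancestry-weighted additive expectation differs from zero in the stated
#' direction, with a standard error that propagates the sampling
#' uncertainty of both estimated parental means (and, on sex-adjusted
#' data with internally estimated offsets, the male-effective sample
#' sizes). Degrees of freedom are Satterthwaite-combined across the three
#' variance components.
#'
#' @param x A phenotype tibble with hybrids and both full-bred groups
#'   (typically sex-adjusted).
#' @param measurement A single measurement code.
#' @param direction `"smaller"` (dysgenesis tail) or `"larger"`
#'   (heterosis tail).
#' @return A one-row tibble: `t_statistic`, `df`, `p_one_tailed`,
#'   `direction`, `n_hybrid`, `mean_deviation`, `se`.
#' @export
midparent_test <- function(x, measurement, direction = c("smaller", "larger")) {
  direction <- match.arg(direction)
  x <- tibble::as_tibble(x)
  stopifnot(measurement %in% names(x))
  male_effective <- isTRUE(attr(x, "sex_adjusted")) &&
    isTRUE(attr(x, "offsets_estimated"))

  val <- x[[measurement]]
  keep <- !is.na(val)
  iv <- val[keep & x$group == "indian"]
  cvl <- val[keep & x$group == "chinese"]
  hyb <- keep & x$group == "hybrid"
  hv <- val[hyb]
  hA <- x$ancestry[hyb]
  hM <- x$sex[hyb] == "M"
  if (length(iv) < 2L || length(cvl) < 2L || length(hv) < 2L) {
    stop("need n >= 2 in each group for measurement ", measurement, call. = FALSE)
  }
  mi <- mean(iv)
  mc <- mean(cvl)
  dev <- hv - expected_value(hA, mi, mc)
  abar <- mean(hA)
  mean_dev <- mean(dev)

  comp <- function(values, weight2) {
    n <- length(values)
    if (n < 2L) {
      stop("male-effective variance needs >= 2 males per group (measurement ",
           measurement, ")", call. = FALSE)
    }
    c(v = weight2 * stats::var(values) / n, df = n - 1)
  }
  if (male_effective) {
    parts <- rbind(
      comp(dev[hM], 1),
      comp(iv[x$sex[keep & x$group == "indian"] == "M"], (1 - abar)^2),
      comp(cvl[x$sex[keep & x$group == "chinese"] == "M"], abar^2)
    )
  } else {
    parts <- rbind(
      comp(dev, 1),
      comp(iv, (1 - abar)^2),
      comp(cvl, abar^2)
    )
  }
  se2 <- sum(parts[, "v"])
  df <- se2^2 / sum(parts[, "v"]^2 / parts[, "df"])
  t_stat <- mean_dev / sqrt(se2)
  tibble::tibble(t_statistic = t_stat, df = df,
                 p_one_tailed = one_tailed_p(t_stat, df, direction),
                 direction = direction, n_hybrid = length(hv),
                 mean_deviation = mean_dev, se = sqrt(se2))
}

#' Run the size t-test battery
#'
#' For each measurement, runs the configured comparison blocks with fixed
#' a-priori directions and applies the Bonferroni threshold `alpha / m`
#' within each block (`m` = number of measurements tested).
#'
#' @param x A phenotype tibble, normally sex-adjusted (a message is
#'   emitted when it is not flagged as adjusted).
#' @param alpha Familywise one-tailed level before correction.
#' @param mode `"one-sample"` (default): both parental-mean blocks plus
#'   the hybridity block; `"two-sample"`: hybrid sample versus each
#'   full-bred sample (pooled variance); `"both"`.
#' @param direction A-priori tail for every block (default `"smaller"`,
#'   the dysgenesis hypothesis).
#' @param measurements Measurement codes to test; default the raw six.
#' @return A tibble with one row per comparison x measurement:
#'   `comparison`, `measurement`, `reference`, `t_statistic`, `df`,
#'   `p_one_tailed`, `alpha_adjusted`, `significant`, `direction`.
#' @export
run_size_battery <- function(x, alpha = 0.05,
                             mode = c("one-sample", "two-sample", "both"),
                             direction = "smaller",
                             measurements = NULL) {
  mode <- match.arg(mode)
  x <- tibble::as_tibble(x)
  if (is.null(measurements)) measurements <- intersect(RAW_MEASUREMENTS, names(x))
  if (!isTRUE(attr(x, "sex_adjusted"))) {
    message("run_size_battery: input is not flagged as sex-adjusted")
  }
  m_tests <- length(measurements)
  alpha_adj <- bonferroni_alpha(alpha, m_tests)

  row_of <- function(comparison, meas, reference, tst, n_hybrid) {
    tibble::tibble(
      comparison = comparison, measurement = meas, reference = reference,
      t_statistic = tst$t_statistic, df = tst$df,
      p_one_tailed = tst$p_one_tailed, alpha_adjusted = alpha_adj,
      significant = tst$p_one_tailed < alpha_adj,
      direction = tst$direction, n_hybrid = n_hybrid
    )
  }

  rows <- list()
  for (meas in measurements) {
    val <- x[[meas]]
    iv <- val[x$group == "indian" & !is.na(val)]
    cvl <- val[x$group == "chinese" & !is.na(val)]
    hv <- val[x$group == "hybrid" & !is.na(val)]
    if (length(iv) < 2L || length(cvl) < 2L || length(hv) < 2L) {
      warning("skipping measurement with n < 2 in some group: ", meas,
              call. = FALSE)
      next
    }
    smaller <- min(mean(iv), mean(cvl))
    larger <- max(mean(iv), mean(cvl))
    if (mode %in% c("one-sample", "both")) {
      rows[[paste("sm", meas)]] <- row_of(
        "vs_smaller_parent_mean", meas, smaller,
        t_test_vs_constant(hv, smaller, direction), length(hv))
      rows[[paste("lg", meas)]] <- row_of(
        "vs_larger_parent_mean", meas, larger,
        t_test_vs_constant(hv, larger, direction), length(hv))
      rows[[paste("mid", meas)]] <- row_of(
        "vs_mid_parental", meas, NA_real_,
        midparent_test(x, meas, direction), length(hv))
    }
    if (mode %in% c("two-sample", "both")) {
      small_sample <- if (mean(iv) <= mean(cvl)) iv else cvl
      large_sample <- if (mean(iv) <= mean(cvl)) cvl else iv
      rows[[paste("2s", meas)]] <- row_of(
        "vs_smaller_parent_sample", meas, mean(small_sample),
        t_test_two_sample(hv, small_sample, direction, "pooled"), length(hv))
      rows[[paste("2l", meas)]] <- row_of(
        "vs_larger_parent_sample", meas, mean(large_sample),
        t_test_two_sample(hv, large_sample, direction, "pooled"), length(hv))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      comparison = character(), measurement = character(), reference = double(),
      t_statistic = double(), df = double(), p_one_tailed = double(),
      alpha_adjusted = double(), significant = logical(),
      direction = character(), n_hybrid = integer()
    ))
  }
  out$comparison <- factor(out$comparison, levels = c(
    "vs_smaller_parent_mean", "vs_larger_parent_mean", "vs_mid_parental",
    "vs_smaller_parent_sample", "vs_larger_parent_sample"))
  out$measurement <- factor(out$measurement, levels = ALL_MEASUREMENTS)
  out <- dplyr::arrange(out, comparison, measurement)
  out$comparison <- as.character(out$comparison)
  out$measurement <- as.character(out$measurement)
  out
}
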