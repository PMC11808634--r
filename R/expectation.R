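# Additive (mid-parent) expectations, parity-line deviations and
# transgression classification.
#
# Under a polygenic model in which very many loci act equally and
# additively (no dominance, no epistasis), the expected value of a trait
# for an admixed individual is the ancestry-weighted average of the two
# full-bred means: an individual with Chinese-ancestry fraction A carries,
# in expectation, a fraction A of Chinese-derived alleles at the trait's
# loci, so E[trait] = (1 - A) * mean_indian + A * mean_chinese.

#' Ancestry-weighted additive expected value
#'
#' @param A Chinese-ancestry fraction(s) in \[0, 1\].
#' @param mean_indian,mean_chinese Full-bred group means of the trait.
#' @return `(1 - A) * mean_indian + A * mean_chinese`, vectorised over `A`.
#' @export
#' @examples
#' expected_value(0.5, 16.02, 12.78) # mid-parent weight, 14.40
expected_value <- function(A, mean_indian, mean_chinese) {
  stopifnot(is.numeric(A), is.numeric(mean_indian), is.numeric(mean_chinese))
  if (any(!is.na(A) & (A < 0 | A > 1))) {
    stop("ancestry fraction A must lie in [0, 1]", call. = FALSE)
  }
  (1 - A) * mean_indian + A * mean_chinese
}

#' Classify transgression of a hybrid value
#'
#' Two independent classifications: against the two parental means
#' (`above_both` / `between` / `below_both`) and against the observed
#' parental range (`above_parental_max` / `within` / `below_parental_min`).
#' Both intervals are closed, so boundary values classify as `between` /
#' `within`.
#'
#' @param value Numeric vector of hybrid values.
#' @param parental_means Length-2 numeric, the two full-bred means (order
#'   irrelevant).
#' @param parental_range Length-2 numeric, the observed full-bred minimum
#'   and maximum, or `NULL` to skip the range classification.
#' @return A tibble with columns `value`, `vs_means`, `vs_range`.
#' @export
classify_transgression <- function(value, parental_means, parental_range = NULL) {
  stopifnot(length(parental_means) == 2L)
  lo <- min(parental_means)
  hi <- max(parental_means)
  vs_means <- dplyr::case_when(
    is.na(value) ~ NA_character_,
    value > hi ~ "above_both",
    value < lo ~ "below_both",
    TRUE ~ "between"
  )
  if (is.null(parental_range)) {
    vs_range <- rep(NA_character_, length(value))
  } else {
    stopifnot(length(parental_range) == 2L)
    rlo <- min(parental_range)
    rhi <- max(parental_range)
    vs_range <- dplyr::case_when(
      is.na(value) ~ NA_character_,
      value > rhi ~ "above_parental_max",
      value < rlo ~ "below_parental_min",
      TRUE ~ "within"
    )
  }
  tibble::tibble(value = value, vs_means = vs_means, vs_range = vs_range)
}

#' Parity-line analysis of hybrids
#'
#' For every hybrid and measurement, computes the additive expected value
#' from the full-bred means, the deviation (actual - expected), which side
#' of the parity line the animal falls on, and both transgression
#' classifications. Per measurement, the counts above/below/on parity are
#' aggregated with the mean deviation and a two-sided exact binomial sign
#' test on the above-vs-below counts (ties excluded). The sign test is an
#' extension beyond simply plotting the parity line: it formalises "are
#' hybrids equally likely to fall on either side?".
#'
#' @param x A phenotype tibble containing hybrids; full-bred rows in `x`
#'   supply the observed parental ranges.
#' @param summaries Full-bred group summaries from [summarize_groups()];
#'   computed from the full-bred rows of `x` when `NULL`. Must contain
#'   groups `indian` and `chinese`.
#' @param measurements Measurement codes to analyse; defaults to all
#'   measurement columns present.
#' @return A list with `results` (per hybrid x measurement) and `summary`
#'   (per measurement: `n_above`, `n_below`, `n_on`, `mean_deviation`,
#'   `sign_test_p`).
#' @export
parity_analysis <- function(x, summaries = NULL, measurements = NULL) {
  x <- tibble::as_tibble(x)
  if (is.null(measurements)) measurements <- intersect(ALL_MEASUREMENTS, names(x))
  if (is.null(summaries)) {
    parents <- x[x$group %in% c("indian", "chinese"), , drop = FALSE]
    if (nrow(parents) == 0L) stop("no full-bred rows to summarise", call. = FALSE)
    summaries <- summarize_groups(parents, measurements = measurements)
  }
  hybrids <- x[x$group == "hybrid", , drop = FALSE]

  results <- list()
  summary_rows <- list()
  for (m in measurements) {
    mi <- summaries$mean[summaries$group == "indian" & summaries$measurement == m]
    mc <- summaries$mean[summaries$group == "chinese" & summaries$measurement == m]
    if (length(mi) != 1L || length(mc) != 1L || is.na(mi) || is.na(mc)) {
      warning("skipping measurement without both parental means: ", m,
              call. = FALSE)
      next
    }
    parent_vals <- c(x[[m]][x$group == "indian"], x[[m]][x$group == "chinese"])
    parent_vals <- parent_vals[!is.na(parent_vals)]
    prange <- if (length(parent_vals) > 0L) range(parent_vals) else NULL

    actual <- hybrids[[m]]
    expected <- expected_value(hybrids$ancestry, mi, mc)
    deviation <- actual - expected
    cls <- classify_transgression(actual, c(mi, mc), prange)
    res <- tibble::tibble(
      record_id = hybrids$id,
      measurement = m,
      ancestry = hybrids$ancestry,
      expected = expected,
      actual = actual,
      deviation = deviation,
      parity_side = dplyr::case_when(
        is.na(deviation) ~ NA_character_,
        deviation > 0 ~ "above",
        deviation < 0 ~ "below",
        TRUE ~ "on"
      ),
      transgression_vs_means = cls$vs_means,
      transgression_vs_range = cls$vs_range
    )
    res <- res[!is.na(res$deviation), , drop = FALSE]
    results[[m]] <- res

    n_above <- sum(res$parity_side == "above")
    n_below <- sum(res$parity_side == "below")
    n_on <- sum(res$parity_side == "on")
    sign_p <- if (n_above + n_below > 0L) {
      stats::binom.test(n_above, n_above + n_below, p = 0.5)$p.value
    } else {
      NA_real_
    }
    summary_rows[[m]] <- tibble::tibble(
      measurement = m, n_above = n_above, n_below = n_below, n_on = n_on,
      mean_deviation = if (nrow(res) > 0L) mean(res$deviation) else NA_real_,
      sign_test_p = sign_p
    )
  }
  list(
    results = dplyr::bind_rows(results),
    summary = dplyr::bind_rows(summary_rows)
  )
}
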