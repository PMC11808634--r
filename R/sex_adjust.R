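# Sex adjustment.
#
# To pool sexes without conflating sexual dimorphism with ancestry effects,
# the male-female mean difference is added to every female value, separately
# within each adjustment group. Because admixed samples rarely contain males
# in every ancestry bin, the default scheme adjusts within each full-bred
# group and within all hybrids pooled; a per-bin scheme is available and
# fails loudly when a bin lacks one sex.
#
# Note an algebraic consequence used downstream: after adjustment with
# offsets estimated from the same data, the mean of a group's adjusted
# values equals its male sample mean exactly (females are shifted onto the
# male mean). Uncertainty calculations on adjusted data must therefore use
# male counts, not total counts (see run_size_battery()).

adjustment_group_of <- function(x, scheme) {
  switch(scheme,
    paper = ifelse(x$group == "hybrid", "hybrid_pooled", x$group),
    `per-bin` = ifelse(x$group == "hybrid",
                       paste0("hybrid_", format(x$ancestry, trim = TRUE)),
                       x$group),
    none = stop("scheme 'none' has no adjustment groups", call. = FALSE),
    stop("unknown adjustment scheme: ", scheme, call. = FALSE)
  )
}

#' Sex-adjustment offsets
#'
#' Computes, for every adjustment group and raw measurement, the offset to
#' be added to female values: the male mean minus the female mean over
#' non-missing values.
#'
#' @param x A phenotype tibble (raw, unadjusted values).
#' @param scheme `"paper"` (default): full-bred groups separately and all
#'   hybrids pooled; `"per-bin"`: each hybrid ancestry bin separately.
#' @param measurements Measurement codes to adjust; defaults to the raw
#'   measurements present. Composites should be recomputed after
#'   adjustment rather than adjusted directly.
#' @return A tibble with columns `adjustment_group`, `measurement`,
#'   `n_female`, `n_male`, `offset`. Errors if any adjustment group lacks
#'   one sex for a measurement (a silent zero offset would bias pooling).
#' @export
sex_offsets <- function(x, scheme = c("paper", "per-bin"), measurements = NULL) {
  scheme <- match.arg(scheme)
  x <- tibble::as_tibble(x)
  if (is.null(measurements)) measurements <- intersect(RAW_MEASUREMENTS, names(x))
  stopifnot(all(measurements %in% names(x)))
  x$adjustment_group <- adjustment_group_of(x, scheme)

  long <- tidyr::pivot_longer(
    x[, c("adjustment_group", "sex", measurements), drop = FALSE],
    cols = dplyr::all_of(measurements),
    names_to = "measurement", values_to = "value"
  ) %>% dplyr::filter(!is.na(value))

  out <- long %>%
    dplyr::group_by(adjustment_group, measurement) %>%
    dplyr::summarise(
      n_female = sum(sex == "F"),
      n_male = sum(sex == "M"),
      mean_f = mean(value[sex == "F"]),
      mean_m = mean(value[sex == "M"]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(offset = mean_m - mean_f) %>%
    dplyr::select(adjustment_group, measurement, n_female, n_male, offset)

  lacking <- out[out$n_female == 0L | out$n_male == 0L, ]
  if (nrow(lacking) > 0L) {
    stop("cannot compute sex offset: group(s) lacking one sex: ",
         paste(unique(paste0(lacking$adjustment_group, "/", lacking$measurement)),
               collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Apply sex adjustment
#'
#' Adds each adjustment group's male-female offset to every female value;
#' male values are untouched and missing values stay missing. Composites
#' present in `x` are recomputed from the adjusted components afterwards,
#' keeping the composite-consistency invariant exact. The result carries
#' attributes `sex_adjusted = TRUE`, `adjustment_scheme`, and
#' `offsets_estimated` (`TRUE` when offsets were computed from `x` itself).
#'
#' @param x A phenotype tibble.
#' @param offsets Offsets from [sex_offsets()]; computed from `x` when
#'   `NULL`.
#' @param scheme Adjustment scheme, see [sex_offsets()]. `"none"` returns
#'   `x` unchanged (flagged unadjusted).
#' @return The adjusted tibble.
#' @export
apply_sex_adjustment <- function(x, offsets = NULL,
                                 scheme = c("paper", "per-bin", "none")) {
  scheme <- match.arg(scheme)
  x <- tibble::as_tibble(x)
  if (identical(scheme, "none")) {
    attr(x, "sex_adjusted") <- FALSE
    attr(x, "adjustment_scheme") <- "none"
    return(x)
  }
  estimated <- is.null(offsets)
  if (estimated) offsets <- sex_offsets(x, scheme = scheme)
  measurements <- unique(offsets$measurement)
  stopifnot(all(measurements %in% names(x)))

  adj_group <- adjustment_group_of(x, scheme)
  female <- x$sex == "F"
  for (m in measurements) {
    key <- offsets$measurement == m
    off <- offsets$offset[key][match(adj_group, offsets$adjustment_group[key])]
    needs <- female & !is.na(x[[m]])
    if (any(needs & is.na(off))) {
      stop("no sex offset for group(s) ",
           paste(unique(adj_group[needs & is.na(off)]), collapse = ", "),
           " / measurement ", m, call. = FALSE)
    }
    x[[m]][needs] <- x[[m]][needs] + off[needs]
  }
  if (any(COMPOSITE_MEASUREMENTS %in% names(x))) x <- derive_composites(x)
  attr(x, "sex_adjusted") <- TRUE
  attr(x, "adjustment_scheme") <- scheme
  attr(x, "offsets_estimated") <- estimated
  x
}
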