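# Phenotype-table I/O and validation.
#
# The on-disk dialect is UTF-8 comma-separated text with a header row and
# columns: id, sex (F/M), chinese_ancestry (fraction in [0, 1]) or
# chinese_ancestry_pct (percent, auto-detected from the column name),
# weight_kg, crown_rump_mm, humerus_mm, radius_mm, femur_mm, tibia_mm.
# Empty cells are missing values. In memory a phenotype table is a tibble
# with columns id, sex, ancestry (fraction), group and one numeric column
# per measurement code.

#' Read a phenotype table
#'
#' Reads a delimited phenotype table, validates it, converts percent
#' ancestry to a fraction when the `chinese_ancestry_pct` column is used,
#' and assigns each animal to the `indian` (ancestry 0), `chinese`
#' (ancestry 1) or `hybrid` group.
#'
#' @param path Path to a CSV file in the package's input dialect.
#' @param strict If `TRUE` (default), rows with an ancestry outside
#'   \[0, 1\] or a non-positive measurement raise an error naming the
#'   offending row; if `FALSE`, such rows are dropped with a warning.
#' @return A validated phenotype tibble (columns `id`, `sex`, `ancestry`,
#'   `group`, then one column per raw measurement).
#' @export
read_phenotypes <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("id", "sex", names(INPUT_MEASUREMENT_COLUMNS))
  anc_col <- intersect(c("chinese_ancestry", "chinese_ancestry_pct"), names(raw))
  if (length(anc_col) == 0L) {
    stop("missing required column: chinese_ancestry (or chinese_ancestry_pct)",
         call. = FALSE)
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  anc_col <- anc_col[[1L]]
  ancestry <- suppressWarnings(as.numeric(raw[[anc_col]]))
  if (identical(anc_col, "chinese_ancestry_pct")) ancestry <- ancestry / 100

  x <- tibble::tibble(
    id = as.character(raw$id),
    sex = as.character(raw$sex),
    ancestry = ancestry
  )
  for (col in names(INPUT_MEASUREMENT_COLUMNS)) {
    x[[INPUT_MEASUREMENT_COLUMNS[[col]]]] <-
      suppressWarnings(as.numeric(ifelse(raw[[col]] == "", NA, raw[[col]])))
  }
  validate_phenotypes(x, strict = strict)
}

#' Validate a phenotype table
#'
#' Checks ids, sex codes, the ancestry range and measurement positivity,
#' and (re)assigns the ancestry `group` column.
#'
#' @param x A phenotype tibble (at least `id`, `sex`, `ancestry` plus
#'   measurement columns).
#' @param strict Error on invalid rows (`TRUE`) or drop them with a warning
#'   (`FALSE`).
#' @return The validated tibble with a `group` column.
#' @export
validate_phenotypes <- function(x, strict = TRUE) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  for (col in c("id", "sex", "ancestry")) {
    if (!col %in% names(x)) stop("missing required column: ", col, call. = FALSE)
  }
  meas <- intersect(RAW_MEASUREMENTS, names(x))
  if (length(meas) == 0L) stop("no measurement columns present", call. = FALSE)

  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) {
    stop("duplicate animal id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  }
  bad_sex <- !x$sex %in% c("F", "M")
  bad_anc <- is.na(x$ancestry) | x$ancestry < 0 | x$ancestry > 1
  bad_val <- rep(FALSE, nrow(x))
  for (m in meas) bad_val <- bad_val | (!is.na(x[[m]]) & x[[m]] <= 0)
  bad <- bad_sex | bad_anc | bad_val
  if (any(bad)) {
    msg <- paste0("invalid row(s): ", paste(x$id[bad], collapse = ", "),
                  " (sex must be F/M, ancestry in [0, 1], measurements > 0)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x$group <- ancestry_group(x$ancestry)
  core <- c("id", "sex", "ancestry", "group")
  x[, c(core, setdiff(names(x), core)), drop = FALSE]
}

#' Write a phenotype table
#'
#' Writes a phenotype tibble back to the input dialect (fractional
#' `chinese_ancestry`, unit-suffixed measurement columns, empty cells for
#' missing values). Derived composites are not written.
#'
#' @param x A phenotype tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  out <- tibble::tibble(id = x$id, sex = x$sex, chinese_ancestry = x$ancestry)
  for (col in names(INPUT_MEASUREMENT_COLUMNS)) {
    code <- INPUT_MEASUREMENT_COLUMNS[[col]]
    out[[col]] <- if (code %in% names(x)) x[[code]] else NA_real_
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Derive limb composites
#'
#' Adds (or recomputes) the forelimb (humerus + radius) and hindlimb
#' (femur + tibia) columns. A composite is missing whenever either of its
#' components is missing.
#'
#' @param x A phenotype tibble with the component columns present.
#' @return `x` with `forelimb` and `hindlimb` columns.
#' @export
#' @examples
#' derive_composites(tibble::tibble(
#'   id = "a", sex = "F", ancestry = 0, group = "indian",
#'   humerus = 165.91, radius = 160.65, femur = 196.14, tibia = 177.17
#' ))
derive_composites <- function(x) {
  x <- tibble::as_tibble(x)
  for (comp in names(COMPOSITE_PARTS)) {
    parts <- COMPOSITE_PARTS[[comp]]
    missing_parts <- setdiff(parts, names(x))
    if (length(missing_parts) > 0L) {
      stop("cannot derive ", comp, ": missing component column(s) ",
           paste(missing_parts, collapse = ", "), call. = FALSE)
    }
    x[[comp]] <- x[[parts[[1L]]]] + x[[parts[[2L]]]]
  }
  x
}

#' Summarise measurements by group
#'
#' Per group and measurement: the number of non-missing values, their mean,
#' and their standard deviation (n - 1 denominator; `NA` when n < 2).
#' Missing values are handled casewise per measurement, so different
#' measurements of the same group may have different n. Group-by-measurement
#' cells with no data are omitted with a warning.
#'
#' @param x A phenotype tibble.
#' @param measurements Measurement codes to summarise; defaults to all
#'   measurement columns present in `x`.
#' @param by Grouping column, by default `"group"`.
#' @return A long tibble with columns `group`, `measurement`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_groups <- function(x, measurements = NULL, by = "group") {
  x <- tibble::as_tibble(x)
  if (is.null(measurements)) measurements <- intersect(ALL_MEASUREMENTS, names(x))
  stopifnot(all(measurements %in% names(x)), by %in% names(x))
  long <- tidyr::pivot_longer(
    x[, c(by, measurements), drop = FALSE],
    cols = dplyr::all_of(measurements),
    names_to = "measurement", values_to = "value"
  )
  names(long)[names(long) == by] <- "group"
  full_grid <- nrow(unique(long[, c("group", "measurement")]))
  out <- long %>%
    dplyr::filter(!is.na(value)) %>%
    dplyr::group_by(group, measurement) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(value),
      sd = if (dplyr::n() >= 2L) stats::sd(value) else NA_real_,
      .groups = "drop"
    )
  if (nrow(out) < full_grid) {
    warning("group x measurement cell(s) with no data were omitted", call. = FALSE)
  }
  out$measurement <- factor(out$measurement, levels = ALL_MEASUREMENTS)
  out <- dplyr::arrange(out, measurement, group)
  out$measurement <- as.character(out$measurement)
  out
}
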