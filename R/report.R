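# End-to-end pipeline and report generation.
#
# analyze_phenotypes() chains the full analysis: validation, composite
# derivation, sex adjustment, group summaries (raw and adjusted),
# the size t-test battery, dispersion (V/V*) tables, the CV-difference
# battery, and the parity-line analysis with plot-ready point data.
# write_report_bundle() serialises every table as CSV, so two runs on the
# same input with the same options produce byte-identical output files.

#' Run the full size-and-variation analysis
#'
#' @param x A phenotype tibble (e.g. from [read_phenotypes()] or
#'   [simulate_colony()]`$records`).
#' @param adjustment Sex-adjustment scheme: `"paper"` (full-bred groups
#'   separately, hybrids pooled), `"per-bin"`, or `"none"`.
#' @param alpha Familywise one-tailed level for both test batteries.
#' @param battery_mode Comparison mode for [run_size_battery()].
#' @return A list of class `hybridsize_report`: `group_summaries_raw`,
#'   `group_summaries_adjusted`, `sex_offsets`, `battery`, `dispersion`,
#'   `cv_tests`, `parity_summary`, `parity_points`, and `options`.
#' @export
analyze_phenotypes <- function(x, adjustment = c("paper", "per-bin", "none"),
                               alpha = 0.05,
                               battery_mode = c("one-sample", "two-sample", "both")) {
  adjustment <- match.arg(adjustment)
  battery_mode <- match.arg(battery_mode)
  x <- validate_phenotypes(x, strict = TRUE)
  x <- derive_composites(x)

  offsets <- if (identical(adjustment, "none")) {
    tibble::tibble(adjustment_group = character(), measurement = character(),
                   n_female = integer(), n_male = integer(), offset = double())
  } else {
    sex_offsets(x, scheme = adjustment)
  }
  adj <- apply_sex_adjustment(x, scheme = adjustment)

  parity <- parity_analysis(adj)
  list2 <- list(
    group_summaries_raw = summarize_groups(x),
    group_summaries_adjusted = summarize_groups(adj),
    sex_offsets = offsets,
    battery = run_size_battery(adj, alpha = alpha, mode = battery_mode),
    dispersion = group_dispersion(adj),
    cv_tests = run_cv_battery(adj, alpha = alpha),
    parity_summary = parity$summary,
    parity_points = parity$results[, c("record_id", "measurement", "ancestry",
                                       "expected", "actual", "deviation")],
    options = list(adjustment = adjustment, alpha = alpha,
                   battery_mode = battery_mode)
  )
  structure(list2, class = "hybridsize_report")
}

#' Write a report bundle to disk
#'
#' Writes every table of an [analyze_phenotypes()] result as a CSV file
#' (full precision, deterministic bytes) plus an `options.json` echo.
#'
#' @param report A `hybridsize_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "hybridsize_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("group_summaries_raw", "group_summaries_adjusted", "sex_offsets",
              "battery", "dispersion", "cv_tests", "parity_summary",
              "parity_points")
  for (tb in tables) {
    readr::write_csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  jsonlite::write_json(report$options, file.path(dir, "options.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Simulate a colony and write it in the input dialect
#'
#' Writes the simulated dataset as a phenotype CSV plus a JSON sidecar
#' with the generating truth (true parental means, dominance, dimorphism,
#' loci and seed).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
simulate_to_files <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  colony <- simulate_colony(config)
  data_path <- file.path(dir, "phenotypes.csv")
  truth_path <- file.path(dir, "truth.json")
  write_phenotypes(colony$records, data_path)
  truth <- colony$truth
  jsonlite::write_json(
    list(means = truth$means, loci = truth$loci, seed = config$seed,
         realized_ancestry = config$realized_ancestry),
    truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(data = data_path, truth = truth_path))
}

#' @export
print.hybridsize_report <- function(x, ...) {
  cat("hybridsize analysis report\n")
  cat("  adjustment:", x$options$adjustment,
      "| battery mode:", x$options$battery_mode,
      "| alpha:", x$options$alpha, "\n")
  cat("  group means (adjusted):\n")
  gm <- tidyr::pivot_wider(x$group_summaries_adjusted[, c("group", "measurement", "mean")],
                           names_from = "group", values_from = "mean")
  print(as.data.frame(gm), digits = 5)
  cat("  significant battery rows:",
      sum(x$battery$significant), "of", nrow(x$battery), "\n")
  cat("  significant CV tests:",
      sum(x$cv_tests$significant), "of", nrow(x$cv_tests), "\n")
  invisible(x)
}
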