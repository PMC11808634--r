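# Measurement vocabulary shared across the package.
#
# Six raw measurements are read from input; the two limb composites are
# always derived, never read.

RAW_MEASUREMENTS <- c("weight", "crown_rump", "humerus", "radius", "femur", "tibia")
COMPOSITE_MEASUREMENTS <- c("forelimb", "hindlimb")
ALL_MEASUREMENTS <- c(RAW_MEASUREMENTS, COMPOSITE_MEASUREMENTS)

# composite -> components
COMPOSITE_PARTS <- list(
  forelimb = c("humerus", "radius"),
  hindlimb = c("femur", "tibia")
)

# input column -> internal measurement code
INPUT_MEASUREMENT_COLUMNS <- c(
  weight_kg     = "weight",
  crown_rump_mm = "crown_rump",
  humerus_mm    = "humerus",
  radius_mm     = "radius",
  femur_mm      = "femur",
  tibia_mm      = "tibia"
)

GROUP_LEVELS <- c("indian", "chinese", "hybrid")

#' Measurement dictionary
#'
#' Returns the data dictionary for the measurements handled by the package:
#' code, unit, whether the variable is a derived composite, and a short
#' anatomical definition. Weight is recorded in kilograms at examination;
#' all skeletal lengths are maximum lengths in millimetres taken between
#' anatomical extremes. The limb composites are sums of their two component
#' bones and are always recomputed from components, never read from input.
#'
#' @return A tibble with columns `code`, `unit`, `derived`, `definition`.
#' @export
#' @examples
#' measurement_dictionary()
measurement_dictionary <- function() {
  tibble::tibble(
    code = ALL_MEASUREMENTS,
    unit = c("kg", rep("mm", 7L)),
    derived = ALL_MEASUREMENTS %in% COMPOSITE_MEASUREMENTS,
    definition = c(
      "body weight at examination",
      "jointed axial length from the glabella to the notch below the third sacral vertebra's spinous process",
      "maximum humeral length, humeral head to medial trochlea",
      "maximum radial length, radial head to styloid process",
      "maximum femoral length, greater trochanter to lateral condyle",
      "maximum tibial length, proximal medial condyle margin to medial malleolus",
      "forelimb length, humerus plus radius",
      "hindlimb length, femur plus tibia"
    )
  )
}

#' Ancestry group of a record
#'
#' An animal is full-bred Indian when its Chinese-ancestry fraction is
#' exactly 0, full-bred Chinese when it is exactly 1, and hybrid otherwise.
#'
#' @param ancestry Numeric vector of Chinese-ancestry fractions in \[0, 1\].
#' @return Character vector with values `"indian"`, `"chinese"`, `"hybrid"`.
#' @export
ancestry_group <- function(ancestry) {
  stopifnot(is.numeric(ancestry))
  if (any(!is.na(ancestry) & (ancestry < 0 | ancestry > 1))) {
    stop("ancestry fractions must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    ancestry == 0 ~ "indian",
    ancestry == 1 ~ "chinese",
    TRUE ~ "hybrid"
  )
}
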