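# Fixtures are built in code at test time.

# Published group means of the four limb components, encoded as records so
# that derive_composites() + summarize_groups() must reproduce the printed
# composite means. Two identical rows per group keep every summary's n >= 2.
table3_component_fixture <- function() {
  rows <- list(
    list(group = "indian", ancestry = 0,
         humerus = 165.91, radius = 160.65, femur = 196.14, tibia = 177.17),
    list(group = "chinese", ancestry = 1,
         humerus = 180.61, radius = 176.49, femur = 209.96, tibia = 192.09)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(ancestry = r$ancestry, humerus = r$humerus, radius = r$radius,
               femur = r$femur, tibia = r$tibia)
  }))
  out <- out[rep(seq_len(nrow(out)), each = 2L), ]
  tibble::tibble(
    id = sprintf("fix%02d", seq_len(nrow(out))),
    sex = rep(c("F", "M"), times = nrow(out) / 2L),
    ancestry = out$ancestry,
    group = ancestry_group(out$ancestry),
    humerus = out$humerus, radius = out$radius,
    femur = out$femur, tibia = out$tibia
  )
}

# small generic phenotype table builder
make_phenotypes <- function(ancestry, sex = NULL, ...) {
  n <- length(ancestry)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  vals <- list(...)
  x <- tibble::tibble(
    id = sprintf("a%02d", seq_len(n)), sex = sex,
    ancestry = ancestry, group = ancestry_group(ancestry)
  )
  for (nm in names(vals)) x[[nm]] <- vals[[nm]]
  x
}

# a small, fast colony configuration for property tests
small_colony_config <- function(seed = 1L, ...) {
  sim_config(
    bin_counts = tibble::tibble(
      ancestry = c(0, 0.25, 0.5, 0.75, 1),
      n_female = c(8L, 10L, 10L, 10L, 8L),
      n_male = c(6L, 8L, 8L, 8L, 6L)
    ),
    seed = seed, ...
  )
}

write_temp_phenotypes <- function(x, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pheno.csv")
  write_phenotypes(x, path)
  path
}
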