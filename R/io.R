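#' Paths to packaged example tables
#'
#' The package ships two tiny stratified-population tables: `table1.csv`, a
#' population where physical activity confounds the hypertension–disease
#' relationship with a constant stratum relative risk of 1.5, and
#' `table1_em.csv`, the same population with the exposed low-activity risk
#' raised to 0.6 so that the causal relative risk varies across strata
#' (effect modification).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
pafbias_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pafbias")))
  }
  path <- system.file("extdata", file, package = "pafbias")
  if (!nzchar(path)) {
    paf_abort(sprintf("No packaged example file named '%s'.", file),
              "pafbias_error_io")
  }
  path
}

read_checked_csv <- function(path, col_types, what) {
  if (!file.exists(path)) {
    paf_abort(sprintf("%s file not found: %s", what, path), "pafbias_error_io")
  }
  # parsing problems are promoted to a structured error below, so readr's
  # advisory warning would be redundant
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE,
                    lazy = FALSE, show_col_types = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    paf_abort(
      sprintf("Malformed value in %s '%s' at row %d, column %d (expected %s, got %s).",
              what, path, p$row, p$col, p$expected, p$actual),
      "pafbias_error_io"
    )
  }
  df
}

#' Read / write stratified-population tables
#'
#' CSV with header `stratum,exposure,proportion,risk`, UTF-8, `.` decimal
#' separator — one row per (confounder stratum, exposure level) cell.
#'
#' @param path File path.
#' @param ... Passed to [stratified_population()] (e.g. `normalize`).
#' @return `read_population_csv()` returns a [stratified_population()];
#'   `write_population_csv()` returns `path` invisibly.
#' @export
read_population_csv <- function(path, ...) {
  df <- read_checked_csv(
    path,
    readr::cols(
      stratum = readr::col_character(),
      exposure = readr::col_integer(),
      proportion = readr::col_double(),
      risk = readr::col_double()
    ),
    "population table"
  )
  stratified_population(df, ...)
}

#' @rdname read_population_csv
#' @param pop A [stratified_population()].
#' @export
write_population_csv <- function(pop, path) {
  pop <- assert_population(pop)
  readr::write_csv(as_tibble(pop), path)
  invisible(path)
}

#' Read / write gridded exposure profiles
#'
#' CSV with header `x,density,rr_c` and optionally `rr_u`.
#'
#' @param path File path.
#' @param kind,mrev Passed to [exposure_profile()].
#' @return `read_profile_csv()` returns an [exposure_profile()].
#' @export
read_profile_csv <- function(path, kind = c("multicategory", "continuous"),
                             mrev = 0) {
  df <- read_checked_csv(
    path,
    readr::cols(.default = readr::col_double()),
    "exposure profile"
  )
  exposure_profile(df, kind = kind, mrev = mrev)
}

#' @rdname read_profile_csv
#' @param profile An [exposure_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  assert_profile(profile)
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}
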