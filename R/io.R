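# CSV dialects for the pipeline inputs (header required, UTF-8, dot
# decimal). All readers return tibbles and validate the schema loudly.

read_checked_csv <- function(path, cols, what, col_types) {
  if (!file.exists(path)) stop_input("%s file not found: %s", what, path)
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  check_columns(df, cols, what)
  df
}

#' Read a water-column profile table
#'
#' Columns: `date`, `depth_m`, `temp_c`, `do_mgl`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_profile_csv <- function(path) {
  read_checked_csv(path, c("date", "depth_m", "temp_c", "do_mgl"),
                   "profile", readr::cols(date = readr::col_date(),
                                          .default = readr::col_double()))
}

#' Read a phytoplankton count table
#'
#' Columns: `date`, `depth_m`, `taxon`, `shape`, `dim1_um`, `dim2_um`,
#' `cells_per_ml`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_phyto_csv <- function(path) {
  read_checked_csv(path,
                   c("date", "depth_m", "taxon", "shape", "dim1_um",
                     "dim2_um", "cells_per_ml"),
                   "phytoplankton",
                   readr::cols(date = readr::col_date(),
                               taxon = readr::col_character(),
                               shape = readr::col_character(),
                               .default = readr::col_double()))
}

#' Read an individual trait table
#'
#' Columns: `date`, `female_id`, `length_um`, `egg_major_um`,
#' `egg_minor_um`, `clutch_size`, `hatched`; empty cells mean "not
#' measured".
#' @param path CSV path.
#' @return Tibble.
#' @export
read_trait_csv <- function(path) {
  read_checked_csv(path,
                   c("date", "female_id", "length_um", "egg_major_um",
                     "egg_minor_um", "clutch_size", "hatched"),
                   "trait records",
                   readr::cols(date = readr::col_date(),
                               .default = readr::col_double()))
}

#' Read a multi-population size/temperature database
#'
#' Columns: `population_id`, `species`, `latitude_deg`, `habitat`,
#' `month`, `size_value`, `size_unit`, `temperature_c`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_population_csv <- function(path) {
  read_checked_csv(path,
                   c("population_id", "species", "latitude_deg", "habitat",
                     "month", "size_value", "size_unit", "temperature_c"),
                   "population database",
                   readr::cols(population_id = readr::col_character(),
                               species = readr::col_character(),
                               habitat = readr::col_character(),
                               size_unit = readr::col_character(),
                               .default = readr::col_double()))
}

#' Read a length-weight model registry
#'
#' Columns: `taxon`, `rank`, `a`, `b`, `length_unit`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_model_registry_csv <- function(path) {
  read_checked_csv(path, c("taxon", "rank", "a", "b", "length_unit"),
                   "model registry",
                   readr::cols(taxon = readr::col_character(),
                               rank = readr::col_character(),
                               length_unit = readr::col_character(),
                               .default = readr::col_double()))
}
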