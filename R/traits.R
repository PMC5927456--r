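#' Length-weight allometry for a calanoid copepod
#'
#' Dry weight from total length via the power law `W = 7.9e-7 * L^2.33`
#' (W in ug, L in um, total length excluding the furcal rami).
#'
#' @param length_um Numeric vector of total lengths (um), > 0.
#' @return Dry weights (ug).
#' @examples
#' dry_weight_from_length(821)  # ~4.88 ug
#' @export
dry_weight_from_length <- function(length_um) {
  if (any(length_um <= 0, na.rm = TRUE)) {
    stop_input("length must be positive (um)")
  }
  7.9e-7 * length_um^2.33
}

#' Wet weight from dry weight
#'
#' Wet weight is taken as dry weight times 10, putting zooplankton and
#' phytoplankton biomass on the same (wet) scale.
#'
#' @param dry_ug Dry weights (ug), >= 0.
#' @return Wet weights (ug).
#' @export
wet_weight_from_dry <- function(dry_ug) {
  if (any(dry_ug < 0, na.rm = TRUE)) stop_input("dry weight must be >= 0")
  10 * dry_ug
}

#' Egg wet weight from measured axes
#'
#' Egg volume from geometric formulae — a sphere `(pi/6) d^3` when only the
#' major axis is given, a prolate spheroid `(pi/6) a b^2` when both axes are
#' given — converted to wet weight assuming density 1 (1 um^3 = 1e-6 ug).
#'
#' @param major_um Major axis / diameter (um), > 0.
#' @param minor_um Minor axis (um), `NA` for spherical eggs; must not exceed
#'   `major_um`.
#' @return Egg wet weights (ug). Vectorised over both axes.
#' @examples
#' egg_wet_weight(130)        # ~1.15 ug (sphere)
#' egg_wet_weight(150, 100)   # ~0.785 ug (prolate spheroid)
#' @export
egg_wet_weight <- function(major_um, minor_um = NA_real_) {
  if (any(major_um <= 0, na.rm = TRUE) || any(minor_um <= 0, na.rm = TRUE)) {
    stop_input("egg axes must be positive (um)")
  }
  if (any(minor_um > major_um, na.rm = TRUE)) {
    stop_input("egg minor axis cannot exceed the major axis")
  }
  b <- ifelse(is.na(minor_um), major_um, minor_um)
  pi / 6 * major_um * b^2 * 1e-6
}

#' Reproductive effort of a single clutch
#'
#' Total biomass a female invests per clutch: `RE = EW x CS`, egg weight
#' times clutch size.
#'
#' @param egg_weight_ug Egg wet weight (ug), >= 0.
#' @param clutch_size Eggs per sac, >= 0.
#' @return RE (ug), vectorised.
#' @export
reproductive_effort <- function(egg_weight_ug, clutch_size) {
  if (any(egg_weight_ug < 0, na.rm = TRUE) ||
      any(clutch_size < 0, na.rm = TRUE)) {
    stop_input("egg weight and clutch size must be >= 0")
  }
  egg_weight_ug * clutch_size
}

#' Relative reproductive effort
#'
#' RE as a percentage of the female's own wet biomass:
#' `RRE = RE * 100 / female wet weight`, removing the effect of female size
#' from the investment measure.
#'
#' @param re_ug Reproductive effort (ug), >= 0.
#' @param female_wet_ug Female wet weight (ug), > 0.
#' @return RRE (%), vectorised.
#' @export
relative_reproductive_effort <- function(re_ug, female_wet_ug) {
  if (any(female_wet_ug <= 0, na.rm = TRUE)) {
    stop_input("female wet weight must be positive")
  }
  re_ug * 100 / female_wet_ug
}

#' Hatching outcome of a monitored clutch
#'
#' @param hatched Number of nauplii that emerged, `0 <= hatched <= clutch`.
#' @param clutch_size Eggs in the sac, >= 1.
#' @return Tibble with `hatch_fraction` (in \[0, 1\]) and
#'   `nauplii` (= `hatched`), one row per input clutch.
#' @export
hatch_outcomes <- function(hatched, clutch_size) {
  if (any(clutch_size < 1, na.rm = TRUE)) {
    stop_input("clutch size must be >= 1 for hatching assays")
  }
  if (any(hatched < 0 | hatched > clutch_size, na.rm = TRUE)) {
    stop_input("hatched count must lie in [0, clutch_size]")
  }
  tibble::tibble(hatch_fraction = hatched / clutch_size,
                 nauplii = hatched)
}

#' Derive per-individual traits from raw female records
#'
#' Adds every derived life-history trait to a table of individual records
#' *before* any averaging, so that monthly means are means of individual
#' values (e.g. `mean(EW x CS)`, not `mean(EW) x mean(CS)`).
#'
#' @param records Data frame with columns `date`, `length_um`, and
#'   optionally `egg_major_um`, `egg_minor_um`, `clutch_size`, `hatched`
#'   (`NA` = not measured).
#' @return The input as a tibble with added columns `month`,
#'   `dry_weight_ug`, `wet_weight_ug`, `egg_weight_ug`, `re_ug`, `rre_pct`,
#'   `hatch_fraction`, `nauplii` (NA where the inputs are absent).
#' @export
add_traits <- function(records) {
  check_columns(records, c("date", "length_um"), "records")
  if (nrow(records) == 0) stop_input("records is empty")
  rec <- tibble::as_tibble(records)
  for (col in c("egg_major_um", "egg_minor_um", "clutch_size", "hatched")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_real_
  }
  rec |>
    dplyr::mutate(
      month = month_key(.data$date),
      dry_weight_ug = dry_weight_from_length(.data$length_um),
      wet_weight_ug = wet_weight_from_dry(.data$dry_weight_ug),
      egg_weight_ug = ifelse(is.na(.data$egg_major_um), NA_real_,
                             egg_wet_weight(.data$egg_major_um,
                                            .data$egg_minor_um)),
      re_ug = ifelse(is.na(.data$egg_weight_ug) | is.na(.data$clutch_size),
                     NA_real_,
                     reproductive_effort(.data$egg_weight_ug,
                                         .data$clutch_size)),
      rre_pct = ifelse(is.na(.data$re_ug), NA_real_,
                       relative_reproductive_effort(.data$re_ug,
                                                    .data$wet_weight_ug)),
      hatch_fraction = ifelse(
        is.na(.data$hatched) | is.na(.data$clutch_size), NA_real_,
        .data$hatched / pmax(.data$clutch_size, 1)),
      nauplii = ifelse(is.na(.data$hatched), NA_real_, .data$hatched)
    )
}

# Traits summarised by monthly_trait_means, in reporting order.
trait_columns <- c("length_um", "dry_weight_ug", "wet_weight_ug",
                   "egg_weight_ug", "clutch_size", "re_ug", "rre_pct",
                   "hatch_fraction", "nauplii")

#' Monthly population means of life-history traits
#'
#' Per-individual derived traits are computed first (via [add_traits()],
#' unless already present) and then averaged within each sampling month.
#' Traits absent for an individual are simply left out of that trait's
#' monthly mean; months with no carrier of a trait are gaps, never
#' interpolated.
#'
#' @param records Data frame of individual records (see [add_traits()]).
#' @return Long tibble with one row per month x trait: `month`, `trait`,
#'   `mean`, `sd` (sample SD, `NA` when n = 1), `n`.
#' @export
monthly_trait_means <- function(records) {
  if (!all(trait_columns %in% names(records))) records <- add_traits(records)
  records |>
    dplyr::mutate(month = month_key(.data$date)) |>
    dplyr::select("month", dplyr::all_of(trait_columns)) |>
    tidyr::pivot_longer(-"month", names_to = "trait", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$month, .data$trait) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd_or_na(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(trait = factor(.data$trait, levels = trait_columns)) |>
    dplyr::arrange(.data$month, .data$trait) |>
    dplyr::mutate(trait = as.character(.data$trait))
}
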