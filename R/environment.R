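#' Detect the top of a sustained anoxic layer in a water-column profile
#'
#' In a warm-monomictic lake the hypolimnion turns anoxic during
#' stratification and the anoxic layer expands upward as a single block.
#' This function finds the shallowest depth at which dissolved oxygen drops
#' below `oxygen_threshold` *and stays below it down to the bottom of the
#' cast*. Transient oxygen dips that recover deeper in the column (sensor
#' spikes, microstructure) are not counted as an anoxic top.
#'
#' @param profile A data frame with one row per depth, holding at least
#'   `depth_m` (metres, >= 0) and `do_mgl` (dissolved oxygen, mg/L).
#'   Rows may be in any depth order.
#' @param oxygen_threshold Oxygen concentration (mg/L) below which water is
#'   considered anoxic. Default 1.0 mg/L.
#' @return The depth (metres) of the top of the anoxic layer, or `NA_real_`
#'   when the column is oxygenated to the bottom.
#' @examples
#' prof <- tibble::tibble(depth_m = 0:60,
#'                        do_mgl  = ifelse(0:60 >= 27, 0.2, 6))
#' detect_anoxic_top(prof)  # 27
#' @export
detect_anoxic_top <- function(profile, oxygen_threshold = 1.0) {
  check_columns(profile, c("depth_m", "do_mgl"), "profile")
  if (nrow(profile) == 0) stop_input("profile is empty")
  if (any(profile$depth_m < 0)) stop_input("profile has negative depths")
  prof <- dplyr::arrange(profile, .data$depth_m)
  anoxic <- prof$do_mgl < oxygen_threshold
  if (!anoxic[length(anoxic)]) return(NA_real_)
  # longest all-anoxic suffix of the cast
  first_ok_from_bottom <- max(which(!anoxic), 0L)
  prof$depth_m[first_ok_from_bottom + 1L]
}

#' Mean temperature of the oxygenated layer a migrating copepod occupies
#'
#' Vertically migrating copepods avoid both the immediate surface and the
#' anoxic hypolimnion, so the temperature they experience is summarised as
#' the arithmetic mean over the epilimnion plus metalimnion: all
#' measurements deeper than `surface_exclusion` metres and, when an anoxic
#' layer is present, shallower than its top.
#'
#' @param profile Data frame with `depth_m` and `temp_c` columns.
#' @param anoxic_top Depth (m) of the anoxic-layer top, or `NA`/`NULL` when
#'   the column is fully oxygenated (see [detect_anoxic_top()]).
#' @param surface_exclusion Depth (m); only samples strictly deeper are
#'   used. Default 1.
#' @return One-row tibble: `mean_temperature`, `sd_temperature` (sample SD,
#'   `NA` when a single depth remains), `n_depths`.
#' @export
oxygenated_layer_temperature <- function(profile, anoxic_top = NA,
                                         surface_exclusion = 1) {
  check_columns(profile, c("depth_m", "temp_c"), "profile")
  if (nrow(profile) == 0) stop_input("profile is empty")
  if (is.null(anoxic_top)) anoxic_top <- NA_real_
  keep <- profile$depth_m > surface_exclusion &
    (is.na(anoxic_top) | profile$depth_m < anoxic_top)
  temps <- profile$temp_c[keep]
  if (length(temps) == 0) {
    stop_degenerate("no profile samples remain after surface/anoxia exclusion")
  }
  tibble::tibble(mean_temperature = mean(temps),
                 sd_temperature   = sd_or_na(temps),
                 n_depths         = length(temps))
}

#' Summarise dated profile casts into monthly environmental conditions
#'
#' Applies [detect_anoxic_top()] and [oxygenated_layer_temperature()] to
#' each dated cast and, when phytoplankton counts are supplied, attaches
#' the mean biomass over the sampled depths of the same month.
#'
#' @param profiles Data frame with `date`, `depth_m`, `temp_c`, `do_mgl`.
#' @param phyto Optional data frame of phytoplankton counts with `date`,
#'   `depth_m`, `taxon`, `shape`, `dim1_um`, `dim2_um`, `cells_per_ml`
#'   (see [phyto_biomass()]); biomass is computed per depth then averaged.
#' @param oxygen_threshold,surface_exclusion Passed through to the
#'   per-cast functions.
#' @return Tibble with one row per month: `month`, `mean_temperature`,
#'   `sd_temperature`, `n_depths`, `anoxic_top_m`, and `phyto_biomass_mgl`
#'   when counts were given.
#' @export
summarise_environment <- function(profiles, phyto = NULL,
                                  oxygen_threshold = 1.0,
                                  surface_exclusion = 1) {
  check_columns(profiles, c("date", "depth_m", "temp_c", "do_mgl"), "profiles")
  env <- profiles |>
    dplyr::mutate(month = month_key(.data$date)) |>
    dplyr::group_by(.data$month) |>
    dplyr::group_modify(function(cast, key) {
      top <- detect_anoxic_top(cast, oxygen_threshold)
      out <- oxygenated_layer_temperature(cast, top, surface_exclusion)
      out$anoxic_top_m <- top
      out
    }) |>
    dplyr::ungroup()
  if (!is.null(phyto)) {
    check_columns(phyto, c("date", "depth_m"), "phyto")
    pb <- phyto |>
      dplyr::mutate(month = month_key(.data$date)) |>
      dplyr::group_by(.data$month, .data$depth_m) |>
      dplyr::summarise(biomass = phyto_biomass(dplyr::pick(dplyr::everything())),
                       .groups = "drop_last") |>
      dplyr::summarise(phyto_biomass_mgl = mean(.data$biomass), .groups = "drop")
    env <- dplyr::left_join(env, pb, by = "month")
  }
  dplyr::arrange(env, .data$month)
}

#' Cell biovolume from geometric shape
#'
#' Supported shapes: `"sphere"` (`dim1` = diameter), `"cylinder"`
#' (`dim1` = diameter, `dim2` = height) and `"prolate_spheroid"`
#' (`dim1` = major axis, `dim2` = minor axis). Dimensions in micrometres,
#' volume in cubic micrometres.
#'
#' @param shape Character vector of shape labels.
#' @param dim1,dim2 Shape dimensions (um); `dim2` may be `NA` for spheres.
#' @return Numeric vector of volumes (um^3).
#' @export
cell_volume <- function(shape, dim1, dim2 = NA_real_) {
  known <- c("sphere", "cylinder", "prolate_spheroid")
  bad <- setdiff(unique(shape), known)
  if (length(bad) > 0) {
    stop_input("unknown cell shape(s): %s (supported: %s)",
               paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  if (any(dim1 <= 0, na.rm = TRUE) ||
      any(dim2 <= 0, na.rm = TRUE)) {
    stop_input("cell dimensions must be positive")
  }
  needs2 <- shape %in% c("cylinder", "prolate_spheroid")
  if (any(needs2 & is.na(dim2))) {
    stop_input("dim2 is required for cylinder and prolate_spheroid shapes")
  }
  dplyr::case_when(
    shape == "sphere"           ~ pi / 6 * dim1^3,
    shape == "cylinder"         ~ pi / 4 * dim1^2 * dim2,
    shape == "prolate_spheroid" ~ pi / 6 * dim1 * dim2^2
  )
}

#' Total phytoplankton biomass from a count table
#'
#' Converts taxon counts to biomass assuming a cellular density of 1
#' (1 cm^3 = 1 g): each taxon contributes cell volume (um^3, from
#' [cell_volume()]) times its cell density, with the convention that
#' 1 um^3 per cell at 1 cell/mL contributes 1e-9 mg/L.
#'
#' @param counts Data frame with `shape`, `dim1_um`, `dim2_um`,
#'   `cells_per_ml` (a `taxon` column is conventional but not required).
#'   Zero rows give zero biomass.
#' @return Total biomass, mg/L (scalar).
#' @examples
#' phyto_biomass(tibble::tibble(
#'   taxon = "Cyclotella", shape = "sphere",
#'   dim1_um = 50, dim2_um = NA, cells_per_ml = 20000))  # ~1.31 mg/L
#' @export
phyto_biomass <- function(counts) {
  check_columns(counts, c("shape", "dim1_um", "cells_per_ml"), "counts")
  if (nrow(counts) == 0) return(0)
  if (any(counts$cells_per_ml < 0)) stop_input("cell densities must be >= 0")
  dim2 <- if ("dim2_um" %in% names(counts)) counts$dim2_um else NA_real_
  vols <- cell_volume(counts$shape, counts$dim1_um, dim2)
  sum(vols * counts$cells_per_ml * 1e-9)
}

#' Thermal covariates of a monthly temperature series
#'
#' From at least two monthly mean temperatures, computes the temperature of
#' the coldest month (`t_min`), of the warmest month (`t_max`), the
#' temperature annual range (`tar = t_max - t_min`) and the temperature
#' seasonality (`ts`, sample standard deviation of the monthly means).
#'
#' @param monthly_temps Numeric vector of monthly mean temperatures (degC),
#'   length >= 2.
#' @return One-row tibble: `t_min`, `t_max`, `tar`, `ts`, `n_months`.
#' @examples
#' thermal_covariates(c(14.9, 15.3, 16.8, 18.1))
#' @export
thermal_covariates <- function(monthly_temps) {
  monthly_temps <- monthly_temps[!is.na(monthly_temps)]
  if (length(monthly_temps) < 2) {
    stop_input("at least two monthly mean temperatures are required")
  }
  tibble::tibble(
    t_min    = min(monthly_temps),
    t_max    = max(monthly_temps),
    tar      = max(monthly_temps) - min(monthly_temps),
    ts       = sd(monthly_temps),
    n_months = length(monthly_temps)
  )
}
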