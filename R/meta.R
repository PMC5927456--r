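#' Exclude populations with too few monthly records
#'
#' Short series cannot support an annual PPI; populations with fewer than
#' `min_months` monthly records are set aside with a reason.
#'
#' @param populations Long tibble in the population-database schema:
#'   `population_id`, `species`, `latitude_deg`, `habitat`, `month`,
#'   `size_value`, `size_unit` (`"dry-ug"` or `"length-um"`),
#'   `temperature_c`.
#' @param min_months Minimum number of monthly records to keep a
#'   population (default 5; series of 3-4 months are the canonical
#'   exclusions).
#' @return List with `kept` (the filtered long tibble) and `excluded`
#'   (tibble `population_id`, `n_months`, `reason`).
#' @export
filter_short_series <- function(populations, min_months = 5) {
  check_columns(populations, c("population_id", "month"), "populations")
  if (min_months < 2) stop_input("min_months must be >= 2")
  counts <- populations |>
    dplyr::count(.data$population_id, name = "n_months")
  short <- dplyr::filter(counts, .data$n_months < min_months)
  list(
    kept = dplyr::filter(populations,
                         !.data$population_id %in% short$population_id),
    excluded = dplyr::mutate(
      short,
      reason = sprintf("only %d monthly records (< %d required)",
                       .data$n_months, min_months))
  )
}

#' Convert length series to dry biomass via a length-weight registry
#'
#' Rows already in dry micrograms pass through untouched. Length rows are
#' converted with the nearest available power-law model `W = a * L^b`,
#' resolved by taxonomic rank fallback: an entry matching the species, else
#' the genus (first word of the binomial), else a `family`/`order`/
#' `default` entry named in the optional `fallback` column of the
#' population table. The model actually used is recorded per population.
#'
#' @param populations Long population tibble (see [filter_short_series()]).
#' @param registry Tibble with columns `taxon`, `rank`, `a`, `b`,
#'   `length_unit` (only `"um"` supported).
#' @return The population tibble with `size_value` in dry ug,
#'   `size_unit = "dry-ug"`, and a `lw_model` column naming the taxon whose
#'   model was applied (`"native biomass"` for pass-through rows).
#' @export
bridge_length_to_biomass <- function(populations, registry) {
  check_columns(populations,
                c("population_id", "species", "size_value", "size_unit"),
                "populations")
  check_columns(registry, c("taxon", "rank", "a", "b", "length_unit"),
                "registry")
  if (any(!registry$length_unit %in% "um")) {
    stop_input("registry length units other than 'um' are not supported")
  }
  lookup <- function(species) {
    hit <- registry[registry$taxon == species, ]
    if (nrow(hit) == 0) {
      genus <- strsplit(species, "\\s+")[[1]][1]
      hit <- registry[registry$taxon == genus, ]
    }
    if (nrow(hit) == 0) hit <- registry[registry$rank == "default", ]
    if (nrow(hit) == 0) {
      stop_input("no length-weight model for taxon '%s' at any rank",
                 species)
    }
    hit[1, ]
  }
  populations |>
    dplyr::group_by(.data$population_id) |>
    dplyr::group_modify(function(d, key) {
      unit <- unique(d$size_unit)
      if (length(unit) != 1) {
        stop_input("population %s mixes size units", key$population_id)
      }
      if (unit == "dry-ug") {
        d$lw_model <- "native biomass"
      } else if (unit == "length-um") {
        m <- lookup(unique(d$species))
        d$size_value <- m$a * d$size_value^m$b
        d$size_unit <- "dry-ug"
        d$lw_model <- sprintf("%s (%s): a=%g, b=%g", m$taxon, m$rank, m$a,
                              m$b)
      } else {
        stop_input("unknown size unit '%s'", unit)
      }
      d
    }) |>
    dplyr::ungroup()
}

#' Classify latitudes into tropical vs extratropical zones
#'
#' @param abs_latitude Absolute latitude in degrees, in \[0, 90\].
#' @param tropic_cutoff Zone boundary (default 23.5, the Tropic line);
#'   tropical means strictly below the cutoff.
#' @return Character vector, `"tropical"` or `"extratropical"`.
#' @export
zone_classify <- function(abs_latitude, tropic_cutoff = 23.5) {
  if (any(abs_latitude < 0 | abs_latitude > 90, na.rm = TRUE)) {
    stop_input("absolute latitude must be in [0, 90]")
  }
  ifelse(abs_latitude < tropic_cutoff, "tropical", "extratropical")
}

#' Per-population plasticity and thermal covariates
#'
#' For each population: PPI of the monthly mean body-mass series
#' ([ppi()]), thermal covariates of the matching monthly temperatures
#' ([thermal_covariates()]), intensity (`PPI/TAR`) when TAR > 0, and the
#' latitudinal zone. Size and temperature must come from the same month;
#' months missing either are dropped from both computations.
#'
#' @param populations Long population tibble in dry-ug units (see
#'   [bridge_length_to_biomass()]).
#' @param tropic_cutoff Passed to [zone_classify()].
#' @return Tibble with one row per population: `population_id`, `species`,
#'   `abs_latitude`, `habitat`, `n_months`, `mean_size_ug`, `ppi_pct`,
#'   `t_min`, `t_max`, `tar`, `ts`, `intensity_pct_per_c`, `zone`,
#'   `lw_model` when present.
#' @export
population_ppi <- function(populations, tropic_cutoff = 23.5) {
  check_columns(populations,
                c("population_id", "species", "latitude_deg", "month",
                  "size_value", "size_unit", "temperature_c"),
                "populations")
  if (any(populations$size_unit != "dry-ug")) {
    stop_input("sizes must be in dry-ug; run bridge_length_to_biomass() first")
  }
  populations |>
    dplyr::filter(!is.na(.data$size_value), !is.na(.data$temperature_c)) |>
    dplyr::group_by(.data$population_id) |>
    dplyr::group_modify(function(d, key) {
      p <- ppi(d$size_value)
      th <- thermal_covariates(d$temperature_c)
      tibble::tibble(
        species = unique(d$species),
        abs_latitude = abs(unique(d$latitude_deg)),
        habitat = if ("habitat" %in% names(d)) unique(d$habitat)
                  else NA_character_,
        n_months = nrow(d),
        mean_size_ug = mean(d$size_value),
        ppi_pct = p$ppi_pct,
        t_min = th$t_min, t_max = th$t_max, tar = th$tar, ts = th$ts,
        intensity_pct_per_c = if (th$tar > 0) p$ppi_pct / th$tar
                              else NA_real_,
        lw_model = if ("lw_model" %in% names(d)) unique(d$lw_model)
                   else NA_character_
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(zone = zone_classify(.data$abs_latitude, tropic_cutoff))
}

#' Keep, per species, the population with the highest PPI
#'
#' Species-level analysis uses the most plastic population of each
#' species. Ties are broken deterministically: more monthly records first,
#' then the lexicographically smallest population id; tied winners are
#' flagged.
#'
#' @param rows Per-population tibble from [population_ppi()].
#' @return One row per species, with a logical `ppi_tie` column.
#' @export
species_maximum <- function(rows) {
  check_columns(rows, c("population_id", "species", "ppi_pct"), "rows")
  rows |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(ppi_tie = sum(.data$ppi_pct == max(.data$ppi_pct)) > 1) |>
    dplyr::arrange(dplyr::desc(.data$ppi_pct),
                   dplyr::desc(.data$n_months),
                   .data$population_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Latitudinal correlation and zone-comparison report
#'
#' The cross-population synthesis: Spearman correlations of PPI against
#' absolute latitude and each thermal covariate, of intensity against TAR,
#' Mann-Whitney comparisons of TAR, PPI and intensity between the tropical
#' and extratropical zones, and per-zone means.
#'
#' @param rows Per-population (or per-species, via [species_maximum()])
#'   tibble from [population_ppi()]; needs >= 5 rows.
#' @param level Label recorded in the report (`"population"` or
#'   `"species"`).
#' @return List of tibbles: `correlations` (`response`, `predictor`,
#'   `rho`, `p`, `n`), `zone_tests` (`variable`, `u`, `p`, `n_tropical`,
#'   `n_extratropical`; empty with a warning when a zone has no rows) and
#'   `zone_means` (`zone`, `variable`, `mean`, `sd`, `n`); plus `level`.
#' @export
latitudinal_report <- function(rows, level = "population") {
  check_columns(rows, c("ppi_pct", "abs_latitude", "t_min", "t_max", "tar",
                        "ts", "intensity_pct_per_c", "zone"), "rows")
  if (nrow(rows) < 5) stop_input("at least 5 populations are required")
  cor_cell <- function(y, x, response, predictor) {
    s <- spearman_rho(x, y)
    tibble::tibble(response = response, predictor = predictor,
                   rho = s$rho, p = s$p, n = s$n)
  }
  correlations <- dplyr::bind_rows(
    cor_cell(rows$ppi_pct, rows$abs_latitude, "ppi_pct", "abs_latitude"),
    cor_cell(rows$ppi_pct, rows$t_min, "ppi_pct", "t_min"),
    cor_cell(rows$ppi_pct, rows$t_max, "ppi_pct", "t_max"),
    cor_cell(rows$ppi_pct, rows$tar, "ppi_pct", "tar"),
    cor_cell(rows$ppi_pct, rows$ts, "ppi_pct", "ts"),
    cor_cell(rows$intensity_pct_per_c, rows$tar, "intensity_pct_per_c",
             "tar")
  )
  vars <- c("tar", "ppi_pct", "intensity_pct_per_c")
  trop <- dplyr::filter(rows, .data$zone == "tropical")
  extra <- dplyr::filter(rows, .data$zone == "extratropical")
  if (nrow(trop) == 0 || nrow(extra) == 0) {
    warn("a latitudinal zone is empty; zone comparisons skipped")
    zone_tests <- tibble::tibble(variable = character(), u = numeric(),
                                 p = numeric(), n_tropical = integer(),
                                 n_extratropical = integer())
  } else {
    zone_tests <- purrr::map_dfr(vars, function(v) {
      mw <- mann_whitney_u(trop[[v]], extra[[v]])
      tibble::tibble(variable = v, u = mw$u, p = mw$p,
                     n_tropical = mw$n_a, n_extratropical = mw$n_b)
    })
  }
  zone_means <- rows |>
    dplyr::select("zone", dplyr::all_of(vars)) |>
    tidyr::pivot_longer(-"zone", names_to = "variable",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$zone, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd_or_na(.data$value),
                     n = dplyr::n(), .groups = "drop")
  list(level = level, correlations = correlations,
       zone_tests = zone_tests, zone_means = zone_means)
}
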