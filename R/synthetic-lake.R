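# Synthetic tropical monomictic lake-year generator. Defaults emulate the
# seasonal structure of a warm-monomictic crater lake: a small-amplitude
# temperature cycle (minimum in January, peak in September), a roughly
# 17-fold phytoplankton fluctuation (minimum in March, maximum in
# November), an anoxic hypolimnion that appears in April, expands upward
# until September and contracts again, and life-history traits whose
# reaction norms are known by construction (female length and egg size
# decreasing in temperature, clutch size increasing in food).

#' Configuration for the synthetic lake year
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 13 monthly samplings (January to January), oxygenated-layer
#' temperatures cycling between 14.9 and 18.1 degC, phytoplankton biomass
#' cycling between 0.2 and 3.5 mg/L, 50 ovigerous females per month, and
#' generating reaction-norm coefficients chosen so the noise-free monthly
#' trait means span the realistic ranges for a small diaptomid
#' (length ~821-1025 um, clutch ~2.1-9.3 eggs, egg diameter ~89-131 um).
#'
#' @param months Number of monthly samplings starting in January
#'   (default 13).
#' @param t_min_gen,t_max_gen Generating temperature extremes (degC).
#' @param phyto_min,phyto_max Generating phytoplankton biomass extremes
#'   (mg/L).
#' @param anoxia_start,anoxia_peak Months (1-12) when the anoxic layer
#'   first appears and when it is widest; `anoxia_depths` gives the
#'   corresponding top depths (m), interpolated linearly in between.
#' @param max_depth Cast depth (m).
#' @param length_intercept_um,length_slope_t Female length model:
#'   `L = intercept + slope * T + noise` (um, um/degC).
#' @param length_noise_sd Individual length SD (um).
#' @param egg_intercept_um,egg_slope_t,egg_noise_sd Egg diameter model in
#'   temperature (um, um/degC, um); eggs are spherical.
#' @param clutch_intercept_log,clutch_slope_logp Clutch-size model:
#'   Poisson with `log(mean) = intercept + slope * log(phyto)`.
#' @param hatch_prob Per-egg hatching probability, or `NULL` to use a
#'   logistic link on clutch size (`plogis(hatch_logit_intercept +
#'   hatch_logit_slope * clutch)`).
#' @param hatch_logit_intercept,hatch_logit_slope Coefficients of the
#'   optional clutch-linked hatching model.
#' @param n_females_per_month Ovigerous females measured per month.
#' @param temp_profile_noise_sd Within-layer temperature SD across depths
#'   (degC).
#' @return A `lake_sim_config` list, validated.
#' @export
lake_sim_config <- function(months = 13,
                            t_min_gen = 14.9, t_max_gen = 18.1,
                            phyto_min = 0.2, phyto_max = 3.5,
                            anoxia_start = 4, anoxia_peak = 9,
                            anoxia_depths = c(57, 27),
                            max_depth = 60,
                            length_intercept_um = 1975,
                            length_slope_t = -63.75,
                            length_noise_sd = 40,
                            egg_intercept_um = 324.5,
                            egg_slope_t = -13,
                            egg_noise_sd = 5,
                            clutch_intercept_log = 1.579,
                            clutch_slope_logp = 0.520,
                            hatch_prob = 0.9,
                            hatch_logit_intercept = 0.5,
                            hatch_logit_slope = 0.35,
                            n_females_per_month = 50,
                            temp_profile_noise_sd = 0.1) {
  cfg <- as.list(environment())
  if (cfg$t_max_gen < cfg$t_min_gen) {
    stop_input("t_max_gen must be >= t_min_gen")
  }
  if (cfg$phyto_min <= 0 || cfg$phyto_max < cfg$phyto_min) {
    stop_input("phytoplankton extremes must be positive and ordered")
  }
  if (cfg$n_females_per_month < 1) stop_input("need at least one female")
  if (cfg$length_noise_sd < 0 || cfg$egg_noise_sd < 0 ||
      cfg$temp_profile_noise_sd < 0) {
    stop_input("noise SDs must be >= 0")
  }
  structure(cfg, class = "lake_sim_config")
}

# Piecewise-cosine annual cycle: minimum at month `low`, maximum at month
# `high`, for calendar months 1..12 (wrapped for longer series).
seasonal_cycle <- function(month_index, low, high, vmin, vmax) {
  m <- ((month_index - 1) %% 12) + 1
  up_span <- (high - low) %% 12
  phase <- ((m - low) %% 12)
  frac <- ifelse(phase <= up_span,
                 phase / up_span,
                 1 - (phase - up_span) / (12 - up_span))
  vmin + (vmax - vmin) * (1 - cos(pi * frac)) / 2
}

lake_month_schedule <- function(config) {
  m <- seq_len(config$months)
  cal <- ((m - 1) %% 12) + 1
  temp <- seasonal_cycle(m, low = 1, high = config$anoxia_peak,
                         vmin = config$t_min_gen, vmax = config$t_max_gen)
  phyto <- seasonal_cycle(m, low = 3, high = 11,
                          vmin = config$phyto_min, vmax = config$phyto_max)
  # anoxic top: appears at anoxia_start, shallowest at anoxia_peak, then
  # deepens again; absent during the winter mixing
  a0 <- config$anoxia_depths[1]; a1 <- config$anoxia_depths[2]
  anoxic <- rep(NA_real_, length(m))
  rising <- cal >= config$anoxia_start & cal <= config$anoxia_peak
  anoxic[rising] <- a0 + (a1 - a0) *
    (cal[rising] - config$anoxia_start) /
    (config$anoxia_peak - config$anoxia_start)
  falling <- cal > config$anoxia_peak
  anoxic[falling] <- a1 + (a0 - a1) *
    (cal[falling] - config$anoxia_peak) / (12 - config$anoxia_peak)
  tibble::tibble(
    month_index = m,
    month = sprintf("%04d-%02d", 2008 + (m - 1) %/% 12, cal),
    temperature = temp, phyto = phyto,
    anoxic_top = round(anoxic))
}

#' Simulate one lake year: profiles, phytoplankton counts, female records
#'
#' Generates the three raw tables the lake pipeline consumes, with the
#' generating monthly conditions and noise-free trait expectations as a
#' ground-truth table. Deterministic under `seed`.
#'
#' @param config A [lake_sim_config()].
#' @param seed Integer seed.
#' @return List with tibbles `profiles` (`date`, `depth_m`, `temp_c`,
#'   `do_mgl`), `phyto` (`date`, `depth_m`, `taxon`, `shape`, `dim1_um`,
#'   `dim2_um`, `cells_per_ml`), `records` (`date`, `female_id`,
#'   `length_um`, `egg_major_um`, `egg_minor_um`, `clutch_size`,
#'   `hatched`) and `truth` (monthly generating values).
#' @export
simulate_lake_year <- function(config = lake_sim_config(), seed = 1) {
  if (!inherits(config, "lake_sim_config")) {
    config <- do.call(lake_sim_config, config)
  }
  set.seed(seed)
  sched <- lake_month_schedule(config)
  dates <- as.Date(paste0(sched$month, "-15"))

  profiles <- purrr::pmap_dfr(
    list(dates, sched$temperature, sched$anoxic_top),
    function(date, t_month, anoxic_top, depth = config$max_depth) {
      depths <- 0:depth
      oxic <- is.na(anoxic_top) | depths < anoxic_top
      temp <- t_month + rnorm(length(depths), 0,
                              config$temp_profile_noise_sd)
      # anoxic hypolimnion stays near the winter minimum
      temp[!oxic] <- config$t_min_gen - 0.2 +
        rnorm(sum(!oxic), 0, config$temp_profile_noise_sd)
      tibble::tibble(date = date, depth_m = depths, temp_c = temp,
                     do_mgl = ifelse(oxic, 6, 0.2))
    })

  # dominant centric diatom: spheres of 50 um diameter whose density is
  # back-calculated so phyto_biomass() recovers the scheduled biomass
  vol50 <- pi / 6 * 50^3
  phyto <- purrr::map2_dfr(dates, sched$phyto, function(date, biomass) {
    tibble::tibble(date = date, depth_m = c(10, 25),
                   taxon = "Cyclotella_synthetic", shape = "sphere",
                   dim1_um = 50, dim2_um = NA_real_,
                   cells_per_ml = biomass / (vol50 * 1e-9))
  })

  n <- config$n_females_per_month
  records <- purrr::pmap_dfr(
    list(dates, sched$temperature, sched$phyto),
    function(date, t_month, p_month) {
      len <- config$length_intercept_um + config$length_slope_t * t_month +
        rnorm(n, 0, config$length_noise_sd)
      egg <- config$egg_intercept_um + config$egg_slope_t * t_month +
        rnorm(n, 0, config$egg_noise_sd)
      lambda <- exp(config$clutch_intercept_log +
                      config$clutch_slope_logp * log(p_month))
      clutch <- pmax(1L, rpois(n, lambda))
      p_hatch <- if (is.null(config$hatch_prob)) {
        stats::plogis(config$hatch_logit_intercept +
                        config$hatch_logit_slope * clutch)
      } else rep(config$hatch_prob, n)
      tibble::tibble(
        date = date, female_id = seq_len(n),
        length_um = pmax(len, 1),
        egg_major_um = pmax(egg, 1), egg_minor_um = NA_real_,
        clutch_size = clutch,
        hatched = rbinom(n, clutch, p_hatch))
    })

  truth <- sched |>
    dplyr::mutate(
      expected_length_um = config$length_intercept_um +
        config$length_slope_t * .data$temperature,
      expected_egg_um = config$egg_intercept_um +
        config$egg_slope_t * .data$temperature,
      expected_clutch = exp(config$clutch_intercept_log +
                              config$clutch_slope_logp * log(.data$phyto)))
  list(profiles = profiles, phyto = phyto, records = records,
       truth = truth, config = config, seed = seed)
}
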