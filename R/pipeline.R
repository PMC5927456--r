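#' Run the lake stage end-to-end
#'
#' Profiles + phytoplankton + individual records in; monthly environment,
#' monthly trait means, the trait x environment reaction-norm grid, and
#' the plasticity amplitude table out.
#'
#' @param profiles,phyto,records Input tibbles (see [read_profile_csv()],
#'   [read_phyto_csv()], [read_trait_csv()]).
#' @param alpha Significance level for the plasticity calls.
#' @param oxygen_threshold,surface_exclusion Passed to
#'   [summarise_environment()].
#' @return List of tibbles: `environment`, `trait_means`,
#'   `reaction_norms`, `plasticity` (PPI per trait with intensity over the
#'   season's TAR), `thermal` (the one-row [thermal_covariates()] summary).
#' @export
analyse_lake <- function(profiles, phyto, records, alpha = 0.05,
                         oxygen_threshold = 1.0, surface_exclusion = 1) {
  env <- summarise_environment(profiles, phyto,
                               oxygen_threshold = oxygen_threshold,
                               surface_exclusion = surface_exclusion)
  tm <- monthly_trait_means(records)
  norms <- reaction_norm_grid(
    tm, dplyr::select(env, "month", "mean_temperature",
                      "phyto_biomass_mgl"),
    alpha = alpha)
  thermal <- thermal_covariates(env$mean_temperature)
  plast <- plasticity_table(tm, tar_c = thermal$tar)
  list(environment = env, trait_means = tm, reaction_norms = norms,
       plasticity = plast, thermal = thermal)
}

#' Run the latitudinal meta-analysis stage end-to-end
#'
#' Filters short series, bridges lengths to biomass when a registry is
#' given, computes per-population PPI and thermal covariates, and produces
#' the population-level and species-maximum reports.
#'
#' @param populations Long population tibble.
#' @param registry Optional length-weight model registry (required when
#'   any series is in length units).
#' @param min_months Passed to [filter_short_series()].
#' @param tropic_cutoff Passed to [zone_classify()].
#' @return List: `rows` (per-population [population_ppi()] table),
#'   `species_rows`, `excluded`, `population_report`, `species_report`.
#' @export
analyse_meta <- function(populations, registry = NULL, min_months = 5,
                         tropic_cutoff = 23.5) {
  flt <- filter_short_series(populations, min_months)
  kept <- flt$kept
  if (any(kept$size_unit != "dry-ug")) {
    if (is.null(registry)) {
      stop_input("length series present but no model registry supplied")
    }
    kept <- bridge_length_to_biomass(kept, registry)
  }
  rows <- population_ppi(kept, tropic_cutoff)
  sp <- species_maximum(rows)
  list(rows = rows, species_rows = sp, excluded = flt$excluded,
       population_report = latitudinal_report(rows, "population"),
       species_report = latitudinal_report(sp, "species"))
}

#' Run the whole pipeline from a configuration
#'
#' Executes environment -> traits -> plasticity -> meta-analysis (and the
#' contrast stage when a tree is supplied) and writes every result table
#' as CSV under `config$out_dir`, together with a JSON log of the seed,
#' package version and decisions. The configuration is a named list (or a
#' YAML file path) with either file inputs (`profiles`, `phyto`,
#' `records`, `populations`, optional `registry`, optional `tree`) or a
#' `synthetic = TRUE` flag to generate them with the default simulators.
#'
#' @param config Named list or YAML path. Recognised fields: `out_dir`
#'   (required), `seed` (default 1), `synthetic`, the input paths above,
#'   `alpha`, `min_months`, `tropic_cutoff`.
#' @return (Invisibly) the list of results that were written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("yaml package required to read a config file")
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop_input("config must name an out_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  synthetic <- isTRUE(config$synthetic)
  if (!synthetic) {
    needed <- c("profiles", "phyto", "records", "populations")
    missing <- needed[!vapply(needed, function(f)
      !is.null(config[[f]]) && file.exists(config[[f]]), logical(1))]
    if (length(missing) > 0) {
      stop_input("config lacks input file(s) %s and no synthetic block",
                 paste(missing, collapse = ", "))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (synthetic) {
    lake <- simulate_lake_year(seed = seed)
    profiles <- lake$profiles; phyto <- lake$phyto
    records <- lake$records
    db <- simulate_population_database(seed = seed + 1)
    populations <- db$populations
    readr::write_csv(db$truth, file.path(config$out_dir,
                                         "ground_truth.csv"))
  } else {
    profiles <- read_profile_csv(config$profiles)
    phyto <- read_phyto_csv(config$phyto)
    records <- read_trait_csv(config$records)
    populations <- read_population_csv(config$populations)
  }
  registry <- if (!is.null(config$registry)) {
    read_model_registry_csv(config$registry)
  }
  alpha <- config$alpha %||% 0.05
  lake_res <- analyse_lake(profiles, phyto, records, alpha = alpha)
  meta_res <- analyse_meta(populations, registry,
                           min_months = config$min_months %||% 5,
                           tropic_cutoff = config$tropic_cutoff %||% 23.5)

  out <- list(
    monthly_environment = lake_res$environment,
    monthly_traits = lake_res$trait_means,
    reaction_norms = lake_res$reaction_norms,
    plasticity_indices = lake_res$plasticity,
    meta_rows = meta_res$rows,
    meta_species_rows = meta_res$species_rows,
    meta_excluded = meta_res$excluded,
    meta_correlations_population = meta_res$population_report$correlations,
    meta_correlations_species = meta_res$species_report$correlations,
    meta_zone_means = meta_res$population_report$zone_means,
    meta_zone_tests = meta_res$population_report$zone_tests
  )

  if (!is.null(config$tree)) {
    tree <- assign_convention_lengths(read_phylo(config$tree))
    sp <- meta_res$species_rows
    keep <- sp$species %in% tree$tip.label
    x <- stats::setNames(sp$tar[keep], sp$species[keep])
    y <- stats::setNames(sp$ppi_pct[keep], sp$species[keep])
    tree <- ape::keep.tip(tree, names(x))
    contr <- pic_contrasts(tree, x, y)
    out$contrasts <- contr
    fit <- origin_regression(contr)
    out$contrast_regression <- glance(fit)
  }

  for (nm in names(out)) {
    readr::write_csv(out[[nm]], file.path(config$out_dir,
                                          paste0(nm, ".csv")))
  }
  log <- list(seed = seed,
              package_version = as.character(utils::packageVersion("plastinorm")),
              r_version = R.version.string,
              synthetic = synthetic,
              alpha = alpha,
              decisions = c(
                "oxygen threshold for anoxia: 1.0 mg/L, sustained to cast bottom",
                "surface exclusion: depths > 1 m",
                "sample (n-1) SD throughout",
                "no multiple-testing correction across the trait x environment grid"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(log, file.path(config$out_dir, "log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
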